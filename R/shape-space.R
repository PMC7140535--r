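# Bit-string shape space: receptors, ligands, MHC molecules and peptides are
# binary strings of a common length l; affinity is complementarity measured by
# the Hamming distance (number of mismatching bits), so a perfect complement
# has affinity l.  Strings are stored as non-negative integers < 2^l.

.pkg <- new.env(parent = emptyenv())

# 16-bit popcount lookup, built lazily (65536 ints, ~256 KB in memory only).
.popcount16 <- function() {
  if (is.null(.pkg$pc16)) {
    v <- 0:65535L
    pc <- integer(65536L)
    for (b in 0:15) pc <- pc + bitwAnd(bitwShiftR(v, b), 1L)
    .pkg$pc16 <- pc
  }
  .pkg$pc16
}

popcount <- function(x) {
  pc <- .popcount16()
  lo <- bitwAnd(x, 65535L)
  hi <- bitwShiftR(x, 16L)
  pc[lo + 1L] + pc[hi + 1L]
}

#' Repertoire and binding parameters
#'
#' Parameters of the bit-string shape space: the receptor string length `l`
#' (the potential repertoire has size `2^l`), the minimal mismatch allowance
#' `m0` used by thymic selection (positive-selection threshold `l/2 - m0`),
#' the fixed probability `p_aspecific` used for aspecific (non-receptor)
#' interactions, and the base of the geometric binding-probability law.
#'
#' @param bitstring_length Even positive integer `l` (bits). Default 16.
#' @param min_mismatch_m0 Non-negative integer `m0 <= l/2`. Default 2.
#' @param aspecific_probability Probability in `[0,1]` used for aspecific
#'   Bernoulli interactions. Default 0.1.
#' @param affinity_base Base in `(0,1)` of the binding law
#'   `affinity_base^(l - affinity)`. Default 0.7.
#' @return An object of class `repertoire_params`.
#' @examples
#' p <- repertoire_params()
#' bind_probability(16, p)  # perfect complement -> 1
#' @export
repertoire_params <- function(bitstring_length = 16L, min_mismatch_m0 = 2L,
                              aspecific_probability = 0.1,
                              affinity_base = 0.7) {
  l <- as.integer(bitstring_length)
  m0 <- as.integer(min_mismatch_m0)
  if (length(l) != 1L || is.na(l) || l <= 0L || l %% 2L != 0L)
    stop("bitstring_length must be a positive even integer")
  if (l > 30L) stop("bitstring_length above 30 bits is not supported")
  if (m0 < 0L || m0 > l %/% 2L)
    stop("min_mismatch_m0 must satisfy 0 <= m0 <= l/2")
  if (aspecific_probability < 0 || aspecific_probability > 1)
    stop("aspecific_probability must lie in [0,1]")
  if (affinity_base <= 0 || affinity_base >= 1)
    stop("affinity_base must lie strictly inside (0,1)")
  structure(list(bitstring_length = l, min_mismatch_m0 = m0,
                 aspecific_probability = aspecific_probability,
                 affinity_base = affinity_base),
            class = "repertoire_params")
}

#' @export
print.repertoire_params <- function(x, ...) {
  cat(sprintf("repertoire_params: l=%d (2^l=%s), m0=%d, p'=%.3g, base=%.3g\n",
              x$bitstring_length, format(2^x$bitstring_length),
              x$min_mismatch_m0, x$aspecific_probability, x$affinity_base))
  invisible(x)
}

# Coerce a bit string given either as a "0101..." character scalar or as an
# integer code; returns the integer code and records the length.
as_bitstring <- function(x, length = NULL) {
  if (is.character(x)) {
    bits <- strsplit(x, "")[[1L]]
    if (!all(bits %in% c("0", "1"))) stop("bit strings may contain only 0/1")
    n <- length(bits)
    code <- 0L
    for (b in bits) code <- bitwShiftL(code, 1L) + (b == "1")
    structure(as.integer(code), bits = n)
  } else {
    x <- as.integer(x)
    if (is.null(length)) stop("integer bit strings need an explicit length")
    if (any(x < 0L) || any(x >= 2^length)) stop("bit code out of range for length")
    structure(x, bits = as.integer(length))
  }
}

bitstring_to_chr <- function(code, length) {
  vapply(code, function(z)
    paste(rev(as.integer(intToBits(z))[seq_len(length)]), collapse = ""), "")
}

#' Hamming affinity between two bit strings
#'
#' Counts the mismatching bits between two equal-length binary strings.  Under
#' the complementarity convention used throughout the simulator this count
#' *is* the affinity: a perfect complement mismatches at every position and
#' has maximal affinity `l`.
#'
#' @param a,b Bit strings, either `"0101"`-style character scalars/vectors or
#'   integer codes (then `length` is required).
#' @param length String length in bits when `a`/`b` are integer codes.
#' @return Integer vector of mismatch counts.
#' @examples
#' hamming_affinity("0000", "1111")  # 4: exact complement
#' hamming_affinity("10110010", "10010110")  # 2
#' @export
hamming_affinity <- function(a, b, length = NULL) {
  if (is.character(a)) {
    la <- nchar(a); lb <- nchar(b)
    if (any(la != lb)) stop("bit strings must have equal length")
    ca <- vapply(a, function(s) as.integer(as_bitstring(s)), 0L)
    cb <- vapply(b, function(s) as.integer(as_bitstring(s)), 0L)
    popcount(bitwXor(ca, cb))
  } else {
    if (is.null(length)) stop("integer bit strings need an explicit length")
    popcount(bitwXor(as.integer(a), as.integer(b)))
  }
}

#' Binding probability from affinity
#'
#' The Bernoulli success probability of a specific receptor/ligand
#' interaction: zero below the activation threshold `l/2`, and
#' `affinity_base^(l - affinity)` at or above it, reaching 1 only at a
#' perfect complement.  Vectorised over `affinity`.
#'
#' @param affinity Integer affinity (mismatching bits), `0 <= affinity <= l`.
#' @param params A [repertoire_params()] object.
#' @return Probability vector.
#' @examples
#' p <- repertoire_params(bitstring_length = 8, affinity_base = 0.5)
#' bind_probability(6, p)  # 0.5^2 = 0.25
#' @export
bind_probability <- function(affinity, params) {
  l <- params$bitstring_length
  if (any(affinity < 0L | affinity > l)) stop("affinity out of [0, l]")
  ifelse(affinity < l / 2, 0, params$affinity_base^(l - affinity))
}

#' Generate a random receptor repertoire
#'
#' Draws `n_cells` resting cells whose receptors are sampled uniformly from
#' the `2^l` shape space.  The same seed reproduces the same repertoire
#' bit-for-bit; different seeds give different repertoires with overwhelming
#' probability.
#'
#' @param n_cells Number of cells (>= 0).
#' @param cell_type Catalogue entry name (e.g. `"B"`, `"TH"`, `"TC"`).
#' @param params A [repertoire_params()] object.
#' @param rng_seed Integer seed; `NULL` uses the current RNG stream.
#' @return A data frame with columns `cell_type`, `state`, `receptor`
#'   (integer shape-space code) and `division_count`.
#' @export
generate_repertoire <- function(n_cells, cell_type = "TH",
                                params = repertoire_params(),
                                rng_seed = NULL) {
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells < 0L) stop("n_cells must be >= 0")
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  rec <- draw_receptors(n_cells, params$bitstring_length)
  data.frame(cell_type = rep(cell_type, n_cells),
             state = rep("resting", n_cells),
             receptor = rec,
             division_count = rep(0L, n_cells))
}

# Uniform draw of n integer codes from {0, ..., 2^l - 1}.
draw_receptors <- function(n, l) {
  if (n == 0L) return(integer(0))
  # sample.int is exact and fast for 2^l <= 2^30
  sample.int(2^l, n, replace = TRUE) - 1L
}

#' Entity catalogue (initial counts and half-lives)
#'
#' Reads the bundled entity table: one row per cellular or molecular entity
#' with its initial count per microliter (equivalently per cubic millimeter)
#' and its half-life.  The bundled default transcribes the literature-derived
#' values used by the simulator (e.g. TH 876/uL with a 3.3-day half-life;
#' generic chemokine 3.0 h).
#'
#' @param path CSV path; default the bundled table.
#' @return A data frame with columns `entity`, `initial_count_per_uL`,
#'   `half_life_value`, `half_life_unit`, plus `half_life_days` (derived).
#' @export
entity_table <- function(path = system.file("extdata", "entity_table.csv",
                                            package = "mssim")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("entity", "initial_count_per_uL", "half_life_value",
            "half_life_unit")
  if (!all(need %in% names(tab)))
    stop("entity table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$entity)) stop("duplicate entity rows")
  if (any(tab$half_life_value <= 0)) stop("half-lives must be positive")
  if (any(tab$initial_count_per_uL < 0)) stop("initial counts must be >= 0")
  tab$half_life_days <- ifelse(tab$half_life_unit == "hours",
                               tab$half_life_value / 24,
                               tab$half_life_value)
  tab
}

#' MHC and self-peptide context
#'
#' The binary-string genetic background of a simulated subject: MHC class I
#' and class II allele strings and the set of self peptides (including the
#' myelin basic protein peptide).  An MHC-peptide complex string is the
#' bitwise XOR of the two strings.
#'
#' @param mhc1_alleles,mhc2_alleles Integer shape-space codes.
#' @param self_peptides Integer codes of self peptides.
#' @param mbp_peptide Integer code of the MBP peptide (must be a self peptide).
#' @param params A [repertoire_params()] object.
#' @return An object of class `mhc_context`.
#' @export
mhc_context <- function(mhc1_alleles, mhc2_alleles, self_peptides,
                        mbp_peptide, params = repertoire_params()) {
  if (length(mhc1_alleles) == 0L || length(mhc2_alleles) == 0L ||
      length(self_peptides) == 0L)
    stop("MHC allele and self-peptide sets must be non-empty")
  lim <- 2^params$bitstring_length
  all_codes <- c(mhc1_alleles, mhc2_alleles, self_peptides, mbp_peptide)
  if (any(all_codes < 0L) || any(all_codes >= lim))
    stop("bit codes out of shape-space range")
  if (!(mbp_peptide %in% self_peptides))
    self_peptides <- c(self_peptides, mbp_peptide)
  structure(list(mhc1_alleles = as.integer(mhc1_alleles),
                 mhc2_alleles = as.integer(mhc2_alleles),
                 self_peptides = as.integer(self_peptides),
                 mbp_peptide = as.integer(mbp_peptide),
                 params = params),
            class = "mhc_context")
}

# Random MHC context for a subject.  hla_predisposition selects MHC-I strings
# with elevated affinity to the MBP peptide (polymorphisms that favour
# presentation of the autoantigen).
random_mhc_context <- function(params, n_mhc1 = 2L, n_mhc2 = 2L,
                               n_self = 8L, hla_predisposition = FALSE) {
  l <- params$bitstring_length
  mbp <- draw_receptors(1L, l)
  self <- unique(c(mbp, draw_receptors(n_self - 1L, l)))
  mhc2 <- draw_receptors(n_mhc2, l)
  if (hla_predisposition) {
    # polymorphisms that bind the myelin autoantigen well: under the
    # complementarity convention, alleles with high Hamming affinity to the
    # MBP peptide
    cand <- draw_receptors(64L, l)
    aff <- popcount(bitwXor(cand, mbp))
    mhc1 <- cand[order(-aff)][seq_len(n_mhc1)]
  } else {
    mhc1 <- draw_receptors(n_mhc1, l)
  }
  mhc_context(mhc1, mhc2, self, mbp, params)
}

# Bitwise complement within l bits.
bitwNot_l <- function(x, l) bitwXor(as.integer(x), as.integer(2^l - 1))

mhc_complex <- function(mhc, peptide) bitwXor(as.integer(mhc), as.integer(peptide))
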
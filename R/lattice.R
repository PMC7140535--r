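# 2D hexagonal lattice (six neighbours per interior site) with periodic or
# rigid-wall boundaries.  Sites are indexed 1..L^2 in row-major "odd-r"
# offset coordinates.  Each biological compartment (lymph node, white
# matter) is one such lattice; they are joined only by the migration
# operation, not by a spatial interface.

#' Hexagonal lattice
#'
#' @param side_length Positive integer `L`; the lattice has `L^2` sites.
#' @param boundary `"periodic"` (every site keeps six neighbours) or
#'   `"rigid"` (walls; edge sites have fewer).
#' @return An object of class `hex_lattice` with a neighbour table `nb`
#'   (`L^2 x 7`; column 1 is the site itself, 0 marks a missing neighbour
#'   under rigid walls).
#' @export
hex_lattice <- function(side_length = 16L, boundary = c("periodic", "rigid")) {
  L <- as.integer(side_length)
  boundary <- match.arg(boundary)
  if (is.na(L) || L < 2L) stop("side_length must be an integer >= 2")
  S <- L * L
  idx <- function(col, row, wrap) {
    if (wrap) {
      col <- (col - 1L) %% L + 1L
      row <- (row - 1L) %% L + 1L
      (row - 1L) * L + col
    } else {
      out <- (row - 1L) * L + col
      out[col < 1L | col > L | row < 1L | row > L] <- 0L
      out
    }
  }
  site <- seq_len(S)
  row <- (site - 1L) %/% L + 1L
  col <- (site - 1L) %% L + 1L
  odd <- row %% 2L == 1L
  # odd-r offset hex neighbourhood
  dc_even <- list(c(1L, 0L), c(-1L, 0L), c(0L, -1L), c(-1L, -1L),
                  c(0L, 1L), c(-1L, 1L))
  dc_odd <- list(c(1L, 0L), c(-1L, 0L), c(1L, -1L), c(0L, -1L),
                 c(1L, 1L), c(0L, 1L))
  wrap <- boundary == "periodic"
  nb <- matrix(0L, S, 7L)
  nb[, 1L] <- site
  for (k in 1:6) {
    de <- dc_even[[k]]; do <- dc_odd[[k]]
    dcol <- ifelse(odd, do[1L], de[1L])
    drow <- ifelse(odd, do[2L], de[2L])
    nb[, k + 1L] <- idx(col + dcol, row + drow, wrap)
  }
  avail <- nb > 0L
  n_avail <- rowSums(avail)
  # cached cumulative destination probabilities for the uniform walk
  P <- matrix(0, S, 7L)
  P[avail] <- 1
  P <- P / n_avail
  cum <- P
  for (k in 2:7) cum[, k] <- cum[, k - 1L] + P[, k]
  structure(list(side = L, n_sites = S, boundary = boundary, nb = nb,
                 n_avail = n_avail, avail = avail, cum_unif = cum),
            class = "hex_lattice")
}

#' Crowding parameters
#'
#' Movement into a site is accepted with probability
#' `1 - min((n/Mcells) * K, 1)` where `n` is the number of motile cell agents
#' already at the target.  Because `K < 1`, even a nominally full site
#' (`n = Mcells`) still admits entry with probability `1 - K`, reflecting
#' immune-cell infiltration of crowded inflamed tissue.  The alternative
#' reading `1 - min(n/(Mcells*K), 1)` is available as `form = "divided"`.
#'
#' @param max_entities_per_site Positive integer `Mcells`. Default 100.
#' @param crowding_constant `K` strictly inside `(0,1)`. Default 0.5.
#' @param form `"scaled"` (default) or `"divided"`.
#' @return An object of class `crowding_params`.
#' @export
crowding_params <- function(max_entities_per_site = 100L,
                            crowding_constant = 0.5,
                            form = c("scaled", "divided")) {
  form <- match.arg(form)
  M <- as.integer(max_entities_per_site)
  K <- crowding_constant
  if (is.na(M) || M <= 0L) stop("max_entities_per_site must be positive")
  if (!(K > 0 && K < 1)) stop("crowding_constant must lie strictly in (0,1)")
  structure(list(max_entities_per_site = M, crowding_constant = K,
                 form = form),
            class = "crowding_params")
}

#' Chemotactic destination probabilities
#'
#' Converts the chemokine counts of a site and its six neighbours into the
#' seven destination probabilities of one movement draw: proportional to the
#' counts when any chemokine is present, uniform `1/7` otherwise.
#'
#' @param counts Seven non-negative numbers `C0..C6` (current site first).
#' @return Seven probabilities summing to 1.
#' @examples
#' chemotactic_probabilities(c(0, 6, 2, 0, 0, 0, 0))  # c(0, .75, .25, 0, ...)
#' @export
chemotactic_probabilities <- function(counts) {
  if (length(counts) != 7L) stop("exactly seven counts expected (site + 6 neighbours)")
  if (any(counts < 0)) stop("chemokine counts must be non-negative")
  s <- sum(counts)
  if (s > 0) counts / s else rep(1 / 7, 7L)
}

#' Crowding acceptance probability
#'
#' @param total_entities_at_target Number of motile cell agents already at
#'   the target site (>= 0).
#' @param params A [crowding_params()] object.
#' @return Acceptance probability in `[0,1]`; vectorised.
#' @examples
#' acceptance_probability(100, crowding_params(100, 0.5))  # 0.5
#' @export
acceptance_probability <- function(total_entities_at_target, params) {
  n <- total_entities_at_target
  if (any(n < 0)) stop("entity counts must be non-negative")
  M <- params$max_entities_per_site
  K <- params$crowding_constant
  load <- if (params$form == "scaled") (n / M) * K else n / (M * K)
  1 - pmin(load, 1)
}

# --- vectorised movement / diffusion primitives ----------------------------

# For every agent at `sites`, draw a destination column (1..7) from per-site
# cumulative probability rows `cum7` (n_sites x 7, last column 1).
draw_destination_cols <- function(sites, cum7) {
  n <- length(sites)
  u <- stats::runif(n)
  # column index = 1 + number of cumulative cells strictly below u
  dest <- rep(1L, n)
  for (k in 1:6) dest <- dest + (u > cum7[sites + (k - 1L) * nrow(cum7)])
  dest
}

# Per-site 7-way destination probabilities given a chemokine count vector.
# Missing neighbours (rigid walls) get probability zero; zero-chemokine rows
# fall back to uniform over available options.
site_move_probs <- function(latt, chem = NULL) {
  nb <- latt$nb
  avail <- latt$avail
  if (is.null(chem)) {
    P <- matrix(0, latt$n_sites, 7L)
    P[avail] <- 1
  } else {
    P <- matrix(0, latt$n_sites, 7L)
    idx <- ifelse(avail, nb, 1L)
    C <- matrix(chem[idx], latt$n_sites, 7L)
    C[!avail] <- 0
    rs <- rowSums(C)
    zero <- rs == 0
    P[!zero, ] <- C[!zero, , drop = FALSE] / rs[!zero]
    Pu <- matrix(0, latt$n_sites, 7L); Pu[avail] <- 1
    P[zero, ] <- Pu[zero, , drop = FALSE]
  }
  P / rowSums(P)
}

# Cumulative version of site_move_probs.
site_move_cum <- function(latt, chem) {
  P <- site_move_probs(latt, chem)
  for (k in 2:7) P[, k] <- P[, k - 1L] + P[, k]
  P
}

#' Diffuse molecule fields one step
#'
#' Every molecule unit independently jumps to one of the site itself and its
#' available neighbours, uniformly.  Counts are integers and the total per
#' species is conserved exactly.
#'
#' @param fields `n_sites x n_species` integer matrix.
#' @param latt A [hex_lattice()].
#' @return Updated matrix of the same shape and column totals.
#' @export
diffuse_molecules <- function(fields, latt) {
  if (any(fields < 0)) stop("molecule counts must be non-negative")
  nz <- which(fields > 0L)            # flat (site, species) cells
  if (!length(nz)) return(fields)
  nb <- latt$nb
  avail <- latt$avail
  S <- nrow(fields)
  site <- (nz - 1L) %% S + 1L
  col0 <- nz - site                   # flat offset of the species column
  out <- fields
  out[nz] <- 0L
  remaining <- fields[nz]
  ropt <- latt$n_avail[site]
  for (k in 1:7) {
    ak <- avail[site, k]
    take <- integer(length(nz))
    sel <- which(ak & ropt > 1L & remaining > 0L)
    if (length(sel)) take[sel] <- stats::rbinom(length(sel), remaining[sel],
                                                1 / ropt[sel])
    # the last available option takes everything left
    last <- ak & ropt == 1L
    take[last] <- remaining[last]
    remaining <- remaining - take
    ropt <- ropt - as.integer(ak)
    got <- which(take > 0L)
    if (length(got)) {
      # a fixed direction maps distinct sites to distinct targets within a
      # species column, so the indexed add is collision-free
      tgt <- nb[site[got], k] + col0[got]
      out[tgt] <- out[tgt] + take[got]
    }
  }
  out
}

# Move a set of agents (positions `sites`, all in the same compartment
# lattice) one step.  `sens` flags chemokine-sensitive agents; occupancy is
# the per-site motile-agent count used for crowding.
move_on_lattice <- function(sites, sens, latt, chem, occupancy, crowd) {
  n <- length(sites)
  if (n == 0L) return(sites)
  cum_chem <- if (any(sens) && any(chem > 0)) site_move_cum(latt, chem)
  else NULL
  dest_col <- integer(n)
  if (!is.null(cum_chem)) {
    dest_col[sens] <- draw_destination_cols(sites[sens], cum_chem)
  }
  rest <- if (!is.null(cum_chem)) !sens else rep(TRUE, n)
  if (any(rest)) dest_col[rest] <- draw_destination_cols(sites[rest],
                                                         latt$cum_unif)
  dest <- latt$nb[cbind(sites, dest_col)]
  dest[dest == 0L] <- sites[dest == 0L]
  moving <- dest != sites
  if (any(moving)) {
    p_acc <- acceptance_probability(occupancy[dest[moving]], crowd)
    ok <- stats::runif(sum(moving)) < p_acc
    idx <- which(moving)[ok]
    sites[idx] <- dest[idx]
  }
  sites
}
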
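# Discrete-time engine.  The simulation state is a single list advanced step
# by step.  Cells are tracked individually as parallel integer vectors;
# molecules are per-site integer count fields.  One step = 8 hours by
# default (3 steps/day), which resolves the fastest half-life in the entity
# table (chemokine, 3 h) to within a factor ~2.7 while keeping a 4.5-year
# course below 5,000 steps.

# -- internal catalogues ----------------------------------------------------
TYPES <- c("B", "TH", "TC", "CDC", "M", "P", "TREG")
iB <- 1L; iTH <- 2L; iTC <- 3L; iCDC <- 4L; iM <- 5L; iP <- 6L; iTREG <- 7L

STATES <- c("resting", "active", "anergic", "intern", "PresI", "PresII",
            "duplicating", "BoundToAb", "infected_active", "infected_silent")
sRES <- 1L; sACT <- 2L; sANE <- 3L; sINT <- 4L; sP1 <- 5L; sP2 <- 6L
sDUP <- 7L; sBAB <- 8L

SPECIES <- c("IFN-G", "IL-2", "IL-4", "IL-10", "IL-12", "IL-17", "IL-23",
             "TGFB", "MBP", "IgG", "Chemokine", "IC", "EBV")
mIFNG <- 1L; mIL2 <- 2L; mIL4 <- 3L; mIL10 <- 4L; mIL12 <- 5L; mIL17 <- 6L
mIL23 <- 7L; mTGFB <- 8L; mMBP <- 9L; mIGG <- 10L; mCHEM <- 11L
mIC <- 12L; mEBV <- 13L

COMPARTMENTS <- c("lymph_node", "white_matter")
cLN <- 1L; cWM <- 2L

REC_SERIES <- c("odc", "active_th1", "resting_th1", "active_treg",
                "resting_treg", "active_tc", "resting_tc", "il2", "ifng",
                "b_cells", "igg", "mbp", "chemokine")

# -- hematopoiesis ----------------------------------------------------------

#' Hematopoiesis (bone-marrow homeostasis) parameters
#'
#' Cell production is a mean-reverting Ornstein-Uhlenbeck process:
#' `dx = (ln2/tau) (xbar - x) dt + sigma dW`.  With `noise_sd = 0` the count
#' relaxes deterministically to `mean_level`.
#'
#' @param mean_level Target mean count `xbar` (the entity-table initial count
#'   by default).
#' @param reversion_timescale `tau` in days; the reversion rate is `ln2/tau`.
#' @param noise_sd Noise amplitude `sigma` (counts per sqrt(day)); 0 gives a
#'   deterministic process.
#' @return An object of class `hematopoiesis_params`.
#' @export
hematopoiesis_params <- function(mean_level, reversion_timescale,
                                 noise_sd = 0) {
  if (reversion_timescale <= 0) stop("reversion_timescale must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(mean_level = mean_level,
                 reversion_timescale = reversion_timescale,
                 noise_sd = noise_sd),
            class = "hematopoiesis_params")
}

#' One hematopoiesis update
#'
#' Applies `delta = (ln2/tau) (xbar - x) dt + sigma sqrt(dt) z` with `z`
#' standard normal, clamping the result at zero.
#'
#' @param current_count Current cell count `x`.
#' @param params A [hematopoiesis_params()] object.
#' @param dt Time step in days.
#' @return Updated (real-valued) count.
#' @examples
#' p <- hematopoiesis_params(876, 3.3)
#' hematopoiesis_step(1000, p, 1)  # moves ~26 cells back towards the mean
#' @export
hematopoiesis_step <- function(current_count, params, dt) {
  if (dt <= 0) stop("dt must be positive")
  delta <- (log(2) / params$reversion_timescale) *
    (params$mean_level - current_count) * dt
  if (params$noise_sd > 0)
    delta <- delta + params$noise_sd * sqrt(dt) * stats::rnorm(1)
  max(current_count + delta, 0)
}

# -- thymic selection -------------------------------------------------------

# Vector core: keep mask for receptors of one T-cell class.
thymus_keep <- function(receptors, class_mhc, ctx, params,
                        central_impairment = 0) {
  l <- params$bitstring_length
  m0 <- params$min_mismatch_m0
  if (length(receptors) == 0L) return(logical(0))
  # positive selection: affinity to at least one class MHC >= l/2 - m0
  best <- rep(-1L, length(receptors))
  for (m in class_mhc) best <- pmax(best, popcount(bitwXor(receptors, m)))
  keep <- best >= l %/% 2L - m0
  # negative selection: delete high affinity to any MHC-self-peptide complex;
  # central-tolerance impairment raises the deletion threshold, letting more
  # autoreactive receptors through
  thr <- l - m0 + as.integer(round(central_impairment * m0 * 2))
  worst <- rep(0L, length(receptors))
  for (m in class_mhc) for (sp in ctx$self_peptides)
    worst <- pmax(worst, popcount(bitwXor(receptors, mhc_complex(m, sp))))
  keep & worst < thr
}

#' Thymic selection of T-cell candidates
#'
#' Two-phase stochastic filter of T-cell receptors: positive selection keeps
#' receptors whose affinity to at least one MHC string of the relevant class
#' (class I for TC, class II for TH) is at least `l/2 - m0`; negative
#' selection then deletes survivors whose affinity to any MHC-self-peptide
#' complex (bitwise XOR of the two strings) reaches the high-affinity
#' deletion threshold `l - m0`.  Central-tolerance impairment raises the
#' deletion threshold by `round(impairment * m0 * 2)` bits.
#'
#' @param candidates Data frame with columns `cell_type` (`"TH"`/`"TC"`) and
#'   `receptor` (integer codes), e.g. from [generate_repertoire()].
#' @param ctx An [mhc_context()].
#' @param params A [repertoire_params()].
#' @param central_impairment Central-tolerance impairment in `[0,1]`.
#' @return The surviving subset of `candidates`.
#' @export
thymus_select <- function(candidates, ctx, params = ctx$params,
                          central_impairment = 0) {
  if (nrow(candidates) == 0L) return(candidates)
  if (!all(candidates$cell_type %in% c("TH", "TC")))
    stop("thymic selection applies to TH and TC candidates only")
  if (any(is.na(candidates$receptor)))
    stop("every candidate needs a receptor")
  keep <- logical(nrow(candidates))
  th <- candidates$cell_type == "TH"
  keep[th] <- thymus_keep(candidates$receptor[th], ctx$mhc2_alleles, ctx,
                          params, central_impairment)
  keep[!th] <- thymus_keep(candidates$receptor[!th], ctx$mhc1_alleles, ctx,
                           params, central_impairment)
  candidates[keep, , drop = FALSE]
}

# Draw `n` thymus-selected receptors for class `class` ("TH"/"TC").
draw_selected_receptors <- function(n, class, ctx, params, impairment = 0) {
  out <- integer(0)
  mhc <- if (class == "TH") ctx$mhc2_alleles else ctx$mhc1_alleles
  guard <- 0L
  while (length(out) < n && guard < 50L) {
    cand <- draw_receptors(max(n - length(out), 16L), params$bitstring_length)
    out <- c(out, cand[thymus_keep(cand, mhc, ctx, params, impairment)])
    guard <- guard + 1L
  }
  out[seq_len(n)]
}

# -- agent store ------------------------------------------------------------

ag_empty <- function() {
  list(type = integer(0), state = integer(0), comp = integer(0),
       pos = integer(0), recep = integer(0), pep = integer(0),
       div = integer(0), mem = logical(0), th2 = logical(0),
       noB7 = logical(0))
}

ag_bind <- function(a, b) {
  for (f in names(a)) a[[f]] <- c(a[[f]], b[[f]])
  a
}

ag_keep <- function(a, mask) {
  for (f in names(a)) a[[f]] <- a[[f]][mask]
  a
}

ag_n <- function(a) length(a$type)

ag_new <- function(n, type, state = sRES, comp = cLN, pos, recep = NA_integer_,
                   pep = NA_integer_, div = 0L, mem = FALSE, th2 = FALSE,
                   noB7 = FALSE) {
  list(type = rep_len(as.integer(type), n), state = rep_len(as.integer(state), n),
       comp = rep_len(as.integer(comp), n), pos = rep_len(as.integer(pos), n),
       recep = rep_len(as.integer(recep), n), pep = rep_len(as.integer(pep), n),
       div = rep_len(as.integer(div), n), mem = rep_len(mem, n),
       th2 = rep_len(th2, n), noB7 = rep_len(noB7, n))
}

#' Agents of a simulation state as a data frame
#'
#' @param state A simulation state from [init_state()].
#' @return Data frame with one row per tracked cell.
#' @export
agents_df <- function(state) {
  a <- state$ag
  data.frame(cell_type = TYPES[a$type], state = STATES[a$state],
             compartment = COMPARTMENTS[a$comp], site = a$pos,
             receptor = a$recep, presented_peptide = a$pep,
             division_count = a$div, memory = a$mem)
}

# -- decay ------------------------------------------------------------------

# Molecule half-lives in days, aligned with SPECIES.
species_half_lives <- function(et = NULL) {
  if (is.null(et)) et <- entity_table()
  hl <- stats::setNames(et$half_life_days, et$entity)
  c(hl[["IFN-G"]], hl[["IL-2"]], hl[["IL-4"]], hl[["IL-10"]], hl[["IL-12"]],
    hl[["IL-17"]], hl[["IL-23"]], hl[["TGFB"]], hl[["MBP"]], hl[["IgG"]],
    hl[["Chemokine"]], hl[["IC"]], hl[["IC"]])  # EBV antigen decays like IC
}

#' One decay step
#'
#' Molecule counts are binomially thinned with survival `2^(-dt/t_half)`
#' (exact in expectation for exponential decay); mortal cells die with
#' probability `1 - 2^(-dt/t_half)`.  Naive resting (non-memory) cells are
#' exempt: their turnover is carried entirely by the mean-reverting
#' bone-marrow process, which keeps long-run means at the entity-table
#' values.  Memory cells and oligodendrocytes are long-lived and exempt.
#'
#' @param state Simulation state.
#' @param dt Time step in days; `dt = 0` leaves the state unchanged.
#' @return Updated state.
#' @export
decay_step <- function(state, dt) {
  if (dt < 0) stop("dt must be >= 0")
  if (dt == 0) return(state)
  surv <- 2^(-dt / state$cfg$mol_half_lives)
  for (cp in 1:2) {
    f <- state$fields[[cp]]
    nz <- which(f > 0L)
    if (length(nz)) {
      sp <- (nz - 1L) %/% nrow(f) + 1L
      f[nz] <- stats::rbinom(length(nz), f[nz], surv[sp])
      state$fields[[cp]] <- f
    }
  }
  a <- state$ag
  mortal <- a$state != sRES & !a$mem
  if (any(mortal)) {
    hl <- state$cfg$cell_half_life[a$type]
    # active regulatory T cells persist longer (sustained suppression)
    treg_act <- a$type == iTREG & a$state == sACT
    hl[treg_act] <- state$cfg$cal$treg_active_half_life
    p_die <- 1 - 2^(-dt / hl)
    die <- mortal & stats::runif(ag_n(a)) < p_die
    if (any(die)) state$ag <- ag_keep(a, !die)
  }
  state
}

# -- state construction -----------------------------------------------------

#' Initialize a simulation state
#'
#' Builds the full mutable simulation state: two hexagonal lattice
#' compartments (lymph node, white matter), the initial immune repertoire
#' (T cells thymus-selected against the subject's MHC context), resident
#' white-matter antigen-presenting cells, the oligodendrocyte field, and
#' empty molecule fields.
#'
#' @param params [repertoire_params()].
#' @param disease [disease_params()]; the all-zero default is a healthy
#'   control.
#' @param wm [white_matter_config()].
#' @param lattice_side Lattice side length per compartment.
#' @param boundary Lattice boundary behaviour.
#' @param crowd [crowding_params()].
#' @param plans List of [treatment_plan()] objects.
#' @param risk Optional [risk_factor_profile()]; applied via
#'   [seed_risk_factors()].
#' @param calibration Calibration constants, see [default_calibration()].
#' @param scale Population scale factor multiplying initial immune counts and
#'   `Mcells`.
#' @param seed Master RNG seed (integer); the whole trajectory is a
#'   deterministic function of config + seed.
#' @param dt_hours Step duration in hours (default 8).
#' @return An object of class `ms_state`.
#' @export
init_state <- function(params = repertoire_params(),
                       disease = disease_params(),
                       wm = white_matter_config(),
                       lattice_side = 16L,
                       boundary = "periodic",
                       crowd = crowding_params(),
                       plans = list(),
                       risk = NULL,
                       calibration = default_calibration(),
                       scale = 1,
                       seed = 1L,
                       dt_hours = 8) {
  set.seed(as.integer(seed))
  cal <- calibration
  plans <- precompute_plan_effects(plans)
  latt <- hex_lattice(lattice_side, boundary)
  S <- latt$n_sites
  et <- entity_table()
  counts <- stats::setNames(et$initial_count_per_uL, et$entity)

  hla <- !is.null(risk) && isTRUE(risk$hla_predisposition)
  ctx <- random_mhc_context(params, hla_predisposition = hla)

  if (crowd$max_entities_per_site != crowding_params()$max_entities_per_site ||
      scale != 1) {
    crowd$max_entities_per_site <-
      max(1L, as.integer(round(crowd$max_entities_per_site * scale)))
  }

  n_of <- function(nm) as.integer(round(counts[[nm]] * scale))
  ag <- ag_empty()
  add_pool <- function(ag, n, type, comp, recep) {
    if (n == 0L) return(ag)
    ag_bind(ag, ag_new(n, type, sRES, comp, sample.int(S, n, replace = TRUE),
                       recep))
  }
  ag <- add_pool(ag, n_of("B"), iB, cLN,
                 draw_receptors(n_of("B"), params$bitstring_length))
  ag <- add_pool(ag, n_of("TH"), iTH, cLN,
                 draw_selected_receptors(n_of("TH"), "TH", ctx, params,
                                         disease$central_tolerance_impairment))
  ag <- add_pool(ag, n_of("TC"), iTC, cLN,
                 draw_selected_receptors(n_of("TC"), "TC", ctx, params,
                                         disease$central_tolerance_impairment))
  n_treg <- as.integer(round(cal$treg_count * scale))
  ag <- add_pool(ag, n_treg, iTREG, cLN, NA_integer_)
  ag <- add_pool(ag, n_of("CDC"), iCDC, cLN, NA_integer_)
  ag <- add_pool(ag, n_of("M"), iM, cLN, NA_integer_)
  n_wm_apc <- as.integer(round(cal$wm_apc_fraction * counts[["CDC"]] * scale))
  ag <- add_pool(ag, n_wm_apc, iCDC, cWM, NA_integer_)
  ag <- add_pool(ag, n_wm_apc, iM, cWM, NA_integer_)

  odc_total <- as.integer(round(wm$volume_mm3 * wm$odc_density))
  odc <- rep(odc_total %/% S, S)
  rem <- odc_total - sum(odc)
  if (rem > 0) {
    extra <- sample.int(S, rem, replace = TRUE)
    odc <- odc + tabulate(extra, S)
  }

  # homeostasis targets per (type, compartment): lymph-node pools at entity
  # table means; resident white-matter APCs at their seeded level
  hp <- list()
  cv <- cal$homeostasis_cv
  mk <- function(mean, tau) {
    hematopoiesis_params(mean, tau, cv * mean * sqrt(2 * log(2) / tau))
  }
  for (tp in c("B", "TH", "TC", "CDC", "M"))
    hp[[paste0(tp, ".", cLN)]] <- mk(n_of(tp), 3.3)
  hp[[paste0("TREG.", cLN)]] <- mk(n_treg, 3.3)
  hp[[paste0("CDC.", cWM)]] <- mk(n_wm_apc, 3.3)
  hp[[paste0("M.", cWM)]] <- mk(n_wm_apc, 3.3)

  cell_hl <- c(B = 3.3, TH = 3.3, TC = 3.3, CDC = 3.3, M = 3.3, P = 3.3,
               TREG = 3.3)

  state <- structure(list(
    cfg = list(params = params, latt = latt, crowd = crowd, wm = wm,
               disease = disease, plans = plans, cal = cal,
               mol_half_lives = species_half_lives(et),
               cell_half_life = unname(cell_hl[TYPES]),
               dt = dt_hours / 24, scale = scale, seed = as.integer(seed),
               hematopoiesis = hp, odc_baseline = odc_total),
    ctx = ctx,
    clock = 0L,
    ag = ag,
    fields = list(matrix(0L, S, length(SPECIES)),
                  matrix(0L, S, length(SPECIES))),
    odc = odc,
    odc_ops = rep(0L, S),
    effects = neutral_drug_effects(),
    hla_boost = if (hla) calibration$hla_capture_boost else 1,
    ebv_pep = NA_integer_,
    rules = NULL,
    rec = NULL
  ), class = "ms_state")

  state$rules <- register_ms_rules(core_rules())
  if (!is.null(risk)) state <- seed_risk_factors(state, risk)
  state
}

#' @export
print.ms_state <- function(x, ...) {
  cat(sprintf(paste0("ms_state: step %d (%.1f days), %d agents, ",
                     "ODC %d/%d\n"),
              x$clock, x$clock * x$cfg$dt, ag_n(x$ag),
              sum(x$odc) + sum(x$odc_ops), x$cfg$odc_baseline))
  invisible(x)
}

# -- per-step phases --------------------------------------------------------

#' Move all agents one step
#'
#' Chemokine-sensitive agents (non-resting cells and professional
#' antigen-presenting cells) choose a destination among the current site and
#' its six neighbours with probabilities proportional to chemokine counts;
#' everything else walks uniformly.  The move is then accepted with the
#' crowding probability of the target site.  Agents never change compartment
#' here.
#'
#' @param state Simulation state.
#' @return Updated state.
#' @export
move_agents <- function(state) {
  a <- state$ag
  latt <- state$cfg$latt
  for (cp in 1:2) {
    in_cp <- a$comp == cp
    if (!any(in_cp)) next
    occ <- tabulate(a$pos[in_cp], latt$n_sites)
    sens <- (a$state != sRES | a$type %in% c(iM, iCDC))[in_cp]
    chem <- state$fields[[cp]][, mCHEM]
    a$pos[in_cp] <- move_on_lattice(a$pos[in_cp], sens, latt, chem, occ,
                                    state$cfg$crowd)
  }
  state$ag <- a
  state
}

#' Migrate cells and antibody between compartments
#'
#' Activated effector T cells leave the lymph node for the white matter with
#' per-step probability `ingress_prob`, gated by the egress probability
#' (fingolimod drives egress towards zero, natalizumab scales white-matter
#' ingress down).  Presenting antigen-presenting cells return from the white
#' matter to the lymph node.  A fraction of lymph-node immunoglobulin
#' transfers to the white matter each step (circulation).
#'
#' @param state Simulation state.
#' @param egress_prob Lymph-node egress gate in `[0,1]`.
#' @param ingress_prob Per-step white-matter entry probability for activated
#'   effector cells.
#' @return Updated state.
#' @export
migrate_between_compartments <- function(state,
                                         egress_prob = state$effects$egress_scale,
                                         ingress_prob = NULL) {
  cal <- state$cfg$cal
  if (is.null(ingress_prob))
    ingress_prob <- cal$p_ingress * state$effects$wm_ingress_scale
  a <- state$ag
  S <- state$cfg$latt$n_sites
  eff <- a$comp == cLN & (a$type == iTH | a$type == iTC) &
    (a$state == sACT | a$state == sDUP)
  p_cross <- ingress_prob * egress_prob
  go <- eff & stats::runif(ag_n(a)) < p_cross
  if (any(go)) {
    a$comp[go] <- cWM
    a$pos[go] <- sample.int(S, sum(go), replace = TRUE)
  }
  apc <- a$comp == cWM & (a$type == iCDC | a$type == iM | a$type == iB) &
    (a$state == sP1 | a$state == sP2)
  back <- apc & stats::runif(ag_n(a)) < cal$p_apc_migrate
  if (any(back)) {
    a$comp[back] <- cLN
    a$pos[back] <- sample.int(S, sum(back), replace = TRUE)
  }
  state$ag <- a
  # circulation of soluble species: antibody into the white matter, free
  # myelin antigen draining to the lymph node
  state <- transfer_field(state, cLN, cWM, mIGG, cal$igg_wm_fraction)
  state <- transfer_field(state, cWM, cLN, mMBP, cal$mbp_drain_fraction)
  state
}

# Move a binomial fraction of one species from one compartment to random
# sites of the other.
transfer_field <- function(state, from, to, sp, fraction) {
  if (fraction <= 0) return(state)
  src <- state$fields[[from]][, sp]
  pos <- which(src > 0L)
  if (!length(pos)) return(state)
  moved <- stats::rbinom(length(pos), src[pos], fraction)
  tot <- sum(moved)
  if (tot > 0) {
    S <- state$cfg$latt$n_sites
    state$fields[[from]][pos, sp] <- src[pos] - moved
    tgt <- sample.int(S, tot, replace = TRUE)
    state$fields[[to]][, sp] <- state$fields[[to]][, sp] + tabulate(tgt, S)
  }
  state
}

# Hematopoiesis + thymus + oligodendrocyte regeneration phase.
homeostasis_phase <- function(state) {
  a <- state$ag
  dt <- state$cfg$dt
  S <- state$cfg$latt$n_sites
  params <- state$cfg$params
  imp <- state$cfg$disease$central_tolerance_impairment
  new_ag <- list()
  drop <- logical(ag_n(a))
  naive <- a$state == sRES & !a$mem
  pool_key <- a$type + 7L * (a$comp - 1L)
  pool_cnt <- tabulate(pool_key[naive], 14L)
  for (key in names(state$cfg$hematopoiesis)) {
    hpp <- state$cfg$hematopoiesis[[key]]
    if (hpp$mean_level <= 0) next
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    ti <- match(parts[1L], TYPES); cp <- as.integer(parts[2L])
    x <- pool_cnt[ti + 7L * (cp - 1L)]
    delta <- as.integer(round(hematopoiesis_step(x, hpp, dt) - x))
    if (delta > 0L) {
      rec <- if (parts[1L] == "TH" || parts[1L] == "TC") {
        draw_selected_receptors(delta, parts[1L], state$ctx, params, imp)
      } else if (parts[1L] == "B") {
        draw_receptors(delta, params$bitstring_length)
      } else NA_integer_
      new_ag[[key]] <- ag_new(delta, ti, sRES, cp,
                              sample.int(S, delta, replace = TRUE), rec)
    } else if (delta < 0L) {
      idx <- which(naive & a$type == ti & a$comp == cp)
      rm_idx <- idx[sample.int(length(idx), min(-delta, length(idx)))]
      drop[rm_idx] <- TRUE
    }
  }
  if (any(drop)) a <- ag_keep(a, !drop)
  for (na in new_ag) a <- ag_bind(a, na)
  state$ag <- a
  # oligodendrocyte regeneration towards baseline (mean-reverting, no noise)
  x <- sum(state$odc) + sum(state$odc_ops)
  regen <- hematopoiesis_params(state$cfg$odc_baseline,
                                state$cfg$wm$odc_regeneration_days)
  delta <- as.integer(round(hematopoiesis_step(x, regen, dt) - x))
  if (delta > 0L) {
    tgt <- sample.int(S, delta, replace = TRUE)
    state$odc <- state$odc + tabulate(tgt, S)
  }
  state
}

# Secretion by active cells; also plasma-cell antibody output.
secretion_phase <- function(state) {
  a <- state$ag
  cal <- state$cfg$cal
  S <- state$cfg$latt$n_sites
  u <- cal$secrete_units
  dep <- function(cp, sel, sp, units) {
    if (!any(sel)) return()
    add <- tabulate(a$pos[sel], S) * units
    state$fields[[cp]][, sp] <<- state$fields[[cp]][, sp] + add
  }
  act <- a$state == sACT | a$state == sDUP
  pres <- a$state == sP1 | a$state == sP2
  for (cp in 1:2) {
    in_cp <- a$comp == cp
    th_act <- in_cp & act & a$type == iTH
    th1 <- th_act & !a$th2
    dep(cp, th1, mIL2, u)
    dep(cp, th1, mIFNG, u)
    if (!state$effects$il17_suppressed) dep(cp, th1, mIL17, 1L)
    th2 <- th_act & a$th2
    dep(cp, th2, mIL4, u)
    dep(cp, th2, mIL10, u)
    treg <- in_cp & a$type == iTREG & a$state == sACT
    dep(cp, treg, mIL10, u)
    dep(cp, treg, mTGFB, u)
    apc <- in_cp & pres & (a$type == iCDC | a$type == iM | a$type == iB)
    dep(cp, apc, mIL12, cal$il12_units)
    pc <- in_cp & a$type == iP
    dep(cp, pc, mIGG, cal$igg_per_plasma_step)
  }
  state
}

record_phase <- function(state) {
  a <- state$ag
  f <- state$fields
  tot <- function(sp) sum(f[[cLN]][, sp]) + sum(f[[cWM]][, sp])
  act <- a$state == sACT | a$state == sDUP
  row <- c(sum(state$odc) + sum(state$odc_ops),
           sum(a$type == iTH & act & !a$th2),
           sum(a$type == iTH & a$state == sRES),
           sum(a$type == iTREG & a$state == sACT),
           sum(a$type == iTREG & a$state == sRES),
           sum(a$type == iTC & act),
           sum(a$type == iTC & a$state == sRES),
           tot(mIL2), tot(mIFNG),
           sum(a$type == iB | a$type == iP),
           tot(mIGG), tot(mMBP), tot(mCHEM))
  if (is.null(state$rec)) {
    state$rec <- matrix(NA_real_, 0L, length(REC_SERIES),
                        dimnames = list(NULL, REC_SERIES))
  }
  state$rec <- rbind(state$rec, row)
  state
}

#' Advance the simulation by one time interval
#'
#' Sub-steps run in a fixed order: treatment-schedule application,
#' hematopoiesis/thymic output and tissue regeneration, movement and
#' diffusion, Bernoulli interactions (in a fresh random rule order),
#' half-life decay, and recording.  Identical config + seed gives identical
#' trajectories.
#'
#' @param state Simulation state.
#' @return The state advanced by one step.
#' @export
sim_step <- function(state) {
  state$effects <- apply_treatment_effects(state, state$cfg$plans)
  state <- maybe_reinject_ebv(state)
  state <- homeostasis_phase(state)
  state <- move_agents(state)
  for (cp in 1:2)
    state$fields[[cp]] <- diffuse_molecules(state$fields[[cp]], state$cfg$latt)
  state <- migrate_between_compartments(state)
  state <- execute_interactions(state, state$rules)
  state <- secretion_phase(state)
  state <- decay_step(state, state$cfg$dt)
  state$clock <- state$clock + 1L
  record_phase(state)
}

#' Run a state forward
#'
#' @param state Simulation state.
#' @param n_steps Number of steps to run.
#' @param record Keep the per-step record (default TRUE).
#' @return The advanced state; trajectories in `state$rec`.
#' @export
run_steps <- function(state, n_steps, record = TRUE) {
  if (!record) {
    keep <- state$rec
    for (k in seq_len(n_steps)) {
      state$rec <- NULL
      state <- sim_step(state)
    }
    state$rec <- keep
    return(state)
  }
  # preallocate the record to avoid quadratic rbind growth
  old <- state$rec
  n_old <- if (is.null(old)) 0L else nrow(old)
  rec <- matrix(NA_real_, n_old + n_steps, length(REC_SERIES),
                dimnames = list(NULL, REC_SERIES))
  if (n_old) rec[seq_len(n_old), ] <- old
  for (k in seq_len(n_steps)) {
    state$rec <- NULL
    state <- sim_step(state)
    rec[n_old + k, ] <- state$rec[1L, ]
  }
  state$rec <- rec
  state
}

# periodic EBV antigen reinjection for EBV-exposed subjects
maybe_reinject_ebv <- function(state) {
  if (is.na(state$ebv_pep)) return(state)
  cal <- state$cfg$cal
  every <- max(1L, as.integer(round(cal$ebv_reactivation_days / state$cfg$dt)))
  if (state$clock %% every == 0L) {
    S <- state$cfg$latt$n_sites
    tgt <- sample.int(S, cal$ebv_units, replace = TRUE)
    state$fields[[cLN]][, mEBV] <- state$fields[[cLN]][, mEBV] + tabulate(tgt, S)
  }
  state
}
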
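# Bernoulli interaction rules.  Every rule is a declarative object naming a
# vectorised handler; the engine executes the active registry once per step
# in a fresh random order, shuffling actor and partner lists inside each
# rule.  A rule never touches entities outside the actor's lattice site, and
# agents created by a rule are buffered and join the population only after
# the whole interaction phase (so they cannot act within the same step);
# agents deleted by a rule are removed immediately (so they cannot act in a
# later rule of the same step).

#' Construct an interaction rule
#'
#' @param rule_name Unique identifier.
#' @param handler Name of a built-in rule handler.
#' @param compartment `"lymph_node"`, `"white_matter"` or `"both"`.
#' @param specificity `"specific"` (receptor/ligand Hamming binding) or
#'   `"aspecific"` (fixed probability).
#' @param params Named list of per-rule overrides (e.g. `p` for an aspecific
#'   probability).
#' @return An object of class `interaction_rule`.
#' @export
interaction_rule <- function(rule_name, handler,
                             compartment = c("both", "lymph_node",
                                             "white_matter"),
                             specificity = c("aspecific", "specific"),
                             params = list()) {
  compartment <- match.arg(compartment)
  specificity <- match.arg(specificity)
  if (!handler %in% names(.rule_handlers()))
    stop("unknown rule handler: ", handler)
  structure(list(rule_name = rule_name, handler = handler,
                 compartment = compartment, specificity = specificity,
                 params = params),
            class = "interaction_rule")
}

rule_comps <- function(rule) {
  switch(rule$compartment, both = c(cLN, cWM),
         lymph_node = cLN, white_matter = cWM)
}

#' Core (pathogen-independent) interaction rule registry
#'
#' The standard immune-machinery rules: immunocomplex formation, antigen
#' capture and presentation by B cells, macrophages and dendritic cells,
#' T-helper priming with interleukin secretion and B-cell differentiation
#' into plasma/memory cells, IL-2-gated cytotoxic T-cell priming, clonal
#' division up to the Hayflick limit, memory formation, regulatory T-cell
#' activation, and antibody-dependent (ADCC) killing of opsonized cells.
#'
#' @return Named list of [interaction_rule()] objects.
#' @export
core_rules <- function() {
  rl <- list(
    interaction_rule("IG_Ag", "h_ig_ag", "both", "aspecific"),
    interaction_rule("B_Antigen", "h_b_capture", "both", "specific"),
    interaction_rule("M_Antigen", "h_apc_capture", "both", "aspecific",
                     list(type = "M")),
    interaction_rule("DC_Antigen", "h_apc_capture", "both", "aspecific",
                     list(type = "CDC")),
    interaction_rule("TH_APC", "h_th_priming", "both", "specific"),
    interaction_rule("TC_priming", "h_tc_priming", "both", "specific"),
    interaction_rule("clonal_division", "h_duplication", "both", "aspecific"),
    interaction_rule("memory_formation", "h_memory", "both", "aspecific"),
    interaction_rule("Treg_activation", "h_treg", "both", "aspecific"),
    interaction_rule("Treg_suppression", "h_suppression", "both",
                     "aspecific"),
    interaction_rule("ADCC_kill", "h_adcc", "both", "aspecific")
  )
  stats::setNames(rl, vapply(rl, `[[`, "", "rule_name"))
}

#' Append the five MS-specific autoimmune rules
#'
#' Adds: (1) dendritic-cell cross-presentation of oligodendrocyte-derived
#' antigen as peptide/MHC-I without B7 costimulation (folded into antigen
#' capture, flagged by the self/no-B7 marker); (2) activation of auto-reactive
#' cytotoxic clones by no-B7 APCs, with probability proportional to the
#' peripheral-tolerance impairment (zero in a healthy subject); (3) IgG
#' opsonization of oligodendrocytes; (4) macrophage killing of opsonized
#' oligodendrocytes with chemokine release; (5) MHC-I-restricted killing of
#' oligodendrocytes by activated cytotoxic T cells with chemokine release.
#' Spontaneous (lesion-load-mapped) oligodendrocyte apoptosis is registered
#' here as well.
#'
#' @param registry A rule registry, e.g. [core_rules()].
#' @return Extended registry.
#' @export
register_ms_rules <- function(registry) {
  ms <- list(
    interaction_rule("ODC_apoptosis", "h_odc_apoptosis", "white_matter",
                     "aspecific"),
    interaction_rule("ODC_IgG_opsonization", "h_opsonize", "white_matter",
                     "aspecific"),
    interaction_rule("M_opsonized_ODC", "h_m_kill_ops", "white_matter",
                     "aspecific"),
    interaction_rule("TC_ODC_kill", "h_tc_kill", "white_matter", "specific"),
    interaction_rule("B_cell_opsonization", "h_ocrelizumab", "both",
                     "aspecific")
  )
  names(ms) <- vapply(ms, `[[`, "", "rule_name")
  dup <- intersect(names(ms), names(registry))
  if (length(dup)) stop("duplicate rule registration: ",
                        paste(dup, collapse = ", "))
  c(registry, ms)
}

#' Write / read a rule registry as YAML
#'
#' @param registry Named list of [interaction_rule()]s.
#' @param path File path.
#' @return `read_rules` returns the registry.
#' @export
write_rules <- function(registry, path) {
  yaml::write_yaml(lapply(unname(registry), unclass), path)
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  rl <- lapply(raw, function(r)
    interaction_rule(r$rule_name, r$handler, r$compartment, r$specificity,
                     if (is.null(r$params)) list() else r$params))
  stats::setNames(rl, vapply(rl, `[[`, "", "rule_name"))
}

#' Execute the interaction phase
#'
#' Runs every rule of the registry once, in a fresh random order; malformed
#' registries fail at load time, never mid-run.  Buffered agent creations
#' are flushed after the last rule.
#'
#' @param state Simulation state.
#' @param rules Rule registry.
#' @return Updated state.
#' @export
execute_interactions <- function(state, rules = state$rules) {
  state$pending <- list()
  for (rule in rules[sample.int(length(rules))]) {
    h <- .rule_handlers()[[rule$handler]]
    state <- h(state, rule)
  }
  for (na in state$pending) state$ag <- ag_bind(state$ag, na)
  state$pending <- NULL
  state
}

# -- pair machinery ---------------------------------------------------------

# All (actor, partner) index pairs sharing a lattice site.
pair_expand <- function(actor_sites, partner_idx, partner_sites, n_sites) {
  ord <- order(partner_sites)
  cnt <- tabulate(partner_sites, n_sites)
  start <- cumsum(c(0L, cnt))
  k <- cnt[actor_sites]
  ai <- rep(seq_along(actor_sites), k)
  if (!length(ai)) return(list(ai = integer(0), pi = integer(0)))
  first <- start[actor_sites] + 1L
  pos <- sequence(k) + rep(first, k) - 1L
  list(ai = ai, pi = partner_idx[ord][pos])
}

# Sequential Bernoulli scan: every actor tests its partners in a random
# order until the first success.  Returns, per pair row, whether that pair
# is the actor's winning interaction.  P(actor has any success with n
# partners of probability q) is exactly 1 - (1-q)^n.
bernoulli_scan <- function(ai, q) {
  n <- length(ai)
  if (!n) return(logical(0))
  hit <- stats::runif(n) < q
  ord <- order(ai, stats::runif(n))   # random partner order within actor
  h <- hit[ord]
  a <- ai[ord]
  sel <- logical(n)
  idx <- which(h)
  if (length(idx)) sel[idx[!duplicated(a[idx])]] <- TRUE
  out <- logical(n)
  out[ord] <- sel
  out
}

# Per-receptor best binding probability against a peptide through any allele.
best_bind <- function(recep, pep, alleles, params) {
  q <- rep(0, length(recep))
  for (al in alleles) {
    aff <- popcount(bitwXor(recep, mhc_complex(al, pep)))
    q <- pmax(q, bind_probability(aff, params))
  }
  q
}

# Vectorised over pairs with per-pair peptides.
best_bind_pairs <- function(recep, peps, alleles, params) {
  q <- rep(0, length(recep))
  for (al in alleles) {
    aff <- popcount(bitwXor(recep, bitwXor(al, peps)))
    q <- pmax(q, bind_probability(aff, params))
  }
  q
}

# Suppression by anti-inflammatory cytokines (IL-10 + TGF-beta).  The
# suppressive tone is systemic within a compartment (cytokines circulate),
# so the per-site factor is computed from the compartment mean
# concentration; returned as a per-site vector for uniform indexing.
site_suppression <- function(state, cp) {
  f <- state$fields[[cp]]
  S <- state$cfg$latt$n_sites
  tone <- (sum(f[, mIL10]) + sum(f[, mTGFB])) /
    (state$cfg$cal$k_suppression * S)
  rep(1 / (1 + tone), S)
}

queue_agents <- function(state, na) {
  state$pending[[length(state$pending) + 1L]] <- na
  state
}

# -- handlers ---------------------------------------------------------------

.handlers_env <- new.env(parent = emptyenv())
.rule_handlers <- function() {
  if (is.null(.handlers_env$h)) {
    .handlers_env$h <- list(
      h_ig_ag = h_ig_ag, h_b_capture = h_b_capture,
      h_apc_capture = h_apc_capture, h_th_priming = h_th_priming,
      h_tc_priming = h_tc_priming, h_duplication = h_duplication,
      h_memory = h_memory, h_treg = h_treg, h_suppression = h_suppression,
      h_adcc = h_adcc,
      h_odc_apoptosis = h_odc_apoptosis, h_opsonize = h_opsonize,
      h_m_kill_ops = h_m_kill_ops, h_tc_kill = h_tc_kill,
      h_ocrelizumab = h_ocrelizumab)
  }
  .handlers_env$h
}

rule_p <- function(state, rule, name, default_name = name) {
  if (!is.null(rule$params[[name]])) rule$params[[name]]
  else state$cfg$cal[[default_name]]
}

# Soluble immunoglobulin + free antigen -> immunocomplex (consumes both).
h_ig_ag <- function(state, rule) {
  p <- rule_p(state, rule, "p", "p_ig_ag")
  for (cp in rule_comps(rule)) {
    f <- state$fields[[cp]]
    for (ag_sp in c(mMBP, mEBV)) {
      n <- pmin(f[, mIGG], f[, ag_sp])
      pos <- n > 0L
      if (!any(pos)) next
      formed <- stats::rbinom(sum(pos), n[pos], p)
      f[pos, mIGG] <- f[pos, mIGG] - formed
      f[pos, ag_sp] <- f[pos, ag_sp] - formed
      f[pos, mIC] <- f[pos, mIC] + formed
    }
    state$fields[[cp]] <- f
  }
  state
}

# Capturable antigen units at each site: myelin basic protein, viral antigen
# and immunocomplexes.  Returns the per-site total and a sampler that picks
# which species a successful capture consumed.
capture_fields <- c(mMBP, mEBV, mIC)

# Aspecific antigen capture by macrophages or dendritic cells.  A dendritic
# cell cross-presents as peptide/MHC-I (PresI); since oligodendrocyte-derived
# antigen is self, B7 costimulation stays off for it.  Macrophages present
# through MHC-II (PresII).
h_apc_capture <- function(state, rule) {
  type <- match(rule$params$type, TYPES)
  p <- rule_p(state, rule, "p", "p_capture_apc") *
    state$effects$mhc2_presentation_scale * (state$hla_boost %||% 1)
  a <- state$ag
  for (cp in rule_comps(rule)) {
    f <- state$fields[[cp]]
    tot <- f[, mMBP] + f[, mEBV] + f[, mIC]
    sel <- which(a$type == type & a$state == sRES & a$comp == cp)
    if (!length(sel)) next
    n <- tot[a$pos[sel]]
    cand <- sel[n > 0L]
    if (!length(cand)) next
    psucc <- 1 - (1 - p)^tot[a$pos[cand]]
    win <- cand[stats::runif(length(cand)) < psucc]
    if (!length(win)) next
    for (i in win) {
      s <- a$pos[i]
      avail <- c(f[s, mMBP], f[s, mEBV], f[s, mIC])
      if (sum(avail) == 0L) next
      pick <- sample.int(3L, 1L, prob = avail)
      sp <- capture_fields[pick]
      f[s, sp] <- f[s, sp] - 1L
      is_self <- pick != 2L           # MBP or IgG-MBP immunocomplex
      a$state[i] <- if (type == iCDC) sP1 else sP2
      a$pep[i] <- if (is_self) state$ctx$mbp_peptide else state$ebv_pep
      a$noB7[i] <- is_self
    }
    state$fields[[cp]] <- f
  }
  state$ag <- a
  state
}

# Specific antigen capture by naive B cells through their membrane Ig.
h_b_capture <- function(state, rule) {
  params <- state$cfg$params
  a <- state$ag
  for (cp in rule_comps(rule)) {
    f <- state$fields[[cp]]
    sel <- which(a$type == iB & a$state == sRES & a$comp == cp)
    if (!length(sel)) next
    for (ag_sp in c(mMBP, mEBV)) {
      ag_str <- if (ag_sp == mMBP) state$ctx$mbp_peptide else state$ebv_pep
      if (is.na(ag_str)) next
      n <- f[a$pos[sel], ag_sp]
      cand <- sel[n > 0L & a$state[sel] == sRES]
      if (!length(cand)) next
      q <- bind_probability(popcount(bitwXor(a$recep[cand], ag_str)), params) *
        state$effects$mhc2_presentation_scale
      psucc <- 1 - (1 - q)^f[a$pos[cand], ag_sp]
      win <- cand[stats::runif(length(cand)) < psucc]
      # several B cells may contend for few units at a site: cap consumption
      if (!length(win)) next
      tab <- table(a$pos[win])
      for (s in as.integer(names(tab))) {
        at_s <- win[a$pos[win] == s]
        take <- min(length(at_s), f[s, ag_sp])
        if (take < length(at_s)) at_s <- at_s[seq_len(take)]
        f[s, ag_sp] <- f[s, ag_sp] - take
        a$state[at_s] <- sP2
        a$pep[at_s] <- ag_str
        a$noB7[at_s] <- ag_sp == mMBP
      }
    }
    state$fields[[cp]] <- f
  }
  state$ag <- a
  state
}

# T-helper priming against MHC-II-presenting APCs; successful help to a
# presenting B cell differentiates it into a plasma cell plus a memory B
# cell.  Priming against self-presenting (no-B7) APCs is gated by the
# peripheral-tolerance impairment and local suppressive cytokines.
h_th_priming <- function(state, rule) {
  a <- state$ag
  cal <- state$cfg$cal
  dis <- state$cfg$disease
  params <- state$cfg$params
  for (cp in rule_comps(rule)) {
    actors <- which(a$type == iTH & a$state == sRES & a$comp == cp)
    partners <- which(a$state == sP2 & a$comp == cp &
                        a$type %in% c(iB, iM, iCDC))
    if (!length(actors) || !length(partners)) next
    pr <- pair_expand(a$pos[actors], partners, a$pos[partners],
                      state$cfg$latt$n_sites)
    if (!length(pr$ai)) next
    supp <- site_suppression(state, cp)^cal$suppression_exponent
    q <- best_bind_pairs(a$recep[actors[pr$ai]], a$pep[pr$pi],
                         state$ctx$mhc2_alleles, params)
    gate <- ifelse(a$noB7[pr$pi], dis$peripheral_tolerance_impairment, 1)
    q <- pmin(q * gate * cal$priming_scale * dis$immune_reactivity *
                supp[a$pos[actors[pr$ai]]], 1)
    winpair <- bernoulli_scan(pr$ai, q)
    if (any(winpair)) {
      wa <- actors[pr$ai[winpair]]
      wp <- pr$pi[winpair]
      a$state[wa] <- sACT
      a$mem[wa] <- FALSE
      a$th2[wa] <- stats::runif(length(wa)) < state$effects$th1_to_th2_shift
      # B-cell differentiation: only self-reactive (autoantigen-binding)
      # clones feed the pathogenic IgG pool tracked by the model
      bsel <- unique(wp[a$type[wp] == iB])
      if (length(bsel)) {
        qb <- bind_probability(popcount(bitwXor(a$recep[bsel],
                                                state$ctx$mbp_peptide)),
                               params)
        bsel <- bsel[qb > 0]
        if (length(bsel)) {
          state <- queue_agents(state, ag_new(length(bsel), iP, sACT, cp,
                                              a$pos[bsel]))
          mem_rec <- a$recep[bsel]
          # hypermutation: one random bit flip per differentiation event
          flip <- stats::runif(length(bsel)) < cal$p_hypermutation
          if (any(flip)) {
            bit <- sample.int(params$bitstring_length, sum(flip),
                              replace = TRUE) - 1L
            mem_rec[flip] <- bitwXor(mem_rec[flip],
                                     bitwShiftL(1L, bit))
          }
          state <- queue_agents(state, ag_new(length(bsel), iB, sRES, cp,
                                              a$pos[bsel], mem_rec,
                                              mem = TRUE))
          drop <- rep(FALSE, ag_n(a)); drop[bsel] <- TRUE
          a <- ag_keep(a, !drop)
          # re-run loop safely: indices invalidated; stop this compartment
          state$ag <- a
          next
        }
      }
    }
    # anergy induction after unproductive self (no-B7) engagement
    if (cal$p_anergy > 0) {
      had_self <- unique(pr$ai[a$noB7[pr$pi]])
      won <- unique(pr$ai[winpair])
      lose <- setdiff(had_self, won)
      if (length(lose)) {
        an <- actors[lose][stats::runif(length(lose)) < cal$p_anergy]
        a$state[an] <- sANE
      }
    }
  }
  state$ag <- a
  state
}

# Cytotoxic T-cell priming against MHC-I-presenting dendritic cells,
# requiring local IL-2, and gated by the peripheral-tolerance impairment
# when the APC presents self without B7.
h_tc_priming <- function(state, rule) {
  a <- state$ag
  cal <- state$cfg$cal
  dis <- state$cfg$disease
  params <- state$cfg$params
  for (cp in rule_comps(rule)) {
    f <- state$fields[[cp]]
    actors <- which(a$type == iTC & a$state == sRES & a$comp == cp)
    partners <- which(a$state == sP1 & a$comp == cp)
    if (!length(actors) || !length(partners)) next
    pr <- pair_expand(a$pos[actors], partners, a$pos[partners],
                      state$cfg$latt$n_sites)
    if (!length(pr$ai)) next
    supp <- site_suppression(state, cp)^cal$suppression_exponent
    q <- best_bind_pairs(a$recep[actors[pr$ai]], a$pep[pr$pi],
                         state$ctx$mhc1_alleles, params)
    gate <- ifelse(a$noB7[pr$pi], dis$peripheral_tolerance_impairment, 1)
    il2 <- f[a$pos[actors[pr$ai]], mIL2] > 0
    q <- pmin(q * gate * cal$priming_scale * dis$immune_reactivity *
                supp[a$pos[actors[pr$ai]]] * il2, 1)
    winpair <- bernoulli_scan(pr$ai, q)
    if (any(winpair)) {
      wa <- actors[unique(pr$ai[winpair])]
      a$state[wa] <- sACT
      a$mem[wa] <- FALSE
    }
    if (cal$p_anergy > 0) {
      had_self <- unique(pr$ai[a$noB7[pr$pi]])
      won <- unique(pr$ai[winpair])
      lose <- setdiff(had_self, won)
      if (length(lose)) {
        an <- actors[lose][stats::runif(length(lose)) < cal$p_anergy]
        a$state[an] <- sANE
      }
    }
  }
  state$ag <- a
  state
}

# Clonal division of activated T cells (IL-2 dependent, Hayflick-limited);
# the proliferation multiplier carries the teriflunomide effect.  Expansion
# happens in lymphoid tissue only; effectors in the white matter are
# terminally differentiated.
h_duplication <- function(state, rule) {
  a <- state$ag
  cal <- state$cfg$cal
  p <- cal$p_div * state$effects$proliferation_multiplier
  for (cp in cLN) {
    f <- state$fields[[cp]]
    sel <- which(a$type %in% c(iTH, iTC) & a$state == sACT & a$comp == cp &
                   a$div < cal$hayflick_limit)
    if (!length(sel)) next
    sel <- sel[f[a$pos[sel], mIL2] > 0]
    if (!length(sel)) next
    win <- sel[stats::runif(length(sel)) < p]
    if (!length(win)) next
    a$div[win] <- a$div[win] + 1L
    state <- queue_agents(state, list(
      type = a$type[win], state = rep(sACT, length(win)),
      comp = a$comp[win], pos = a$pos[win], recep = a$recep[win],
      pep = a$pep[win], div = a$div[win], mem = rep(FALSE, length(win)),
      th2 = a$th2[win], noB7 = rep(FALSE, length(win))))
  }
  state$ag <- a
  state
}

# Activated T cells convert to long-lived resting memory at a small rate.
h_memory <- function(state, rule) {
  a <- state$ag
  sel <- which(a$type %in% c(iTH, iTC) & a$state == sACT)
  if (length(sel)) {
    win <- sel[stats::runif(length(sel)) < state$cfg$cal$p_mem]
    if (length(win)) {
      a$state[win] <- sRES
      a$mem[win] <- TRUE
    }
  }
  state$ag <- a
  state
}

# Regulatory T-cell activation: tonic self-recognition plus an
# inflammation-driven component (local antigen presentation or IL-2), damped
# by the peripheral-tolerance impairment (the model's regulatory
# malfunction), by vitamin D / smoking factors, and boosted under IFN-beta1a.
h_treg <- function(state, rule) {
  a <- state$ag
  cal <- state$cfg$cal
  dis <- state$cfg$disease
  mod <- max(1 - cal$treg_impair_weight * dis$peripheral_tolerance_impairment,
             cal$treg_floor) * dis$treg_scale * state$effects$treg_boost
  # inflammation is sensed systemically: mean IL-2 per site over both
  # compartments (effectors secrete mostly in the white matter while
  # regulatory T cells sit in the lymph node)
  S <- state$cfg$latt$n_sites
  il2_tone <- (sum(state$fields[[cLN]][, mIL2]) +
                 sum(state$fields[[cWM]][, mIL2])) / (2 * S)
  infl <- il2_tone > cal$il2_treg_threshold
  p <- pmin(1, (cal$treg_tonic + cal$treg_pres_bonus * infl) * mod)
  for (cp in 1:2) {
    sel <- which(a$type == iTREG & a$state == sRES & a$comp == cp)
    if (!length(sel)) next
    win <- sel[stats::runif(length(sel)) < p]
    a$state[win] <- sACT
  }
  state$ag <- a
  state
}

# Regulatory suppression: active effector T cells are shut down
# (activation-induced death) at a rate that grows with the local
# suppressive cytokine load (IL-10 + TGF-beta).
h_suppression <- function(state, rule) {
  a <- state$ag
  cal <- state$cfg$cal
  drop <- logical(ag_n(a))
  for (cp in 1:2) {
    sel <- which((a$type == iTH | a$type == iTC) & a$state == sACT &
                   a$comp == cp)
    if (!length(sel)) next
    supp <- site_suppression(state, cp)
    p <- cal$deact_max * (1 - supp[a$pos[sel]])
    drop[sel[stats::runif(length(sel)) < p]] <- TRUE
  }
  if (any(drop)) state$ag <- ag_keep(a, !drop)
  state
}

# Antibody-dependent killing of cells flagged BoundToAb (NK/complement).
h_adcc <- function(state, rule) {
  a <- state$ag
  sel <- a$state == sBAB
  if (any(sel)) {
    die <- sel & stats::runif(ag_n(a)) < state$cfg$cal$p_adcc
    if (any(die)) state$ag <- ag_keep(a, !die)
  }
  state
}

# Spontaneous oligodendrocyte apoptosis releasing myelin basic protein.
h_odc_apoptosis <- function(state, rule) {
  odc_apoptosis_step(state, state$cfg$disease)
}

# IgG opsonization of oligodendrocytes (antibody-coated, CDC/ADCC-eligible).
h_opsonize <- function(state, rule) {
  p <- rule_p(state, rule, "p", "p_opsonize")
  f <- state$fields[[cWM]]
  n <- pmin(f[, mIGG], state$odc)
  pos <- n > 0L
  if (any(pos)) {
    k <- stats::rbinom(sum(pos), n[pos], p)
    state$odc[pos] <- state$odc[pos] - k
    state$odc_ops[pos] <- state$odc_ops[pos] + k
    f[pos, mIGG] <- f[pos, mIGG] - k
    state$fields[[cWM]] <- f
  }
  state
}

# Activated macrophages kill opsonized oligodendrocytes, releasing antigen
# and chemokines in situ.
h_m_kill_ops <- function(state, rule) {
  p <- rule_p(state, rule, "p", "p_kill_m")
  a <- state$ag
  cal <- state$cfg$cal
  S <- state$cfg$latt$n_sites
  sel <- which(a$type == iM & a$comp == cWM & a$state != sRES)
  if (!length(sel)) return(state)
  n <- state$odc_ops[a$pos[sel]]
  cand <- sel[n > 0L]
  if (!length(cand)) return(state)
  psucc <- 1 - (1 - p)^state$odc_ops[a$pos[cand]]
  win <- cand[stats::runif(length(cand)) < psucc]
  if (!length(win)) return(state)
  kills <- pmin(tabulate(a$pos[win], S), state$odc_ops)
  state$odc_ops <- state$odc_ops - kills
  f <- state$fields[[cWM]]
  f[, mMBP] <- f[, mMBP] + kills * cal$mbp_per_death
  f[, mCHEM] <- f[, mCHEM] + kills * cal$chem_per_kill
  state$fields[[cWM]] <- f
  state
}

# Activated cytotoxic T cells kill oligodendrocytes through the MBP/MHC-I
# complex; each killing releases myelin antigen and chemokines locally.
h_tc_kill <- function(state, rule) {
  a <- state$ag
  cal <- state$cfg$cal
  S <- state$cfg$latt$n_sites
  params <- state$cfg$params
  sel <- which(a$type == iTC & a$comp == cWM & a$state %in% c(sACT, sDUP))
  if (!length(sel)) return(state)
  tgt <- state$odc + state$odc_ops
  n <- tgt[a$pos[sel]]
  cand <- sel[n > 0L]
  if (!length(cand)) return(state)
  q <- best_bind(a$recep[cand], state$ctx$mbp_peptide,
                 state$ctx$mhc1_alleles, params)
  psucc <- 1 - (1 - q)^pmin(tgt[a$pos[cand]], cal$tc_scan_cap)
  win <- cand[stats::runif(length(cand)) < psucc]
  if (!length(win)) return(state)
  kills <- pmin(tabulate(a$pos[win], S), tgt)
  # plain oligodendrocytes are hit first, then opsonized ones
  k1 <- pmin(kills, state$odc)
  k2 <- kills - k1
  state$odc <- state$odc - k1
  state$odc_ops <- state$odc_ops - k2
  f <- state$fields[[cWM]]
  f[, mMBP] <- f[, mMBP] + kills * cal$mbp_per_death
  f[, mCHEM] <- f[, mCHEM] + kills * cal$chem_per_kill
  state$fields[[cWM]] <- f
  state
}

# Anti-CD20 therapy: circulating B cells (not plasma cells) become
# antibody-bound targets for NK/ADCC killing while the drug is active.
h_ocrelizumab <- function(state, rule) {
  if (!state$effects$b_cell_opsonization_active) return(state)
  a <- state$ag
  sel <- which(a$type == iB & a$state != sBAB)
  if (length(sel)) {
    win <- sel[stats::runif(length(sel)) < state$cfg$cal$p_anti_cd20]
    a$state[win] <- sBAB
  }
  state$ag <- a
  state
}
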
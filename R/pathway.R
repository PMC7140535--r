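# Molecular-pathway sub-model: an ODE network of de-novo pyrimidine
# biosynthesis whose DHODH step is inhibited non-competitively by
# teriflunomide.  The network ships as an editable YAML fixture (29 species,
# 13 enzymatic reactions); integration uses deSolve.

#' Load a reaction-network pathway model
#'
#' Reads the documented YAML network format: a species block (initial
#' concentration, nitrogen content for the conservation check, boundary
#' flag) and a reaction block (mass-action or Michaelis-Menten kinetic laws,
#' with an optional non-competitive inhibitor on one reaction).
#'
#' @param path Network file; default the bundled teriflunomide network.
#' @return An object of class `pathway_model`.
#' @export
load_pathway_model <- function(path = system.file("extdata",
                                                  "teriflunomide_network.yaml",
                                                  package = "mssim")) {
  net <- yaml::read_yaml(path)
  spn <- names(net$species)
  nsp <- length(spn)
  nrx <- length(net$reactions)
  stoich <- matrix(0, nsp, nrx, dimnames = list(spn, NULL))
  for (j in seq_len(nrx)) {
    rx <- net$reactions[[j]]
    bad <- setdiff(c(names(rx$substrates), names(rx$products)), spn)
    if (length(bad))
      stop("reaction ", rx$name, " references undeclared species: ",
           paste(bad, collapse = ", "))
    for (s in names(rx$substrates))
      stoich[s, j] <- stoich[s, j] - rx$substrates[[s]]
    for (s in names(rx$products))
      stoich[s, j] <- stoich[s, j] + rx$products[[s]]
    if (!rx$law %in% c("mass_action", "michaelis_menten"))
      stop("unknown kinetic law: ", rx$law)
    if (rx$law == "mass_action" && (is.null(rx$k) || rx$k <= 0))
      stop("mass-action reaction ", rx$name, " needs k > 0")
    if (rx$law == "michaelis_menten" &&
        (is.null(rx$vmax) || rx$vmax <= 0 || is.null(rx$km) || rx$km <= 0))
      stop("Michaelis-Menten reaction ", rx$name, " needs vmax, km > 0")
  }
  colnames(stoich) <- vapply(net$reactions, `[[`, "", "name")
  structure(list(species = net$species, reactions = net$reactions,
                 stoich = stoich,
                 boundary = vapply(net$species, function(s)
                   isTRUE(s$boundary), TRUE),
                 init = vapply(net$species, function(s) as.numeric(s$init), 0),
                 nitrogen = vapply(net$species, function(s)
                   as.numeric(s$nitrogen), 0),
                 readout_reaction = net$readout_reaction,
                 inhibited_reaction = net$inhibited_reaction,
                 dose_to_concentration = net$dose_to_concentration),
            class = "pathway_model")
}

# Per-reaction rates at concentrations y (named).  Co-substrates of an MM
# reaction saturate with a small generic half-constant so a depleted
# co-substrate stalls the reaction.
pathway_rates <- function(y, model, clamp_boundary = TRUE) {
  y <- pmax(y, 0)
  rates <- vapply(model$reactions, function(rx) {
    subs <- names(rx$substrates)
    if (rx$law == "mass_action") {
      v <- rx$k
      for (s in subs) v <- v * y[[s]]^rx$substrates[[s]]
    } else {
      s0 <- rx$mm_substrate
      v <- rx$vmax * y[[s0]] / (rx$km + y[[s0]])
      for (s in setdiff(subs, s0)) v <- v * y[[s]] / (y[[s]] + 0.05)
      if (!is.null(rx$inhibitor)) {
        v <- v / (1 + y[[rx$inhibitor]] / rx$ki)
      }
    }
    v
  }, 0)
  names(rates) <- vapply(model$reactions, `[[`, "", "name")
  rates
}

pathway_derivs <- function(t, y, parms) {
  model <- parms$model
  rates <- pathway_rates(y, model)
  dy <- as.numeric(model$stoich %*% rates)
  names(dy) <- rownames(model$stoich)
  if (parms$clamp) dy[model$boundary] <- 0
  list(dy)
}

#' Integrate a pathway model
#'
#' @param model A [pathway_model()].
#' @param inhibitor_conc Concentration of the inhibitor species.
#' @param t_end Integration horizon (default 400 time units, long enough for
#'   the downstream fluxes to reach steady state).
#' @param clamp_boundary Clamp boundary species (default TRUE); disabling
#'   this closes the system, under which total nitrogen is conserved.
#' @return deSolve output matrix (time course of every species).
#' @export
integrate_pathway <- function(model, inhibitor_conc = 0, t_end = 400,
                              clamp_boundary = TRUE) {
  y0 <- model$init
  if (!is.null(model$inhibited_reaction)) {
    inh <- NULL
    for (rx in model$reactions)
      if (identical(rx$name, model$inhibited_reaction)) inh <- rx$inhibitor
    if (!is.null(inh)) y0[[inh]] <- inhibitor_conc
  }
  out <- deSolve::ode(y = y0, times = seq(0, t_end, length.out = 81),
                      func = pathway_derivs,
                      parms = list(model = model, clamp = clamp_boundary),
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  if (attr(out, "istate")[1L] < 0) stop("pathway integration failed")
  out
}

# Readout flux (rate of the demand reaction) at the final time point.
pathway_readout_flux <- function(model, inhibitor_conc = 0, t_end = 400) {
  out <- integrate_pathway(model, inhibitor_conc, t_end)
  yT <- out[nrow(out), -1L]
  rates <- pathway_rates(yT, model)
  unname(rates[[model$readout_reaction]])
}

#' Teriflunomide proliferation multiplier
#'
#' Integrates the pyrimidine-biosynthesis network to steady state with the
#' intracellular inhibitor concentration proportional to the daily dose, and
#' returns the steady-state nucleic-acid-demand flux relative to the
#' uninhibited flux.  The value multiplies T- and B-cell proliferation in the
#' main simulation: 1 at dose zero, strictly decreasing with dose.
#'
#' @param dose Daily dose in mg (>= 0).
#' @param model A [pathway_model()].
#' @return Multiplier in `(0, 1]`.
#' @examples
#' \dontrun{teriflunomide_multiplier(14)}
#' @export
teriflunomide_multiplier <- function(dose, model = load_pathway_model()) {
  if (dose < 0) stop("dose must be >= 0")
  if (dose == 0) return(1)
  flux0 <- pathway_readout_flux(model, 0)
  conc <- dose * model$dose_to_concentration
  flux <- pathway_readout_flux(model, conc)
  min(flux / flux0, 1)
}
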
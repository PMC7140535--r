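# High-level drivers: run a full disease course, healthy and reference MS
# scenarios, and scenario files.

#' Simulate a disease course
#'
#' Initializes a state and runs it for the requested horizon, returning the
#' per-step trajectories and the detected relapse events.
#'
#' @param disease [disease_params()]; defaults to a healthy control with the
#'   minimal background apoptosis rate.
#' @param horizon_years Simulated time (default 4.5 years).
#' @param seed Master seed.
#' @param wm [white_matter_config()].
#' @param plans List of [treatment_plan()]s.
#' @param risk Optional [risk_factor_profile()].
#' @param pregnancy_intervals Optional data frame with `start_day`,
#'   `end_day`: tolerance impairments are strengthened inside the intervals.
#' @param calibration Calibration constants.
#' @param scale Population scale factor.
#' @param lattice_side Lattice side length.
#' @param record Keep per-step trajectories (default TRUE).
#' @param dt_hours Step duration (default 8 h).
#' @return An object of class `ms_course`: list with `trajectories` (data
#'   frame, one row per step), `relapses`, `inflammatory`, `final_state`,
#'   and scalar summaries.
#' @export
simulate_course <- function(disease = NULL,
                            horizon_years = 4.5,
                            seed = 1L,
                            wm = white_matter_config(),
                            plans = list(),
                            risk = NULL,
                            pregnancy_intervals = NULL,
                            calibration = default_calibration(),
                            scale = 1,
                            lattice_side = 16L,
                            record = TRUE,
                            dt_hours = 8) {
  cal <- calibration
  if (is.null(disease)) {
    if (!is.null(risk)) disease <- map_patient_to_params(risk, cal)
    else disease <- healthy_control_params(cal)
  }
  n_steps <- as.integer(round(horizon_years * 365 * 24 / dt_hours))
  state <- init_state(disease = disease, wm = wm, plans = plans, risk = risk,
                      calibration = cal, scale = scale,
                      lattice_side = lattice_side, seed = seed,
                      dt_hours = dt_hours)
  if (!is.null(pregnancy_intervals) && nrow(pregnancy_intervals)) {
    state <- run_with_pregnancy(state, n_steps, pregnancy_intervals, cal)
  } else {
    state <- run_steps(state, n_steps, record = TRUE)
  }
  finish_course(state, wm, record)
}

run_with_pregnancy <- function(state, n_steps, intervals, cal) {
  base <- state$cfg$disease
  rec <- matrix(NA_real_, n_steps, length(REC_SERIES),
                dimnames = list(NULL, REC_SERIES))
  for (k in seq_len(n_steps)) {
    day <- state$clock * state$cfg$dt
    preg <- any(day >= intervals$start_day & day <= intervals$end_day)
    state$cfg$disease <- apply_pregnancy_modulation(base, preg,
                                                   cal$pregnancy_factor)
    state$rec <- NULL
    state <- sim_step(state)
    rec[k, ] <- state$rec[1L, ]
  }
  state$cfg$disease <- base
  state$rec <- rec
  state
}

finish_course <- function(state, wm, record) {
  rec <- state$rec
  traj <- as.data.frame(rec)
  traj$step <- seq_len(nrow(traj))
  traj$day <- traj$step * state$cfg$dt
  baseline <- state$cfg$odc_baseline
  ev <- detect_relapses(pmin(traj$odc, baseline), wm, baseline = baseline)
  structure(list(
    trajectories = traj,
    relapses = ev$relapses,
    inflammatory = ev$inflammatory,
    relapse_count = nrow(ev$relapses),
    total_odc_loss = sum(pmax(baseline - traj$odc, 0)) * state$cfg$dt,
    peak_odc_loss = max(baseline - min(traj$odc), 0),
    mean_active_th1 = mean(traj$active_th1),
    mean_active_tc = mean(traj$active_tc),
    mean_active_treg = mean(traj$active_treg),
    mean_il2 = mean(traj$il2),
    mean_ifng = mean(traj$ifng),
    baseline_odc = baseline,
    seed = state$cfg$seed,
    final_state = if (record) state else NULL
  ), class = "ms_course")
}

#' @export
print.ms_course <- function(x, ...) {
  cat(sprintf(paste0("ms_course: %d steps, %d relapse(s), peak ODC loss ",
                     "%.0f of %.0f\n"),
              nrow(x$trajectories), x$relapse_count, x$peak_odc_loss,
              x$baseline_odc))
  invisible(x)
}

#' Healthy-control and reference MS parameter sets
#'
#' The healthy control has both tolerance impairments at zero and only the
#' minimal background oligodendrocyte apoptosis; the reference
#' relapsing-remitting parameter set puts both impairments at the
#' calibration's reference level with a moderate lesion-load-equivalent
#' apoptosis rate.
#'
#' @param calibration Calibration constants.
#' @return A [disease_params()] object.
#' @export
healthy_control_params <- function(calibration = default_calibration()) {
  disease_params(odc_apoptosis_prob = calibration$apoptosis_p_min,
                 central_tolerance_impairment = 0,
                 peripheral_tolerance_impairment = 0)
}

#' @rdname healthy_control_params
#' @export
ms_reference_params <- function(calibration = default_calibration()) {
  disease_params(odc_apoptosis_prob = calibration$ms_reference_apoptosis,
                 central_tolerance_impairment =
                   calibration$ms_reference_impairment,
                 peripheral_tolerance_impairment =
                   calibration$ms_reference_impairment)
}

#' Read or write a scenario file
#'
#' Scenario YAML: label, lattice (side, boundary, Mcells, K), repertoire
#' parameters, disease parameters or risk profile, treatment plans, horizon,
#' seed and replicate count.
#'
#' @param path YAML file.
#' @return `read_scenario` returns a named list ready for
#'   [run_scenario()].
#' @export
read_scenario <- function(path) {
  sc <- yaml::read_yaml(path)
  if (is.null(sc$horizon_years)) sc$horizon_years <- 4.5
  if (is.null(sc$seed)) sc$seed <- 1L
  sc
}

#' Run a scenario list
#'
#' @param scenario List from [read_scenario()].
#' @return An `ms_course` object.
#' @export
run_scenario <- function(scenario) {
  disease <- if (!is.null(scenario$disease))
    do.call(disease_params, scenario$disease) else NULL
  risk <- if (!is.null(scenario$risk))
    do.call(risk_factor_profile, scenario$risk) else NULL
  plans <- lapply(scenario$treatments %||% list(), function(p)
    do.call(treatment_plan, p))
  wm <- if (!is.null(scenario$white_matter))
    do.call(white_matter_config, scenario$white_matter)
  else white_matter_config()
  simulate_course(disease = disease, risk = risk, plans = plans, wm = wm,
                  horizon_years = scenario$horizon_years,
                  seed = scenario$seed,
                  scale = scenario$scale %||% 1,
                  lattice_side = scenario$lattice_side %||% 16L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
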
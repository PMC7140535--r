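# Effect-level models of the five disease-modifying drugs.  Each drug acts
# on one or more effect axes of the engine; magnitudes are calibration
# constants, doses and schedules follow the licensed regimens.

DRUGS <- c("ifnb1a", "teriflunomide", "fingolimod", "natalizumab",
           "ocrelizumab")

drug_defaults <- list(
  ifnb1a        = list(dose = 44,  unit = "mcg", schedule = "3x_week"),
  teriflunomide = list(dose = 14,  unit = "mg",  schedule = "daily"),
  fingolimod    = list(dose = 0.5, unit = "mg",  schedule = "daily"),
  natalizumab   = list(dose = 300, unit = "mg",  schedule = "every_4_weeks"),
  ocrelizumab   = list(dose = 600, unit = "mg",  schedule = "every_6_months")
)

#' Treatment plan
#'
#' A drug with its dose, dosing schedule and active window on the simulation
#' calendar.  Defaults reproduce the licensed regimens: IFN-beta1a 44 mcg
#' three times a week; teriflunomide 14 mg daily; fingolimod 0.5 mg daily;
#' natalizumab 300 mg every four weeks; ocrelizumab 600 mg every six months.
#'
#' @param drug One of `"ifnb1a"`, `"teriflunomide"`, `"fingolimod"`,
#'   `"natalizumab"`, `"ocrelizumab"`.
#' @param start_day,end_day Active window in simulation days (`end_day`
#'   `Inf` for open-ended).
#' @param dose Dose per administration (drug default if `NULL`).
#' @return An object of class `treatment_plan`.
#' @export
treatment_plan <- function(drug, start_day = 0, end_day = Inf, dose = NULL) {
  if (!drug %in% DRUGS) stop("unsupported drug: ", drug)
  if (end_day < start_day) stop("treatment window ends before it starts")
  def <- drug_defaults[[drug]]
  structure(list(drug = drug, dose = if (is.null(dose)) def$dose else dose,
                 dose_unit = def$unit, schedule = def$schedule,
                 start_day = start_day, end_day = end_day),
            class = "treatment_plan")
}

#' Expand a dosing schedule to explicit dosing days
#'
#' Deterministic calendar arithmetic over the half-open window
#' `[start_day, end_day)`: three-times-a-week drugs dose on days 0, 2 and 4
#' of each week of the window; daily drugs every day; interval drugs every
#' 28 or 182 days from the window start.  Effects persist between doses
#' (effect-level model, no pharmacokinetic decay).
#'
#' @param plan A [treatment_plan()].
#' @param horizon_days Simulation horizon (days).
#' @return Integer vector of dosing days within the window and horizon.
#' @export
expand_schedule <- function(plan, horizon_days) {
  from <- plan$start_day
  to <- min(plan$end_day, horizon_days)
  if (to <= from) return(integer(0))
  days <- switch(plan$schedule,
    daily = seq(from, to, by = 1),
    "3x_week" = {
      weeks <- seq(from, to, by = 7)
      sort(c(weeks, weeks + 2, weeks + 4))
    },
    every_4_weeks = seq(from, to, by = 28),
    every_6_months = seq(from, to, by = 182),
    stop("unknown schedule: ", plan$schedule))
  as.integer(days[days >= from & days < to])
}

#' Neutral drug-effect state
#'
#' The effect axes consulted by the engine, at their no-drug values:
#' proliferation unchanged, no Th1-to-Th2 shift, full MHC-II presentation,
#' no regulatory boost, free lymph-node egress and white-matter ingress, no
#' B-cell opsonization, IL-17 production on.
#'
#' @return Named list of effect values.
#' @export
neutral_drug_effects <- function() {
  list(proliferation_multiplier = 1, th1_to_th2_shift = 0,
       mhc2_presentation_scale = 1, treg_boost = 1, egress_scale = 1,
       wm_ingress_scale = 1, b_cell_opsonization_active = FALSE,
       il17_suppressed = FALSE)
}

#' Fold active treatment plans into a drug-effect state
#'
#' Evaluates which plans are active at the state's clock and composes their
#' effects: IFN-beta1a shifts Th1 activation towards Th2, reduces MHC-II
#' presentation and boosts regulatory T-cell activity; teriflunomide scales
#' proliferation through the DHODH pathway sub-model; fingolimod closes
#' lymph-node egress and suppresses IL-17 production; natalizumab scales
#' white-matter ingress down; ocrelizumab routes B cells into the
#' opsonization/ADCC killing path.  Overlapping drugs compose
#' multiplicatively on shared axes; outside all windows the neutral state
#' holds.
#'
#' @param state Simulation state (uses clock and calibration).
#' @param plans List of [treatment_plan()]s.
#' @return Effect state as from [neutral_drug_effects()].
#' @export
apply_treatment_effects <- function(state, plans = state$cfg$plans) {
  eff <- neutral_drug_effects()
  if (!length(plans)) return(eff)
  cal <- state$cfg$cal
  day <- state$clock * state$cfg$dt
  for (plan in plans) {
    if (day < plan$start_day || day >= plan$end_day) next
    switch(plan$drug,
      ifnb1a = {
        eff$th1_to_th2_shift <- 1 - (1 - eff$th1_to_th2_shift) *
          (1 - cal$ifnb1a_th1_to_th2)
        eff$mhc2_presentation_scale <- eff$mhc2_presentation_scale *
          cal$ifnb1a_mhc2_scale
        eff$treg_boost <- eff$treg_boost * cal$ifnb1a_treg_boost
      },
      teriflunomide = {
        mult <- if (!is.null(plan$multiplier)) plan$multiplier
        else teriflunomide_multiplier(plan$dose)
        eff$proliferation_multiplier <- eff$proliferation_multiplier * mult
      },
      fingolimod = {
        eff$egress_scale <- eff$egress_scale * cal$fingolimod_egress
        eff$il17_suppressed <- TRUE
      },
      natalizumab = {
        eff$wm_ingress_scale <- eff$wm_ingress_scale *
          cal$natalizumab_ingress
      },
      ocrelizumab = {
        eff$b_cell_opsonization_active <- TRUE
      })
  }
  eff
}

# Precompute the teriflunomide multiplier once per plan list (the pathway
# integration is far too slow to run every step).
precompute_plan_effects <- function(plans) {
  lapply(plans, function(plan) {
    if (plan$drug == "teriflunomide" && is.null(plan$multiplier))
      plan$multiplier <- teriflunomide_multiplier(plan$dose)
    plan
  })
}
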
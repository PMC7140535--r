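# MS-specific biology: oligodendrocyte injury and regeneration, tolerance
# impairment parameters, patient-feature parameter mapping, risk factors and
# MRI-detectable relapse detection.

#' White-matter configuration
#'
#' The simulated tissue is a block of white matter populated by
#' oligodendrocytes (ODC) at a uniform density.  A lesion is MRI-detectable
#' when the ODC loss from baseline reaches `mri_loss_threshold`; smaller
#' losses count as (MRI-silent) inflammatory biological activity.
#'
#' @param volume_mm3 Tissue volume in cubic millimeters (default 3).
#' @param odc_density ODC per cubic millimeter (default 50e3, the patient
#'   scenario density; the entity table's 45e3/uL is the generic default for
#'   non-patient runs and can be passed here explicitly).
#' @param mri_loss_threshold ODC loss defining an MRI-detectable event
#'   (default 50e3).
#' @param odc_regeneration_days Mean-reversion timescale of ODC regeneration
#'   towards baseline (default 60 days).
#' @param inflammatory_fraction Fraction of the MRI threshold a dip must
#'   reach to be logged as inflammatory activity (default 0.1).
#' @return An object of class `white_matter_config`.
#' @export
white_matter_config <- function(volume_mm3 = 3, odc_density = 50e3,
                                mri_loss_threshold = 50e3,
                                odc_regeneration_days = 60,
                                inflammatory_fraction = 0.1) {
  baseline <- volume_mm3 * odc_density
  if (mri_loss_threshold > baseline)
    stop("mri_loss_threshold cannot exceed the baseline ODC count")
  structure(list(volume_mm3 = volume_mm3, odc_density = odc_density,
                 mri_loss_threshold = mri_loss_threshold,
                 odc_regeneration_days = odc_regeneration_days,
                 inflammatory_fraction = inflammatory_fraction),
            class = "white_matter_config")
}

#' Disease parameters
#'
#' The two regulatory-system control parameters (central and peripheral
#' tolerance impairment), the per-step oligodendrocyte apoptosis
#' probability mapped from the baseline lesion load, and the generic
#' immune-reactivity multiplier mapped from onset age.  The all-zero default
#' is a healthy control.
#'
#' @param odc_apoptosis_prob Per-step spontaneous ODC apoptosis probability.
#' @param central_tolerance_impairment,peripheral_tolerance_impairment
#'   Impairments in `[0,1]`; both 0 for a healthy control.
#' @param immune_reactivity Positive multiplier on effector activation.
#' @param treg_scale Multiplier on regulatory T-cell activation carrying the
#'   vitamin D / smoking environmental factors (1 = unaffected).
#' @return An object of class `disease_params`.
#' @export
disease_params <- function(odc_apoptosis_prob = 0,
                           central_tolerance_impairment = 0,
                           peripheral_tolerance_impairment = 0,
                           immune_reactivity = 1,
                           treg_scale = 1) {
  chk01 <- function(x, nm) if (x < 0 || x > 1) stop(nm, " must lie in [0,1]")
  chk01(odc_apoptosis_prob, "odc_apoptosis_prob")
  chk01(central_tolerance_impairment, "central_tolerance_impairment")
  chk01(peripheral_tolerance_impairment, "peripheral_tolerance_impairment")
  if (immune_reactivity <= 0) stop("immune_reactivity must be positive")
  structure(list(odc_apoptosis_prob = odc_apoptosis_prob,
                 central_tolerance_impairment = central_tolerance_impairment,
                 peripheral_tolerance_impairment = peripheral_tolerance_impairment,
                 immune_reactivity = immune_reactivity,
                 treg_scale = treg_scale),
            class = "disease_params")
}

#' Risk-factor profile
#'
#' The prognostic factors used as simulator inputs: age, vitamin D level,
#' smoking habit, lesion numerosity and volume, oligoclonal bands, EBV
#' exposure and HLA predisposition.
#'
#' @param age_years Positive age.
#' @param vitamin_d_level `"normal"`, `"low"` or `"very_low"`.
#' @param smoking `"negligible"` or `"not_negligible"`.
#' @param lesion_count Non-negative integer.
#' @param lesion_volume `"light"`, `"medium"` or `"high"`.
#' @param ocb_igg_igm Oligoclonal bands present (logical).
#' @param ebv_exposure,hla_predisposition Logical risk flags.
#' @return An object of class `risk_factor_profile`.
#' @export
risk_factor_profile <- function(age_years = 40,
                                vitamin_d_level = "normal",
                                smoking = "negligible",
                                lesion_count = 0L,
                                lesion_volume = "light",
                                ocb_igg_igm = FALSE,
                                ebv_exposure = FALSE,
                                hla_predisposition = FALSE) {
  if (!vitamin_d_level %in% c("normal", "low", "very_low"))
    stop("unsupported vitamin_d_level: ", vitamin_d_level)
  if (!smoking %in% c("negligible", "not_negligible"))
    stop("unsupported smoking value: ", smoking)
  if (!lesion_volume %in% c("light", "medium", "high"))
    stop("unsupported lesion_volume: ", lesion_volume)
  if (lesion_count < 0) stop("lesion_count must be >= 0")
  structure(list(age_years = age_years, vitamin_d_level = vitamin_d_level,
                 smoking = smoking, lesion_count = as.integer(lesion_count),
                 lesion_volume = lesion_volume, ocb_igg_igm = ocb_igg_igm,
                 ebv_exposure = ebv_exposure,
                 hla_predisposition = hla_predisposition),
            class = "risk_factor_profile")
}

#' One step of spontaneous oligodendrocyte apoptosis
#'
#' Every oligodendrocyte dies this step with the configured probability;
#' each death deposits myelin-basic-protein units at its lattice site, where
#' they are available for capture by antigen-presenting cells.
#'
#' @param state Simulation state.
#' @param params [disease_params()] (uses `odc_apoptosis_prob`).
#' @return Updated state.
#' @export
odc_apoptosis_step <- function(state, params = state$cfg$disease) {
  p <- params$odc_apoptosis_prob
  if (p <= 0) return(state)
  pos <- state$odc > 0L
  if (!any(pos)) return(state)
  deaths <- stats::rbinom(sum(pos), state$odc[pos], p)
  state$odc[pos] <- state$odc[pos] - deaths
  state$fields[[cWM]][pos, mMBP] <- state$fields[[cWM]][pos, mMBP] +
    deaths * state$cfg$cal$mbp_per_death
  state
}

#' Map clinical features to disease parameters
#'
#' Deterministic, documented mapping from a patient's baseline clinical
#' features to simulator parameters: apoptosis probability increases with
#' the lesion load at onset
#' (`p_min + (p_max - p_min) * min(lesions / lesion_ref, 1)`), both
#' tolerance impairments gain a fixed bonus when oligoclonal bands are
#' present, and immune reactivity decreases with onset age
#' (`clamp(age_ref / onset_age, r_min, r_max)`).  All constants live in the
#' calibration file.
#'
#' @param profile A [patient_profile()] or [risk_factor_profile()].
#' @param calibration Calibration constants ([default_calibration()]).
#' @return A [disease_params()] object.
#' @export
map_patient_to_params <- function(profile,
                                  calibration = default_calibration()) {
  cal <- calibration
  if (inherits(profile, "patient_profile")) {
    lesions <- if (nrow(profile$lesion_timeline))
      profile$lesion_timeline$count[1L] else 0L
    ocb <- profile$ocb_positive
    age <- profile$onset_age_years
    vit <- 1
  } else if (inherits(profile, "risk_factor_profile")) {
    lesions <- profile$lesion_count
    ocb <- profile$ocb_igg_igm
    age <- profile$age_years
    vit <- cal$vitamin_d_factor[[profile$vitamin_d_level]] *
      cal$smoking_factor[[profile$smoking]]
  } else stop("profile must be a patient_profile or risk_factor_profile")
  apop <- cal$apoptosis_p_min +
    (cal$apoptosis_p_max - cal$apoptosis_p_min) *
    min(lesions / cal$lesion_ref, 1)
  imp_c <- min(cal$impairment_base + cal$ocb_impairment_bonus * ocb, 1)
  imp_p <- min(cal$impairment_base + cal$ocb_impairment_bonus * ocb, 1)
  react <- min(max(cal$age_ref / age, cal$reactivity_min),
               cal$reactivity_max)
  disease_params(odc_apoptosis_prob = apop,
                 central_tolerance_impairment = imp_c,
                 peripheral_tolerance_impairment = imp_p,
                 immune_reactivity = react,
                 treg_scale = vit)
}

#' Pregnancy immunomodulation
#'
#' During a pregnancy interval the central and peripheral tolerance
#' mechanisms are transiently strengthened: both impairment values are
#' multiplied by a factor below one.  Outside pregnancy the parameters are
#' returned unchanged; the operation is idempotent per step.
#'
#' @param params A [disease_params()] object.
#' @param in_pregnancy Logical.
#' @param factor Multiplier in `(0,1]` (default 0.5).
#' @return Possibly modified [disease_params()].
#' @export
apply_pregnancy_modulation <- function(params, in_pregnancy,
                                       factor = 0.5) {
  if (!in_pregnancy) return(params)
  params$central_tolerance_impairment <-
    params$central_tolerance_impairment * factor
  params$peripheral_tolerance_impairment <-
    params$peripheral_tolerance_impairment * factor
  params
}

#' Detect MRI-detectable relapses in an ODC trajectory
#'
#' A relapse opens at each downward crossing of
#' `baseline - mri_loss_threshold` and closes at the subsequent upward
#' crossing (or at the end of the trajectory).  Dips that reach at least
#' `inflammatory_fraction * mri_loss_threshold` of loss but never the MRI
#' threshold are reported separately as inflammatory-activity intervals.
#'
#' @param odc_trajectory Numeric vector of total ODC counts per step.
#' @param config A [white_matter_config()]; its implied baseline is
#'   `volume_mm3 * odc_density` unless `baseline` is given.
#' @param baseline Baseline ODC count (default from `config`).
#' @return A list with data frames `relapses` (onset_step, offset_step,
#'   nadir_odc) and `inflammatory` (same columns).
#' @export
detect_relapses <- function(odc_trajectory, config = white_matter_config(),
                            baseline = config$volume_mm3 * config$odc_density) {
  x <- as.numeric(odc_trajectory)
  if (any(x > baseline + 1e-9)) stop("trajectory values exceed the baseline")
  if (any(x < 0)) stop("trajectory values must be non-negative")
  relapse_level <- baseline - config$mri_loss_threshold
  inflam_level <- baseline -
    config$inflammatory_fraction * config$mri_loss_threshold
  crossings <- function(level) {
    below <- x <= level
    if (!any(below)) return(data.frame(onset_step = integer(0),
                                       offset_step = integer(0),
                                       nadir_odc = numeric(0)))
    r <- rle(below)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- r$values
    data.frame(onset_step = starts[sel], offset_step = ends[sel],
               nadir_odc = vapply(which(sel), function(k)
                 min(x[starts[k]:ends[k]]), 0))
  }
  rel <- crossings(relapse_level)
  inf <- crossings(inflam_level)
  # inflammatory intervals are the sub-threshold dips: drop any interval
  # that contains a relapse
  if (nrow(inf) && nrow(rel)) {
    keep <- vapply(seq_len(nrow(inf)), function(k)
      !any(rel$onset_step >= inf$onset_step[k] &
             rel$onset_step <= inf$offset_step[k]), TRUE)
    inf <- inf[keep, , drop = FALSE]
  }
  list(relapses = rel, inflammatory = inf)
}

#' Seed risk factors into an initialized state
#'
#' Applies the components of a [risk_factor_profile()] that act on the
#' state rather than on scalar parameters: EBV exposure injects a viral
#' antigen whose epitope lies within `d_mimic` bits of the myelin-basic-
#' protein peptide (molecular mimicry, cross-reactive priming with B7
#' costimulation on); HLA predisposition is consumed at state construction
#' (MHC-I strings with elevated affinity for the MBP peptide); vitamin D
#' and smoking act through the regulatory-T-cell scale of
#' [map_patient_to_params()].
#'
#' @param state Simulation state.
#' @param profile A [risk_factor_profile()].
#' @return Updated state.
#' @export
seed_risk_factors <- function(state, profile) {
  if (!inherits(profile, "risk_factor_profile"))
    stop("profile must be a risk_factor_profile")
  cal <- state$cfg$cal
  if (profile$ebv_exposure) {
    l <- state$cfg$params$bitstring_length
    pep <- state$ctx$mbp_peptide
    if (cal$d_mimic > 0) {
      bits <- sample.int(l, cal$d_mimic) - 1L
      for (b in bits) pep <- bitwXor(pep, bitwShiftL(1L, b))
    }
    state$ebv_pep <- pep
    S <- state$cfg$latt$n_sites
    tgt <- sample.int(S, cal$ebv_units, replace = TRUE)
    state$fields[[cLN]][, mEBV] <- state$fields[[cLN]][, mEBV] +
      tabulate(tgt, S)
  }
  state
}
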
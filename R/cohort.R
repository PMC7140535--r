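# Patient records, virtual cohorts, the 10-repertoire patient protocol and
# run summaries.

#' Patient profile
#'
#' Clinical features of one relapsing-remitting MS patient: onset age,
#' oligoclonal-band status, pregnancy intervals, MRI lesion-load timeline
#' and treatment timeline.  Spinal lesions are recorded but not simulated.
#'
#' @param patient_id Identifier.
#' @param age_range Character like `"30-39"`.
#' @param onset_age_years Age at MS onset.
#' @param ocb_positive Oligoclonal bands present.
#' @param pregnancy_intervals Data frame `start`, `end` (Dates), possibly
#'   empty.
#' @param lesion_timeline Data frame `date` (Date), `count` (integer).
#' @param spinal_lesion_timeline Same shape or NULL.
#' @param treatment_timeline Data frame `start` (Date), `drug`, `end`
#'   (Date or NA), possibly empty.
#' @return Object of class `patient_profile`.
#' @export
patient_profile <- function(patient_id, age_range, onset_age_years,
                            ocb_positive,
                            pregnancy_intervals = empty_intervals(),
                            lesion_timeline = empty_timeline(),
                            spinal_lesion_timeline = NULL,
                            treatment_timeline = empty_treatments()) {
  if (nrow(lesion_timeline) > 1 &&
      is.unsorted(lesion_timeline$date, strictly = FALSE))
    stop("lesion timeline dates must be ordered")
  if (nrow(treatment_timeline)) {
    bad <- setdiff(treatment_timeline$drug, c(DRUGS, "none"))
    if (length(bad)) stop("unsupported drug(s): ", paste(bad, collapse = ", "))
  }
  structure(list(patient_id = as.character(patient_id),
                 age_range = age_range,
                 onset_age_years = onset_age_years,
                 ocb_positive = isTRUE(ocb_positive),
                 pregnancy_intervals = pregnancy_intervals,
                 lesion_timeline = lesion_timeline,
                 spinal_lesion_timeline = spinal_lesion_timeline,
                 treatment_timeline = treatment_timeline),
            class = "patient_profile")
}

empty_intervals <- function()
  data.frame(start = as.Date(character(0)), end = as.Date(character(0)))
empty_timeline <- function()
  data.frame(date = as.Date(character(0)), count = integer(0))
empty_treatments <- function()
  data.frame(start = as.Date(character(0)), drug = character(0),
             end = as.Date(character(0)))

month_date <- function(x) as.Date(paste0(x, "-01"))

parse_pairs <- function(txt, row, col) {
  if (is.na(txt) || txt == "" || txt %in% c("N/D", "N/A"))
    return(empty_timeline())
  parts <- strsplit(txt, ";", fixed = TRUE)[[1L]]
  out <- lapply(parts, function(p) {
    kv <- strsplit(p, ":", fixed = TRUE)[[1L]]
    if (length(kv) != 2L)
      stop(sprintf("malformed entry '%s' at row %s, column %s", p, row, col))
    data.frame(date = month_date(kv[1L]), count = as.integer(kv[2L]))
  })
  do.call(rbind, out)
}

parse_intervals <- function(txt, row) {
  if (is.na(txt) || txt == "") return(empty_intervals())
  parts <- strsplit(txt, ";", fixed = TRUE)[[1L]]
  out <- lapply(parts, function(p) {
    se <- strsplit(p, "/", fixed = TRUE)[[1L]]
    if (length(se) != 2L)
      stop(sprintf("malformed pregnancy interval '%s' at row %s", p, row))
    data.frame(start = month_date(se[1L]), end = month_date(se[2L]))
  })
  do.call(rbind, out)
}

parse_treatments <- function(txt, row) {
  if (is.na(txt) || txt == "" || txt == "N/A") return(empty_treatments())
  parts <- strsplit(txt, ";", fixed = TRUE)[[1L]]
  out <- lapply(parts, function(p) {
    kv <- strsplit(p, ":", fixed = TRUE)[[1L]]
    if (length(kv) != 2L)
      stop(sprintf("malformed treatment entry '%s' at row %s", p, row))
    span <- strsplit(kv[1L], "..", fixed = TRUE)[[1L]]
    data.frame(start = month_date(span[1L]), drug = kv[2L],
               end = if (length(span) == 2L) month_date(span[2L])
               else as.Date(NA))
  })
  do.call(rbind, out)
}

#' Parse the bundled patient table
#'
#' Reads patient records (CSV; semicolon-separated `YYYY-MM:count` pair
#' lists for timelines, `YYYY-MM/YYYY-MM` ranges for pregnancies,
#' `YYYY-MM:drug` entries for treatments; `N/A` means untreated, `N/D`
#' means spinal data absent) into [patient_profile()] objects.
#'
#' @param path CSV path; default the bundled six-patient table.
#' @return List of [patient_profile()]s.
#' @export
parse_patient_table <- function(path = system.file("extdata", "patients.csv",
                                                   package = "mssim")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("patient_id", "age_range", "onset_age", "ocb", "pregnancy",
            "lesions", "spinal_lesions", "treatments")
  if (!all(need %in% names(tab)))
    stop("patient table must have columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(tab)), function(k) {
    r <- tab[k, ]
    spinal <- if (r$spinal_lesions %in% c("N/D", ""))
      NULL else parse_pairs(r$spinal_lesions, r$patient_id, "spinal_lesions")
    patient_profile(
      patient_id = r$patient_id,
      age_range = r$age_range,
      onset_age_years = as.numeric(r$onset_age),
      ocb_positive = identical(r$ocb, "yes"),
      pregnancy_intervals = parse_intervals(r$pregnancy, r$patient_id),
      lesion_timeline = parse_pairs(r$lesions, r$patient_id, "lesions"),
      spinal_lesion_timeline = spinal,
      treatment_timeline = parse_treatments(r$treatments, r$patient_id))
  })
}

#' Serialize patient profiles back to the table format
#'
#' Inverse of [parse_patient_table()]; a parse/serialize/parse round trip is
#' lossless.
#'
#' @param profiles List of [patient_profile()]s.
#' @param path Output CSV path.
#' @export
write_patient_table <- function(profiles, path) {
  ym <- function(d) format(d, "%Y-%m")
  rows <- lapply(profiles, function(p) {
    data.frame(
      patient_id = p$patient_id, age_range = p$age_range,
      onset_age = p$onset_age_years,
      ocb = if (p$ocb_positive) "yes" else "no",
      pregnancy = if (nrow(p$pregnancy_intervals))
        paste(paste0(ym(p$pregnancy_intervals$start), "/",
                     ym(p$pregnancy_intervals$end)), collapse = ";") else "",
      lesions = paste(paste0(ym(p$lesion_timeline$date), ":",
                             p$lesion_timeline$count), collapse = ";"),
      spinal_lesions = if (is.null(p$spinal_lesion_timeline)) "N/D"
      else paste(paste0(ym(p$spinal_lesion_timeline$date), ":",
                        p$spinal_lesion_timeline$count), collapse = ";"),
      treatments = if (!nrow(p$treatment_timeline)) "N/A"
      else paste(vapply(seq_len(nrow(p$treatment_timeline)), function(j) {
        tt <- p$treatment_timeline[j, ]
        pre <- if (!is.na(tt$end)) paste0(ym(tt$start), "..", ym(tt$end))
        else ym(tt$start)
        paste0(pre, ":", tt$drug)
      }, ""), collapse = ";"))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Derive replicate seeds from a master seed
#'
#' Deterministic 31-bit mixing (splitmix-style multiply/add/xor) so that
#' replicate streams are reproducible and documented in output metadata.
#'
#' @param master Master seed (integer).
#' @param n Number of seeds.
#' @return Integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(master, n) {
  z <- (as.double(master) %% 2147483647) + 1
  out <- numeric(n)
  for (k in seq_len(n)) {
    z <- (z * 48271) %% 2147483647        # Lehmer step
    mixed <- (z * 2654435761 + k * 40503) %% 2147483647
    out[k] <- mixed
  }
  as.integer(out %% 2147483645 + 1)
}

#' Generate a virtual cohort for one severity stratum
#'
#' Samples risk-factor profiles from the stratum's documented ranges:
#' low severity combines normal vitamin D, light lesion load, no oligoclonal
#' bands, middle age and negligible smoking; medium has low vitamin D,
#' medium lesion load, oligoclonal bands, middle age and not-negligible
#' smoking; high has very low vitamin D, high lesion load, oligoclonal
#' bands, older age and not-negligible smoking.
#'
#' @param n Number of subjects (>= 0).
#' @param severity `"low"`, `"medium"` or `"high"`.
#' @param seed RNG seed.
#' @return List of [risk_factor_profile()]s.
#' @export
generate_cohort <- function(n, severity = c("low", "medium", "high"),
                            seed = 1L) {
  severity <- match.arg(severity)
  n <- as.integer(n)
  if (n < 0L) stop("n must be >= 0")
  set.seed(as.integer(seed))
  spec <- switch(severity,
    low = list(vitd = "normal", smoke = "negligible", lesions = c(3, 10),
               vol = "light", ocb = FALSE, age = c(35, 45)),
    medium = list(vitd = "low", smoke = "not_negligible", lesions = c(20, 40),
                  vol = "medium", ocb = TRUE, age = c(35, 45)),
    high = list(vitd = "very_low", smoke = "not_negligible",
                lesions = c(50, 90), vol = "high", ocb = TRUE,
                age = c(50, 60)))
  lapply(seq_len(n), function(k)
    risk_factor_profile(
      age_years = round(stats::runif(1, spec$age[1], spec$age[2])),
      vitamin_d_level = spec$vitd, smoking = spec$smoke,
      lesion_count = sample(spec$lesions[1]:spec$lesions[2], 1L),
      lesion_volume = spec$vol, ocb_igg_igm = spec$ocb))
}

#' Run the severity-stratified cohort experiment
#'
#' Simulates `n_per_stratum` virtual subjects in each severity stratum and
#' summarizes disease severity as total oligodendrocyte loss.
#'
#' @param n_per_stratum Subjects per stratum.
#' @param seed Master seed.
#' @param horizon_years Simulated time per subject.
#' @param wm [white_matter_config()].
#' @param scale Population scale factor.
#' @param lattice_side Lattice side.
#' @return Data frame with one row per subject (stratum, seed, relapse
#'   count, total and peak ODC loss).
#' @export
run_cohort_experiment <- function(n_per_stratum = 10L, seed = 1L,
                                  horizon_years = 2,
                                  wm = white_matter_config(),
                                  scale = 1, lattice_side = 16L) {
  res <- list()
  for (sev in c("low", "medium", "high")) {
    profiles <- generate_cohort(n_per_stratum, sev,
                                seed = derive_seeds(seed, 3)[
                                  match(sev, c("low", "medium", "high"))])
    seeds <- derive_seeds(seed + match(sev, c("low", "medium", "high")),
                          n_per_stratum)
    for (k in seq_along(profiles)) {
      cr <- simulate_course(risk = profiles[[k]],
                            horizon_years = horizon_years, seed = seeds[k],
                            wm = wm, scale = scale,
                            lattice_side = lattice_side, record = FALSE)
      res[[length(res) + 1L]] <- data.frame(
        stratum = sev, subject = k, seed = seeds[k],
        relapse_count = cr$relapse_count,
        total_odc_loss = cr$total_odc_loss,
        peak_odc_loss = cr$peak_odc_loss)
    }
  }
  do.call(rbind, res)
}

#' Summarize replicate runs
#'
#' Pointwise mean and standard deviation (sample convention, divisor
#' `n - 1`; a single replicate yields an all-zero SD series) of every
#' tracked series across replicates, plus the relapse-count distribution.
#'
#' @param replicates List of `ms_course` objects with equal horizons.
#' @param csv_path Optional path; writes a tidy CSV (series, step, mean, sd).
#' @return Object of class `run_summary`.
#' @export
summarize_runs <- function(replicates, csv_path = NULL) {
  if (!length(replicates)) stop("at least one replicate required")
  ns <- vapply(replicates, function(r) nrow(r$trajectories), 0L)
  if (length(unique(ns)) != 1L) stop("replicates have unequal horizons")
  series <- REC_SERIES
  arr <- vapply(replicates, function(r)
    as.matrix(r$trajectories[, series]), matrix(0, ns[1L], length(series)))
  mu <- apply(arr, c(1, 2), mean)
  sdv <- apply(arr, c(1, 2), stats::sd)
  sdv[is.na(sdv)] <- 0
  out <- structure(list(
    mean = as.data.frame(mu), sd = as.data.frame(sdv),
    relapse_counts = vapply(replicates, `[[`, 0, "relapse_count"),
    n_replicates = length(replicates)), class = "run_summary")
  if (!is.null(csv_path)) {
    tidy <- do.call(rbind, lapply(series, function(s)
      data.frame(series = s, step = seq_len(ns[1L]), mean = mu[, s],
                 sd = sdv[, s])))
    utils::write.csv(tidy, csv_path, row.names = FALSE)
  }
  out
}

#' Run the multi-repertoire patient protocol
#'
#' For one patient, runs `n_repertoires` independent simulations differing
#' only in the repertoire seed, and selects the replicate whose relapse
#' history best fits the patient's MRI timeline.  The discrepancy metric is
#' the sum over MRI dates of the absolute difference between the simulated
#' cumulative relapse count and the observed cumulative count of
#' new-lesion episodes (dates where the lesion count increased).
#'
#' @param profile A [patient_profile()].
#' @param n_repertoires Number of repertoire replicates (default 10).
#' @param base_seed Master seed; replicate seeds via [derive_seeds()].
#' @param extra_years Horizon extension beyond the recorded timeline
#'   (default 1 year, for forward prediction).
#' @param wm [white_matter_config()].
#' @param scale Population scale factor.
#' @param lattice_side Lattice side.
#' @param calibration Calibration constants.
#' @return List with `summary` ([summarize_runs()] output), `courses`,
#'   `discrepancies`, `best_index` and `best_fit`.
#' @export
run_patient_protocol <- function(profile, n_repertoires = 10L, base_seed = 1L,
                                 extra_years = 1,
                                 wm = white_matter_config(),
                                 scale = 1, lattice_side = 16L,
                                 calibration = default_calibration()) {
  cal <- calibration
  disease <- map_patient_to_params(profile, cal)
  tl <- patient_calendar(profile)
  horizon_years <- tl$span_years + extra_years
  seeds <- derive_seeds(base_seed, n_repertoires)
  courses <- lapply(seeds, function(s)
    simulate_course(disease = disease, horizon_years = horizon_years,
                    seed = s, wm = wm, plans = tl$plans,
                    pregnancy_intervals = tl$pregnancy,
                    calibration = cal, scale = scale,
                    lattice_side = lattice_side, record = FALSE))
  disc <- vapply(courses, function(cr)
    relapse_discrepancy(cr, tl$mri_days, tl$observed_cum), 0)
  best <- which.min(disc)
  list(summary = summarize_runs(courses), courses = courses,
       discrepancies = disc, best_index = best,
       best_fit = courses[[best]], seeds = seeds)
}

# Map a patient's calendar to simulation days (day 0 = first recorded
# event) and derive treatment plans and observed lesion episodes.
patient_calendar <- function(profile) {
  dates <- c(profile$lesion_timeline$date, profile$treatment_timeline$start,
             profile$pregnancy_intervals$start)
  if (!length(dates)) stop("patient profile has an empty timeline")
  d0 <- min(dates)
  to_day <- function(d) as.numeric(d - d0)
  last <- max(c(profile$lesion_timeline$date,
                profile$treatment_timeline$start,
                profile$pregnancy_intervals$end))
  plans <- list()
  tt <- profile$treatment_timeline
  if (nrow(tt)) {
    tt <- tt[order(tt$start), ]
    for (j in seq_len(nrow(tt))) {
      end_day <- if (!is.na(tt$end[j])) to_day(tt$end[j])
      else if (j < nrow(tt)) to_day(tt$start[j + 1L]) else Inf
      plans[[j]] <- treatment_plan(tt$drug[j], start_day = to_day(tt$start[j]),
                                   end_day = end_day)
    }
  }
  preg <- NULL
  if (nrow(profile$pregnancy_intervals)) {
    preg <- data.frame(start_day = to_day(profile$pregnancy_intervals$start),
                       end_day = to_day(profile$pregnancy_intervals$end))
  }
  lt <- profile$lesion_timeline
  observed_new <- if (nrow(lt)) {
    inc <- c(lt$count[1L] > 0, diff(lt$count) > 0)
    cumsum(as.integer(inc))
  } else integer(0)
  list(span_years = max(as.numeric(last - d0) / 365, 0.5),
       plans = plans, pregnancy = preg,
       mri_days = to_day(lt$date), observed_cum = observed_new)
}

relapse_discrepancy <- function(course, mri_days, observed_cum) {
  if (!length(mri_days)) return(0)
  dt <- course$trajectories$day[2L] - course$trajectories$day[1L]
  onsets <- course$relapses$onset_step * dt
  sim_cum <- vapply(mri_days, function(d) sum(onsets <= d), 0L)
  sum(abs(sim_cum - observed_cum))
}

#' Write a course's trajectories to CSV with a metadata header
#'
#' @param course An `ms_course`.
#' @param path Output path.
#' @param label Scenario label recorded in the header.
#' @export
write_course_csv <- function(course, path, label = "course") {
  meta <- c(
    sprintf("# mssim %s", as.character(utils::packageVersion("mssim"))),
    sprintf("# label: %s", label),
    sprintf("# seed: %d", course$seed),
    sprintf("# baseline_odc: %.0f", course$baseline_odc))
  con <- file(path, "w")
  writeLines(meta, con)
  utils::write.csv(course$trajectories, con, row.names = FALSE)
  close(con)
  invisible(path)
}
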
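# Patient-table parsing, seed derivation, cohort generation, run summaries.

test_that("the bundled patient table parses into six complete profiles", {
  profs <- parse_patient_table()
  expect_length(profs, 6L)
  ids <- vapply(profs, `[[`, "", "patient_id")
  expect_setequal(ids, c("1070", "3736", "2789", "5793", "2070", "2961"))
  p1070 <- profs[[match("1070", ids)]]
  expect_identical(nrow(p1070$treatment_timeline), 3L)
  expect_identical(p1070$treatment_timeline$drug,
                   c("ifnb1a", "fingolimod", "natalizumab"))
  expect_identical(p1070$treatment_timeline$start,
                   as.Date(c("2007-09-01", "2013-05-01", "2015-12-01")))
  expect_true(p1070$ocb_positive)
  expect_identical(p1070$onset_age_years, 20)
  expect_identical(nrow(p1070$spinal_lesion_timeline), 2L)
  p2961 <- profs[[match("2961", ids)]]
  expect_identical(nrow(p2961$treatment_timeline), 0L)
  expect_false(p2961$ocb_positive)
  expect_identical(p2961$lesion_timeline$count, c(49L, 43L, 65L))
  p2789 <- profs[[match("2789", ids)]]
  expect_identical(nrow(p2789$pregnancy_intervals), 2L)
  p3736 <- profs[[match("3736", ids)]]
  expect_identical(p3736$treatment_timeline$end[1], as.Date("2015-12-01"))
})

test_that("patient-table round trip is lossless", {
  profs <- parse_patient_table()
  tmp <- tempfile(fileext = ".csv")
  write_patient_table(profs, tmp)
  again <- parse_patient_table(tmp)
  expect_equal(again, profs)
})

test_that("malformed rows fail with a located parse error", {
  tmp <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,age_range,onset_age,ocb,pregnancy,lesions,spinal_lesions,treatments",
               "9,30-39,31,no,,2014-10;23,N/D,N/A"), tmp)
  expect_error(parse_patient_table(tmp), "row 9")
})

test_that("seed derivation is deterministic, distinct and in integer range", {
  s1 <- derive_seeds(42, 10)
  s2 <- derive_seeds(42, 10)
  expect_identical(s1, s2)
  expect_identical(length(unique(s1)), 10L)
  expect_true(all(s1 >= 1 & s1 < 2^31 - 1))
  expect_false(identical(derive_seeds(43, 10), s1))
})

test_that("cohort strata follow their documented feature ranges", {
  expect_length(generate_cohort(0, "low"), 0L)
  low <- generate_cohort(15, "low", seed = 3)
  expect_true(all(vapply(low, function(p) !p$ocb_igg_igm, TRUE)))
  expect_true(all(vapply(low, `[[`, "", "vitamin_d_level") == "normal"))
  expect_true(all(vapply(low, `[[`, 0L, "lesion_count") <= 10))
  high <- generate_cohort(15, "high", seed = 3)
  expect_true(all(vapply(high, function(p) p$ocb_igg_igm, TRUE)))
  expect_true(all(vapply(high, `[[`, "", "vitamin_d_level") == "very_low"))
  expect_true(all(vapply(high, `[[`, 0L, "lesion_count") >= 50))
  expect_true(all(vapply(high, `[[`, 0, "age_years") >= 50))
  expect_identical(generate_cohort(5, "medium", seed = 9),
                   generate_cohort(5, "medium", seed = 9))
  expect_error(generate_cohort(3, "extreme"))
})

test_that("run summaries use the sample SD convention", {
  mk <- function(vals) {
    tr <- as.data.frame(matrix(vals, nrow = length(vals),
                               ncol = length(mssim:::REC_SERIES)))
    names(tr) <- mssim:::REC_SERIES
    structure(list(trajectories = tr, relapse_count = 0L), class = "ms_course")
  }
  one <- summarize_runs(list(mk(c(5, 5, 5))))
  expect_true(all(one$sd == 0))
  two <- summarize_runs(list(mk(rep(2, 3)), mk(rep(6, 3))))
  expect_equal(unique(as.numeric(as.matrix(two$mean))), 4)
  expect_equal(unique(as.numeric(as.matrix(two$sd))), 4 / sqrt(2))
  expect_error(summarize_runs(list(mk(1:3), mk(1:4))), "unequal")
  # tidy CSV export
  tmp <- tempfile(fileext = ".csv")
  summarize_runs(list(mk(1:3), mk(3:1)), csv_path = tmp)
  tidy <- read.csv(tmp)
  expect_setequal(names(tidy), c("series", "step", "mean", "sd"))
  expect_identical(nrow(tidy), 3L * length(mssim:::REC_SERIES))
})

test_that("the multi-repertoire patient protocol is deterministic and ranks
           replicates by timeline fit", {
  prof <- patient_profile(
    patient_id = "synthetic-1", age_range = "30-39", onset_age_years = 31,
    ocb_positive = TRUE,
    lesion_timeline = data.frame(date = as.Date(c("2015-01-01", "2015-04-01")),
                                 count = c(10L, 14L)),
    treatment_timeline = data.frame(start = as.Date("2015-03-01"),
                                    drug = "fingolimod", end = as.Date(NA)))
  res <- run_patient_protocol(prof, n_repertoires = 2L, base_seed = 5,
                              extra_years = 0, scale = 0.2, lattice_side = 8,
                              wm = white_matter_config(0.6, mri_loss_threshold = 1e4))
  expect_length(res$courses, 2L)
  expect_identical(res$best_index, which.min(res$discrepancies))
  expect_identical(res$summary$n_replicates, 2L)
  res2 <- run_patient_protocol(prof, n_repertoires = 2L, base_seed = 5,
                               extra_years = 0, scale = 0.2, lattice_side = 8,
                               wm = white_matter_config(0.6, mri_loss_threshold = 1e4))
  expect_identical(res2$best_index, res$best_index)
  expect_identical(res2$discrepancies, res$discrepancies)
  # n_repertoires = 1: the summary covers that single run and it is the best
  res1 <- run_patient_protocol(prof, n_repertoires = 1L, base_seed = 5,
                               extra_years = 0, scale = 0.2, lattice_side = 8,
                               wm = white_matter_config(0.6, mri_loss_threshold = 1e4))
  expect_identical(res1$best_index, 1L)
  expect_true(all(res1$summary$sd == 0))
})

test_that("pregnancy intervals damp the impairments inside the window", {
  d <- disease_params(central_tolerance_impairment = 0.6,
                      peripheral_tolerance_impairment = 0.6)
  # direct check of the per-step modulation used by the course driver
  m <- apply_pregnancy_modulation(d, TRUE, 0.5)
  expect_equal(m$peripheral_tolerance_impairment, 0.3)
  expect_identical(apply_pregnancy_modulation(d, FALSE, 0.5), d)
})
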
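# MS-specific biology: apoptosis, parameter mapping, pregnancy modulation,
# relapse detection, risk factors, rule registration.

test_that("oligodendrocyte apoptosis is binomial and deposits antigen", {
  st <- init_state(disease = disease_params(), seed = 2, lattice_side = 8)
  st$fields[[2]][, mssim:::mMBP] <- 0L
  n0 <- sum(st$odc)
  # probability zero: nothing happens
  st0 <- odc_apoptosis_step(st, disease_params(odc_apoptosis_prob = 0))
  expect_identical(sum(st0$odc), n0)
  # probability one: all die, each deposits antigen units
  st1 <- odc_apoptosis_step(st, disease_params(odc_apoptosis_prob = 1))
  expect_identical(sum(st1$odc), 0L)
  expect_equal(sum(st1$fields[[2]][, mssim:::mMBP]),
               n0 * default_calibration()$mbp_per_death)
  # small probability: deaths within the 3-sigma binomial band
  set.seed(4)
  st2 <- odc_apoptosis_step(st, disease_params(odc_apoptosis_prob = 0.001))
  deaths <- n0 - sum(st2$odc)
  expect_lt(abs(deaths - n0 * 0.001), 3 * sqrt(n0 * 0.001) + 1)
})

test_that("patient-feature mapping is monotone in the documented directions", {
  base <- parse_patient_table()[[1]]
  with_lesions <- function(p, n) {
    p$lesion_timeline <- data.frame(date = as.Date("2014-01-01"),
                                    count = as.integer(n))
    p
  }
  d9 <- map_patient_to_params(with_lesions(base, 9))
  d65 <- map_patient_to_params(with_lesions(base, 65))
  expect_lt(d9$odc_apoptosis_prob, d65$odc_apoptosis_prob)
  ocb_yes <- base; ocb_yes$ocb_positive <- TRUE
  ocb_no <- base; ocb_no$ocb_positive <- FALSE
  expect_gt(map_patient_to_params(ocb_yes)$peripheral_tolerance_impairment,
            map_patient_to_params(ocb_no)$peripheral_tolerance_impairment)
  expect_gt(map_patient_to_params(ocb_yes)$central_tolerance_impairment,
            map_patient_to_params(ocb_no)$central_tolerance_impairment)
  young <- base; young$onset_age_years <- 20
  older <- base; older$onset_age_years <- 33
  expect_gt(map_patient_to_params(young)$immune_reactivity,
            map_patient_to_params(older)$immune_reactivity)
  # risk-factor route: vitamin D / smoking degrade the regulatory scale
  rf_bad <- risk_factor_profile(vitamin_d_level = "very_low",
                                smoking = "not_negligible")
  rf_ok <- risk_factor_profile()
  expect_lt(map_patient_to_params(rf_bad)$treg_scale,
            map_patient_to_params(rf_ok)$treg_scale)
})

test_that("pregnancy modulation halves impairments and is idempotent", {
  d <- disease_params(central_tolerance_impairment = 0.8,
                      peripheral_tolerance_impairment = 0.6)
  expect_identical(apply_pregnancy_modulation(d, FALSE), d)
  m <- apply_pregnancy_modulation(d, TRUE, factor = 0.5)
  expect_equal(m$central_tolerance_impairment, 0.4)
  expect_equal(m$peripheral_tolerance_impairment, 0.3)
  healthy <- disease_params()
  h <- apply_pregnancy_modulation(healthy, TRUE)
  expect_equal(h$central_tolerance_impairment, 0)
})

test_that("relapse detection uses level-crossing semantics", {
  cfg <- white_matter_config()   # baseline 150e3, threshold 50e3
  flat <- rep(150e3, 100)
  ev <- detect_relapses(flat, cfg)
  expect_identical(nrow(ev$relapses), 0L)
  expect_identical(nrow(ev$inflammatory), 0L)
  # loss of exactly the threshold qualifies ("at least")
  dip <- c(rep(150e3, 10), rep(100e3, 5), rep(150e3, 10))
  ev1 <- detect_relapses(dip, cfg)
  expect_identical(nrow(ev1$relapses), 1L)
  expect_identical(ev1$relapses$onset_step, 11L)
  expect_identical(ev1$relapses$offset_step, 15L)
  expect_equal(ev1$relapses$nadir_odc, 100e3)
  # a 49e3 loss is inflammatory activity, not a relapse
  dip2 <- c(rep(150e3, 10), rep(101e3, 5), rep(150e3, 10))
  ev2 <- detect_relapses(dip2, cfg)
  expect_identical(nrow(ev2$relapses), 0L)
  expect_identical(nrow(ev2$inflammatory), 1L)
  expect_error(detect_relapses(c(150e3, 151e3), cfg), "baseline")
})

test_that("relapse detection agrees with a brute-force interval scan", {
  cfg <- white_matter_config(volume_mm3 = 1, odc_density = 100,
                             mri_loss_threshold = 40)
  oracle <- function(x, level) {
    res <- list()
    open <- FALSE
    for (i in seq_along(x)) {
      if (!open && x[i] <= level) { open <- TRUE; s <- i }
      if (open && (x[i] > level || i == length(x))) {
        e <- if (x[i] > level) i - 1L else i
        res[[length(res) + 1L]] <- c(s, e, min(x[s:e]))
        open <- FALSE
      }
    }
    if (!length(res)) return(data.frame(onset_step = integer(0),
                                        offset_step = integer(0),
                                        nadir_odc = numeric(0)))
    m <- do.call(rbind, res)
    data.frame(onset_step = m[, 1], offset_step = m[, 2], nadir_odc = m[, 3])
  }
  set.seed(17)
  for (k in 1:1000) {
    x <- pmin(pmax(round(100 + cumsum(rnorm(40, 0, 25))), 0), 100)
    got <- detect_relapses(x, cfg, baseline = 100)$relapses
    want <- oracle(x, 60)
    expect_equal(got$onset_step, want$onset_step)
    expect_equal(got$offset_step, want$offset_step)
    expect_equal(got$nadir_odc, want$nadir_odc)
  }
})

test_that("risk factors seed the state as documented", {
  # all-benign profile leaves the state identical to the healthy default
  benign <- risk_factor_profile()
  s_ref <- init_state(disease = disease_params(), seed = 11, lattice_side = 8)
  s_rf <- init_state(disease = disease_params(), seed = 11, lattice_side = 8,
                     risk = benign)
  expect_identical(s_rf$ag, s_ref$ag)
  expect_identical(s_rf$fields, s_ref$fields)
  expect_true(is.na(s_rf$ebv_pep))
  # EBV mimicry: epitope within d_mimic bits of the MBP peptide
  ebv <- risk_factor_profile(ebv_exposure = TRUE)
  s_ebv <- init_state(disease = disease_params(), seed = 11, lattice_side = 8,
                      risk = ebv)
  d <- hamming_affinity(s_ebv$ebv_pep, s_ebv$ctx$mbp_peptide, length = 16)
  expect_lte(d, default_calibration()$d_mimic)
  expect_gt(sum(s_ebv$fields[[1]][, mssim:::mEBV]), 0)
  expect_error(risk_factor_profile(vitamin_d_level = "none"), "unsupported")
})

test_that("the MS rule registry extends the core registry exactly once", {
  reg <- core_rules()
  ext <- register_ms_rules(reg)
  added <- setdiff(names(ext), names(reg))
  expect_setequal(added, c("ODC_apoptosis", "ODC_IgG_opsonization",
                           "M_opsonized_ODC", "TC_ODC_kill",
                           "B_cell_opsonization"))
  expect_error(register_ms_rules(ext), "duplicate")
  # white-matter autoimmune rules are scoped to the white matter
  expect_identical(ext$TC_ODC_kill$compartment, "white_matter")
  expect_identical(ext$M_opsonized_ODC$compartment, "white_matter")
  # registry round-trips through YAML
  tmp <- tempfile(fileext = ".yaml")
  write_rules(ext, tmp)
  expect_equal(read_rules(tmp), ext)
})

test_that("tolerance gating: no autoreactive priming at zero impairment", {
  # co-located no-B7 presenting DC and resting TC with certain binding: the
  # healthy gate keeps activation probability at zero
  st <- init_state(disease = disease_params(), seed = 3, lattice_side = 6)
  a <- st$ag
  keep <- which(a$type == mssim:::iTC)[1:5]
  drop <- rep(TRUE, mssim:::ag_n(a)); drop[keep] <- FALSE
  st$ag <- a <- mssim:::ag_keep(a, !drop)
  a$comp[] <- 1L; a$pos[] <- 1L; a$state[] <- mssim:::sRES
  a$recep[] <- mssim:::bitwNot_l(mssim:::mhc_complex(st$ctx$mhc1_alleles[1],
                                                     st$ctx$mbp_peptide), 16L)
  dc <- mssim:::ag_new(3L, mssim:::iCDC, mssim:::sP1, 1L, 1L,
                       pep = st$ctx$mbp_peptide, noB7 = TRUE)
  st$ag <- mssim:::ag_bind(a, dc)
  st$fields[[1]][1, mssim:::mIL2] <- 100L
  st2 <- st
  for (k in 1:20) st2 <- mssim:::h_tc_priming(st2, core_rules()$TC_priming)
  expect_identical(sum(st2$ag$state == mssim:::sACT), 0L)
  # with impaired peripheral tolerance the same configuration activates
  st$cfg$disease <- ms_reference_params()
  st3 <- st
  act <- 0L
  for (k in 1:20) {
    st3 <- mssim:::h_tc_priming(st3, core_rules()$TC_priming)
    act <- act + sum(st3$ag$state == mssim:::sACT)
  }
  expect_gt(act, 0L)
})
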
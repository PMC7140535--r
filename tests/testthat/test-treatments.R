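# Drug-effect models, dosing schedules and the DHODH pathway sub-model.

test_that("treatment plans reproduce the licensed regimens", {
  p <- treatment_plan("ifnb1a")
  expect_equal(p$dose, 44); expect_identical(p$dose_unit, "mcg")
  expect_identical(p$schedule, "3x_week")
  expect_equal(treatment_plan("teriflunomide")$dose, 14)
  expect_equal(treatment_plan("fingolimod")$dose, 0.5)
  expect_equal(treatment_plan("natalizumab")$dose, 300)
  expect_equal(treatment_plan("ocrelizumab")$dose, 600)
  expect_error(treatment_plan("aspirin"), "unsupported")
  expect_error(treatment_plan("ifnb1a", start_day = 10, end_day = 5),
               "ends before")
})

test_that("schedules expand to the documented dosing days", {
  daily <- treatment_plan("fingolimod", 0, 7)
  expect_identical(expand_schedule(daily, 100), 0:6)       # 7 daily doses
  nata <- treatment_plan("natalizumab", 0, 56)
  expect_identical(expand_schedule(nata, 100), c(0L, 28L)) # every 4 weeks
  ocr <- treatment_plan("ocrelizumab", 0, 400)
  expect_identical(expand_schedule(ocr, 400), c(0L, 182L, 364L))
  tiw <- treatment_plan("ifnb1a", 0, 14)
  expect_identical(expand_schedule(tiw, 100), c(0L, 2L, 4L, 7L, 9L, 11L))
  empty <- treatment_plan("fingolimod", 5, 5)
  expect_identical(expand_schedule(empty, 100), integer(0))
  # horizon truncates the window
  expect_identical(expand_schedule(daily, 3), 0:2)
})

test_that("drug effects compose and are neutral outside windows", {
  st <- init_state(seed = 1, scale = 0.2, lattice_side = 6)
  expect_identical(apply_treatment_effects(st, list()),
                   neutral_drug_effects())
  plans <- list(treatment_plan("natalizumab", 0, Inf),
                treatment_plan("fingolimod", 0, Inf))
  eff <- apply_treatment_effects(st, plans)
  cal <- default_calibration()
  expect_equal(eff$wm_ingress_scale, cal$natalizumab_ingress)
  expect_equal(eff$egress_scale, cal$fingolimod_egress)
  expect_true(eff$il17_suppressed)
  # two overlapping natalizumab windows compose multiplicatively
  eff2 <- apply_treatment_effects(st, list(treatment_plan("natalizumab"),
                                           treatment_plan("natalizumab")))
  expect_equal(eff2$wm_ingress_scale, cal$natalizumab_ingress^2)
  # outside the window the neutral state holds
  late <- list(treatment_plan("ocrelizumab", start_day = 1e5))
  expect_identical(apply_treatment_effects(st, late), neutral_drug_effects())
})

test_that("the bundled pathway network has 29 species and 13 reactions", {
  pm <- load_pathway_model()
  expect_identical(length(pm$species), 29L)
  expect_identical(length(pm$reactions), 13L)
  expect_identical(dim(pm$stoich), c(29L, 13L))
  # every reaction is nitrogen-balanced (stoichiometric consistency)
  expect_equal(unname(as.numeric(pm$nitrogen %*% pm$stoich)), rep(0, 13))
  # kinetic parameters positive (validated at load); inhibitor on DHODH
  dh <- Filter(function(r) r$name == "dhodh", pm$reactions)[[1]]
  expect_identical(dh$inhibitor, "Teriflunomide")
  expect_gt(dh$ki, 0)
})

test_that("non-competitive inhibition halves the DHODH rate at I = Ki", {
  pm <- load_pathway_model()
  dh <- Filter(function(r) r$name == "dhodh", pm$reactions)[[1]]
  y <- pm$init
  y[["DHO"]] <- 1e6   # saturating substrate
  y[["CoQ"]] <- 1e6
  y0 <- y; y0[["Teriflunomide"]] <- 0
  y1 <- y; y1[["Teriflunomide"]] <- dh$ki
  r0 <- mssim:::pathway_rates(y0, pm)[["dhodh"]]
  r1 <- mssim:::pathway_rates(y1, pm)[["dhodh"]]
  expect_equal(r1 / r0, 0.5, tolerance = 1e-9)
  expect_equal(r0, dh$vmax, tolerance = 1e-4)
})

test_that("closed-system integration conserves total nitrogen", {
  pm <- load_pathway_model()
  out <- integrate_pathway(pm, inhibitor_conc = 0, t_end = 40,
                           clamp_boundary = FALSE)
  totals <- as.matrix(out[, names(pm$init)]) %*% pm$nitrogen
  expect_lt(max(abs(totals - totals[1])) / totals[1], 1e-6)
})

test_that("teriflunomide multiplier is 1 at dose zero and strictly decreasing", {
  pm <- load_pathway_model()
  expect_identical(teriflunomide_multiplier(0, pm), 1)
  ladder <- vapply(c(7, 14, 28), teriflunomide_multiplier, 0, model = pm)
  expect_true(all(ladder > 0 & ladder < 1))
  expect_true(all(diff(ladder) < 0))
  expect_error(teriflunomide_multiplier(-1, pm), "dose")
})

test_that("trafficking blockade reduces oligodendrocyte damage and anti-CD20
           depletes B cells", {
  wm <- white_matter_config(volume_mm3 = 0.75, mri_loss_threshold = 12500)
  seeds <- derive_seeds(88, 2)
  loss <- function(plans) vapply(seeds, function(sd)
    simulate_course(disease = ms_reference_params(), horizon_years = 1,
                    seed = sd, scale = 0.25, lattice_side = 12, wm = wm,
                    plans = plans, record = FALSE)$total_odc_loss, 0)
  untreated <- loss(list())
  nata <- loss(list(treatment_plan("natalizumab")))
  expect_lt(mean(nata), mean(untreated))
  # anti-CD20: circulating B-cell count falls and stays depressed
  ocr <- simulate_course(disease = ms_reference_params(), horizon_years = 0.5,
                         seed = seeds[1], scale = 0.25, lattice_side = 12,
                         wm = wm, plans = list(treatment_plan("ocrelizumab")),
                         record = FALSE)
  base <- simulate_course(disease = ms_reference_params(), horizon_years = 0.5,
                          seed = seeds[1], scale = 0.25, lattice_side = 12,
                          wm = wm, record = FALSE)
  tail_idx <- seq(nrow(ocr$trajectories) - 100, nrow(ocr$trajectories))
  expect_lt(mean(ocr$trajectories$b_cells[tail_idx]),
            0.6 * mean(base$trajectories$b_cells[tail_idx]))
})
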
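# Engine: homeostasis, thymic selection, decay, interaction execution,
# step determinism.

test_that("hematopoiesis relaxes to the mean at rate ln2/tau", {
  p <- hematopoiesis_params(876, 3.3, noise_sd = 0)
  # fixed point
  expect_equal(hematopoiesis_step(876, p, 1), 876)
  # direct evaluation: delta = (ln2/3.3) * (876 - 1000) ~ -26.04
  delta <- hematopoiesis_step(1000, p, 1) - 1000
  expect_equal(delta, -26.04, tolerance = 0.001)
  # monotone deterministic convergence from both sides
  x <- 400
  for (k in 1:50) {
    x1 <- hematopoiesis_step(x, p, 1)
    expect_gt(x1, x); expect_lte(x1, 876)
    x <- x1
  }
  expect_error(hematopoiesis_step(100, p, 0), "dt")
  expect_error(hematopoiesis_params(876, 0), "positive")
})

test_that("thymic selection matches brute-force enumeration at l = 8", {
  params <- repertoire_params(bitstring_length = 8, min_mismatch_m0 = 1)
  ctx <- mhc_context(mhc1_alleles = c(0xB4L, 0x2FL), mhc2_alleles = 0x5AL,
                     self_peptides = c(0x0FL, 0xC3L), mbp_peptide = 0x0FL,
                     params = params)
  all_rec <- 0:255
  aff <- function(a, b) sum(as.integer(intToBits(bitwXor(a, b)))[1:8])
  oracle_keep <- function(rec, mhc_set) {
    pos <- max(vapply(mhc_set, function(m) aff(rec, m), 0)) >= 8 / 2 - 1
    complexes <- unlist(lapply(mhc_set, function(m)
      lapply(ctx$self_peptides, function(sp) bitwXor(m, sp))))
    neg <- max(vapply(complexes, function(cx) aff(rec, cx), 0)) >= 8 - 1
    pos && !neg
  }
  cand_tc <- data.frame(cell_type = "TC", receptor = all_rec)
  got <- thymus_select(cand_tc, ctx, params)$receptor
  want <- all_rec[vapply(all_rec, oracle_keep, TRUE,
                         mhc_set = ctx$mhc1_alleles)]
  expect_identical(got, want)
  cand_th <- data.frame(cell_type = "TH", receptor = all_rec)
  got_th <- thymus_select(cand_th, ctx, params)$receptor
  want_th <- all_rec[vapply(all_rec, oracle_keep, TRUE,
                            mhc_set = ctx$mhc2_alleles)]
  expect_identical(got_th, want_th)
  # boundary: affinity exactly l/2 - m0 to one MHC-II passes positive phase
  boundary <- want_th[vapply(want_th, function(r)
    aff(r, ctx$mhc2_alleles[1]) == 3, TRUE)]
  expect_gt(length(boundary), 0L)
  # maximal autoreactivity (perfect complement of a complex) is deleted
  worst <- mssim:::bitwNot_l(bitwXor(ctx$mhc1_alleles[1], 0x0FL), 8L)
  expect_false(worst %in% got)
  # empty input, and receptors are mandatory
  expect_identical(nrow(thymus_select(cand_tc[0, ], ctx, params)), 0L)
  expect_error(thymus_select(data.frame(cell_type = "TC", receptor = NA),
                             ctx, params), "receptor")
  # central-tolerance impairment admits more autoreactive receptors
  n_imp <- nrow(thymus_select(cand_tc, ctx, params, central_impairment = 1))
  expect_gte(n_imp, length(got))
})

test_that("decay halves molecule counts per half-life and spares ODC", {
  st <- init_state(seed = 8, lattice_side = 8, scale = 0.2)
  means <- replicate(100, {
    s <- st
    s$fields[[1]][, mssim:::mIL2] <- 0L
    s$fields[[1]][1:10, mssim:::mIL2] <- 100L
    s <- decay_step(s, 1.6)    # one IL-2 half-life
    sum(s$fields[[1]][, mssim:::mIL2])
  })
  expect_lt(abs(mean(means) - 500), 3 * sqrt(1000 * 0.25) / sqrt(100))
  # dt = 0 leaves the state untouched
  expect_identical(decay_step(st, 0), st)
  # oligodendrocytes are exempt from half-life decay
  odc0 <- sum(st$odc)
  st2 <- decay_step(st, 10)
  expect_identical(sum(st2$odc), odc0)
  # resting naive cells are exempt; active cells are mortal
  a <- st$ag
  a$state[a$type == mssim:::iTH] <- mssim:::sACT
  st$ag <- a
  n_th <- sum(a$type == mssim:::iTH)
  st3 <- decay_step(st, 3.3)  # one half-life
  left <- sum(st3$ag$type == mssim:::iTH)
  expect_lt(abs(left - n_th / 2), 3 * sqrt(n_th * 0.25) + 1)
})

test_that("immunocomplex formation consumes antibody and antigen exactly", {
  st <- init_state(seed = 4, lattice_side = 6, scale = 0.1)
  st$fields[[1]][, ] <- 0L
  st$fields[[2]][, ] <- 0L
  st$fields[[1]][5, mssim:::mIGG] <- 1L
  st$fields[[1]][5, mssim:::mMBP] <- 1L
  rule <- interaction_rule("IG_Ag", "h_ig_ag", "both", "aspecific",
                           params = list(p = 1))
  st1 <- mssim:::h_ig_ag(st, rule)
  expect_identical(st1$fields[[1]][5, mssim:::mIGG], 0L)
  expect_identical(st1$fields[[1]][5, mssim:::mMBP], 0L)
  expect_identical(st1$fields[[1]][5, mssim:::mIC], 1L)
})

test_that("sequential partner scan reproduces 1 - (1-q)^n", {
  set.seed(99)
  q <- 0.3; n_partners <- 5L; reps <- 4000L
  ai <- rep(seq_len(reps), each = n_partners)
  hits <- vapply(seq_len(reps), function(k) {
    win <- mssim:::bernoulli_scan(rep(1L, n_partners), rep(q, n_partners))
    any(win)
  }, TRUE)
  p_hat <- mean(hits)
  p_true <- 1 - (1 - q)^n_partners
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / reps))
  # at most one winning partner per actor, ever
  win <- mssim:::bernoulli_scan(ai, rep(0.9, length(ai)))
  expect_true(all(tapply(win, ai, sum) <= 1))
})

test_that("pair expansion enumerates exactly the co-located pairs", {
  actor_sites <- c(1L, 2L, 2L, 5L)
  partner_idx <- c(10L, 11L, 12L, 13L)
  partner_sites <- c(2L, 2L, 1L, 7L)
  pr <- mssim:::pair_expand(actor_sites, partner_idx, partner_sites, 10L)
  got <- data.frame(ai = pr$ai, pi = pr$pi)
  got <- got[order(got$ai, got$pi), ]
  want <- data.frame(ai = c(1L, 2L, 2L, 3L, 3L), pi = c(12L, 10L, 11L, 10L, 11L))
  expect_equal(got$ai, want$ai)
  expect_equal(got$pi, want$pi)
})

test_that("a fixed seed reproduces the trajectory bit for bit", {
  run <- function() {
    st <- init_state(disease = ms_reference_params(), seed = 123,
                     lattice_side = 8, scale = 0.25)
    run_steps(st, 40)$rec
  }
  expect_identical(run(), run())
})

test_that("an empty state is unchanged by a step except for the clock", {
  st <- init_state(seed = 6, lattice_side = 6, scale = 0.1)
  st$ag <- mssim:::ag_keep(st$ag, rep(FALSE, mssim:::ag_n(st$ag)))
  st$odc[] <- 0L
  st$cfg$hematopoiesis <- list()
  st$cfg$disease <- disease_params()   # apoptosis off
  st$cfg$odc_baseline <- 0
  st1 <- sim_step(st)
  expect_identical(st1$clock, st$clock + 1L)
  expect_identical(mssim:::ag_n(st1$ag), 0L)
  expect_identical(sum(st1$fields[[1]]) + sum(st1$fields[[2]]), 0L)
})

test_that("antigen-free pools stay inside the stationary homeostasis band", {
  st <- init_state(disease = disease_params(), seed = 14,
                   lattice_side = 8, scale = 0.5)
  st <- run_steps(st, 200)
  rec <- st$rec
  cv <- default_calibration()$homeostasis_cv
  for (series in c("resting_th1", "resting_tc", "resting_treg")) {
    mean_target <- rec[1, series]
    expect_true(all(abs(rec[, series] - mean_target) <
                      5 * cv * mean_target + 3 * sqrt(mean_target)))
  }
  # division counts never exceed the Hayflick limit
  expect_true(all(st$ag$div <= default_calibration()$hayflick_limit))
})
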
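# The synthetic summary-statistics generator: determinism, calibration of
# the variance explained and analytic SEs, scenario presets, and recovery
# of the generating parameters.

test_that("identical seeds give bit-identical datasets, different seeds differ", {
  t1 <- synthetic_truth(j_snps = 8, seed = 123)
  a <- generate_dataset(t1)
  b <- generate_dataset(t1)
  expect_identical(a$exposure, b$exposure)
  expect_identical(a$outcome, b$outcome)
  expect_identical(unclass(a$ld), unclass(b$ld))
  c <- generate_dataset(synthetic_truth(j_snps = 8, seed = 124))
  expect_false(identical(a$exposure$beta, c$exposure$beta))
  # generation does not disturb the caller's RNG stream
  set.seed(1)
  u1 <- runif(1)
  set.seed(1)
  invisible(generate_dataset(t1))
  u2 <- runif(1)
  expect_identical(u1, u2)
})

test_that("the generating identity theta_total = direct + kappa*mediated holds", {
  t <- synthetic_truth(theta_direct = -0.36, kappa = 0.3,
                       theta_mediator = -0.8)
  expect_equal(t$theta_total, -0.36 + 0.3 * -0.8)
  expect_equal(t$proportion_mediated, 0.3 * -0.8 / t$theta_total)
  expect_equal(t$proportion_mediated, 0.4)
})

test_that("true instrument effects reproduce the requested R2 to 1e-6", {
  for (seed in c(1, 7, 42)) {
    ds <- generate_dataset(synthetic_truth(j_snps = 6,
                                           instrument_r2 = 0.0137,
                                           seed = seed))
    r2 <- sum(variance_explained(ds$true_effects$eaf,
                                 ds$true_effects$exposure))
    expect_equal(r2, 0.0137, tolerance = 1e-6)
    if (ds$truth$j_mediator_snps > 0) {
      r2m <- sum(variance_explained(
        ds$true_effects$eaf[ds$true_effects$variant_id %in%
                              ds$mediator_instruments],
        ds$true_effects$mediator[ds$true_effects$variant_id %in%
                                   ds$mediator_instruments]))
      expect_equal(r2m, ds$truth$mediator_r2, tolerance = 1e-6)
    }
  }
})

test_that("sampling noise matches the analytic standard errors", {
  # standardised deviations (observed - true)/se across regenerations
  # should be standard normal; flips preserve |beta| so use flip-free runs
  reps <- 500
  z <- sapply(seq_len(reps), function(i) {
    ds <- generate_dataset(synthetic_truth(
      j_snps = 2, kappa = 0, theta_direct = -0.4, instrument_r2 = 0.002,
      seed = 5000L + i, flip_fraction = 0))
    c((ds$exposure$beta - ds$true_effects$exposure) / ds$exposure$se,
      (ds$outcome$beta - ds$true_effects$outcome) / ds$outcome$se)
  })
  expect_lt(abs(sd(as.vector(z)) - 1), 0.05)
  expect_lt(abs(mean(as.vector(z))), 3 / sqrt(length(z)))
  # analytic SE formula itself
  ds <- generate_dataset(synthetic_truth(j_snps = 3, seed = 1))
  v <- 2 * ds$true_effects$eaf * (1 - ds$true_effects$eaf)
  expect_equal(ds$exposure$se, 1 / sqrt(v * ds$truth$n_exposure),
               tolerance = 1e-12)
  cf <- ds$truth$case_fraction
  expect_equal(ds$outcome$se,
               1 / sqrt(v * ds$truth$n_outcome * cf * (1 - cf)),
               tolerance = 1e-12)
})

test_that("LD blocks produce correlated estimation noise and a matching matrix", {
  truth <- synthetic_truth(j_snps = 6, ld_block_r = 0.6, ld_block_size = 3,
                           seed = 2)
  ds <- generate_dataset(truth)
  R <- unclass(ds$ld)
  expect_equal(R[1, 2], 0.6)
  expect_equal(R[1, 4], 0)
  expect_equal(R, t(R))
  # empirical correlation of the outcome noise across regenerations
  reps <- 300
  zs <- sapply(seq_len(reps), function(i) {
    d <- generate_dataset(synthetic_truth(
      j_snps = 2, ld_block_r = 0.6, ld_block_size = 2, seed = 9000L + i,
      kappa = 0, theta_direct = 0, flip_fraction = 0))
    d$outcome$beta / d$outcome$se - 0  # true outcome beta is gamma*0 = 0
  })
  expect_lt(abs(cor(zs[1, ], zs[2, ]) - 0.6), 0.15)
})

test_that("sample overlap correlates exposure and outcome noise", {
  reps <- 300
  zs <- sapply(seq_len(reps), function(i) {
    d <- generate_dataset(synthetic_truth(
      j_snps = 1, overlap_fraction = 0.7, kappa = 0, theta_direct = 0,
      seed = 20000L + i, flip_fraction = 0))
    big <- generate_dataset(synthetic_truth(
      j_snps = 1, overlap_fraction = 0.7, kappa = 0, theta_direct = 0,
      seed = 20000L + i, flip_fraction = 0, n_exposure = 1e12))
    c((d$exposure$beta - big$exposure$beta) / d$exposure$se,
      d$outcome$beta / d$outcome$se)
  })
  expect_lt(abs(cor(zs[1, ], zs[2, ]) - 0.7), 0.15)
})

test_that("scenario presets carry the published instrument descriptions", {
  s <- study_scenario("mvpa")
  expect_equal(s$j_snps, 7L)
  expect_equal(s$n_exposure, 385790)
  expect_equal(s$instrument_r2, 7e-4)
  expect_equal(s$theta_total, log(0.56), tolerance = 1e-12)
  s2 <- study_scenario("ampa")
  expect_equal(s2$j_snps, 5L)
  expect_equal(s2$instrument_r2, 2e-3)
  expect_equal(s2$n_exposure, 91105)
  expect_equal(s2$proportion_mediated, 0.32, tolerance = 1e-12)
  s3 <- study_scenario("ampa_strict")
  expect_equal(s3$j_snps, 3L)
  expect_equal(s3$instrument_r2, 1e-3)
  s4 <- study_scenario("sedentary")
  expect_equal(s4$j_snps, 6L)
  expect_equal(s4$theta_total, 0)
  expect_error(study_scenario("unknown"))
  # overrides flow through while preserving the identity
  s5 <- study_scenario("ampa", theta_total = log(0.60),
                       proportion_mediated = 0.30)
  expect_equal(s5$theta_direct + s5$kappa * s5$theta_mediator,
               log(0.60), tolerance = 1e-12)
  expect_equal(s5$proportion_mediated, 0.30, tolerance = 1e-12)
})

test_that("univariable IVW recovers theta on a kappa-free scenario", {
  truth <- synthetic_truth(theta_direct = -0.4, kappa = 0, j_snps = 10,
                           instrument_r2 = 0.01, seed = 3)
  reps <- 100
  ests <- sapply(seq_len(reps), function(i) {
    ds <- generate_dataset(synthetic_truth(
      theta_direct = -0.4, kappa = 0, j_snps = 10, instrument_r2 = 0.01,
      seed = 30000L + i))
    mr_ivw(harmonise(ds$exposure, ds$outcome))$beta
  })
  mc_se <- sd(ests) / sqrt(reps)
  expect_lt(abs(mean(ests) - -0.4), 3 * mc_se + 0.01)
})

test_that("directional pleiotropy is detected by the Egger intercept", {
  reps <- 60
  hits <- sapply(seq_len(reps), function(i) {
    ds <- generate_dataset(synthetic_truth(
      theta_direct = -0.3, kappa = 0, j_snps = 30, instrument_r2 = 0.02,
      pleiotropy_mode = "directional", pleiotropy_sd = 0.05,
      seed = 40000L + i))
    mr_egger(harmonise(ds$exposure, ds$outcome))$intercept_pvalue < 0.05
  })
  expect_gte(mean(hits), 0.80)
})

test_that("datasets round-trip through the on-disk dialect", {
  ds <- generate_dataset(synthetic_truth(j_snps = 5, seed = 11))
  dir <- tempfile()
  paths <- write_dataset(ds, dir)
  expect_true(all(file.exists(paths)))
  back <- suppressMessages(read_summary_stats(paths[["exposure"]],
                                              "exposure"))
  expect_equal(back$beta, ds$exposure$beta, tolerance = 1e-12)
  ld <- read_ld_matrix(paths[["ld"]])
  expect_equal(unclass(ld), unclass(ds$ld), tolerance = 1e-12)
  truth_json <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth_json$theta_total, ds$truth$theta_total,
               tolerance = 1e-12)
  expect_equal(truth_json$seed, ds$truth$seed)
})
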
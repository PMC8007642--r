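# Univariable estimators against independent oracles, plus their
# invariants (scale equivariance, LD consistency, random >= fixed SE).

test_that("Wald ratios equal elementwise division with first-order SEs", {
  h <- toy_harmonised(bx = c(0.5, 0.1, -0.2), by = c(0.25, 0.05, 0.1),
                      sx = 0.01, sy = c(0.1, 0.02, 0.03))
  r <- ratio_estimates(h)
  expect_equal(r$ratio, c(0.25 / 0.5, 0.05 / 0.1, 0.1 / -0.2))
  expect_equal(r$se, c(0.1 / 0.5, 0.02 / 0.1, 0.03 / 0.2))
  # joint sign flip leaves the ratio unchanged
  h2 <- toy_harmonised(bx = -c(0.5, 0.1, -0.2), by = -c(0.25, 0.05, 0.1),
                       sx = 0.01, sy = c(0.1, 0.02, 0.03))
  expect_equal(ratio_estimates(h2)$ratio, r$ratio)
  h0 <- toy_harmonised(bx = c(0.5, 0), by = c(0.1, 0.1), sx = 0.01,
                       sy = 0.1)
  expect_error(ratio_estimates(h0), "zero exposure beta")
})

test_that("IVW equals the closed-form weighted regression oracle", {
  bx <- c(0.1, 0.2, 0.3)
  by <- c(0.05, 0.12, 0.14)
  sy <- rep(0.01, 3)
  h <- toy_harmonised(bx, by, sx = 0.005, sy = sy)
  o <- oracle_ivw(bx, by, sy)
  fixed <- mr_ivw(h, "fixed")
  expect_equal(fixed$beta, o$beta, tolerance = 1e-10)
  expect_equal(fixed$se, o$se, tolerance = 1e-10)
  q <- oracle_q(bx, by, sy, o$beta)
  expect_equal(fixed$q_statistic, q, tolerance = 1e-10)
  expect_equal(fixed$q_df, 2L)
  rand <- mr_ivw(h, "random")
  expect_equal(rand$se, o$se * max(1, sqrt(q / 2)), tolerance = 1e-10)
  expect_equal(rand$or, exp(rand$beta))
  expect_equal(rand$or_ci_low, exp(rand$beta - qnorm(0.975) * rand$se))
})

test_that("identical ratios collapse IVW to the common value with Q = 0", {
  bx <- c(0.1, 0.2, 0.4)
  h <- toy_harmonised(bx, 0.5 * bx, sx = 0.01, sy = c(0.01, 0.02, 0.05))
  e <- mr_ivw(h)
  expect_equal(e$beta, 0.5, tolerance = 1e-12)
  expect_equal(e$q_statistic, 0, tolerance = 1e-12)
  expect_equal(e$q_pvalue, 1)
})

test_that("a single variant degenerates to the Wald ratio with a warning", {
  h <- toy_harmonised(0.5, 0.25, 0.01, 0.1)
  expect_warning(e <- mr_ivw(h), "Wald ratio")
  expect_equal(e$beta, 0.5)
  expect_equal(e$se, 0.1 / 0.5)
})

test_that("IVW with an identity LD matrix equals IVW without LD", {
  ds <- generate_dataset(synthetic_truth(j_snps = 8, seed = 21))
  h0 <- harmonise(ds$exposure, ds$outcome)
  h1 <- harmonise(ds$exposure, ds$outcome, ld = ds$ld)
  e0 <- mr_ivw(h0)
  e1 <- mr_ivw(h1)
  expect_equal(e1$beta, e0$beta, tolerance = 1e-12)
  expect_equal(e1$se, e0$se, tolerance = 1e-12)
  expect_equal(e1$q_statistic, e0$q_statistic, tolerance = 1e-12)
})

test_that("correlated instruments are handled by generalised least squares", {
  truth <- synthetic_truth(j_snps = 12, seed = 31, ld_block_r = 0.5,
                           ld_block_size = 3L, theta_direct = -0.4,
                           kappa = 0, instrument_r2 = 0.05)
  ds <- generate_dataset(truth)
  h <- harmonise(ds$exposure, ds$outcome, ld = ds$ld)
  e <- mr_ivw(h)
  expect_true(abs(e$beta - truth$theta_total) < 4 * e$se)
  # ignoring the correlation misstates the precision relative to GLS
  e_naive <- mr_ivw(harmonise(ds$exposure, ds$outcome))
  expect_gt(e_naive$se * 1.5, e$se)  # GLS se not wildly larger
  expect_false(isTRUE(all.equal(e_naive$se, e$se, tolerance = 0.01)))
})

test_that("Egger recovers an exact affine relation to machine precision", {
  bx <- c(0.1, 0.2, 0.3, 0.5)
  a <- 0.02
  b <- -0.4
  by <- a + b * bx
  h <- toy_harmonised(bx, by, sx = 0.01, sy = c(0.01, 0.02, 0.01, 0.03))
  e <- mr_egger(h)
  expect_equal(e$beta, b, tolerance = 1e-12)
  expect_equal(e$intercept, a, tolerance = 1e-12)
  expect_equal(e$q_statistic, 0, tolerance = 1e-10)
  expect_equal(e$q_df, 2L)
})

test_that("Egger equals the two-parameter normal-equations oracle", {
  bx <- c(0.12, -0.2, 0.33, 0.5)   # includes a negative beta: orientation
  by <- c(0.05, -0.11, 0.1, 0.22)
  sy <- c(0.01, 0.02, 0.015, 0.03)
  h <- toy_harmonised(bx, by, sx = 0.01, sy = sy)
  o <- oracle_egger(bx, by, sy)
  e <- mr_egger(h)
  expect_equal(e$beta, o$slope, tolerance = 1e-10)
  expect_equal(e$intercept, o$intercept, tolerance = 1e-10)
  q <- oracle_q(abs(bx), by * sign(bx), sy, o$slope, o$intercept)
  scale <- max(1, sqrt(q / 2))
  expect_equal(e$se, o$se_slope * scale, tolerance = 1e-10)
  expect_equal(e$intercept_se, o$se_intercept * scale, tolerance = 1e-10)
})

test_that("Egger refuses equal exposure betas (collinear with intercept)", {
  h <- toy_harmonised(c(0.2, 0.2, 0.2), c(0.1, 0.12, 0.08), 0.01, 0.02)
  expect_error(mr_egger(h), "identifiable")
})

test_that("weighted median matches the exhaustive weighted-CDF oracle", {
  h <- toy_harmonised(bx = c(1, 1, 1), by = c(0.1, 0.5, 0.9), sx = 0.01,
                      sy = c(0.1, 0.1, 0.1))
  e <- mr_weighted_median(h, n_boot = 200, seed = 1)
  expect_equal(e$beta, 0.5)
  set.seed(33)
  for (rep in 1:10) {
    J <- 4 + rep %% 3
    bx <- runif(J, 0.1, 0.5)
    by <- rnorm(J, 0.3 * bx, 0.05)
    sy <- runif(J, 0.02, 0.1)
    h <- toy_harmonised(bx, by, sx = 0.01, sy = sy)
    e <- mr_weighted_median(h, n_boot = 50, seed = 1)
    expect_equal(e$beta,
                 oracle_weighted_median(by / bx, bx^2 / sy^2),
                 tolerance = 1e-10)
  }
})

test_that("weighted median refuses correlated instruments, naming the pair", {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.6
  ids <- sprintf("rs%d", 1:3)
  dimnames(R) <- list(ids, ids)
  h <- toy_harmonised(c(0.1, 0.2, 0.3), c(0.05, 0.1, 0.15), 0.01, 0.02,
                      ld = ld_matrix(R), ids = ids)
  expect_error(mr_weighted_median(h, n_boot = 10, seed = 1),
               "rs1 and rs2")
})

test_that("mode-based estimate matches the fine-grid density maximiser", {
  # majority mass at ratio 0.3, minority at 1.0
  bx <- rep(1, 10)
  by <- c(rep(0.3, 7), rep(1.0, 3)) + seq(-0.015, 0.015,
                                          length.out = 10)
  sy <- rep(0.05, 10)
  h <- toy_harmonised(bx, by, sx = 0.01, sy = sy)
  e <- mr_mode(h, n_boot = 100, seed = 2)
  ratio <- by / bx
  bw <- 0.9 * min(sd(ratio), mad(ratio)) * 10^(-1 / 5)
  o <- oracle_mode(ratio, bx^2 / sy^2, bw)
  expect_equal(e$beta, o, tolerance = 1e-4)
  expect_lt(abs(e$beta - 0.3), 0.1)
  # doubling phi smooths: the mode moves towards the overall centre
  e2 <- mr_mode(h, phi = 2, n_boot = 50, seed = 2)
  o2 <- oracle_mode(ratio, bx^2 / sy^2, 2 * bw)
  expect_equal(e2$beta, o2, tolerance = 1e-3)
  expect_true(e2$beta > min(ratio) && e2$beta < max(ratio))
  # degenerate case: identical ratios return the common value
  h3 <- toy_harmonised(c(1, 1, 1), c(0.5, 0.5, 0.5), 0.01, 0.05)
  e3 <- mr_mode(h3, n_boot = 50, seed = 3)
  expect_equal(e3$beta, 0.5)
})

test_that("simple and weighted modes differ when weights are informative", {
  bx <- rep(1, 9)
  by <- c(rep(0.3, 4), rep(0.8, 5))
  sy <- c(rep(0.02, 4), rep(0.2, 5))  # precise minority at 0.3
  h <- toy_harmonised(bx, by + rnorm(9, 0, 1e-3), sx = 0.01, sy = sy)
  ew <- mr_mode(h, weighted = TRUE, n_boot = 50, seed = 4)
  es <- mr_mode(h, weighted = FALSE, n_boot = 50, seed = 4)
  expect_lt(abs(ew$beta - 0.3), 0.1)
  expect_lt(abs(es$beta - 0.8), 0.1)
})

test_that("robust MM regression matches IVW on clean data", {
  set.seed(7)
  bx <- runif(10, 0.1, 0.4)
  by <- -0.3 * bx
  sy <- rep(0.02, 10)
  h <- toy_harmonised(bx, by, sx = 0.01, sy = sy)
  expect_equal(mr_robust(h)$beta, mr_ivw(h, "fixed")$beta,
               tolerance = 1e-6)
})

test_that("robust regression downweights a gross outlier", {
  set.seed(8)
  J <- 20
  bx <- runif(J, 0.1, 0.4)
  theta <- -0.3
  sy <- rep(0.02, J)
  by <- rnorm(J, theta * bx, sy)
  by[5] <- 10 * by[5]   # gross inflation
  h <- toy_harmonised(bx, by, sx = 0.01, sy = sy)
  rob <- mr_robust(h)
  ivw <- mr_ivw(h, "fixed")
  expect_lt(abs(rob$beta - theta), 2 * rob$se)
  expect_gt(abs(ivw$beta - theta), abs(rob$beta - theta))
  w <- attr(rob, "irls_weights")
  expect_lt(w[[5]], 0.01)
})

test_that("Cochran's Q equals the hand-computed weighted residual sum", {
  bx <- c(0.1, 0.2, 0.3)
  by <- c(0.05, 0.12, 0.14)
  sy <- c(0.01, 0.02, 0.015)
  h <- toy_harmonised(bx, by, sx = 0.01, sy = sy)
  q <- cochran_q(h, 0.45)
  expect_equal(q$q, oracle_q(bx, by, sy, 0.45), tolerance = 1e-12)
  expect_equal(q$df, 2L)
  expect_equal(q$pvalue, pchisq(q$q, 2, lower.tail = FALSE))
  expect_error(cochran_q(toy_harmonised(0.1, 0.1, 0.01, 0.02), 1),
               "degrees of freedom")
})

test_that("null Q is chi-square distributed (mean ~ J - 1)", {
  set.seed(12)
  J <- 30
  qs <- replicate(400, {
    bx <- runif(J, 0.1, 0.4)
    sy <- runif(J, 0.01, 0.05)
    by <- rnorm(J, 0.2 * bx, sy)
    h <- toy_harmonised(bx, by, sx = 1e-6, sy = sy)
    mr_ivw(h, "fixed")$q_statistic
  })
  expect_lt(abs(mean(qs) - (J - 1)), 3 * sqrt(2 * (J - 1) / 400))
})

test_that("estimates are scale-equivariant in the exposure betas", {
  ds <- generate_dataset(synthetic_truth(j_snps = 10, seed = 13))
  h <- harmonise(ds$exposure, ds$outcome)
  h2 <- h
  h2$exposure_beta <- h$exposure_beta * 2
  h2$exposure_se <- h$exposure_se * 2
  for (fit in list(function(g) mr_ivw(g)$beta,
                   function(g) mr_egger(g)$beta,
                   function(g) mr_weighted_median(g, 100, seed = 5)$beta,
                   function(g) mr_robust(g)$beta)) {
    expect_equal(fit(h2), fit(h) / 2, tolerance = 1e-6)
  }
})

test_that("random-effects SE is never below fixed-effects SE", {
  set.seed(14)
  for (rep in 1:10) {
    J <- 8
    bx <- runif(J, 0.1, 0.4)
    sy <- runif(J, 0.01, 0.05)
    by <- rnorm(J, 0.2 * bx, sy * sample(c(1, 3), 1))
    h <- toy_harmonised(bx, by, sx = 0.01, sy = sy)
    er <- mr_ivw(h, "random")
    ef <- mr_ivw(h, "fixed")
    expect_gte(er$se, ef$se)
    if (er$q_statistic <= J - 1) expect_equal(er$se, ef$se)
  }
})

test_that("all estimators agree with the truth on clean large-n data", {
  truth <- synthetic_truth(theta_direct = -0.5, kappa = 0,
                           j_snps = 50, instrument_r2 = 0.1,
                           n_exposure = 5e5, n_outcome = 5e5, seed = 17)
  ds <- generate_dataset(truth)
  h <- harmonise(ds$exposure, ds$outcome)
  res <- mr_all(h, n_boot = 300, seed = 18)
  for (i in seq_len(nrow(res))) {
    expect_lt(abs(res$beta[i] - truth$theta_total), 4 * res$se[i] + 0.02)
  }
  expect_setequal(res$method,
                  c("ivw_random", "ivw_fixed", "egger", "weighted_median",
                    "weighted_mode", "simple_mode", "robust"))
})

test_that("Egger intercept test holds its size under no pleiotropy", {
  set.seed(19)
  J <- 50
  reject <- replicate(400, {
    bx <- runif(J, 0.05, 0.3)
    sx <- rep(1e-6, J)
    sy <- runif(J, 0.01, 0.05)
    by <- rnorm(J, -0.2 * bx, sy)
    h <- toy_harmonised(bx, by, sx = sx, sy = sy)
    mr_egger(h)$intercept_pvalue < 0.05
  })
  rate <- mean(reject)
  expect_lt(abs(rate - 0.05), 0.05 / 2 + 2 * sqrt(0.05 * 0.95 / 400))
})
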
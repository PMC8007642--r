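# Multivariable MR: set assembly, the normal-equations oracle, reduction
# to univariable IVW, and beta-beta correlations.

toy_mv_h <- function(B, y, sy, ids = sprintf("rs%d", seq_len(nrow(B)))) {
  ex <- lapply(seq_len(ncol(B)), function(k) {
    toy_table(ids, "A", "G", 0.3, B[, k], 0.005,
              trait = paste0("X", k))
  })
  names(ex) <- paste0("X", seq_len(ncol(B)))
  out <- toy_table(ids, "A", "G", 0.3, y, sy, trait = "Y")
  suppressMessages(harmonise(ex, out))
}

test_that("mvmr_ivw equals the hand-solved weighted normal equations", {
  B <- cbind(c(0.10, 0.22, 0.31, 0.08, 0.15, 0.27),
             c(0.05, -0.10, 0.20, 0.12, -0.06, 0.09))
  y <- c(-0.02, -0.08, -0.05, -0.01, -0.06, -0.09)
  sy <- c(0.01, 0.02, 0.015, 0.02, 0.01, 0.02)
  h <- toy_mv_h(B, y, sy)
  o <- oracle_mvmr(B, y, sy)
  m <- mvmr_ivw(h, effects = "fixed")
  betas <- vapply(m$direct_estimates, `[[`, numeric(1), "beta")
  ses <- vapply(m$direct_estimates, `[[`, numeric(1), "se")
  expect_equal(unname(betas), o$coef, tolerance = 1e-10)
  expect_equal(unname(ses), o$se, tolerance = 1e-10)
  expect_equal(m$q_df, 4L)
  # random-effects scaling
  mr <- mvmr_ivw(h, effects = "random")
  scale <- max(1, sqrt(m$q_statistic / 4))
  expect_equal(vapply(mr$direct_estimates, `[[`, numeric(1), "se"),
               ses * scale, tolerance = 1e-10)
})

test_that("with one exposure mvmr_ivw reproduces univariable ivw exactly", {
  set.seed(41)
  bx <- runif(6, 0.1, 0.4)
  sy <- runif(6, 0.01, 0.03)
  by <- rnorm(6, -0.3 * bx, sy)
  hu <- toy_harmonised(bx, by, sx = 0.005, sy = sy)
  hm <- toy_mv_h(matrix(bx, ncol = 1), by, sy)
  u <- mr_ivw(hu, "random")
  m <- mvmr_ivw(hm, "random")
  expect_equal(m$direct_estimates[[1]]$beta, u$beta, tolerance = 1e-12)
  expect_equal(m$direct_estimates[[1]]$se, u$se, tolerance = 1e-12)
})

test_that("a zero second-exposure column reduces to univariable ivw", {
  set.seed(42)
  bx <- runif(6, 0.1, 0.4)
  sy <- rep(0.02, 6)
  by <- rnorm(6, -0.3 * bx, sy)
  B2 <- cbind(bx, 0)
  expect_warning(m <- mvmr_ivw(toy_mv_h(B2, by, sy), "fixed"),
                 "all-zero exposure column")
  u <- mr_ivw(toy_harmonised(bx, by, sx = 0.005, sy = sy), "fixed")
  expect_equal(m$direct_estimates[[1]]$beta, u$beta, tolerance = 1e-12)
  expect_true(is.na(m$direct_estimates[[2]]$beta))
})

test_that("permuting exposure columns permutes coefficients unchanged", {
  B <- cbind(c(0.1, 0.2, 0.3, 0.15, 0.25),
             c(0.05, -0.1, 0.2, 0.12, -0.06))
  y <- c(-0.02, -0.08, -0.05, -0.01, -0.06)
  sy <- rep(0.02, 5)
  m12 <- mvmr_ivw(toy_mv_h(B, y, sy))
  m21 <- mvmr_ivw(toy_mv_h(B[, 2:1], y, sy))
  expect_equal(m21$direct_estimates[[2]]$beta,
               m12$direct_estimates[[1]]$beta, tolerance = 1e-12)
  expect_equal(m21$direct_estimates[[1]]$beta,
               m12$direct_estimates[[2]]$beta, tolerance = 1e-12)
})

test_that("mvmr_egger recovers an exact affine model to machine precision", {
  B <- cbind(c(0.1, 0.2, 0.3, 0.15, 0.25, 0.05),
             c(0.05, -0.1, 0.2, 0.12, -0.06, 0.18))
  a <- 0.01
  th <- c(-0.4, 0.25)
  y <- a + drop(B %*% th)
  sy <- rep(0.02, 6)
  m <- mvmr_egger(toy_mv_h(B, y, sy))
  expect_equal(m$egger_intercept, a, tolerance = 1e-10)
  expect_equal(unname(vapply(m$direct_estimates, `[[`, numeric(1), "beta")),
               th, tolerance = 1e-10)
  expect_equal(m$q_df, 3L)
})

test_that("debiased MVMR solves the variance-corrected normal equations", {
  set.seed(47)
  J <- 8
  B <- cbind(runif(J, 0.1, 0.4), runif(J, -0.2, 0.3))
  sy <- runif(J, 0.01, 0.03)
  y <- rnorm(J, B %*% c(-0.3, 0.2), sy)
  sx <- matrix(runif(2 * J, 0.002, 0.01), J, 2)
  ids <- sprintf("rs%d", seq_len(J))
  ex <- lapply(1:2, function(k) {
    toy_table(ids, "A", "G", 0.3, B[, k], sx[, k], trait = paste0("X", k))
  })
  names(ex) <- c("X1", "X2")
  h <- suppressMessages(harmonise(ex, toy_table(ids, "A", "G", 0.3, y, sy,
                                                trait = "Y")))
  m <- mvmr_ivw(h, "fixed", debias = TRUE)
  # oracle: subtract the exposure sampling variances from the Gram matrix
  w <- 1 / sy^2
  A <- matrix(0, 2, 2)
  b <- numeric(2)
  for (j in seq_len(J)) {
    A <- A + w[j] * tcrossprod(B[j, ])
    b <- b + w[j] * B[j, ] * y[j]
  }
  A <- A - diag(colSums(w * sx^2))
  expect_equal(unname(vapply(m$direct_estimates, `[[`, numeric(1), "beta")),
               drop(solve(A, b)), tolerance = 1e-10)
  # with negligible exposure noise the correction vanishes
  ex0 <- lapply(ex, function(t) { t$se <- 1e-9; t })
  h0 <- suppressMessages(harmonise(ex0, toy_table(ids, "A", "G", 0.3, y,
                                                  sy, trait = "Y")))
  m0 <- mvmr_ivw(h0, "fixed", debias = TRUE)
  plain <- mvmr_ivw(h0, "fixed")
  expect_equal(vapply(m0$direct_estimates, `[[`, numeric(1), "beta"),
               vapply(plain$direct_estimates, `[[`, numeric(1), "beta"),
               tolerance = 1e-8)
})

test_that("rank deficiency is reported with the collinear pair", {
  bx <- c(0.1, 0.2, 0.3, 0.15, 0.25)
  B <- cbind(bx, 2 * bx)
  y <- rnorm(5, -0.3 * bx, 0.02)
  expect_error(mvmr_ivw(toy_mv_h(B, y, rep(0.02, 5))),
               "rank-deficient.*X1.*X2")
})

test_that("build_mvmr_set unions, de-duplicates and prunes across sets", {
  ids_a <- c("rs1", "rs2", "rs3")
  ids_b <- c("rs3", "rs4", "rs5", "rs6")
  all_ids <- c("rs1", "rs2", "rs3", "rs4", "rs5", "rs6")
  ex1 <- toy_table(all_ids, "A", "G", 0.3,
                   c(0.3, 0.28, 0.25, 0.01, 0.02, 0.01), 0.01, trait = "pa")
  ex2 <- toy_table(all_ids, "A", "G", 0.3,
                   c(0.01, 0.02, 0.2, 0.3, 0.28, 0.26), 0.01, trait = "fat")
  out <- toy_table(all_ids, "A", "G", 0.3, rnorm(6, 0, 0.02), 0.02,
                   trait = "crc")
  i1 <- select_instruments(ex1[ex1$variant_id %in% ids_a, ], 1)
  i2 <- select_instruments(ex2[ex2$variant_id %in% ids_b, ], 1)
  h <- suppressMessages(build_mvmr_set(list(pa = i1, fat = i2),
                                       list(pa = ex1, fat = ex2), out))
  expect_setequal(h$variant_id, all_ids)          # union, rs3 once
  expect_equal(n_variants(h), 6L)
  # cross-set LD: rs1 (smaller p in pa) correlated with rs4
  R <- diag(6)
  dimnames(R) <- list(all_ids, all_ids)
  R["rs1", "rs4"] <- R["rs4", "rs1"] <- sqrt(0.5)
  h2 <- suppressMessages(build_mvmr_set(list(pa = i1, fat = i2),
                                        list(pa = ex1, fat = ex2), out,
                                        ld = ld_matrix(R)))
  kept_of_pair <- intersect(h2$variant_id, c("rs1", "rs4"))
  expect_length(kept_of_pair, 1L)
  dropped_of_pair <- setdiff(c("rs1", "rs4"), kept_of_pair)
  lower_p <- if (min(i1$pvalues[c("rs1")]) <=
                   min(i2$pvalues[c("rs4")])) "rs1" else "rs4"
  expect_identical(kept_of_pair, lower_p)
  expect_true(dropped_of_pair %in% h2$dropped$variant_id)
})

test_that("union variants missing from a table are dropped, not imputed", {
  ids <- sprintf("rs%d", 1:5)
  ex1 <- toy_table(ids, "A", "G", 0.3, rep(0.3, 5), 0.01, trait = "pa")
  ex2 <- toy_table(ids[1:3], "A", "G", 0.3, rep(0.25, 3), 0.01,
                   trait = "fat")
  out <- toy_table(ids, "A", "G", 0.3, rnorm(5, 0, 0.02), 0.02,
                   trait = "crc")
  i1 <- select_instruments(ex1, 1)
  i2 <- select_instruments(ex2, 1)
  expect_warning(
    suppressMessages(build_mvmr_set(list(pa = i1, fat = i2),
                                    list(pa = ex1, fat = ex2), out)),
    "20%")
  h <- suppressMessages(suppressWarnings(
    build_mvmr_set(list(pa = i1, fat = i2),
                   list(pa = ex1, fat = ex2), out)))
  expect_false("rs5" %in% h$variant_id)
  expect_setequal(h$dropped$variant_id[h$dropped$reason == "missing"],
                  c("rs4", "rs5"))
})

test_that("beta-beta correlation is the aligned Pearson coefficient", {
  ids <- sprintf("rs%d", 1:5)
  b1 <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  b2 <- c(0.12, 0.18, 0.33, 0.38, 0.52)
  t1 <- toy_table(ids, "A", "G", 0.3, b1, 0.01, trait = "a")
  t2 <- toy_table(ids, "A", "G", 0.3, b2, 0.01, trait = "b")
  cc <- beta_beta_correlation(list(a = t1, b = t2))
  expect_equal(cc["a", "b"], cor(b1, b2), tolerance = 1e-12)
  expect_equal(diag(cc), c(a = 1, b = 1))
  # a table reported on swapped alleles gives the same correlation
  t2f <- t2
  t2f$effect_allele <- "G"
  t2f$other_allele <- "A"
  t2f$beta <- -t2f$beta
  t2f$eaf <- 1 - t2f$eaf
  cc2 <- beta_beta_correlation(list(a = t1, b = t2f))
  expect_equal(cc2["a", "b"], cor(b1, b2), tolerance = 1e-12)
  # negated effects correlate at -1 with themselves
  t3 <- toy_table(ids, "A", "G", 0.3, -b1, 0.01, trait = "c")
  cc3 <- beta_beta_correlation(list(a = t1, c = t3))
  expect_equal(cc3["a", "c"], -1, tolerance = 1e-12)
  # fewer than 3 shared variants -> NA
  cc4 <- beta_beta_correlation(list(a = t1[1:2, ], b = t2))
  expect_true(is.na(cc4["a", "b"]))
})

test_that("mvmr direct and univariable total bracket a mediated effect", {
  truth <- study_scenario("ampa", seed = 77)
  ds <- generate_dataset(truth)
  hu <- harmonise(ds$exposure[ds$exposure$variant_id %in%
                                ds$exposure_instruments, ], ds$outcome)
  total <- mr_ivw(hu)
  inst <- list(exposure = select_instruments(ds$exposure, 1e-4),
               mediator = select_instruments(ds$mediator, 5e-8))
  hm <- suppressMessages(build_mvmr_set(
    inst, list(exposure = ds$exposure, mediator = ds$mediator),
    ds$outcome))
  m <- mvmr_ivw(hm)
  direct <- m$direct_estimates$exposure
  med <- m$direct_estimates$mediator
  expect_lt(abs(total$beta - truth$theta_total), 4 * total$se)
  expect_lt(abs(direct$beta - truth$theta_direct), 4 * direct$se)
  expect_lt(abs(med$beta - truth$theta_mediator), 4 * med$se)
})
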
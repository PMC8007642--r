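# Univariable two-sample MR estimators on a harmonised set.
#
# Throughout, x = variant-exposure betas (SD units), y = variant-outcome
# betas (log-OR), weights w = 1/se_y^2.  With an LD matrix R attached, the
# outcome betas have covariance Sigma with Sigma_jk = se_yj * se_yk * r_jk
# and all least-squares fits become generalised least squares.

new_mr_estimate <- function(method, beta, se, n_snps, q = NA_real_,
                            q_df = NA_integer_, intercept = NA_real_,
                            intercept_se = NA_real_, exposure = NA_character_,
                            outcome = NA_character_) {
  beta <- unname(beta)
  se <- unname(se)
  q <- unname(q)
  intercept <- unname(intercept)
  intercept_se <- unname(intercept_se)
  ci_low <- beta - Z95 * se
  ci_high <- beta + Z95 * se
  q_pvalue <- if (is.finite(q) && !is.na(q_df) && q_df > 0)
    stats::pchisq(q, q_df, lower.tail = FALSE) else NA_real_
  structure(list(
    method = method,
    exposure = exposure,
    outcome = outcome,
    beta = beta,
    se = se,
    ci_low = ci_low,
    ci_high = ci_high,
    pvalue = normal_p(beta, se),
    or = exp(beta),
    or_ci_low = exp(ci_low),
    or_ci_high = exp(ci_high),
    n_snps = n_snps,
    q_statistic = q,
    q_df = q_df,
    q_pvalue = q_pvalue,
    heterogeneity = is.finite(q_pvalue) && q_pvalue < 0.10,
    intercept = intercept,
    intercept_se = intercept_se,
    intercept_pvalue = if (is.finite(intercept)) normal_p(intercept, intercept_se)
                       else NA_real_
  ), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.4f (SE %.4f), OR = %.3f (95%% CI %.3f, %.3f), p = %.3g, %d SNPs\n",
              x$method, x$beta, x$se, x$or, x$or_ci_low, x$or_ci_high,
              x$pvalue, x$n_snps))
  if (is.finite(x$q_statistic) && !is.na(x$q_df) && x$q_df > 0) {
    cat(sprintf("  Cochran's Q = %.3f on %d df, p = %.3g%s\n", x$q_statistic,
                x$q_df, x$q_pvalue,
                if (isTRUE(x$heterogeneity)) " (heterogeneity at P < 0.10)" else ""))
  }
  if (is.finite(x$intercept)) {
    cat(sprintf("  intercept = %.4g (SE %.4g), p = %.3g\n", x$intercept,
                x$intercept_se, x$intercept_pvalue))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, exposure = x$exposure, outcome = x$outcome,
             beta = x$beta, se = x$se, ci_low = x$ci_low, ci_high = x$ci_high,
             pvalue = x$pvalue, or = x$or, or_ci_low = x$or_ci_low,
             or_ci_high = x$or_ci_high, n_snps = x$n_snps,
             q_statistic = x$q_statistic, q_df = x$q_df,
             q_pvalue = x$q_pvalue, intercept = x$intercept,
             intercept_se = x$intercept_se,
             intercept_pvalue = x$intercept_pvalue,
             stringsAsFactors = FALSE)
}

# pull the single-exposure columns, checking preconditions
xy_of <- function(h, exposure = 1L, require_nonzero = TRUE) {
  if (is.character(exposure)) exposure <- match(exposure, h$exposure_ids)
  x <- h$exposure_beta[, exposure]
  if (require_nonzero && any(x == 0)) {
    stop_mr("zero exposure beta for variant(s): ",
            paste(h$variant_id[x == 0], collapse = ", "))
  }
  list(x = x, sx = h$exposure_se[, exposure], y = h$outcome_beta,
       sy = h$outcome_se, ids = h$variant_id,
       exposure = h$exposure_ids[exposure], outcome = h$outcome_id)
}

sigma_of <- function(h) {
  if (is.null(h$ld)) return(NULL)
  R <- unclass(h$ld)
  outer(h$outcome_se, h$outcome_se) * R
}

# GLS fit of y on design X with error covariance Sigma (or diag(sy^2)).
# Returns coefficients, their covariance (fixed-effects), and the weighted
# residual sum of squares (Cochran's Q generalisation).
gls_fit <- function(X, y, sy, Sigma = NULL) {
  X <- as.matrix(X)
  if (is.null(Sigma)) {
    w <- 1 / sy^2
    XtWX <- crossprod(X * w, X)
    XtWy <- crossprod(X * w, y)
  } else {
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) {
      stop_mr("singular outcome covariance (LD matrix); prune correlated ",
              "variants or regularise the matrix",
              class = "mrmediate_singular_error")
    }
    Xs <- backsolve(ch, X, transpose = TRUE)
    ys <- backsolve(ch, y, transpose = TRUE)
    XtWX <- crossprod(Xs)
    XtWy <- crossprod(Xs, ys)
  }
  cov_fixed <- tryCatch(solve(XtWX), error = function(e) {
    stop_mr("singular normal equations in weighted regression",
            class = "mrmediate_singular_error")
  })
  coef <- drop(cov_fixed %*% XtWy)
  resid <- y - drop(X %*% coef)
  q <- if (is.null(Sigma)) sum(resid^2 / sy^2) else {
    rs <- backsolve(chol(Sigma), resid, transpose = TRUE)
    sum(rs^2)
  }
  list(coef = coef, cov = cov_fixed, q = q)
}

#' Per-variant Wald ratio estimates
#'
#' The ratio `beta_outcome / beta_exposure` per variant with first-order
#' standard error `se_outcome / |beta_exposure|`.
#'
#' @param h A single-exposure `harmonised_set` (see [harmonise()]).
#' @param exposure Column index or name of the exposure (default first).
#' @return A data.frame with `variant_id`, `ratio`, `se`.
#' @export
ratio_estimates <- function(h, exposure = 1L) {
  d <- xy_of(h, exposure)
  data.frame(variant_id = d$ids, ratio = d$y / d$x, se = d$sy / abs(d$x),
             stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted estimator
#'
#' Weighted regression of outcome betas on exposure betas through the
#' origin with weights `1/se_outcome^2` (equivalently, the inverse-variance
#' pooled Wald ratio).  With an LD matrix attached the fit is generalised
#' least squares under the induced outcome covariance, which is how
#' correlated instruments are accommodated.  The random-effects
#' (multiplicative) model scales the fixed-effects standard error by
#' `max(1, sqrt(Q / (J - 1)))`.
#'
#' @param h A single-exposure `harmonised_set`.
#' @param effects `"random"` (default) or `"fixed"`.
#' @param exposure Exposure column to use.
#' @return An `mr_estimate` with Cochran's Q on `J - 1` df; heterogeneity is
#'   flagged at `q_pvalue < 0.10`.
#' @examples
#' ds <- generate_dataset(synthetic_truth(j_snps = 8, seed = 3))
#' mr_ivw(harmonise(ds$exposure, ds$outcome))
#' @export
mr_ivw <- function(h, effects = c("random", "fixed"), exposure = 1L) {
  effects <- match.arg(effects)
  d <- xy_of(h, exposure)
  J <- length(d$x)
  if (J == 1L) {
    warning("single-variant set: IVW degenerates to the Wald ratio",
            call. = FALSE)
    return(new_mr_estimate(paste0("ivw_", effects), d$y / d$x,
                           d$sy / abs(d$x), 1L, q = 0, q_df = 0L,
                           exposure = d$exposure, outcome = d$outcome))
  }
  fit <- gls_fit(matrix(d$x, ncol = 1L), d$y, d$sy, sigma_of(h))
  se <- sqrt(fit$cov[1L, 1L])
  if (effects == "random") se <- se * max(1, sqrt(fit$q / (J - 1)))
  new_mr_estimate(paste0("ivw_", effects), fit$coef[1L], se, J, q = fit$q,
                  q_df = J - 1L, exposure = d$exposure, outcome = d$outcome)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas with an intercept.
#' Rows are first oriented so all exposure betas are positive (the intercept
#' is only interpretable on a fixed orientation).  A non-zero intercept
#' (tested at p < 0.05) indicates directional pleiotropy or an InSIDE
#' violation; the slope is the pleiotropy-adjusted causal estimate.
#' Standard errors use the multiplicative random-effects scaling
#' `max(1, sqrt(Q / (J - 2)))`.
#'
#' @inheritParams mr_ivw
#' @return An `mr_estimate` with `intercept`, `intercept_se`,
#'   `intercept_pvalue` and Q on `J - 2` df.
#' @export
mr_egger <- function(h, exposure = 1L) {
  d <- xy_of(h, exposure)
  J <- length(d$x)
  if (J < 3L) stop_mr("MR-Egger needs at least 3 variants")
  s <- sign(d$x)
  x <- abs(d$x)
  y <- d$y * s
  if (max(x) - min(x) < 1e-12 * max(x)) {
    stop_mr("exposure betas all equal after orientation; Egger slope and ",
            "intercept are not separately identifiable",
            class = "mrmediate_identifiability_error")
  }
  Sigma <- sigma_of(h)
  if (!is.null(Sigma)) Sigma <- Sigma * outer(s, s)  # flip rows consistently
  fit <- gls_fit(cbind(1, x), y, d$sy, Sigma)
  scale <- max(1, sqrt(fit$q / (J - 2)))
  new_mr_estimate("egger", fit$coef[2L], sqrt(fit$cov[2L, 2L]) * scale, J,
                  q = fit$q, q_df = J - 2L,
                  intercept = fit$coef[1L],
                  intercept_se = sqrt(fit$cov[1L, 1L]) * scale,
                  exposure = d$exposure, outcome = d$outcome)
}

# weighted median of values v with weights w: linear interpolation of the
# weighted empirical CDF evaluated at midpoints of the cumulative weights
weighted_median_point <- function(v, w) {
  ord <- order(v)
  v <- v[ord]
  w <- w[ord] / sum(w)
  cum <- cumsum(w) - w / 2
  if (0.5 <= cum[1L]) return(v[1L])
  if (0.5 >= cum[length(cum)]) return(v[length(v)])
  stats::approx(cum, v, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median estimator
#'
#' The inverse-variance weighted median of per-variant Wald ratios, giving a
#' consistent estimate when at least half the weight comes from valid
#' instruments.  The standard error comes from a parametric bootstrap that
#' redraws exposure and outcome betas from their sampling distributions.
#' Instruments must be mutually uncorrelated: sets built with a retained
#' correlation structure must be pruned first (see [prune_correlated()]).
#'
#' @inheritParams mr_ivw
#' @param n_boot Bootstrap replicates for the SE (default 10000).
#' @param seed Optional seed for the bootstrap (RNG state is restored).
#' @param ld_r2_threshold Maximum tolerated pairwise squared correlation when
#'   an LD matrix is attached (default 0.2).
#' @return An `mr_estimate` (no Q statistic: the estimator is not a
#'   regression fit).
#' @export
mr_weighted_median <- function(h, n_boot = 10000L, seed = NULL,
                               exposure = 1L, ld_r2_threshold = 0.2) {
  d <- xy_of(h, exposure)
  J <- length(d$x)
  if (J < 3L) stop_mr("weighted median needs at least 3 variants")
  if (!is.null(h$ld)) {
    R2 <- unclass(h$ld)^2
    diag(R2) <- 0
    if (max(R2) > ld_r2_threshold) {
      worst <- sort(which(R2 == max(R2), arr.ind = TRUE)[1L, ])
      stop_mr("weighted median requires uncorrelated instruments; r2 = ",
              format(max(R2), digits = 3), " between ",
              h$variant_id[worst[1L]], " and ", h$variant_id[worst[2L]],
              "; prune the set first")
    }
  }
  ratio <- d$y / d$x
  w <- d$x^2 / d$sy^2
  beta <- weighted_median_point(ratio, w)
  boots <- with_seed(seed, {
    xs <- matrix(stats::rnorm(n_boot * J, d$x, d$sx), n_boot, J, byrow = TRUE)
    ys <- matrix(stats::rnorm(n_boot * J, d$y, d$sy), n_boot, J, byrow = TRUE)
    vapply(seq_len(n_boot), function(b) {
      weighted_median_point(ys[b, ] / xs[b, ], xs[b, ]^2 / d$sy^2)
    }, numeric(1L))
  })
  new_mr_estimate("weighted_median", beta, stats::sd(boots), J,
                  exposure = d$exposure, outcome = d$outcome)
}

# weighted normal-kernel density of ratios evaluated by grid + local refine
mode_point <- function(ratio, w, bw, n_grid = 512L, refine = TRUE) {
  w <- w / sum(w)
  lo <- min(ratio) - 3 * bw
  hi <- max(ratio) + 3 * bw
  grid <- seq(lo, hi, length.out = n_grid)
  dens <- colSums(w * vapply(grid, function(g) {
    stats::dnorm((g - ratio) / bw)
  }, numeric(length(ratio))))
  best <- grid[which.max(dens)]
  if (!refine) return(best)
  step <- (hi - lo) / (n_grid - 1L)
  f <- function(g) -sum(w * stats::dnorm((g - ratio) / bw))
  stats::optimize(f, lower = best - step, upper = best + step)$minimum
}

# modified Silverman bandwidth (robust scale, rank-based exponent)
mode_bandwidth <- function(ratio, phi) {
  s <- 0.9 * min(stats::sd(ratio), stats::mad(ratio)) *
    length(ratio)^(-1 / 5)
  phi * s
}

#' Mode-based estimator
#'
#' The mode of the smoothed distribution of per-variant Wald ratios (normal
#' kernel, modified-Silverman bandwidth scaled by `phi`), weighted by
#' inverse ratio variance when `weighted = TRUE`.  Consistent when the
#' largest group of instruments sharing one causal estimate is valid.
#' Standard error by parametric bootstrap.
#'
#' @inheritParams mr_weighted_median
#' @param phi Bandwidth multiplier (default 1).
#' @param weighted Use inverse-variance weights (default `TRUE`); `FALSE`
#'   gives the simple mode.
#' @return An `mr_estimate` with method `weighted_mode` or `simple_mode`.
#' @export
mr_mode <- function(h, phi = 1, weighted = TRUE, n_boot = 10000L,
                    seed = NULL, exposure = 1L) {
  d <- xy_of(h, exposure)
  J <- length(d$x)
  if (J < 3L) stop_mr("mode-based estimator needs at least 3 variants")
  ratio <- d$y / d$x
  wts <- function(x) if (weighted) x^2 / d$sy^2 else rep(1, J)
  bw <- mode_bandwidth(ratio, phi)
  beta <- if (bw <= 0 || !is.finite(bw)) ratio[1L]
          else mode_point(ratio, wts(d$x), bw)
  boots <- with_seed(seed, {
    xs <- matrix(stats::rnorm(n_boot * J, d$x, d$sx), n_boot, J, byrow = TRUE)
    ys <- matrix(stats::rnorm(n_boot * J, d$y, d$sy), n_boot, J, byrow = TRUE)
    vapply(seq_len(n_boot), function(b) {
      rb <- ys[b, ] / xs[b, ]
      bwb <- mode_bandwidth(rb, phi)
      if (bwb <= 0 || !is.finite(bwb)) return(rb[1L])
      mode_point(rb, wts(xs[b, ]), bwb, n_grid = 256L, refine = FALSE)
    }, numeric(1L))
  })
  new_mr_estimate(if (weighted) "weighted_mode" else "simple_mode", beta,
                  stats::sd(boots), J, exposure = d$exposure,
                  outcome = d$outcome)
}

#' Robust (MM-estimation) regression estimator
#'
#' MM regression of the precision-standardised outcome betas on the
#' precision-standardised exposure betas through the origin with Tukey's
#' bisquare loss, which bounds the influence of pleiotropic outliers.
#' Fitted with iteratively reweighted least squares via [MASS::rlm()]
#' (tolerance 1e-10, at most 200 iterations).
#'
#' @inheritParams mr_ivw
#' @param tuning Tukey bisquare tuning constant (default 4.685, 95%
#'   Gaussian efficiency).
#' @return An `mr_estimate`; the converged IRLS weights are attached as
#'   attribute `irls_weights` (named by variant).
#' @export
mr_robust <- function(h, tuning = 4.685, exposure = 1L) {
  d <- xy_of(h, exposure)
  J <- length(d$x)
  if (J < 3L) stop_mr("robust estimator needs at least 3 variants")
  dat <- data.frame(yw = unname(d$y / d$sy), xw = unname(d$x / d$sy))
  # an (almost) exact linear fit has zero residual scale, which the robust
  # scale estimate cannot handle; the bisquare M-estimate then coincides
  # with weighted least squares
  ls_beta <- sum(dat$xw * dat$yw) / sum(dat$xw^2)
  resid0 <- dat$yw - ls_beta * dat$xw
  if (stats::mad(resid0, center = 0) < 1e-10 * max(abs(dat$yw), 1e-300)) {
    f <- mr_ivw(h, "fixed", exposure)
    est <- new_mr_estimate("robust", f$beta, f$se, J, q = f$q_statistic,
                           q_df = J - 1L, exposure = d$exposure,
                           outcome = d$outcome)
    attr(est, "irls_weights") <- stats::setNames(rep(1, J), d$ids)
    return(est)
  }
  fit <- MASS::rlm(yw ~ xw - 1, data = dat, method = "MM",
                   psi = MASS::psi.bisquare, c = tuning, maxit = 200L,
                   acc = 1e-10)
  if (!fit$converged) {
    stop_mr("robust MM regression failed to converge after 200 iterations")
  }
  beta <- unname(stats::coef(fit)[1L])
  se <- sqrt(stats::vcov(fit)[1L, 1L])
  q <- cochran_q(h, beta, exposure = exposure)
  est <- new_mr_estimate("robust", beta, se, J, q = q$q, q_df = q$df,
                         exposure = d$exposure, outcome = d$outcome)
  attr(est, "irls_weights") <- stats::setNames(fit$w, d$ids)
  est
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum w_j (y_j - intercept - beta * x_j)^2` with `w = 1/se_y^2`
#' (generalised form under an attached LD matrix), compared to a chi-square
#' distribution on `J - 1` df (`J - 2` when an intercept was fitted).
#' Heterogeneity is conventionally called at p < 0.10.
#'
#' @inheritParams mr_ivw
#' @param beta Fitted causal slope.
#' @param intercept Fitted intercept (default `NULL`: none).
#' @return A list with `q`, `df`, `pvalue`.
#' @export
cochran_q <- function(h, beta, intercept = NULL, exposure = 1L) {
  d <- xy_of(h, exposure, require_nonzero = FALSE)
  J <- length(d$x)
  df <- J - 1L - !is.null(intercept)
  if (df <= 0L) stop_mr("Cochran's Q needs positive degrees of freedom")
  a <- intercept %||% 0
  resid <- d$y - a - beta * d$x
  Sigma <- sigma_of(h)
  q <- if (is.null(Sigma)) sum(resid^2 / d$sy^2) else {
    rs <- backsolve(chol(Sigma), resid, transpose = TRUE)
    sum(rs^2)
  }
  list(q = q, df = df, pvalue = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Run the full univariable estimator suite
#'
#' @inheritParams mr_weighted_median
#' @param methods Which estimators to run.
#' @return A data.frame with one row per estimator (the tidy forest-table
#'   layout); the `mr_estimate` objects are attached as attribute
#'   `estimates`.
#' @export
mr_all <- function(h, methods = c("ivw_random", "ivw_fixed", "egger",
                                  "weighted_median", "weighted_mode",
                                  "simple_mode", "robust"),
                   n_boot = 1000L, seed = NULL, exposure = 1L) {
  correlated <- !is.null(h$ld) && {
    R2 <- unclass(h$ld)^2; diag(R2) <- 0; max(R2) > 0.2
  }
  run <- list(
    ivw_random = function() mr_ivw(h, "random", exposure),
    ivw_fixed = function() mr_ivw(h, "fixed", exposure),
    egger = function() mr_egger(h, exposure),
    weighted_median = function()
      mr_weighted_median(h, n_boot, seed, exposure),
    weighted_mode = function()
      mr_mode(h, weighted = TRUE, n_boot = n_boot, seed = seed,
              exposure = exposure),
    simple_mode = function()
      mr_mode(h, weighted = FALSE, n_boot = n_boot, seed = seed,
              exposure = exposure),
    robust = function() mr_robust(h, exposure = exposure)
  )
  ests <- list()
  for (m in methods) {
    if (correlated && m %in% c("weighted_median", "weighted_mode",
                               "simple_mode")) {
      message(sprintf("[estimators] skipping %s: correlated instruments retained (prune first)", m))
      next
    }
    ests[[m]] <- run[[m]]()
  }
  out <- do.call(rbind, lapply(ests, as.data.frame))
  rownames(out) <- NULL
  attr(out, "estimates") <- ests
  out
}
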
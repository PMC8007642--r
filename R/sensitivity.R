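# Outlier and pleiotropy diagnostics: MR-PRESSO (global, per-variant outlier
# and distortion tests), leave-one-out influence, and the joint rule that
# promotes an outlier-free fit to the main analysis only when both
# diagnostics agree.

ivw_beta_point <- function(x, y, w) sum(w * x * y) / sum(w * x^2)

#' MR-PRESSO pleiotropy residual sum and outlier test
#'
#' The observed statistic is the inverse-variance-weighted residual sum of
#' squares where each variant's residual is taken against the IVW fit that
#' leaves that variant out.  Its null distribution is built by parametric
#' simulation: exposure betas are redrawn from their sampling distributions
#' and outcome betas from the leave-one-out fitted values, and the same
#' statistic is recomputed for each simulated dataset.  The global p-value
#' is the rank-based exceedance probability (Monte-Carlo resolution
#' `1/(n_simulations + 1)`).  Each variant's weighted squared residual is
#' compared with its own simulated distribution and Bonferroni-adjusted
#' across variants; adjusted p-values below `outlier_alpha` flag the variant
#' as a horizontal-pleiotropy outlier.  When any variant is flagged, a
#' distortion test compares the raw and outlier-corrected IVW estimates
#' against the shifts produced by removing equally many randomly chosen
#' non-flagged variants.
#'
#' @inheritParams mr_ivw
#' @param n_simulations Parametric simulations (default 10000).
#' @param outlier_alpha Significance level for the Bonferroni-adjusted
#'   per-variant outlier test (default 0.05).
#' @param seed Optional seed (results are bit-reproducible given
#'   `(data, n_simulations, seed)`).
#' @return A `presso_result` with the observed RSS, global p-value, raw and
#'   adjusted per-variant p-values, flagged variants, distortion p-value
#'   (when applicable) and the raw and outlier-corrected IVW estimates.
#' @export
mr_presso <- function(h, n_simulations = 10000L, outlier_alpha = 0.05,
                      seed = NULL, exposure = 1L) {
  d <- xy_of(h, exposure)
  J <- length(d$x)
  if (J < 4L) {
    stop_mr("MR-PRESSO needs at least 4 variants (leave-one-out IVW inside ",
            "the test needs 3 remaining)", class = "mrmediate_precondition_error")
  }
  if (!is.null(h$ld)) {
    R2 <- unclass(h$ld)^2
    diag(R2) <- 0
    if (max(R2) > 1e-12) {
      warning("MR-PRESSO treats instruments as uncorrelated; the attached LD matrix is ignored",
              call. = FALSE)
    }
  }
  if (J / (n_simulations + 1) >= outlier_alpha) {
    warning(sprintf(
      "n_simulations = %d cannot resolve Bonferroni-adjusted outlier p below %.3g with %d variants; no variant can be flagged at alpha = %.3g",
      n_simulations, J / (n_simulations + 1), J, outlier_alpha),
      call. = FALSE)
  }
  w <- 1 / d$sy^2
  s1 <- sum(w * d$x * d$y)
  s2 <- sum(w * d$x^2)
  b_loo <- (s1 - w * d$x * d$y) / (s2 - w * d$x^2)
  e_obs <- d$y - b_loo * d$x
  t_obs <- w * e_obs^2
  rss_obs <- sum(t_obs)

  sim <- with_seed(seed, {
    xs <- matrix(stats::rnorm(n_simulations * J, d$x, d$sx),
                 n_simulations, J, byrow = TRUE)
    mu <- b_loo * d$x
    ys <- matrix(stats::rnorm(n_simulations * J, mu, d$sy),
                 n_simulations, J, byrow = TRUE)
    W <- matrix(w, n_simulations, J, byrow = TRUE)
    s1s <- rowSums(W * xs * ys)
    s2s <- rowSums(W * xs^2)
    bs <- (s1s - W * xs * ys) / (s2s - W * xs^2)
    Ts <- W * (ys - bs * xs)^2
    list(rss = rowSums(Ts), Ts = Ts)
  })
  global_p <- (1 + sum(sim$rss >= rss_obs)) / (n_simulations + 1)
  p_raw <- (1 + colSums(sim$Ts >= matrix(t_obs, n_simulations, J,
                                         byrow = TRUE))) / (n_simulations + 1)
  p_adj <- pmin(1, p_raw * J)
  flagged <- d$ids[p_adj < outlier_alpha]

  est_raw <- mr_ivw(h, "random", exposure)
  est_corr <- NULL
  dist_p <- NA_real_
  if (length(flagged) && J - length(flagged) >= 2L) {
    keep_ids <- setdiff(d$ids, flagged)
    est_corr <- mr_ivw(subset_variants(h, keep_ids), "random", exposure)
    d_obs <- est_raw$beta - est_corr$beta
    nf <- length(flagged)
    pool <- which(!d$ids %in% flagged)
    if (length(pool) > nf) {
      n_dist <- min(n_simulations, 2000L)
      d_sim <- with_seed(if (is.null(seed)) NULL else seed + 1L, {
        vapply(seq_len(n_dist), function(i) {
          drop_idx <- sample(pool, nf)
          keep <- setdiff(seq_len(J), drop_idx)
          est_raw$beta - ivw_beta_point(d$x[keep], d$y[keep], w[keep])
        }, numeric(1L))
      })
      dist_p <- (1 + sum(abs(d_sim) >= abs(d_obs))) / (n_dist + 1)
    }
  }
  structure(list(
    rss_observed = rss_obs,
    global_pvalue = global_p,
    per_variant_pvalues = stats::setNames(p_raw, d$ids),
    per_variant_pvalues_adjusted = stats::setNames(p_adj, d$ids),
    flagged = flagged,
    distortion_pvalue = dist_p,
    estimate_raw = est_raw,
    estimate_outlier_corrected = est_corr,
    n_simulations = n_simulations,
    seed = seed,
    harmonised = h,
    exposure = d$exposure
  ), class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: observed RSS = %.4g, global p = %.4g (%d simulations)\n",
              x$rss_observed, x$global_pvalue, x$n_simulations))
  if (length(x$flagged)) {
    cat("  outliers flagged:", paste(x$flagged, collapse = ", "), "\n")
    if (is.finite(x$distortion_pvalue)) {
      cat(sprintf("  distortion test p = %.4g\n", x$distortion_pvalue))
    }
  } else cat("  no outliers flagged\n")
  invisible(x)
}

#' Leave-one-out analysis
#'
#' Refits the IVW estimator J times, omitting one variant each time.  The
#' influence score is `|beta_full - beta_loo| / se_fixed_full`, i.e. the
#' shift expressed in fixed-effects standard errors of the full fit; the
#' fixed-effects (precision) SE is used because a gross outlier inflates the
#' random-effects SE and would thereby mask its own influence.
#'
#' @inheritParams mr_ivw
#' @return A data.frame with one row per omitted variant (`omitted`, `beta`,
#'   `se`, `ci_low`, `ci_high`, `pvalue`, `influence`), the full-set estimate
#'   as attribute `full`, and the most influential variant as attribute
#'   `max_influence`.
#' @export
leave_one_out <- function(h, effects = "random", exposure = 1L) {
  J <- n_variants(h)
  if (J < 3L) stop_mr("leave-one-out needs at least 3 variants")
  full <- mr_ivw(h, effects, exposure)
  se_fixed <- mr_ivw(h, "fixed", exposure)$se
  rows <- lapply(seq_len(J), function(j) {
    e <- mr_ivw(subset_variants(h, setdiff(seq_len(J), j)), effects, exposure)
    data.frame(omitted = h$variant_id[j], beta = e$beta, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high, pvalue = e$pvalue,
               influence = abs(full$beta - e$beta) / se_fixed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full") <- full
  attr(out, "max_influence") <- out$omitted[which.max(out$influence)]
  out
}

#' Joint outlier-removal rule
#'
#' A variant is removed only when both diagnostics point at it: it is
#' flagged by the MR-PRESSO outlier test *and* its leave-one-out influence
#' score is at least `influence_threshold`.  The main analysis is then the
#' IVW fit on the reduced set; variants flagged by only one diagnostic are
#' reported with a warning but kept.
#'
#' @param presso A `presso_result` from [mr_presso()].
#' @param loo A leave-one-out table from [leave_one_out()] computed on the
#'   same harmonised set.
#' @param influence_threshold Minimum influence score (default 1: omitting
#'   the variant shifts the estimate by at least one fixed-effects SE).
#' @return A list with `removed` (rsIDs), a per-variant `rationale` table,
#'   the refitted `main` estimate (IVW random-effects on the reduced set;
#'   the raw estimate when nothing is removed) and the harmonised set used.
#' @export
joint_outlier_rule <- function(presso, loo, influence_threshold = 1) {
  h <- presso$harmonised
  if (!setequal(loo$omitted, h$variant_id)) {
    stop_mr("leave-one-out table and PRESSO result cover different variants")
  }
  influential <- loo$omitted[loo$influence >= influence_threshold]
  removed <- intersect(presso$flagged, influential)
  partial <- setdiff(union(presso$flagged, influential), removed)
  if (length(partial)) {
    warning("flagged by only one diagnostic, kept: ",
            paste(partial, collapse = ", "), call. = FALSE)
  }
  rationale <- data.frame(
    variant_id = h$variant_id,
    presso_flagged = h$variant_id %in% presso$flagged,
    loo_influence = loo$influence[match(h$variant_id, loo$omitted)],
    removed = h$variant_id %in% removed,
    stringsAsFactors = FALSE
  )
  main <- if (length(removed)) {
    mr_ivw(subset_variants(h, setdiff(h$variant_id, removed)), "random")
  } else {
    presso$estimate_raw
  }
  list(removed = removed, rationale = rationale, main = main,
       influence_threshold = influence_threshold, harmonised = h)
}
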
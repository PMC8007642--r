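# Multivariable MR: direct effects of an exposure conditional on an
# adiposity covariate, plus the beta-beta correlation analysis across
# traits' instrument effects.

#' Assemble a multivariable harmonised set
#'
#' Takes the per-exposure instrument sets, forms the union of their
#' variants, prunes the union for LD at `ld_r2_threshold` (keeping the
#' variant with the smaller discovery p-value across sets), requires every
#' retained variant to have association records in every exposure table and
#' the outcome table (variants missing anywhere are dropped and logged, not
#' zero-imputed), and harmonises everything to the first exposure's effect
#' alleles.
#'
#' @param instrument_sets Named list of `instrument_set` objects, one per
#'   exposure, in the column order wanted for the model (the PA exposure
#'   first, the adiposity covariate second).
#' @param exposure_tables Named list of full association tables matching
#'   `instrument_sets` (any p-value; instruments discovered in one GWAS need
#'   only be *present* in the others).
#' @param outcome_table Outcome association table.
#' @param ld Optional [ld_matrix()] over the union.
#' @param ld_r2_threshold Pairwise squared-correlation threshold (default
#'   0.2).
#' @param palindrome_eaf_window Passed to [harmonise()].
#' @return A multi-exposure `harmonised_set` (>= 2 exposure columns).
#' @export
build_mvmr_set <- function(instrument_sets, exposure_tables, outcome_table,
                           ld = NULL, ld_r2_threshold = 0.2,
                           palindrome_eaf_window = 0.08) {
  stopifnot(length(instrument_sets) >= 2L,
            identical(names(instrument_sets), names(exposure_tables)))
  ids <- unique(unlist(lapply(instrument_sets, `[[`, "variant_ids")))
  disc_p <- rep(Inf, length(ids))
  names(disc_p) <- ids
  for (s in instrument_sets) {
    p <- s$pvalues[intersect(names(s$pvalues), ids)]
    disc_p[names(p)] <- pmin(disc_p[names(p)], p)
  }
  dropped <- data.frame(variant_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  if (!is.null(ld) && length(ids) > 1L) {
    ord <- ids[order(disc_p[ids], ids)]
    ldm <- unclass(ld_subset(ld, ord))
    kept <- logical(length(ord))
    for (j in seq_along(ord)) {
      against <- which(kept)
      clash <- against[ldm[j, against]^2 > ld_r2_threshold]
      if (length(clash)) {
        dropped <- rbind(dropped, data.frame(
          variant_id = ord[j],
          reason = sprintf("ld-pruned (r2 = %.3g with %s)",
                           ldm[j, clash[1L]]^2, ord[clash[1L]]),
          stringsAsFactors = FALSE))
      } else kept[j] <- TRUE
    }
    ids <- ids[ids %in% ord[kept]]
  }
  tables <- c(exposure_tables, list(outcome_table))
  present <- Reduce(`&`, lapply(tables, function(t) ids %in% t$variant_id))
  if (any(!present)) {
    dropped <- rbind(dropped, data.frame(variant_id = ids[!present],
                                         reason = "missing"))
    message(sprintf("[mvmr] %d union variant(s) absent from some table, dropped",
                    sum(!present)))
    if (mean(!present) > 0.2) {
      warning(sprintf("more than 20%% of union variants dropped (%d of %d)",
                      sum(!present), length(ids)), call. = FALSE)
    }
    ids <- ids[present]
  }
  if (length(ids) <= length(instrument_sets)) {
    stop_mr("too few union variants (", length(ids),
            ") for ", length(instrument_sets), " exposures")
  }
  exp_sub <- lapply(exposure_tables, function(t) {
    t[t$variant_id %in% ids, , drop = FALSE]
  })
  out_sub <- outcome_table[outcome_table$variant_id %in% ids, , drop = FALSE]
  h <- harmonise(exp_sub, out_sub, palindrome_eaf_window,
                 ld = if (is.null(ld)) NULL else ld_subset(ld, ids))
  h$dropped <- rbind(dropped, h$dropped)
  h
}

mvmr_fit <- function(h, intercept = FALSE, effects = "random",
                     model_label = NULL, condition_limit = 1e6,
                     debias = FALSE) {
  B <- h$exposure_beta
  K <- ncol(B)
  J <- nrow(B)
  if (K < 1L) stop_mr("no exposure columns")
  zero_cols <- colSums(B != 0) == 0L
  if (any(zero_cols)) {
    # an all-zero exposure column carries no information: drop it from the
    # fit and report its coefficient as NA, so the remaining coefficients
    # reduce to the lower-dimensional model
    warning("all-zero exposure column(s) dropped from the fit: ",
            paste(h$exposure_ids[zero_cols], collapse = ", "),
            call. = FALSE)
    h_red <- h
    h_red$exposure_beta <- B[, !zero_cols, drop = FALSE]
    h_red$exposure_se <- h$exposure_se[, !zero_cols, drop = FALSE]
    h_red$exposure_pvalue <- h$exposure_pvalue[, !zero_cols, drop = FALSE]
    h_red$exposure_n <- h$exposure_n[, !zero_cols, drop = FALSE]
    h_red$exposure_ids <- h$exposure_ids[!zero_cols]
    res <- mvmr_fit(h_red, intercept, effects, model_label, condition_limit,
                    debias)
    na_est <- lapply(h$exposure_ids[zero_cols], function(id) {
      new_mr_estimate(res$method, NA_real_, NA_real_, J,
                      exposure = id, outcome = h$outcome_id)
    })
    names(na_est) <- h$exposure_ids[zero_cols]
    res$direct_estimates <- c(res$direct_estimates, na_est)[h$exposure_ids]
    res$exposure_ids <- h$exposure_ids
    return(res)
  }
  if (J <= K + intercept) {
    stop_mr("need more variants (", J, ") than coefficients (",
            K + intercept, ")")
  }
  y <- h$outcome_beta
  Sigma <- sigma_of(h)
  if (intercept) {
    # orient rows so the first exposure's betas are positive
    s <- sign(B[, 1L])
    s[s == 0] <- 1
    B <- B * s
    y <- y * s
    if (!is.null(Sigma)) Sigma <- Sigma * outer(s, s)
  }
  X <- if (intercept) cbind(`(intercept)` = 1, B) else B
  Xw <- X / h$outcome_se
  kap <- kappa(Xw, exact = TRUE)
  if (kap > condition_limit) {
    cors <- stats::cor(h$exposure_beta)
    diag(cors) <- 0
    worst <- sort(which(abs(cors) == max(abs(cors)), arr.ind = TRUE)[1L, ])
    stop_mr(sprintf(
      "exposure beta matrix is rank-deficient (condition number %.3g); most collinear pair %s / %s (beta-beta r = %.2f)",
      kap, h$exposure_ids[worst[1L]], h$exposure_ids[worst[2L]],
      cors[worst[1L], worst[2L]]), class = "mrmediate_singular_error")
  }
  if (debias) {
    # Measurement-error correction: the Gram matrix of observed exposure
    # betas overstates the signal by the exposure sampling variance (each
    # observed beta_jk^2 has expectation gamma_jk^2 + se_jk^2), which
    # dilutes coefficients towards zero when the panel contains many
    # variants that instrument only the other exposure.  Subtracting the
    # known sampling variances from the weighted normal equations gives a
    # consistent estimator (the multivariable analogue of debiased IVW).
    # Exposure GWASs are assumed independent, so the correction is
    # diagonal; not available jointly with an LD matrix.
    if (!is.null(Sigma)) {
      stop_mr("debias = TRUE is not supported with an LD matrix; prune ",
              "to independent variants first")
    }
    w <- 1 / h$outcome_se^2
    A <- crossprod(X * w, X)
    corr <- colSums(w * h$exposure_se^2)
    idx0 <- if (intercept) seq_len(K) + 1L else seq_len(K)
    A[cbind(idx0, idx0)] <- A[cbind(idx0, idx0)] - corr
    cov_fixed <- tryCatch(solve(A), error = function(e) {
      stop_mr("singular corrected normal equations in debiased MVMR",
              class = "mrmediate_singular_error")
    })
    coef <- drop(cov_fixed %*% crossprod(X * w, y))
    resid <- y - drop(X %*% coef)
    fit <- list(coef = coef, cov = cov_fixed, q = sum(w * resid^2))
  } else {
    fit <- gls_fit(X, y, h$outcome_se, Sigma)
  }
  df <- J - K - as.integer(intercept)
  scale <- if (effects == "random") max(1, sqrt(fit$q / df)) else 1
  idx <- if (intercept) seq_len(K) + 1L else seq_len(K)
  ests <- lapply(seq_len(K), function(k) {
    new_mr_estimate(if (intercept) "mvmr_egger" else "mvmr_ivw",
                    fit$coef[idx[k]],
                    sqrt(fit$cov[idx[k], idx[k]]) * scale,
                    J, q = fit$q, q_df = df,
                    exposure = h$exposure_ids[k], outcome = h$outcome_id)
  })
  names(ests) <- h$exposure_ids
  structure(list(
    method = if (intercept) "mvmr_egger" else "mvmr_ivw",
    model_label = model_label %||%
      paste0(paste(h$exposure_ids, collapse = " + ")),
    exposure_ids = h$exposure_ids,
    direct_estimates = ests,
    q_statistic = fit$q,
    q_df = df,
    q_pvalue = stats::pchisq(fit$q, df, lower.tail = FALSE),
    egger_intercept = if (intercept) unname(fit$coef[1L]) else NA_real_,
    egger_intercept_se = if (intercept) sqrt(fit$cov[1L, 1L]) * scale
                         else NA_real_,
    egger_intercept_pvalue = if (intercept)
      normal_p(fit$coef[1L], sqrt(fit$cov[1L, 1L]) * scale) else NA_real_,
    n_snps = J,
    condition_number = kap,
    effects = effects
  ), class = "mvmr_result")
}

#' Multivariable IVW estimator
#'
#' Weighted multivariable regression of outcome betas on the exposure beta
#' matrix without intercept, weights `1/se_outcome^2` (GLS under an attached
#' LD matrix).  Coefficient k is the direct effect of exposure k on the
#' outcome holding the other exposures constant.  Random-effects standard
#' errors use the multiplicative scaling `max(1, sqrt(Q/(J-K)))`.
#'
#' @param h A multi-exposure `harmonised_set` from [build_mvmr_set()].
#' @param effects `"random"` (default) or `"fixed"`.
#' @param model_label Optional label (e.g. `"Model 1 (AMPA + BMI)"`).
#' @param condition_limit Condition number above which the exposure matrix
#'   is declared rank-deficient (default 1e6); the error names the most
#'   collinear exposure pair and their beta-beta correlation.
#' @param debias Subtract the exposure sampling variances from the weighted
#'   normal equations (multivariable analogue of debiased IVW).  The
#'   default `FALSE` is the conventional estimator; `TRUE` removes the
#'   regression-dilution bias that arises when the union panel contains
#'   many variants instrumenting only the covariate, at some cost in
#'   variance.  Not available with an LD matrix attached.
#' @return An `mvmr_result` with one direct-effect `mr_estimate` per
#'   exposure and Q on `J - K` df.
#' @export
mvmr_ivw <- function(h, effects = c("random", "fixed"), model_label = NULL,
                     condition_limit = 1e6, debias = FALSE) {
  mvmr_fit(h, intercept = FALSE, effects = match.arg(effects),
           model_label = model_label, condition_limit = condition_limit,
           debias = debias)
}

#' Multivariable MR-Egger estimator
#'
#' As [mvmr_ivw()] but with an intercept, after orienting every row so the
#' first exposure's betas are positive; the intercept p-value is the
#' directional-pleiotropy test for the model.
#'
#' @inheritParams mvmr_ivw
#' @return An `mvmr_result` with `egger_intercept` fields and Q on
#'   `J - K - 1` df.
#' @export
mvmr_egger <- function(h, effects = c("random", "fixed"), model_label = NULL,
                       condition_limit = 1e6) {
  mvmr_fit(h, intercept = TRUE, effects = match.arg(effects),
           model_label = model_label, condition_limit = condition_limit)
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat(sprintf("Multivariable MR (%s): %s, %d SNPs\n", x$method,
              x$model_label, x$n_snps))
  for (e in x$direct_estimates) {
    cat(sprintf("  %s: OR = %.3f (%.3f, %.3f), p = %.3g\n", e$exposure,
                e$or, e$or_ci_low, e$or_ci_high, e$pvalue))
  }
  cat(sprintf("  Q = %.3f on %d df (p = %.3g)\n", x$q_statistic, x$q_df,
              x$q_pvalue))
  if (is.finite(x$egger_intercept)) {
    cat(sprintf("  intercept = %.4g, p = %.3g\n", x$egger_intercept,
                x$egger_intercept_pvalue))
  }
  invisible(x)
}

#' @export
as.data.frame.mvmr_result <- function(x, ...) {
  rows <- do.call(rbind, lapply(x$direct_estimates, as.data.frame))
  rows$method <- x$method
  rows$model_label <- x$model_label
  rows$q_statistic <- x$q_statistic
  rows$q_df <- x$q_df
  rows$q_pvalue <- x$q_pvalue
  rows$intercept <- x$egger_intercept
  rows$intercept_se <- x$egger_intercept_se
  rows$intercept_pvalue <- x$egger_intercept_pvalue
  rownames(rows) <- NULL
  rows
}

#' Beta-beta correlations of instrument effects across traits
#'
#' Pearson correlation of per-variant effect sizes for each trait pair over
#' a variant union, after aligning each table to the first table's effect
#' alleles.  Pairs sharing fewer than 3 variants are reported as `NA`.
#'
#' @param exposure_tables Named list of association tables.
#' @param variant_union Optional rsID vector restricting the union (default:
#'   all variants present in at least two tables).
#' @param palindrome_eaf_window Passed to the allele alignment.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
beta_beta_correlation <- function(exposure_tables, variant_union = NULL,
                                  palindrome_eaf_window = 0.08) {
  K <- length(exposure_tables)
  nm <- names(exposure_tables) %||% paste0("trait", seq_len(K))
  out <- matrix(NA_real_, K, K, dimnames = list(nm, nm))
  diag(out) <- 1
  for (i in seq_len(K - 1L)) {
    for (j in seq(i + 1L, K)) {
      a <- exposure_tables[[i]]
      b <- exposure_tables[[j]]
      shared <- intersect(a$variant_id, b$variant_id)
      if (!is.null(variant_union)) shared <- intersect(shared, variant_union)
      if (length(shared) < 3L) next
      a <- a[match(shared, a$variant_id), ]
      b <- b[match(shared, b$variant_id), ]
      cls <- classify_alleles(a$effect_allele, a$other_allele,
                              b$effect_allele, b$other_allele,
                              a$eaf, b$eaf, palindrome_eaf_window)
      usable <- cls %in% c("keep", "flip")
      if (sum(usable) < 3L) next
      bb <- ifelse(cls == "flip", -b$beta, b$beta)
      out[i, j] <- out[j, i] <-
        stats::cor(a$beta[usable], bb[usable],
                   use = "pairwise.complete.obs")
    }
  }
  out
}
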
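# Mediation decomposition: total effect (univariable MR), direct effect
# (multivariable MR), indirect effect and proportion mediated with a
# Monte-Carlo uncertainty interval.  All arithmetic is on the log-odds
# scale; proportions are reported in percent.

as_beta_se <- function(x, label) {
  if (inherits(x, "mr_estimate")) return(list(beta = x$beta, se = x$se))
  if (is.list(x) && all(c("beta", "se") %in% names(x))) {
    return(list(beta = x$beta, se = x$se))
  }
  stop_mr(label, " must be an mr_estimate or a list(beta, se)")
}

new_mediation_result <- function(exposure_id, mediator_id, total, direct,
                                 indirect, proportion, ci, method, n_draws,
                                 seed, n_discarded, truncate) {
  structure(list(
    exposure_id = exposure_id, mediator_id = mediator_id,
    total = total, direct = direct, indirect = indirect,
    proportion_mediated = proportion,
    ci_low = ci[1L], ci_high = ci[2L],
    method = method, n_draws = n_draws, seed = seed,
    n_discarded = n_discarded, truncated = truncate
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(
    "Mediation (%s method): %s through %s\n  total = %.4f, direct = %.4f, indirect = %.4f\n  proportion mediated = %.1f%% (95%% CI %.1f, %.1f)\n",
    x$method, x$exposure_id, x$mediator_id, x$total, x$direct, x$indirect,
    x$proportion_mediated, x$ci_low, x$ci_high))
  invisible(x)
}

#' @export
as.data.frame.mediation_result <- function(x, ...) {
  data.frame(exposure = x$exposure_id, mediator = x$mediator_id,
             method = x$method, total = x$total, direct = x$direct,
             indirect = x$indirect,
             proportion_mediated = x$proportion_mediated,
             ci_low = x$ci_low, ci_high = x$ci_high,
             stringsAsFactors = FALSE)
}

mediation_interval <- function(props, truncate) {
  ci <- unname(stats::quantile(props, c(0.025, 0.975), type = 7))
  if (truncate) ci <- pmin(pmax(ci, 0), 100)
  ci
}

#' Proportion of a total effect mediated (difference method)
#'
#' Point estimate `100 * (1 - direct/total)` from the total (univariable)
#' and direct (multivariable) log-OR estimates; the indirect effect is
#' `total - direct`.  The uncertainty interval propagates both sampling
#' distributions by Monte Carlo: `(total, direct)` are drawn from
#' independent normals with their standard errors, the 2.5/97.5 percentiles
#' of the resulting proportions are taken, and (by default) truncated to
#' \[0, 100\]; truncation never moves the point estimate.  Draws with
#' `|total|` below 1e-8 are discarded and counted.
#'
#' @param total Univariable `mr_estimate` (or `list(beta, se)`).
#' @param direct Multivariable direct-effect `mr_estimate` for the same
#'   exposure (or `list(beta, se)`).
#' @param n_draws Monte-Carlo draws (default 100000).
#' @param seed Optional seed.
#' @param truncate Truncate the interval ends to \[0, 100\] (default TRUE).
#' @param exposure_id,mediator_id Labels for reporting.
#' @return A `mediation_result`.
#' @examples
#' proportion_mediated(list(beta = log(0.60), se = 0.2),
#'                     list(beta = log(0.70), se = 0.2), seed = 1)
#' @export
proportion_mediated <- function(total, direct, n_draws = 100000L,
                                seed = NULL, truncate = TRUE,
                                exposure_id = NULL, mediator_id = NULL) {
  t <- as_beta_se(total, "total")
  d <- as_beta_se(direct, "direct")
  if (t$beta == 0) {
    stop_mr("total effect is zero: proportion mediated is undefined",
            class = "mrmediate_domain_error")
  }
  if (sign(t$beta) * sign(d$beta) < 0) {
    warning("inconsistent mediation: total and direct effects have opposite signs",
            call. = FALSE)
  }
  point <- 100 * (1 - d$beta / t$beta)
  draws <- with_seed(seed, {
    ts <- stats::rnorm(n_draws, t$beta, t$se)
    ds <- stats::rnorm(n_draws, d$beta, d$se)
    keep <- abs(ts) >= 1e-8
    list(props = 100 * (1 - ds[keep] / ts[keep]),
         discarded = sum(!keep))
  })
  new_mediation_result(
    exposure_id %||% (if (inherits(total, "mr_estimate")) total$exposure
                      else "exposure"),
    mediator_id %||% "mediator",
    t$beta, d$beta, t$beta - d$beta, point,
    mediation_interval(draws$props, truncate),
    "difference", n_draws, seed, draws$discarded, truncate)
}

#' Proportion mediated by two-step network MR (product method)
#'
#' The indirect effect is the product of the exposure-to-mediator and
#' mediator-to-outcome step estimates; the proportion is
#' `100 * indirect / total`.  The interval propagates all three estimates
#' through independent normal draws as in [proportion_mediated()].
#'
#' @param step1 Exposure-to-mediator `mr_estimate` (SD of mediator per SD of
#'   exposure).
#' @param step2 Mediator-to-outcome `mr_estimate` (log-OR per SD of
#'   mediator).
#' @param total Total-effect `mr_estimate` (log-OR per SD of exposure).
#' @inheritParams proportion_mediated
#' @return A `mediation_result` with `method = "product"`.
#' @export
two_step_network <- function(step1, step2, total, n_draws = 100000L,
                             seed = NULL, truncate = TRUE,
                             exposure_id = NULL, mediator_id = NULL) {
  s1 <- as_beta_se(step1, "step1")
  s2 <- as_beta_se(step2, "step2")
  t <- as_beta_se(total, "total")
  if (t$beta == 0) {
    stop_mr("total effect is zero: proportion mediated is undefined",
            class = "mrmediate_domain_error")
  }
  indirect <- s1$beta * s2$beta
  point <- 100 * indirect / t$beta
  draws <- with_seed(seed, {
    a <- stats::rnorm(n_draws, s1$beta, s1$se)
    b <- stats::rnorm(n_draws, s2$beta, s2$se)
    ts <- stats::rnorm(n_draws, t$beta, t$se)
    keep <- abs(ts) >= 1e-8
    list(props = 100 * (a[keep] * b[keep]) / ts[keep],
         discarded = sum(!keep))
  })
  new_mediation_result(
    exposure_id %||% (if (inherits(total, "mr_estimate")) total$exposure
                      else "exposure"),
    mediator_id %||% (if (inherits(step2, "mr_estimate")) step2$exposure
                      else "mediator"),
    t$beta, t$beta - indirect, indirect, point,
    mediation_interval(draws$props, truncate),
    "product", n_draws, seed, draws$discarded, truncate)
}
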
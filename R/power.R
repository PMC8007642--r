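# Non-centrality-parameter power for binary-outcome two-sample MR.
#
# The IVW z statistic under the alternative is approximately normal with
# unit variance and mean sqrt(ncp), where
#   ncp = n_outcome * r2 * case_fraction * (1 - case_fraction) * effect^2
# (the case-fraction factor is the variance of the binary outcome; r2 is
# the exposure variance explained by the instrument).  Two-sided testing.

check_power_domain <- function(r2, n_outcome, case_fraction, alpha) {
  if (any(!is.finite(r2) | r2 <= 0 | r2 >= 1)) {
    stop_mr("r2 must lie in (0, 1)", class = "mrmediate_domain_error")
  }
  if (any(!is.finite(n_outcome) | n_outcome <= 0)) {
    stop_mr("n_outcome must be positive", class = "mrmediate_domain_error")
  }
  if (any(!is.finite(case_fraction) | case_fraction <= 0 |
            case_fraction >= 1)) {
    stop_mr("case_fraction must lie in (0, 1)",
            class = "mrmediate_domain_error")
  }
  if (any(!is.finite(alpha) | alpha <= 0 | alpha >= 1)) {
    stop_mr("alpha must lie in (0, 1)", class = "mrmediate_domain_error")
  }
}

#' Analytic power for two-sample MR with a binary outcome
#'
#' @param r2 Exposure variance explained by the instrument, in (0, 1).
#' @param n_outcome Outcome GWAS sample size (cases + controls).
#' @param case_fraction Proportion of cases, in (0, 1).
#' @param effect Hypothesised causal effect, log-OR per SD of exposure
#'   (vectorised).
#' @param alpha Two-sided type-I error (default 0.05).
#' @return A `power_result` data.frame with `ncp`, `power` and the inputs;
#'   `power` equals `alpha` exactly at `effect = 0` and increases in
#'   `|effect|`, `r2` and `n_outcome`.
#' @examples
#' mr_power(r2 = 0.002, n_outcome = 92967, case_fraction = 31197/92967,
#'          effect = log(0.6))
#' @export
mr_power <- function(r2, n_outcome, case_fraction, effect, alpha = 0.05) {
  check_power_domain(r2, n_outcome, case_fraction, alpha)
  ncp <- n_outcome * r2 * case_fraction * (1 - case_fraction) * effect^2
  z <- stats::qnorm(1 - alpha / 2)
  pow <- 1 - stats::pnorm(z - sqrt(ncp)) + stats::pnorm(-z - sqrt(ncp))
  out <- data.frame(alpha = alpha, r2 = r2, n_outcome = n_outcome,
                    case_fraction = case_fraction, effect = effect,
                    or = exp(effect), ncp = ncp, power = pow)
  class(out) <- c("power_result", "data.frame")
  out
}

#' Minimum detectable effect at a target power
#'
#' Inverts [mr_power()] in `effect > 0` by bisection (tolerance 1e-8 on the
#' log-OR scale).  By symmetry the same magnitude applies to protective
#' effects; the OR transform of both signs is reported.
#'
#' @inheritParams mr_power
#' @param target_power Required power, in (`alpha`, 1) (default 0.80).
#' @return A list with `effect` (log-OR), `or` and `or_protective`.
#' @export
detectable_effect <- function(r2, n_outcome, case_fraction,
                              target_power = 0.80, alpha = 0.05) {
  check_power_domain(r2, n_outcome, case_fraction, alpha)
  if (target_power <= alpha || target_power >= 1) {
    stop_mr("target_power must lie in (alpha, 1)",
            class = "mrmediate_domain_error")
  }
  f <- function(e) {
    mr_power(r2, n_outcome, case_fraction, e, alpha)$power - target_power
  }
  lo <- 0
  hi <- 0.1
  while (f(hi) < 0) {
    hi <- hi * 2
    if (hi > 1e3) stop_mr("detectable effect search failed to bracket")
  }
  while (hi - lo > 1e-8) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  effect <- (lo + hi) / 2
  list(effect = effect, or = exp(effect), or_protective = exp(-effect),
       target_power = target_power, alpha = alpha)
}

#' Power table over a grid of hypothesised effects
#'
#' @inheritParams mr_power
#' @param effects Vector of hypothesised log-ORs per SD.
#' @return A `power_result` data.frame, one row per effect, plus the
#'   80%-power detectable effect as attribute `detectable_80`.
#' @export
power_table <- function(r2, n_outcome, case_fraction,
                        effects = log(seq(0.5, 0.9, by = 0.05)),
                        alpha = 0.05) {
  out <- mr_power(r2, n_outcome, case_fraction, effects, alpha)
  attr(out, "detectable_80") <-
    detectable_effect(r2, n_outcome, case_fraction, 0.80, alpha)
  out
}
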
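# Synthetic two-sample GWAS summary statistics with known causal structure.
#
# Causal diagram: instruments -> exposure -> outcome, with a mediated path
# exposure -> mediator -> outcome and optional direct (pleiotropic) variant
# effects on the outcome.  Statistics are generated directly at the summary
# level: true per-variant effects are fixed, and observed betas are the true
# values plus normal sampling noise with the analytic standard errors
#   se_exposure = 1 / sqrt(2 eaf (1-eaf) n_exposure)
#   se_outcome  = 1 / sqrt(2 eaf (1-eaf) n_outcome cf (1-cf)).
# LD blocks induce correlated estimation noise with the block correlation,
# which is exactly the covariance model the correlation-aware estimators
# assume; a sample-overlap fraction correlates exposure and outcome noise.

#' Define the generating truth of a synthetic dataset
#'
#' The declared identity `theta_total = theta_direct + kappa * theta_mediator`
#' is enforced by construction, and the true proportion mediated is
#' `kappa * theta_mediator / theta_total`.
#'
#' @param theta_direct Direct effect of the exposure on the outcome, log-OR
#'   per SD.
#' @param kappa Effect of the exposure on the mediator, SD per SD.
#' @param theta_mediator Effect of the mediator on the outcome, log-OR per
#'   SD.
#' @param pleiotropy_mode One of `"none"`, `"balanced"` (zero-mean direct
#'   variant effects), `"directional"` (mean `pleiotropy_sd`) or
#'   `"inside_violating"` (direct effects correlated with instrument
#'   strength).
#' @param pleiotropy_sd Scale of the per-variant direct effects (log-OR).
#' @param j_snps Number of exposure instruments.
#' @param j_mediator_snps Number of mediator-specific instruments (zero true
#'   effect on the exposure); needed to identify the direct effect in
#'   multivariable MR.
#' @param instrument_r2 Exposure variance explained by the exposure
#'   instruments jointly.
#' @param mediator_r2 Mediator variance explained by the mediator-specific
#'   instruments jointly.
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes.
#' @param case_fraction Proportion of cases in the outcome GWAS.
#' @param ld_block_r Within-block correlation of estimation noise (0 = no
#'   LD).
#' @param ld_block_size Variants per LD block (default 1).
#' @param overlap_fraction Correlation between exposure and outcome
#'   sampling noise, emulating participant overlap (default 0).
#' @param flip_fraction Fraction of mediator/outcome rows written with
#'   swapped alleles (beta negated, eaf complemented) to exercise
#'   harmonisation (default 0.25).
#' @param allow_palindromic Allow A/T and C/G allele pairs (default FALSE).
#' @param seed Integer seed; identical truths generate bit-identical
#'   datasets.
#' @return A `synthetic_truth` object (list of validated parameters with
#'   `theta_total` and `proportion_mediated` filled in).
#' @export
synthetic_truth <- function(theta_direct = -0.35, kappa = 0.3,
                            theta_mediator = -0.5,
                            pleiotropy_mode = c("none", "balanced",
                                                "directional",
                                                "inside_violating"),
                            pleiotropy_sd = 0, j_snps = 10L,
                            j_mediator_snps = 0L, instrument_r2 = 0.002,
                            mediator_r2 = 0.02, n_exposure = 91105,
                            n_mediator = 322154, n_outcome = 92967,
                            case_fraction = 31197 / 92967,
                            ld_block_r = 0, ld_block_size = 1L,
                            overlap_fraction = 0, flip_fraction = 0.25,
                            allow_palindromic = FALSE, seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(is_scalar_number(theta_direct), is_scalar_number(kappa),
            is_scalar_number(theta_mediator), pleiotropy_sd >= 0,
            is_count(j_snps), j_mediator_snps >= 0,
            instrument_r2 > 0, instrument_r2 < 1,
            n_exposure > 2, n_outcome > 2,
            case_fraction > 0, case_fraction < 1,
            abs(ld_block_r) < 1, ld_block_size >= 1,
            overlap_fraction >= 0, overlap_fraction < 1,
            flip_fraction >= 0, flip_fraction <= 1)
  theta_total <- theta_direct + kappa * theta_mediator
  structure(list(
    theta_total = theta_total, theta_direct = theta_direct, kappa = kappa,
    theta_mediator = theta_mediator,
    proportion_mediated = if (theta_total != 0)
      kappa * theta_mediator / theta_total else NA_real_,
    pleiotropy_mode = pleiotropy_mode, pleiotropy_sd = pleiotropy_sd,
    j_snps = as.integer(j_snps),
    j_mediator_snps = as.integer(j_mediator_snps),
    instrument_r2 = instrument_r2, mediator_r2 = mediator_r2,
    n_exposure = n_exposure, n_mediator = n_mediator,
    n_outcome = n_outcome, case_fraction = case_fraction,
    ld_block_r = ld_block_r, ld_block_size = as.integer(ld_block_size),
    overlap_fraction = overlap_fraction, flip_fraction = flip_fraction,
    allow_palindromic = allow_palindromic, seed = as.integer(seed)
  ), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "Synthetic truth: theta_total = %.4f (direct %.4f + %.2f x %.4f mediated)\n",
    x$theta_total, x$theta_direct, x$kappa, x$theta_mediator))
  cat(sprintf("  %d exposure SNPs (R2 = %.4g), %d mediator SNPs (R2 = %.4g)\n",
              x$j_snps, x$instrument_r2, x$j_mediator_snps, x$mediator_r2))
  cat(sprintf("  pleiotropy: %s (sd %.3g); seed %d\n", x$pleiotropy_mode,
              x$pleiotropy_sd, x$seed))
  invisible(x)
}

# block-diagonal correlation matrix for the instrument panel
block_correlation <- function(J, r, block_size) {
  R <- diag(J)
  if (r != 0 && block_size > 1L) {
    starts <- seq(1L, J, by = block_size)
    for (s in starts) {
      idx <- s:min(s + block_size - 1L, J)
      R[idx, idx] <- r
      diag(R)[idx] <- 1
    }
  }
  R
}

NON_PALINDROMIC_PAIRS <- rbind(
  c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
  c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
ALL_PAIRS <- rbind(NON_PALINDROMIC_PAIRS,
                   c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

#' Generate a synthetic two-sample dataset
#'
#' @param truth A [synthetic_truth()].
#' @return A `synthetic_dataset`: association tables `exposure`, `mediator`,
#'   `outcome` in the [read_summary_stats()] layout, the assumed `ld`
#'   correlation matrix, the noise-free per-variant effects in
#'   `true_effects`, the rsID vectors `exposure_instruments` and
#'   `mediator_instruments` identifying which variants truly instrument
#'   which trait, and the generating `truth`.
#' @examples
#' ds <- generate_dataset(synthetic_truth(j_snps = 5, seed = 7))
#' mr_ivw(harmonise(ds$exposure, ds$outcome))
#' @export
generate_dataset <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  with_seed(truth$seed, {
    Jx <- truth$j_snps
    Jm <- truth$j_mediator_snps
    J <- Jx + Jm
    ids <- sprintf("rs%07d", seq_len(J) + 1000000L)
    eaf <- stats::runif(J, 0.05, 0.5)
    v <- 2 * eaf * (1 - eaf)

    # true instrument effects, scaled to the requested variance explained;
    # effect alleles are coded as the exposure-increasing allele (the usual
    # reporting convention for discovery instruments), so gamma >= 0 and a
    # directional pleiotropy mean survives Egger's orientation step
    gamma <- numeric(J)
    raw <- abs(stats::rnorm(Jx))
    if (sum(v[seq_len(Jx)] * raw^2) <= 0) {
      stop_mr("requested instrument R2 unattainable with j_snps = ", Jx)
    }
    gamma[seq_len(Jx)] <-
      raw * sqrt(truth$instrument_r2 / sum(v[seq_len(Jx)] * raw^2))
    delta <- numeric(J)
    if (Jm > 0L) {
      rawm <- abs(stats::rnorm(Jm))
      delta[Jx + seq_len(Jm)] <-
        rawm * sqrt(truth$mediator_r2 / sum(v[Jx + seq_len(Jm)] * rawm^2))
    }

    alpha <- switch(truth$pleiotropy_mode,
      none = numeric(J),
      balanced = stats::rnorm(J, 0, truth$pleiotropy_sd),
      directional = stats::rnorm(J, truth$pleiotropy_sd,
                                 truth$pleiotropy_sd / 2),
      inside_violating = {
        g_sd <- stats::sd(gamma)
        truth$pleiotropy_sd * gamma / max(g_sd, 1e-12) +
          stats::rnorm(J, 0, truth$pleiotropy_sd / 2)
      })

    b_exposure <- gamma
    b_mediator <- truth$kappa * gamma + delta
    b_outcome <- truth$theta_direct * b_exposure +
      truth$theta_mediator * b_mediator + alpha

    se_x <- 1 / sqrt(v * truth$n_exposure)
    se_m <- 1 / sqrt(v * truth$n_mediator)
    cf <- truth$case_fraction
    se_y <- 1 / sqrt(v * truth$n_outcome * cf * (1 - cf))

    R <- block_correlation(J, truth$ld_block_r, truth$ld_block_size)
    L <- t(chol(R))
    zx <- drop(L %*% stats::rnorm(J))
    zm <- drop(L %*% stats::rnorm(J))
    zy0 <- drop(L %*% stats::rnorm(J))
    ov <- truth$overlap_fraction
    zy <- ov * zx + sqrt(1 - ov^2) * zy0

    make_table <- function(beta_true, z, se, n, trait) {
      beta <- beta_true + z * se
      data.frame(variant_id = ids, effect_allele = NA_character_,
                 other_allele = NA_character_, eaf = eaf, beta = beta,
                 se = se, pvalue = normal_p(beta, se), n = n,
                 trait_id = trait, pvalue_derived = FALSE,
                 stringsAsFactors = FALSE)
    }
    pairs <- if (truth$allow_palindromic) ALL_PAIRS else NON_PALINDROMIC_PAIRS
    pick <- sample(nrow(pairs), J, replace = TRUE)
    a1 <- pairs[pick, 1L]
    a2 <- pairs[pick, 2L]
    exposure <- make_table(b_exposure, zx, se_x, truth$n_exposure, "exposure")
    mediator <- make_table(b_mediator, zm, se_m, truth$n_mediator, "mediator")
    outcome <- make_table(b_outcome, zy, se_y, truth$n_outcome, "outcome")
    for (nm in c("exposure", "mediator", "outcome")) {
      t <- get(nm)
      t$effect_allele <- a1
      t$other_allele <- a2
      assign(nm, t)
    }
    # emit some mediator/outcome rows on the opposite orientation so the
    # harmonisation step has real work to do; the information is identical
    flip_rows <- function(t) {
      k <- which(stats::runif(J) < truth$flip_fraction)
      t$effect_allele[k] <- a2[k]
      t$other_allele[k] <- a1[k]
      t$beta[k] <- -t$beta[k]
      t$eaf[k] <- 1 - t$eaf[k]
      t
    }
    mediator <- flip_rows(mediator)
    outcome <- flip_rows(outcome)
    structure(list(exposure = exposure, mediator = mediator,
                   outcome = outcome, ld = ld_matrix(R, ids),
                   true_effects = data.frame(
                     variant_id = ids, eaf = eaf, exposure = b_exposure,
                     mediator = b_mediator, outcome = b_outcome,
                     pleiotropy = alpha, stringsAsFactors = FALSE),
                   exposure_instruments = ids[seq_len(Jx)],
                   mediator_instruments = if (Jm > 0L) ids[Jx + seq_len(Jm)]
                                          else character(0),
                   truth = truth),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dataset: %d variants (%d exposure + %d mediator instruments)\n",
              nrow(x$exposure), x$truth$j_snps, x$truth$j_mediator_snps))
  print(x$truth)
  invisible(x)
}

#' Study-shaped scenario presets
#'
#' Generating truths matching the instrument descriptions of the source
#' analysis ([study_instruments()]): instrument counts, variance explained
#' and GWAS sample sizes per physical-activity exposure, a BMI-shaped
#' mediator (68 SNPs, R2 = 0.0232, N = 322,154) and a colorectal-cancer
#' shaped outcome GWAS (31,197 cases / 61,770 controls).  Default total
#' effects and mediated proportions are the analysis' headline estimates
#' (MVPA OR 0.56 with 2% mediated through BMI; AMPA OR 0.60 with 32%;
#' sedentary time null); both can be overridden.
#'
#' @param name One of `"mvpa"`, `"ampa"`, `"ampa_strict"` (the
#'   `P < 5e-9` three-variant instrument), `"sedentary"`.
#' @param theta_total Total causal effect, log-OR per SD (default: the
#'   scenario's headline value).
#' @param proportion_mediated True proportion of `theta_total` carried
#'   through the mediator (default: the scenario's headline value).
#' @param kappa Exposure-to-mediator effect used to realise the mediated
#'   path (default 0.3 SD/SD).
#' @param seed Seed stored in the truth.
#' @param ... Further overrides passed to [synthetic_truth()].
#' @return A `synthetic_truth`.
#' @examples
#' study_scenario("ampa", seed = 7)
#' @export
study_scenario <- function(name = c("mvpa", "ampa", "ampa_strict",
                                    "sedentary"),
                           theta_total = NULL, proportion_mediated = NULL,
                           kappa = 0.3, seed = 1L, ...) {
  name <- match.arg(name)
  preset <- switch(name,
    mvpa = list(j = 7L, r2 = 7e-4, n = 385790, theta = log(0.56),
                prop = 0.02),
    ampa = list(j = 5L, r2 = 2e-3, n = 91105, theta = log(0.60),
                prop = 0.32),
    ampa_strict = list(j = 3L, r2 = 1e-3, n = 91105, theta = log(0.54),
                       prop = 0.32),
    sedentary = list(j = 6L, r2 = 1e-3, n = 91105, theta = 0, prop = 0))
  theta_total <- theta_total %||% preset$theta
  prop <- proportion_mediated %||% preset$prop
  theta_mediator <- if (kappa != 0) prop * theta_total / kappa else 0
  theta_direct <- theta_total - kappa * theta_mediator
  synthetic_truth(theta_direct = theta_direct, kappa = kappa,
                  theta_mediator = theta_mediator,
                  j_snps = preset$j, j_mediator_snps = 68L,
                  instrument_r2 = preset$r2, mediator_r2 = 0.0232,
                  n_exposure = preset$n, n_mediator = 322154,
                  n_outcome = 92967, case_fraction = 31197 / 92967,
                  seed = seed, ...)
}

#' Write a synthetic dataset to disk
#'
#' Emits the three association tables and the LD matrix in the dialects
#' [read_summary_stats()] and [read_ld_matrix()] read, plus `truth.json`
#' capturing the generating parameters.
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(exposure = file.path(dir, "exposure.tsv"),
             mediator = file.path(dir, "mediator.tsv"),
             outcome = file.path(dir, "outcome.tsv"),
             ld = file.path(dir, "ld_matrix.tsv"),
             truth = file.path(dir, "truth.json"))
  write_summary_stats(ds$exposure, paths[["exposure"]])
  write_summary_stats(ds$mediator, paths[["mediator"]])
  write_summary_stats(ds$outcome, paths[["outcome"]])
  write_ld_matrix(ds$ld, paths[["ld"]])
  jsonlite::write_json(unclass(ds$truth), paths[["truth"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
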
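# Instrument construction: p-value thresholding, greedy LD pruning,
# variance explained and instrument strength.

#' Variance in the exposure explained by a variant
#'
#' Per-variant variance explained under Hardy-Weinberg equilibrium for an
#' effect `beta` expressed in SD units of the trait:
#' `2 * eaf * (1 - eaf) * beta^2`.  The instrument-level R-squared is the sum
#' over its variants.
#'
#' @param eaf Effect-allele frequency in \[0, 1\] (vectorised).
#' @param beta Per-allele effect in SD units (vectorised).
#' @return Numeric vector of variance fractions.
#' @examples
#' variance_explained(0.25, 0.1)  # 0.00375
#' @export
variance_explained <- function(eaf, beta) {
  if (any(!is.finite(eaf) | eaf < 0 | eaf > 1)) {
    stop_mr("eaf must lie in [0, 1]", class = "mrmediate_domain_error")
  }
  2 * eaf * (1 - eaf) * beta^2
}

#' Instrument strength F-statistic
#'
#' `F = R^2 * (N - 2) / (1 - R^2)` for an instrument explaining a fraction
#' `r2` of the exposure variance in a GWAS of `n` individuals.  Values below
#' 10 conventionally flag a weak instrument.
#'
#' @param r2 Variance explained, in \[0, 1).
#' @param n Exposure GWAS sample size (> 2).
#' @return Numeric vector of F statistics, with attribute-free values; use
#'   `f < 10` for the conventional weak-instrument flag.
#' @examples
#' f_statistic(0.002, 91105)
#' @export
f_statistic <- function(r2, n) {
  if (any(!is.finite(r2) | r2 < 0 | r2 >= 1)) {
    stop_mr("r2 must lie in [0, 1)", class = "mrmediate_domain_error")
  }
  if (any(!is.finite(n) | n <= 2)) {
    stop_mr("n must exceed 2", class = "mrmediate_domain_error")
  }
  r2 * (n - 2) / (1 - r2)
}

#' Select genetic instruments from an exposure table
#'
#' Retains variants with `pvalue <= p_threshold` and, when an LD matrix is
#' supplied, prunes correlated variants greedily: candidates are visited in
#' ascending p-value (ties broken by lexicographic rsID) and a variant is
#' excluded when its squared correlation with an already-kept variant exceeds
#' `ld_r2_threshold`.  With `retain_correlated = TRUE` correlated variants
#' are kept instead and the set is marked so that only correlation-aware
#' estimators (IVW/Egger/robust with the LD matrix) should use it directly;
#' order-statistic methods must prune first (see `prune_correlated`).
#'
#' @param table Exposure association table ([read_summary_stats()]).
#' @param p_threshold Genome-wide significance threshold (e.g. `5e-8` or
#'   `5e-9`).
#' @param ld Optional [ld_matrix()] covering all candidate variants.
#' @param ld_r2_threshold Squared-correlation threshold above which a pair is
#'   considered correlated (default 0.2).
#' @param retain_correlated Keep correlated variants and mark the set.
#' @return An `instrument_set` with the retained `variant_ids`, the summed
#'   `r2_total`, the `f_statistic`, the exposure GWAS size `n_gwas`, a
#'   `weak_instrument` flag (F < 10) and an `exclusions` table.
#' @export
select_instruments <- function(table, p_threshold = 5e-8, ld = NULL,
                               ld_r2_threshold = 0.2,
                               retain_correlated = FALSE) {
  stopifnot(is.data.frame(table))
  pass <- table$pvalue <= p_threshold
  if (!any(pass)) {
    stop_mr("no variants reach p <= ", format(p_threshold), " for trait ",
            table$trait_id[1L] %||% "?")
  }
  cand <- table[pass, , drop = FALSE]
  ord <- order(cand$pvalue, cand$variant_id)
  cand <- cand[ord, , drop = FALSE]
  exclusions <- data.frame(variant_id = character(0), reason = character(0),
                           stringsAsFactors = FALSE)
  if (!is.null(ld) && !retain_correlated && nrow(cand) > 1L) {
    ldm <- unclass(ld_subset(ld, cand$variant_id))
    kept <- logical(nrow(cand))
    for (j in seq_len(nrow(cand))) {
      against <- which(kept)
      clash <- against[ldm[j, against]^2 > ld_r2_threshold]
      if (length(clash)) {
        exclusions <- rbind(exclusions, data.frame(
          variant_id = cand$variant_id[j],
          reason = sprintf("ld-pruned (r2 = %.3g with %s)",
                           ldm[j, clash[1L]]^2, cand$variant_id[clash[1L]]),
          stringsAsFactors = FALSE))
      } else {
        kept[j] <- TRUE
      }
    }
    cand <- cand[kept, , drop = FALSE]
  }
  # restore the input table's variant order among the retained set
  cand <- cand[order(match(cand$variant_id, table$variant_id)), , drop = FALSE]
  r2_total <- sum(variance_explained(cand$eaf, cand$beta))
  n_gwas <- stats::median(cand$n, na.rm = TRUE)
  f <- if (is.finite(n_gwas)) f_statistic(min(r2_total, 1 - 1e-12), n_gwas)
       else NA_real_
  structure(list(
    exposure_id = table$trait_id[1L] %||% "exposure",
    variant_ids = cand$variant_id,
    p_threshold = p_threshold,
    ld_r2_threshold = ld_r2_threshold,
    correlated_retained = isTRUE(retain_correlated) && !is.null(ld),
    r2_total = r2_total,
    f_statistic = f,
    weak_instrument = is.finite(f) && f < 10,
    n_gwas = n_gwas,
    pvalues = stats::setNames(cand$pvalue, cand$variant_id),
    exclusions = exclusions
  ), class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf(
    "Instrument set for %s: %d variants (p <= %s)%s\n  R2 = %.4g, F = %.4g%s\n",
    x$exposure_id, length(x$variant_ids), format(x$p_threshold),
    if (x$correlated_retained) " [correlated-retained]" else "",
    x$r2_total, x$f_statistic,
    if (isTRUE(x$weak_instrument)) "  ** weak instrument (F < 10) **" else ""))
  if (nrow(x$exclusions)) {
    cat("  excluded:", paste(sprintf("%s [%s]", x$exclusions$variant_id,
                                     x$exclusions$reason), collapse = "; "), "\n")
  }
  invisible(x)
}

#' Prune a correlated-retained instrument set for order-statistic methods
#'
#' The weighted-median and mode estimators assume (near-)independent
#' instruments; a set built with `retain_correlated = TRUE` must be pruned
#' pairwise before those methods are applied.
#'
#' @param instruments An `instrument_set`.
#' @param ld The [ld_matrix()] used at selection time.
#' @param ld_r2_threshold Squared-correlation threshold (default: the set's).
#' @return A pruned `instrument_set` (correlation mark cleared).
#' @export
prune_correlated <- function(instruments, ld,
                             ld_r2_threshold = instruments$ld_r2_threshold) {
  ids <- instruments$variant_ids
  p <- instruments$pvalues[ids]
  ord <- order(p, ids)
  ldm <- unclass(ld_subset(ld, ids[ord]))
  kept <- logical(length(ids))
  excl <- instruments$exclusions
  for (j in seq_along(ord)) {
    against <- which(kept)
    clash <- against[ldm[j, against]^2 > ld_r2_threshold]
    if (length(clash)) {
      excl <- rbind(excl, data.frame(
        variant_id = ids[ord][j],
        reason = sprintf("ld-pruned (r2 = %.3g with %s)",
                         ldm[j, clash[1L]]^2, ids[ord][clash[1L]]),
        stringsAsFactors = FALSE))
    } else {
      kept[j] <- TRUE
    }
  }
  keep_ids <- ids[sort(match(ids[ord][kept], ids))]
  out <- instruments
  out$variant_ids <- keep_ids
  out$correlated_retained <- FALSE
  out$pvalues <- instruments$pvalues[keep_ids]
  out$exclusions <- excl
  out
}

#' Serialise an instrument set to a JSON report
#'
#' @param x An `instrument_set`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
instrument_report <- function(x, path = NULL) {
  obj <- list(
    exposure_id = x$exposure_id,
    variant_ids = x$variant_ids,
    p_threshold = x$p_threshold,
    ld_r2_threshold = x$ld_r2_threshold,
    correlated_retained = x$correlated_retained,
    r2_total = x$r2_total,
    f_statistic = x$f_statistic,
    weak_instrument = x$weak_instrument,
    n_gwas = x$n_gwas,
    exclusions = x$exclusions
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Published instrument descriptions used by the study scenarios
#'
#' The instrument sets of the source analysis: per exposure the number of
#' variants, the variance explained by the instrument and the discovery GWAS
#' sample size.  These drive [study_scenario()] presets and desk-scale
#' instrument-strength checks; the corresponding F statistics all exceed the
#' conventional weak-instrument bound of 10 (minimum about 91 for the
#' strict-threshold accelerometer and sedentary-time instruments).
#'
#' @return A data.frame with columns `exposure`, `n_snps`, `r2`, `n_gwas`.
#' @export
study_instruments <- function() {
  data.frame(
    exposure = c("MVPA", "AMPA", "AMPA (P<5e-9)", "Sedentary time", "BMI",
                 "Body fat percentage", "Waist circumference", "AFR", "TFR",
                 "LFR"),
    n_snps = c(7L, 5L, 3L, 6L, 68L, 370L, 59L, 15L, 50L, 46L),
    r2 = c(7e-4, 2e-3, 1e-3, 1e-3, 2.32e-2, 5.3e-2, 1.0e-2, 2e-3, 2e-3, 2e-3),
    n_gwas = c(385790L, 91105L, 91105L, 91105L, 322154L, 331117L, 224459L,
               362499L, 362499L, 362499L),
    stringsAsFactors = FALSE
  )
}
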
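# Allele harmonisation of exposure and outcome summary statistics.
#
# All tables are aligned to the effect allele of the (first) exposure, the
# GWAS on which the instruments were discovered.  For each variant the other
# table's allele pair is classified against the reference pair:
#   same order                    -> keep as is
#   swapped order                 -> flip beta sign, eaf -> 1 - eaf
#   strand complement, same order -> keep (alleles reported on other strand)
#   strand complement, swapped    -> flip beta sign, eaf -> 1 - eaf
#   anything else                 -> irreconcilable, variant dropped
# Palindromic pairs (A/T, C/G) are their own strand complement, so order
# cannot distinguish strand from orientation; the effect-allele frequency
# breaks the tie unless it is too close to 0.5.

# Classify one table's allele pairs against reference pairs.
# Returns character vector: "keep", "flip", "mismatch", "ambiguous".
classify_alleles <- function(ref_a1, ref_a2, a1, a2,
                             ref_eaf, eaf, window) {
  n <- length(ref_a1)
  out <- character(n)
  c1 <- unname(ALLELE_COMPLEMENT[a1])
  c2 <- unname(ALLELE_COMPLEMENT[a2])
  pal <- is_palindromic(ref_a1, ref_a2)
  for (j in seq_len(n)) {
    if (pal[j]) {
      # palindromic: pair identity only tells us the variant matches
      if (!setequal(c(a1[j], a2[j]), c(ref_a1[j], ref_a2[j]))) {
        out[j] <- "mismatch"
        next
      }
      if (is.na(ref_eaf[j]) || is.na(eaf[j])) {
        stop_mr("palindromic variant with missing effect-allele frequency ",
                "cannot be oriented; supply eaf or drop the variant",
                class = "mrmediate_data_error")
      }
      if (abs(ref_eaf[j] - 0.5) < window || abs(eaf[j] - 0.5) < window) {
        out[j] <- "ambiguous"
        next
      }
      same_side <- (ref_eaf[j] - 0.5) * (eaf[j] - 0.5) > 0
      aligned_allele <- a1[j] == ref_a1[j] || c1[j] == ref_a1[j]
      # frequency decides: if the nominal alignment disagrees with the
      # frequency comparison the reporting strand was flipped
      out[j] <- if (aligned_allele == same_side) "keep" else "flip"
    } else if (a1[j] == ref_a1[j] && a2[j] == ref_a2[j]) {
      out[j] <- "keep"
    } else if (a1[j] == ref_a2[j] && a2[j] == ref_a1[j]) {
      out[j] <- "flip"
    } else if (c1[j] == ref_a1[j] && c2[j] == ref_a2[j]) {
      out[j] <- "keep"
    } else if (c1[j] == ref_a2[j] && c2[j] == ref_a1[j]) {
      out[j] <- "flip"
    } else {
      out[j] <- "mismatch"
    }
  }
  out
}

#' Harmonise exposure and outcome summary statistics
#'
#' Joins one or more exposure tables with an outcome table on `variant_id`
#' and aligns every record to the effect allele of the first exposure.
#' Where the outcome (or a further exposure) reports the opposite allele,
#' its beta sign is flipped and its frequency replaced by `1 - eaf`; strand
#' flips are resolved through allele complements.  Palindromic variants
#' (A/T or C/G) whose frequency lies within `palindrome_eaf_window` of 0.5
#' in any table are dropped with reason `"palindromic-ambiguous"`; variants
#' absent from any table are dropped with reason `"missing"`; irreconcilable
#' allele pairs are dropped with reason `"allele-mismatch"` and a warning.
#'
#' @param exposures A single association table ([read_summary_stats()]) or a
#'   named list of them (multivariable case; the first defines the alignment
#'   target and the variant order).
#' @param outcome Association table for the outcome (log-odds scale for a
#'   binary outcome).
#' @param palindrome_eaf_window Half-width of the frequency window around
#'   0.5 inside which a palindromic variant is considered unorientable
#'   (default 0.08, i.e. eaf in (0.42, 0.58) is dropped).
#' @param ld Optional [ld_matrix()]; it is restricted to the retained
#'   variants, in order.
#' @return A `harmonised_set`: aligned exposure beta/SE matrices
#'   (variants x exposures), outcome betas/SEs, allele and frequency vectors
#'   on the common orientation, the restricted LD matrix, and a `dropped`
#'   table of `(variant_id, reason)`.
#' @examples
#' ds <- generate_dataset(synthetic_truth(j_snps = 5, seed = 1))
#' h <- harmonise(ds$exposure, ds$outcome)
#' h
#' @export
harmonise <- function(exposures, outcome, palindrome_eaf_window = 0.08,
                      ld = NULL) {
  if (is.data.frame(exposures)) {
    exposures <- stats::setNames(list(exposures),
                                 exposures$trait_id[1L] %||% "exposure")
  }
  if (is.null(names(exposures)) || any(!nzchar(names(exposures)))) {
    names(exposures) <- vapply(
      exposures, function(t) t$trait_id[1L] %||% "exposure", character(1L))
  }
  tables <- c(exposures, list(.outcome = outcome))
  ref <- exposures[[1L]]
  ids <- ref$variant_id
  dropped <- data.frame(variant_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  present <- Reduce(`&`, lapply(tables, function(t) ids %in% t$variant_id))
  if (any(!present)) {
    dropped <- rbind(dropped, data.frame(variant_id = ids[!present],
                                         reason = "missing"))
  }
  # variants present only in non-reference tables are also "missing"
  extra <- setdiff(unique(unlist(lapply(tables, `[[`, "variant_id"))), ids)
  if (length(extra)) {
    dropped <- rbind(dropped,
                     data.frame(variant_id = extra, reason = "missing"))
  }
  ids <- ids[present]
  if (!length(ids)) {
    stop_mr("no variants shared by all tables; nothing to harmonise")
  }
  ref <- ref[match(ids, ref$variant_id), , drop = FALSE]

  keep <- rep(TRUE, length(ids))
  reasons <- rep(NA_character_, length(ids))
  aligned <- vector("list", length(tables))
  names(aligned) <- names(tables)
  aligned[[1L]] <- ref
  for (k in seq_along(tables)[-1L]) {
    t <- tables[[k]][match(ids, tables[[k]]$variant_id), , drop = FALSE]
    cls <- classify_alleles(ref$effect_allele, ref$other_allele,
                            t$effect_allele, t$other_allele,
                            ref$eaf, t$eaf, palindrome_eaf_window)
    flip <- cls == "flip"
    t$beta[flip] <- -t$beta[flip]
    t$eaf[flip] <- 1 - t$eaf[flip]
    t$effect_allele <- ref$effect_allele
    t$other_allele <- ref$other_allele
    bad <- cls == "mismatch"
    amb <- cls == "ambiguous"
    if (any(bad)) {
      warning(sprintf("harmonise: %d variant(s) with irreconcilable alleles dropped (e.g. %s)",
                      sum(bad), ids[which(bad)[1L]]), call. = FALSE)
      reasons[bad & keep] <- "allele-mismatch"
      keep <- keep & !bad
    }
    if (any(amb)) {
      reasons[amb & keep] <- "palindromic-ambiguous"
      keep <- keep & !amb
    }
    aligned[[k]] <- t
  }
  # reference-side palindrome ambiguity (exposure eaf near 0.5) even when the
  # other table agreed: the reference orientation itself is uncertain only
  # relative to other tables, which classify_alleles already handled.
  if (any(!keep)) {
    dropped <- rbind(dropped, data.frame(variant_id = ids[!keep],
                                         reason = reasons[!keep]))
  }
  ids <- ids[keep]
  if (!length(ids)) stop_mr("all shared variants were dropped during harmonisation")
  aligned <- lapply(aligned, function(t) t[keep, , drop = FALSE])

  K <- length(exposures)
  exposure_beta <- matrix(NA_real_, length(ids), K,
                          dimnames = list(ids, names(exposures)))
  exposure_se <- exposure_beta
  exposure_pvalue <- exposure_beta
  exposure_n <- exposure_beta
  for (k in seq_len(K)) {
    exposure_beta[, k] <- aligned[[k]]$beta
    exposure_se[, k] <- aligned[[k]]$se
    exposure_pvalue[, k] <- aligned[[k]]$pvalue
    exposure_n[, k] <- aligned[[k]]$n
  }
  out <- aligned[[".outcome"]]
  h <- structure(list(
    variant_id = ids,
    effect_allele = aligned[[1L]]$effect_allele,
    other_allele = aligned[[1L]]$other_allele,
    eaf = aligned[[1L]]$eaf,
    exposure_ids = names(exposures),
    exposure_beta = exposure_beta,
    exposure_se = exposure_se,
    exposure_pvalue = exposure_pvalue,
    exposure_n = exposure_n,
    outcome_id = out$trait_id[1L] %||% "outcome",
    outcome_beta = out$beta,
    outcome_se = out$se,
    outcome_pvalue = out$pvalue,
    outcome_n = out$n,
    ld = if (!is.null(ld)) ld_subset(ld, ids) else NULL,
    dropped = dropped
  ), class = "harmonised_set")
  h
}

#' @export
print.harmonised_set <- function(x, ...) {
  cat(sprintf("Harmonised set: %d variants, exposure(s) %s -> outcome %s\n",
              length(x$variant_id), paste(x$exposure_ids, collapse = " + "),
              x$outcome_id))
  if (nrow(x$dropped)) {
    cat("dropped:", paste(sprintf("%s (%s)", x$dropped$variant_id,
                                  x$dropped$reason), collapse = ", "), "\n")
  }
  if (!is.null(x$ld)) cat("LD correlation matrix attached\n")
  invisible(x)
}

#' Number of variants in a harmonised set
#' @param h A `harmonised_set`.
#' @return Integer count.
#' @export
n_variants <- function(h) length(h$variant_id)

#' Restrict a harmonised set to a subset of variants
#'
#' @param h A `harmonised_set`.
#' @param ids rsIDs to keep (order preserved from `h`), or a logical/integer
#'   index vector.
#' @return The restricted `harmonised_set`.
#' @export
subset_variants <- function(h, ids) {
  idx <- if (is.character(ids)) {
    missing <- setdiff(ids, h$variant_id)
    if (length(missing)) {
      stop_mr("variant(s) not in harmonised set: ",
              paste(missing, collapse = ", "))
    }
    which(h$variant_id %in% ids)
  } else if (is.logical(ids)) which(ids) else as.integer(ids)
  h$variant_id <- h$variant_id[idx]
  h$effect_allele <- h$effect_allele[idx]
  h$other_allele <- h$other_allele[idx]
  h$eaf <- h$eaf[idx]
  h$exposure_beta <- h$exposure_beta[idx, , drop = FALSE]
  h$exposure_se <- h$exposure_se[idx, , drop = FALSE]
  h$exposure_pvalue <- h$exposure_pvalue[idx, , drop = FALSE]
  h$exposure_n <- h$exposure_n[idx, , drop = FALSE]
  h$outcome_beta <- h$outcome_beta[idx]
  h$outcome_se <- h$outcome_se[idx]
  h$outcome_pvalue <- h$outcome_pvalue[idx]
  h$outcome_n <- h$outcome_n[idx]
  if (!is.null(h$ld)) h$ld <- ld_subset(h$ld, h$variant_id)
  h
}

#' Recover per-trait association tables from a harmonised set
#'
#' Useful for re-harmonising (harmonisation is idempotent) and for writing
#' aligned tables back to disk.
#'
#' @param h A `harmonised_set`.
#' @return A list with `exposures` (named list of tables) and `outcome`.
#' @export
as_association_tables <- function(h) {
  mk <- function(beta, se, pvalue, n, trait) {
    data.frame(variant_id = h$variant_id,
               effect_allele = h$effect_allele,
               other_allele = h$other_allele,
               eaf = h$eaf, beta = beta, se = se, pvalue = pvalue, n = n,
               trait_id = trait, pvalue_derived = FALSE,
               stringsAsFactors = FALSE, row.names = NULL)
  }
  exposures <- lapply(seq_along(h$exposure_ids), function(k) {
    mk(h$exposure_beta[, k], h$exposure_se[, k], h$exposure_pvalue[, k],
       h$exposure_n[, k], h$exposure_ids[k])
  })
  names(exposures) <- h$exposure_ids
  list(exposures = exposures,
       outcome = mk(h$outcome_beta, h$outcome_se, h$outcome_pvalue,
                    h$outcome_n, h$outcome_id))
}
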
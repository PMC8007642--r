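# Reading, validating and writing GWAS summary statistics and LD matrices.
#
# The on-disk dialect is a GWAS-SSF-like tab-separated table with header
#   variant_id  effect_allele  other_allele  effect_allele_frequency
#   beta  standard_error  p_value  n
# Inside the package the columns are named
#   variant_id, effect_allele, other_allele, eaf, beta, se, pvalue, n, trait_id.

FILE_COLUMNS <- c(
  variant_id = "variant_id",
  effect_allele = "effect_allele",
  other_allele = "other_allele",
  eaf = "effect_allele_frequency",
  beta = "beta",
  se = "standard_error",
  pvalue = "p_value",
  n = "n"
)

MANDATORY_COLUMNS <- c("variant_id", "effect_allele", "other_allele",
                       "beta", "se")

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-separated table of per-variant associations with one trait and
#' validates every row: alleles must be single bases A/C/G/T with
#' `effect_allele != other_allele`, standard errors must be positive,
#' effect-allele frequencies must lie in \[0, 1\], and reported p-values are
#' cross-checked against `2 * pnorm(-|beta/se|)` (a warning is raised when a
#' p-value disagrees by more than a factor of two, since that usually signals
#' a mislabelled column).  When the p-value column is absent, p-values are
#' recomputed from `beta/se` under a two-sided normal test and the rows are
#' flagged in the `pvalue_derived` column.
#'
#' @param path Path to a tab-separated file with a header row.  Canonical
#'   column names are `variant_id`, `effect_allele`, `other_allele`,
#'   `effect_allele_frequency`, `beta`, `standard_error`, `p_value`, `n`.
#' @param trait_id Label attached to every row (e.g. `"AMPA"` or `"CRC"`).
#' @param column_map Optional named character vector mapping canonical names
#'   to the names actually used in the file, e.g.
#'   `c(variant_id = "SNP", se = "stderr")`.
#' @return A `data.frame` of validated associations with columns
#'   `variant_id`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `pvalue`, `n`, `trait_id`, `pvalue_derived`.
#' @examples
#' ds <- generate_dataset(synthetic_truth(j_snps = 4, seed = 1))
#' f <- tempfile(fileext = ".tsv")
#' write_summary_stats(ds$exposure, f)
#' head(read_summary_stats(f, trait_id = "exposure"))
#' @export
read_summary_stats <- function(path, trait_id, column_map = NULL) {
  if (!file.exists(path)) stop_mr("summary-statistics file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  file_names <- FILE_COLUMNS
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), names(FILE_COLUMNS))
    if (length(bad)) {
      stop_mr("column_map refers to unknown canonical column(s): ",
              paste(bad, collapse = ", "))
    }
    file_names[names(column_map)] <- column_map
  }
  missing_mandatory <- MANDATORY_COLUMNS[
    !file_names[MANDATORY_COLUMNS] %in% names(raw)]
  if (length(missing_mandatory)) {
    stop_mr("missing mandatory column(s) in ", path, ": ",
            paste(file_names[missing_mandatory], collapse = ", "),
            class = "mrmediate_config_error")
  }
  grab <- function(canon, default = NA) {
    nm <- file_names[[canon]]
    if (nm %in% names(raw)) raw[[nm]] else rep(default, nrow(raw))
  }
  tbl <- data.frame(
    variant_id = as.character(grab("variant_id")),
    effect_allele = toupper(as.character(grab("effect_allele"))),
    other_allele = toupper(as.character(grab("other_allele"))),
    eaf = as_numeric_col(grab("eaf"), file_names[["eaf"]]),
    beta = as_numeric_col(grab("beta"), file_names[["beta"]]),
    se = as_numeric_col(grab("se"), file_names[["se"]]),
    pvalue = as_numeric_col(grab("pvalue"), file_names[["pvalue"]]),
    n = as_numeric_col(grab("n"), file_names[["n"]]),
    stringsAsFactors = FALSE
  )
  tbl$trait_id <- trait_id
  had_p <- file_names[["pvalue"]] %in% names(raw)
  tbl$pvalue_derived <- FALSE
  if (!had_p || anyNA(tbl$pvalue)) {
    derive <- is.na(tbl$pvalue)
    tbl$pvalue[derive] <- normal_p(tbl$beta[derive], tbl$se[derive])
    tbl$pvalue_derived <- derive
  }
  tbl <- validate_associations(tbl, path)
  message(sprintf("[summary_io] read %d variants for trait '%s' from %s",
                  nrow(tbl), trait_id, path))
  tbl
}

as_numeric_col <- function(x, label) {
  if (is.numeric(x) || all(is.na(x))) return(as.numeric(x))
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & x != "" & x != "NA")
  if (length(bad)) {
    stop_mr("unparseable numeric value in column '", label,
            "' at data row(s) ", paste(bad, collapse = ", "),
            class = "mrmediate_data_error")
  }
  out
}

# Row-level invariant checks shared by read_summary_stats and harmonise.
validate_associations <- function(tbl, label = "table") {
  dup <- tbl$variant_id[duplicated(tbl$variant_id)]
  if (length(dup)) {
    stop_mr("duplicate variant_id in ", label, ": ",
            paste(unique(dup), collapse = ", "),
            class = "mrmediate_data_error")
  }
  ok_allele <- function(a) a %in% c("A", "C", "G", "T")
  bad <- which(!ok_allele(tbl$effect_allele) | !ok_allele(tbl$other_allele) |
                 tbl$effect_allele == tbl$other_allele)
  if (length(bad)) {
    stop_mr("invalid allele pair in ", label, " at row(s) ",
            paste(bad, collapse = ", "), " (alleles must be distinct A/C/G/T)",
            class = "mrmediate_data_error")
  }
  bad <- which(!is.finite(tbl$se) | tbl$se <= 0)
  if (length(bad)) {
    stop_mr("standard_error must be > 0 in ", label, " at row(s) ",
            paste(bad, collapse = ", "), class = "mrmediate_data_error")
  }
  bad <- which(!is.na(tbl$eaf) & (tbl$eaf < 0 | tbl$eaf > 1))
  if (length(bad)) {
    stop_mr("effect_allele_frequency outside [0, 1] in ", label,
            " at row(s) ", paste(bad, collapse = ", "),
            class = "mrmediate_data_error")
  }
  bad <- which(!is.na(tbl$pvalue) & (tbl$pvalue < 0 | tbl$pvalue > 1))
  if (length(bad)) {
    stop_mr("p_value outside (0, 1] in ", label, " at row(s) ",
            paste(bad, collapse = ", "), class = "mrmediate_data_error")
  }
  # p-values that underflowed to zero (a common artefact of very strong
  # associations) are clamped to the smallest positive double
  zero <- which(!is.na(tbl$pvalue) & tbl$pvalue == 0)
  if (length(zero)) {
    warning(sprintf("%s: %d underflowed p-value(s) clamped to %.3g",
                    label, length(zero), .Machine$double.xmin),
            call. = FALSE)
    tbl$pvalue[zero] <- .Machine$double.xmin
  }
  expected <- normal_p(tbl$beta, tbl$se)
  comparable <- !is.na(tbl$pvalue) & !tbl$pvalue_derived &
    expected > .Machine$double.xmin
  off <- comparable &
    (tbl$pvalue / expected > 2 | tbl$pvalue / expected < 0.5)
  if (any(off)) {
    warning(sprintf(
      "%s: p_value inconsistent with |beta/se| (factor > 2) for %d variant(s), e.g. %s",
      label, sum(off), tbl$variant_id[which(off)[1L]]), call. = FALSE)
  }
  invisible(tbl)
}

#' Write a summary-statistics table in the canonical dialect
#'
#' @param tbl A table as returned by [read_summary_stats()] (the
#'   `trait_id`/`pvalue_derived` bookkeeping columns are not written).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(tbl, path) {
  out <- data.frame(
    variant_id = tbl$variant_id,
    effect_allele = tbl$effect_allele,
    other_allele = tbl$other_allele,
    effect_allele_frequency = format_real(tbl$eaf),
    beta = format_real(tbl$beta),
    standard_error = format_real(tbl$se),
    p_value = format_real(tbl$pvalue),
    n = tbl$n,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

format_real <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 15, format = "g"))
}

#' Read an LD correlation matrix
#'
#' Reads a square tab-separated matrix of signed correlations whose first row
#' and first column hold rsIDs.  The matrix must be symmetric within 1e-8
#' (it is then symmetrised as `(M + t(M))/2`), have a unit diagonal within
#' 1e-8, entries in \[-1, 1\], and be positive semi-definite within numerical
#' tolerance (smallest eigenvalue >= -1e-8).
#'
#' @param path Path to the matrix file.
#' @return An `ld_matrix` object.
#' @export
read_ld_matrix <- function(path) {
  if (!file.exists(path)) stop_mr("LD matrix file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1L,
                           check.names = FALSE)
  m <- as.matrix(raw)
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) {
    stop_mr("LD matrix is not square: ", nrow(m), " x ", ncol(m),
            class = "mrmediate_format_error")
  }
  if (!identical(rownames(m), colnames(m))) {
    stop_mr("LD matrix row and column rsIDs disagree",
            class = "mrmediate_format_error")
  }
  ld_matrix(m, rownames(m))
}

#' Construct a validated LD correlation matrix
#'
#' @param values Square numeric matrix of signed correlations.
#' @param variant_ids rsIDs labelling rows/columns, in order.
#' @return An `ld_matrix`: the validated matrix with a `variant_ids`
#'   attribute and an exact unit diagonal.
#' @export
ld_matrix <- function(values, variant_ids = rownames(values)) {
  m <- as.matrix(values)
  if (nrow(m) != ncol(m)) stop_mr("LD matrix must be square")
  if (is.null(variant_ids) || length(variant_ids) != nrow(m)) {
    stop_mr("variant_ids must label every row of the LD matrix")
  }
  asym <- max(abs(m - t(m)))
  if (asym > 1e-8) {
    stop_mr("LD matrix asymmetric beyond tolerance (max |M - t(M)| = ",
            format(asym), ")", class = "mrmediate_data_error")
  }
  m <- (m + t(m)) / 2
  if (max(abs(diag(m) - 1)) > 1e-8) {
    stop_mr("LD matrix diagonal differs from 1 beyond 1e-8",
            class = "mrmediate_data_error")
  }
  diag(m) <- 1
  if (max(abs(m)) > 1 + 1e-8) {
    stop_mr("LD correlations outside [-1, 1]", class = "mrmediate_data_error")
  }
  m[m > 1] <- 1
  m[m < -1] <- -1
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop_mr("LD matrix is not positive semi-definite (min eigenvalue ",
            format(min(ev)), ")", class = "mrmediate_data_error")
  }
  dimnames(m) <- list(as.character(variant_ids), as.character(variant_ids))
  structure(m, class = c("ld_matrix", "matrix", "array"))
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat("LD correlation matrix for", nrow(x), "variants\n")
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))),
                   drop = FALSE])
  invisible(x)
}

#' Look up a signed LD correlation by rsID pair
#'
#' @param ld An [ld_matrix()].
#' @param id1,id2 rsIDs.
#' @return The signed correlation `r`.
#' @export
ld_r <- function(ld, id1, id2) {
  for (id in c(id1, id2)) {
    if (!id %in% rownames(ld)) stop_mr("variant not in LD matrix: ", id)
  }
  unclass(ld)[id1, id2]
}

# Restrict an LD matrix to an ordered subset of variants.
ld_subset <- function(ld, ids) {
  if (is.null(ld)) return(NULL)
  missing <- setdiff(ids, rownames(ld))
  if (length(missing)) {
    stop_mr("LD matrix does not cover variant(s): ",
            paste(missing, collapse = ", "))
  }
  ld_matrix(unclass(ld)[ids, ids, drop = FALSE], ids)
}

#' Write an LD matrix in the canonical dialect
#'
#' @param ld An [ld_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  m <- unclass(ld)
  out <- data.frame(variant_id = rownames(m),
                    apply(m, 2L, format_real),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
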
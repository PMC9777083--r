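#' Construct a cohort object
#'
#' A cohort bundles a gene-by-sample expression matrix with a per-sample
#' clinical table carrying right-censored overall-survival information.
#' Expression values may be on any platform-dependent scale; the pipeline only
#' ever uses within-sample orderings, so the scale never needs to be
#' harmonized across cohorts.
#'
#' @param expr Numeric matrix, genes in rows (rownames = gene IDs), samples in
#'   columns (colnames = sample IDs). `NA` marks missing values.
#' @param clinical Data frame with one row per sample. Must contain columns
#'   `sample_id`, `os_time` (months) and `os_event` (1 = death observed,
#'   0 = censored). Optional columns: `age`, `stage`, `grade`,
#'   `drug_response` (one of CR/PR/SD/PD or `NA`), `platinum_flag`.
#' @param name Cohort label used in messages and reports.
#' @param role One of `"training"`, `"test"`, `"validation"`.
#' @param platform Free-text platform label (defaults to `name`).
#'
#' @return An object of class `reo_cohort`: a list with elements `name`,
#'   `platform`, `role`, `expr`, `clinical`. Samples in `clinical` are stored
#'   in the column order of `expr`.
#' @export
cohort <- function(expr, clinical, name = "cohort",
                   role = c("training", "test", "validation"),
                   platform = name) {
  role <- match.arg(role)
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("'expr' must be a numeric matrix (genes x samples)")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("'expr' needs rownames (gene IDs) and colnames (sample IDs)")
  if (anyDuplicated(colnames(expr)))
    stop("duplicate sample IDs in expression matrix of cohort '", name, "'")
  if (!is.data.frame(clinical) ||
      !all(c("sample_id", "os_time", "os_event") %in% names(clinical)))
    stop("'clinical' must be a data.frame with sample_id, os_time, os_event")
  clinical$sample_id <- as.character(clinical$sample_id)
  if (anyDuplicated(clinical$sample_id))
    stop("duplicate sample IDs in clinical table of cohort '", name, "'")
  if (!setequal(colnames(expr), clinical$sample_id))
    stop("expression and clinical sample IDs differ in cohort '", name,
         "'; use read_cohort() to intersect them")
  clinical <- clinical[match(colnames(expr), clinical$sample_id), , drop = FALSE]
  rownames(clinical) <- NULL
  bad <- !(clinical$os_event %in% c(0, 1, NA))
  if (any(bad)) stop("os_event must be 0/1/NA in cohort '", name, "'")
  structure(
    list(name = name, platform = platform, role = role,
         expr = expr, clinical = clinical),
    class = "reo_cohort"
  )
}

#' @export
print.reo_cohort <- function(x, ...) {
  cat(sprintf("<reo_cohort> %s [%s, platform %s]: %d genes x %d samples, %d events\n",
              x$name, x$role, x$platform, nrow(x$expr), ncol(x$expr),
              sum(x$clinical$os_event == 1, na.rm = TRUE)))
  invisible(x)
}

#' Read a cohort from delimited text files
#'
#' The expression file has genes in rows: first column gene IDs, remaining
#' columns one per sample with a header row of sample IDs. The clinical file
#' has one row per sample with named columns including `sample_id`, `os_time`
#' and `os_event`. Samples are intersected between the two files; counts of
#' dropped IDs are reported via `message()`.
#'
#' @param expression_path Path to the expression table.
#' @param clinical_path Path to the clinical table.
#' @param name,role,platform Passed to [cohort()].
#' @param sep Field separator, `"\t"` (default) or `","`.
#' @param time_unit `"months"` (stored as-is) or `"days"` (divided by 30.44,
#'   the mean month length, so all cohorts share one time unit).
#'
#' @return A [cohort()] object.
#' @export
read_cohort <- function(expression_path, clinical_path, name = "cohort",
                        role = c("training", "test", "validation"),
                        platform = name, sep = "\t",
                        time_unit = c("months", "days")) {
  role <- match.arg(role)
  time_unit <- match.arg(time_unit)
  ex <- tryCatch(
    utils::read.table(expression_path, header = TRUE, sep = sep,
                      check.names = FALSE, stringsAsFactors = FALSE,
                      comment.char = "", quote = ""),
    error = function(e) stop("cannot read expression file '", expression_path,
                             "': ", conditionMessage(e)))
  if (ncol(ex) < 2) stop("expression file '", expression_path,
                         "' needs a gene-ID column plus >= 1 sample column")
  gene_ids <- as.character(ex[[1]])
  m <- as.matrix(ex[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- gene_ids
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample IDs in expression file '", expression_path, "'")

  cl <- tryCatch(
    utils::read.table(clinical_path, header = TRUE, sep = sep,
                      check.names = FALSE, stringsAsFactors = FALSE,
                      comment.char = "", quote = ""),
    error = function(e) stop("cannot read clinical file '", clinical_path,
                             "': ", conditionMessage(e)))
  if (!"sample_id" %in% names(cl)) names(cl)[1] <- "sample_id"
  cl$sample_id <- as.character(cl$sample_id)
  if (anyDuplicated(cl$sample_id))
    stop("duplicate sample IDs in clinical file '", clinical_path, "'")
  if (!all(c("os_time", "os_event") %in% names(cl)))
    stop("clinical file '", clinical_path, "' must have os_time and os_event")
  if (time_unit == "days") cl$os_time <- cl$os_time / 30.44

  keep <- intersect(colnames(m), cl$sample_id)
  if (length(keep) == 0)
    stop("no overlapping samples between '", expression_path, "' and '",
         clinical_path, "'")
  d_ex <- ncol(m) - length(keep)
  d_cl <- nrow(cl) - length(keep)
  if (d_ex > 0) message(name, ": dropped ", d_ex, " expression-only sample(s)")
  if (d_cl > 0) message(name, ": dropped ", d_cl, " clinical-only sample(s)")
  cohort(m[, keep, drop = FALSE],
         cl[cl$sample_id %in% keep, , drop = FALSE],
         name = name, role = role, platform = platform)
}

#' Write a cohort back to delimited text
#'
#' Inverse of [read_cohort()]; values are written with full precision so a
#' read/write round-trip is exact for finite entries.
#'
#' @param c A `reo_cohort`.
#' @param expression_path,clinical_path Output paths.
#' @param sep Field separator.
#' @return Invisibly, the cohort.
#' @export
write_cohort <- function(c, expression_path, clinical_path, sep = "\t") {
  stopifnot(inherits(c, "reo_cohort"))
  df <- data.frame(gene_id = rownames(c$expr), c$expr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, expression_path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  utils::write.table(c$clinical, clinical_path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(c)
}

#' Average rows that share a gene identifier
#'
#' Multiple probes mapping to one gene are collapsed by taking the element-wise
#' mean of their rows, excluding missing values cell by cell. Row order follows
#' the first occurrence of each gene ID.
#'
#' @param expr Numeric matrix with gene-ID rownames (duplicates allowed).
#' @return Matrix with unique rownames.
#' @export
collapse_duplicate_genes <- function(expr) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (!anyDuplicated(rownames(expr))) return(expr)
  g <- factor(rownames(expr), levels = unique(rownames(expr)))
  vals <- expr
  vals[is.na(vals)] <- 0
  sums <- rowsum(vals, g)
  cnts <- rowsum((!is.na(expr)) * 1, g)
  out <- sums / cnts          # 0/0 -> NaN where a cell had no observed value
  out[cnts == 0] <- NA
  rownames(out) <- levels(g)
  out
}

#' Apply survival and low-expression filters to a cohort
#'
#' Removes samples lacking survival information (`NA` in `os_time` or
#' `os_event`) and samples with non-positive survival time, then removes genes
#' whose value is missing or exactly zero in strictly more than
#' `low_expr_fraction` of the remaining samples. Duplicate gene IDs are
#' collapsed first via [collapse_duplicate_genes()]. Idempotent.
#'
#' @param c A `reo_cohort`.
#' @param low_expr_fraction Fraction of samples above which a missing-or-zero
#'   gene is dropped (strict inequality). Default 0.5 ("more than half").
#' @return A filtered `reo_cohort`.
#' @export
preprocess_cohort <- function(c, low_expr_fraction = 0.5) {
  stopifnot(inherits(c, "reo_cohort"),
            low_expr_fraction >= 0, low_expr_fraction <= 1)
  cl <- c$clinical
  keep_s <- !is.na(cl$os_time) & !is.na(cl$os_event) & cl$os_time > 0
  n_drop <- sum(!keep_s)
  if (n_drop > 0)
    message(c$name, ": removed ", n_drop,
            " sample(s) with missing or zero survival")
  if (!any(keep_s))
    stop("cohort '", c$name, "' is empty after sample filtering")
  expr <- collapse_duplicate_genes(c$expr[, keep_s, drop = FALSE])
  cl <- cl[keep_s, , drop = FALSE]

  n_s <- ncol(expr)
  bad_counts <- rowSums(is.na(expr) | expr == 0)
  keep_g <- bad_counts <= low_expr_fraction * n_s
  if (any(!keep_g))
    message(c$name, ": removed ", sum(!keep_g), " low-expression gene(s)")
  if (!any(keep_g))
    stop("cohort '", c$name, "' has no genes left after the low-expression filter")
  cohort(expr[keep_g, , drop = FALSE], cl, name = c$name, role = c$role,
         platform = c$platform)
}

#' Genes shared by every cohort
#'
#' @param cohorts A list of `reo_cohort` objects.
#' @return Sorted character vector of gene IDs present in all cohorts.
#' @export
common_gene_universe <- function(cohorts) {
  stopifnot(is.list(cohorts), length(cohorts) >= 1,
            all(vapply(cohorts, inherits, logical(1), "reo_cohort")))
  common <- Reduce(intersect, lapply(cohorts, function(c) rownames(c$expr)))
  if (length(common) == 0)
    stop("no genes are common to all ", length(cohorts), " cohorts")
  sort(common)
}
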
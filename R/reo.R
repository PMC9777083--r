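#' Screen genes for consistent survival association across training cohorts
#'
#' Restricts to the gene universe common to all cohorts, fits a univariate Cox
#' model of each gene's expression against overall survival in every cohort,
#' and keeps a gene when (i) its Wald p-value is below `alpha` in at least one
#' cohort and (ii) the sign of its hazard coefficient is identical in every
#' cohort where the fit converged. The second condition enforces the
#' cross-platform direction-consistency requirement that makes the downstream
#' pair orientations transferable.
#'
#' @param cohorts List of training `reo_cohort` objects.
#' @param alpha Per-cohort significance level (default 0.05).
#' @return Sorted character vector of kept gene IDs. Attribute `"details"`
#'   holds a data frame of per-cohort coefficients and p-values for all tested
#'   genes.
#' @export
screen_genes <- function(cohorts, alpha = 0.05) {
  genes <- common_gene_universe(cohorts)
  k <- length(cohorts)
  coefs <- matrix(NA_real_, length(genes), k)
  pvals <- matrix(NA_real_, length(genes), k)
  for (c_idx in seq_len(k)) {
    co <- cohorts[[c_idx]]
    tt <- co$clinical$os_time
    ev <- co$clinical$os_event
    ex <- co$expr[genes, , drop = FALSE]
    for (g_idx in seq_along(genes)) {
      f <- cox_fit(ex[g_idx, ], tt, ev)
      if (f$converged[1]) {
        coefs[g_idx, c_idx] <- f$coef[1]
        pvals[g_idx, c_idx] <- f$p[1]
      }
    }
  }
  sig_any <- rowSums(pvals < alpha, na.rm = TRUE) >= 1
  n_conv <- rowSums(!is.na(coefs))
  sgn <- sign(coefs)
  consistent <- n_conv >= 1 &
    (rowSums(sgn == 1, na.rm = TRUE) == n_conv |
     rowSums(sgn == -1, na.rm = TRUE) == n_conv)
  keep <- genes[sig_any & consistent]
  message(length(keep), " of ", length(genes),
          " common genes pass screening (alpha = ", alpha, ")")
  details <- data.frame(gene = genes, coefs, pvals, check.names = FALSE)
  names(details) <- c("gene",
                      paste0("coef_", vapply(cohorts, `[[`, "", "name")),
                      paste0("p_", vapply(cohorts, `[[`, "", "name")))
  structure(sort(keep), details = details)
}

#' Enumerate all unordered gene pairs
#'
#' @param genes Character vector of >= 2 unique gene IDs.
#' @return Data frame with columns `gene_a`, `gene_b` in canonical order
#'   (`gene_a` lexicographically before `gene_b`); `g*(g-1)/2` rows.
#' @export
enumerate_pairs <- function(genes) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("gene IDs must be unique")
  if (length(genes) < 2) stop("need at least 2 genes to form pairs")
  genes <- sort(genes)
  idx <- utils::combn(length(genes), 2)
  data.frame(gene_a = genes[idx[1, ]], gene_b = genes[idx[2, ]],
             stringsAsFactors = FALSE)
}

#' Build the binary relative-expression-ordering matrix
#'
#' Entry (i, j) is 1 when gene_a of pair i has strictly higher expression
#' than gene_b in sample j, and 0 otherwise (ties fall into the
#' "less-than-or-equal" state). Because only within-sample comparisons enter,
#' the matrix is invariant under any strictly increasing transform applied to
#' a sample's values. Pairs whose genes are absent from the matrix (e.g. on a
#' different platform) are excluded and listed in the `"undetected"`
#' attribute.
#'
#' @param expr Numeric matrix, genes x samples; or a `reo_cohort`.
#' @param pairs Data frame with `gene_a`, `gene_b` columns.
#' @return List of class `reo_matrix` with `pairs` (detected pairs), `X`
#'   (integer 0/1 matrix, pairs x samples) and `sample_ids`.
#' @export
build_reo_matrix <- function(expr, pairs) {
  if (inherits(expr, "reo_cohort")) expr <- expr$expr
  stopifnot(is.matrix(expr), all(c("gene_a", "gene_b") %in% names(pairs)))
  present <- pairs$gene_a %in% rownames(expr) & pairs$gene_b %in% rownames(expr)
  undetected <- pairs[!present, , drop = FALSE]
  pairs <- pairs[present, , drop = FALSE]
  if (nrow(pairs) == 0)
    stop("none of the ", nrow(undetected), " pairs are detected in this matrix")
  a <- expr[pairs$gene_a, , drop = FALSE]
  b <- expr[pairs$gene_b, , drop = FALSE]
  if (anyNA(a) || anyNA(b))
    stop("missing expression among pair genes; run preprocess_cohort() first")
  X <- (a > b) * 1L
  rownames(X) <- paste(pairs$gene_a, pairs$gene_b, sep = "|")
  structure(list(pairs = pairs, X = X, sample_ids = colnames(expr)),
            class = "reo_matrix", undetected = undetected)
}

#' Screen and orient gene pairs by pooled Cox regression of their REO state
#'
#' Each pair's binary ordering indicator is fitted against pooled training
#' survival; Benjamini-Hochberg adjustment is applied across all pairs whose
#' indicator was non-constant (constant pairs carry no ordering information
#' and are excluded before adjustment). Significant pairs are oriented so
#' that `risky_state` is the ordering value associated with increased hazard,
#' and each receives a concordance index computed on its risky-state
#' indicator — which is therefore at least 0.5 by construction. The result is
#' sorted by decreasing concordance (ties broken by gene IDs), the order the
#' greedy search consumes.
#'
#' @param reo An `reo_matrix` built on the pooled training samples.
#' @param time,event Pooled training survival (months, 0/1), aligned with
#'   `reo$sample_ids`.
#' @param alpha_adj Threshold on BH-adjusted p-values (default 0.05).
#' @return Data frame of class `reo_pairs` with columns `gene_a`, `gene_b`,
#'   `risky_state`, `coef`, `hr`, `p`, `adj_p`, `c_index`.
#' @export
screen_pairs <- function(reo, time, event, alpha_adj = 0.05) {
  stopifnot(inherits(reo, "reo_matrix"),
            length(time) == ncol(reo$X), length(event) == ncol(reo$X))
  X <- reo$X
  nonconst <- rowSums(X) > 0 & rowSums(X) < ncol(X)
  n_const <- sum(!nonconst)
  if (n_const > 0)
    message(n_const, " pair(s) with constant ordering excluded before adjustment")
  idx <- which(nonconst)
  fits <- lapply(idx, function(i) cox_fit(X[i, ], time, event))
  conv <- vapply(fits, function(f) f$converged[1], logical(1))
  idx <- idx[conv]; fits <- fits[conv]
  if (length(idx) == 0) {
    message("no pair produced a converged fit; returning empty set")
    return(empty_oriented_pairs())
  }
  p <- vapply(fits, function(f) f$p[1], numeric(1))
  coef <- vapply(fits, function(f) f$coef[1], numeric(1))
  hr <- vapply(fits, function(f) f$hr[1], numeric(1))
  adj <- bh_adjust(p)
  keep <- adj < alpha_adj
  if (!any(keep)) {
    message("no pair significant at adjusted alpha = ", alpha_adj)
    return(empty_oriented_pairs())
  }
  idx <- idx[keep]
  risky <- ifelse(coef[keep] > 0, 1L, 0L)
  cmp <- comparable_pairs(time, event)
  cidx <- vapply(seq_along(idx), function(k) {
    score <- as.numeric(X[idx[k], ] == risky[k])
    concordance_fast(score, cmp$i, cmp$j)
  }, numeric(1))
  out <- data.frame(reo$pairs[idx, , drop = FALSE],
                    risky_state = risky,
                    coef = coef[keep], hr = hr[keep],
                    p = p[keep], adj_p = adj[keep], c_index = cidx,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$c_index, out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  message(nrow(out), " significant oriented pair(s) at adjusted alpha = ",
          alpha_adj)
  class(out) <- c("reo_pairs", "data.frame")
  out
}

empty_oriented_pairs <- function() {
  out <- data.frame(gene_a = character(0), gene_b = character(0),
                    risky_state = integer(0), coef = numeric(0),
                    hr = numeric(0), p = numeric(0), adj_p = numeric(0),
                    c_index = numeric(0), stringsAsFactors = FALSE)
  class(out) <- c("reo_pairs", "data.frame")
  out
}
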
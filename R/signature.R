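#' Risky-vote fraction of a pair combination
#'
#' The continuous risk score of a combination: for each sample, the fraction
#' of its detected pairs sitting in their risk-indicating ordering state.
#' Dichotomizing this score at one half gives the majority-vote classifier;
#' the greedy search maximizes its concordance with training survival.
#'
#' @param reo An `reo_matrix` for the samples being scored.
#' @param combo A data frame of oriented pairs (`gene_a`, `gene_b`,
#'   `risky_state`), e.g. rows of a [screen_pairs()] result.
#' @return Named numeric vector in \[0, 1\], one entry per sample.
#' @export
combination_score <- function(reo, combo) {
  stopifnot(inherits(reo, "reo_matrix"),
            all(c("gene_a", "gene_b", "risky_state") %in% names(combo)),
            nrow(combo) >= 1)
  key <- paste(combo$gene_a, combo$gene_b, sep = "|")
  hit <- match(key, rownames(reo$X))
  if (all(is.na(hit)))
    stop("no pair of the combination is detected on samples ",
         paste(utils::head(reo$sample_ids, 3), collapse = ", "), ", ...")
  det <- !is.na(hit)
  votes <- reo$X[hit[det], , drop = FALSE] == combo$risky_state[det]
  colMeans(votes)
}

#' Greedy concordance-maximizing combination search
#'
#' Seeds one combination from each of the `n_seeds` candidate pairs with the
#' highest individual concordance, then sweeps the remaining candidates once
#' in decreasing-concordance order, accepting a pair into the combination only
#' when it strictly increases the concordance of the combination's risky-vote
#' fraction with training survival. The objective is therefore non-decreasing
#' along each accepted addition and every final combination scores at least as
#' well as its seed.
#'
#' @param candidates A [screen_pairs()] result (already sorted by decreasing
#'   `c_index`).
#' @param reo The training `reo_matrix` the candidates were screened on.
#' @param time,event Pooled training survival aligned with `reo$sample_ids`.
#' @param n_seeds Number of top candidates used as seeds (default 10).
#' @param tol Minimum concordance improvement counted as an increase
#'   (absorbs floating-point noise; default 1e-12).
#' @return List of combinations; each has `pairs` (rows of `candidates`),
#'   `train_c_index` and `seed_rank`.
#' @export
greedy_build <- function(candidates, reo, time, event, n_seeds = 10,
                         tol = 1e-12) {
  stopifnot(inherits(reo, "reo_matrix"), nrow(candidates) >= 1)
  n_seeds <- min(n_seeds, nrow(candidates))
  key <- paste(candidates$gene_a, candidates$gene_b, sep = "|")
  rows <- match(key, rownames(reo$X))
  if (anyNA(rows)) stop("candidates contain pairs absent from the REO matrix")
  # vote indicator per candidate x sample; C-index of the vote fraction equals
  # the C-index of the vote sum, so sums are kept incrementally
  V <- (reo$X[rows, , drop = FALSE] == candidates$risky_state) * 1L
  cmp <- comparable_pairs(time, event)

  lapply(seq_len(n_seeds), function(s) {
    members <- s
    vote_sum <- V[s, ]
    best <- concordance_fast(vote_sum, cmp$i, cmp$j)
    for (cand in setdiff(seq_len(nrow(candidates)), s)) {
      trial <- vote_sum + V[cand, ]
      ci <- concordance_fast(trial, cmp$i, cmp$j)
      if (ci > best + tol) {
        members <- c(members, cand)
        vote_sum <- trial
        best <- ci
      }
    }
    list(pairs = candidates[members, , drop = FALSE],
         train_c_index = best, seed_rank = s)
  })
}

#' Select the final signature on an independent test cohort
#'
#' Each candidate combination's risky-vote fraction is evaluated on the test
#' cohort with a univariate Cox model; among combinations significantly
#' associated with test survival (Wald p < `alpha`), the one with the largest
#' test concordance becomes the signature.
#'
#' @param combos Output of [greedy_build()].
#' @param test_cohort A `reo_cohort` disjoint from training.
#' @param alpha Significance gate on the test-set Cox p-value (default 0.05).
#' @return An object of class `reo_signature`: list with `pairs`, `n_pairs`,
#'   `training_c_index`, `test_c_index`, `test_cox_p` and `provenance`.
#' @export
select_final <- function(combos, test_cohort, alpha = 0.05) {
  stopifnot(length(combos) >= 1, inherits(test_cohort, "reo_cohort"))
  tt <- test_cohort$clinical$os_time
  ev <- test_cohort$clinical$os_event
  cmp <- comparable_pairs(tt, ev)
  stats <- lapply(combos, function(cb) {
    reo <- build_reo_matrix(test_cohort, cb$pairs)
    sc <- combination_score(reo, cb$pairs)
    f <- cox_fit(sc, tt, ev)
    list(p = f$p[1], c = concordance_fast(sc, cmp$i, cmp$j))
  })
  p <- vapply(stats, `[[`, numeric(1), "p")
  cidx <- vapply(stats, `[[`, numeric(1), "c")
  ok <- which(p < alpha)
  if (length(ok) == 0)
    stop("no combination is significant on the test cohort (min p = ",
         signif(min(p), 3), "); consider more training data or a different ",
         "number of seeds")
  pick <- ok[which.max(cidx[ok])]
  sig <- list(pairs = combos[[pick]]$pairs,
              n_pairs = nrow(combos[[pick]]$pairs),
              training_c_index = combos[[pick]]$train_c_index,
              test_c_index = cidx[pick],
              test_cox_p = p[pick],
              provenance = list(seed_rank = combos[[pick]]$seed_rank,
                                n_combos = length(combos),
                                test_cohort = test_cohort$name))
  class(sig) <- "reo_signature"
  sig
}

#' @export
print.reo_signature <- function(x, ...) {
  cat(sprintf(paste0("<reo_signature> %d oriented gene pairs\n",
                     "  training C-index %.3f | test C-index %.3f ",
                     "(Cox p = %.3g, test cohort %s)\n"),
              x$n_pairs, x$training_c_index, x$test_c_index, x$test_cox_p,
              x$provenance$test_cohort))
  print(utils::head(x$pairs[, c("gene_a", "gene_b", "risky_state", "c_index")],
                    10))
  if (x$n_pairs > 10) cat("  ...", x$n_pairs - 10, "more pairs\n")
  invisible(x)
}

#' Run the full training cascade and return a signature
#'
#' Convenience wrapper: screens genes across the training cohorts, enumerates
#' and screens pairs on the pooled training samples, runs the greedy search
#' and selects the final combination on the test cohort.
#'
#' @param training List of training `reo_cohort` objects (preprocessed).
#' @param test_cohort The held-out test `reo_cohort`.
#' @param alpha Gene-level and test-selection significance level.
#' @param alpha_adj Pair-level BH-adjusted significance level.
#' @param n_seeds Number of greedy seeds.
#' @param max_candidates Optional cap on the number of top-concordance
#'   candidates entering the greedy search (`Inf` = no cap).
#' @return An `reo_signature`.
#' @export
build_signature <- function(training, test_cohort, alpha = 0.05,
                            alpha_adj = 0.05, n_seeds = 10,
                            max_candidates = Inf) {
  genes <- screen_genes(training, alpha = alpha)
  if (length(genes) < 2)
    stop("fewer than 2 genes passed screening; cannot form pairs")
  pairs <- enumerate_pairs(genes)
  pooled <- pool_training(training, genes)
  reo <- build_reo_matrix(pooled$expr, pairs)
  cand <- screen_pairs(reo, pooled$time, pooled$event, alpha_adj = alpha_adj)
  if (nrow(cand) == 0) stop("no significant pairs; cannot build a signature")
  if (nrow(cand) > max_candidates)
    cand <- cand[seq_len(max_candidates), , drop = FALSE]
  combos <- greedy_build(cand, reo, pooled$time, pooled$event,
                         n_seeds = n_seeds)
  select_final(combos, test_cohort, alpha = alpha)
}

pool_training <- function(training, genes) {
  expr <- do.call(cbind, lapply(training, function(c)
    c$expr[genes, , drop = FALSE]))
  colnames(expr) <- unlist(lapply(training, function(c)
    paste(c$name, colnames(c$expr), sep = ":")))
  list(expr = expr,
       time = unlist(lapply(training, function(c) c$clinical$os_time)),
       event = unlist(lapply(training, function(c) c$clinical$os_event)))
}

#' Majority-vote risk classification
#'
#' Classifies each sample of a cohort as high or low risk by the majority
#' vote of the signature's oriented pairs. Pairs whose genes are not measured
#' on the cohort's platform are dropped first; the remaining pairs vote, and
#' a sample is called high-risk when at least half of the votes are in the
#' risky state (an exact tie is called high-risk and flagged). Each call uses
#' only the sample's own orderings, so it is unchanged by adding, removing or
#' reordering other samples.
#'
#' @param cohort A `reo_cohort` (only its expression matrix is used).
#' @param sig An `reo_signature`.
#' @return Data frame with `sample_id`, `votes_risky`, `votes_total`,
#'   `score` (vote fraction), `label` (factor high/low) and `tie`.
#' @export
classify <- function(cohort, sig) {
  stopifnot(inherits(cohort, "reo_cohort"), inherits(sig, "reo_signature"))
  expr <- cohort$expr
  det <- sig$pairs$gene_a %in% rownames(expr) &
         sig$pairs$gene_b %in% rownames(expr)
  if (!any(det))
    stop("no signature pair is detected on platform '", cohort$platform, "'")
  if (any(!det))
    message(sum(!det), " of ", length(det),
            " signature pair(s) undetected on platform '", cohort$platform,
            "' and removed before voting")
  pairs <- sig$pairs[det, , drop = FALSE]
  reo <- build_reo_matrix(expr, pairs)
  frac <- combination_score(reo, pairs)
  total <- nrow(pairs)
  risky <- as.integer(round(frac * total))
  tie <- (2L * risky) == total
  label <- factor(ifelse(2L * risky >= total, "high", "low"),
                  levels = c("high", "low"))
  data.frame(sample_id = colnames(expr), votes_risky = risky,
             votes_total = total, score = frac, label = label, tie = tie,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a signature to a JSON file
#'
#' @param sig An `reo_signature`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "reo_signature"))
  jsonlite::write_json(unclass(sig), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a signature written by [write_signature()]
#'
#' @param path JSON path.
#' @return An `reo_signature`.
#' @export
read_signature <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$pairs <- as.data.frame(x$pairs, stringsAsFactors = FALSE)
  x$n_pairs <- as.integer(x$n_pairs)
  class(x) <- "reo_signature"
  x
}
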
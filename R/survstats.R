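#' Univariate or multivariate Cox proportional-hazards fit
#'
#' Thin wrapper around [survival::coxph()] with Breslow tie handling that
#' never throws on degenerate screening inputs: a constant covariate, fewer
#' than two events, or a fit that fails to converge yields a flagged
#' `converged = FALSE` row with `p = 1`, so large screening loops can skip
#' uninformative features instead of crashing.
#'
#' @param x Numeric vector (one covariate) or matrix / data frame of numeric
#'   covariates (columns are covariates, fitted jointly).
#' @param time Survival times in months.
#' @param event Event indicator, 1 = death observed, 0 = censored.
#' @param iter_max Maximum Newton iterations (step-halving handled by
#'   `survival`).
#' @return A data frame of class `reo_coxfit`, one row per covariate, with
#'   columns `term`, `coef` (log hazard ratio), `hr`, `se`, `p` (Wald),
#'   `ci_low`, `ci_high` (95% CI on the hazard ratio) and `converged`.
#' @export
cox_fit <- function(x, time, event, iter_max = 50) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1,
                                   dimnames = list(NULL, "x"))
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  stopifnot(nrow(x) == length(time), length(time) == length(event))

  blank <- data.frame(term = colnames(x), coef = NA_real_, hr = NA_real_,
                      se = NA_real_, p = 1, ci_low = NA_real_,
                      ci_high = NA_real_, converged = FALSE,
                      stringsAsFactors = FALSE)
  class(blank) <- c("reo_coxfit", "data.frame")

  const <- apply(x, 2, function(v) length(unique(v[!is.na(v)])) < 2)
  if (sum(event == 1, na.rm = TRUE) < 2 || all(const)) return(blank)

  fit <- tryCatch(
    withCallingHandlers(
      survival::coxph(survival::Surv(time, event) ~ x, ties = "breslow",
                      control = survival::coxph.control(iter.max = iter_max)),
      warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) NULL)
  if (is.null(fit)) return(blank)

  cf <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  ok <- is.finite(cf) & is.finite(se) & se > 0 & !const
  # runaway coefficients (monotone likelihood) are flagged, not reported
  ok <- ok & abs(cf) < 15
  z <- ifelse(ok, cf / se, NA_real_)
  out <- data.frame(
    term = colnames(x),
    coef = ifelse(ok, cf, NA_real_),
    hr = ifelse(ok, exp(cf), NA_real_),
    se = ifelse(ok, se, NA_real_),
    p = ifelse(ok, 2 * stats::pnorm(-abs(z)), 1),
    ci_low = ifelse(ok, exp(cf - 1.96 * se), NA_real_),
    ci_high = ifelse(ok, exp(cf + 1.96 * se), NA_real_),
    converged = ok,
    stringsAsFactors = FALSE)
  class(out) <- c("reo_coxfit", "data.frame")
  out
}

#' Harrell's concordance index
#'
#' Fraction of comparable sample pairs in which the sample with the shorter
#' observed event time also has the higher risk score, counting score ties as
#' one half. A pair (i, j) is comparable when `time[i] < time[j]` and sample
#' i's event was observed; censored-censored pairs and pairs tied on time are
#' not comparable.
#'
#' @param score Numeric risk scores (higher = worse predicted survival).
#' @param time Survival times in months.
#' @param event Event indicator (1 = observed).
#' @return Concordance in \[0, 1\].
#' @export
concordance_index <- function(score, time, event) {
  stopifnot(length(score) == length(time), length(time) == length(event))
  cmp <- comparable_pairs(time, event)
  if (length(cmp$i) == 0)
    stop("no comparable pairs: survival data are uninformative for ranking")
  concordance_fast(score, cmp$i, cmp$j)
}

# Index vectors of comparable pairs: i is the earlier, observed event.
# Precomputed once and reused across the thousands of C-index evaluations in
# the greedy search.
comparable_pairs <- function(time, event) {
  m <- outer(time, time, "<") & (event == 1)
  idx <- which(m, arr.ind = TRUE)
  list(i = idx[, 1], j = idx[, 2])
}

concordance_fast <- function(score, ii, jj) {
  a <- score[ii]; b <- score[jj]
  (sum(a > b) + 0.5 * sum(a == b)) / length(ii)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, order-preserving with the input
#' and capped at 1.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\] (`NA` passed through).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' @param time Survival times in months.
#' @param event Event indicator (1 = observed).
#' @param group Two-level grouping vector.
#' @return List with `fit` (a [survival::survfit()] object), `logrank_p`,
#'   `chisq` and per-group `n` / `events`.
#' @export
km_logrank <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2)
    stop("km_logrank() needs exactly two non-empty groups; got ",
         nlevels(droplevels(group)))
  group <- droplevels(group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  list(fit = fit, logrank_p = p, chisq = unname(sd$chisq),
       n = sd$n, events = sd$obs)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' The p-value sums hypergeometric probabilities of tables at most as likely
#' as the observed one (the classical two-sided convention). The odds ratio is
#' the sample cross-product ratio `(a*d)/(b*c)`, not the conditional MLE, so
#' printed contingency tables reproduce exactly.
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise:
#'   `rbind(c(a, b), c(c, d))`.
#' @return List of class `reo_fisher` with `table`, `odds_ratio` and `p`.
#' @export
fisher_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  tab <- matrix(as.integer(round(cells)), nrow = 2, byrow = TRUE)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  p <- if (degenerate) 1 else stats::fisher.test(tab)$p.value
  structure(list(table = tab, odds_ratio = or, p = p,
                 degenerate = degenerate),
            class = "reo_fisher")
}

#' @export
print.reo_fisher <- function(x, ...) {
  cat("2x2 Fisher exact test\n")
  print(x$table)
  cat(sprintf("odds ratio (ad/bc) = %.4g, two-sided p = %.4g\n",
              x$odds_ratio, x$p))
  invisible(x)
}

#' IPCW time-dependent AUC (cumulative cases / dynamic controls)
#'
#' Area under the time-dependent ROC curve at a fixed horizon: cases are
#' samples with an observed event by the horizon, controls are samples still
#' under observation beyond it. Right-censoring is handled with inverse
#' probability-of-censoring weights from the Kaplan-Meier estimate of the
#' censoring distribution; without censoring the estimator reduces to the
#' plain Mann-Whitney AUC of the dichotomized outcome.
#'
#' @param score Numeric risk scores (higher = worse).
#' @param time Survival times in months.
#' @param event Event indicator (1 = observed).
#' @param horizon Evaluation time in months.
#' @return AUC in \[0, 1\].
#' @export
td_auc <- function(score, time, event, horizon) {
  stopifnot(length(score) == length(time), length(time) == length(event),
            is.finite(horizon), horizon > 0)
  is_case <- time <= horizon & event == 1
  is_ctrl <- time > horizon
  if (!any(is_case) || !any(is_ctrl))
    stop("no cases or no controls at horizon ", horizon, " months")

  # KM of the censoring distribution; G(t-) for cases, G(horizon) for controls
  cfit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  G <- stats::stepfun(cfit$time, c(1, cfit$surv), right = FALSE)
  g_case <- vapply(time[is_case], function(t) G(t - 1e-10), numeric(1))
  g_ctrl <- G(horizon)
  if (g_ctrl <= 0 || any(g_case <= 0))
    stop("censoring-distribution weight is zero at horizon ", horizon,
         " months; AUC not identifiable there")
  w_case <- 1 / g_case
  w_ctrl <- rep(1 / g_ctrl, sum(is_ctrl))

  sc <- score[is_case]; sn <- score[is_ctrl]
  conc <- outer(sc, sn, ">") + 0.5 * outer(sc, sn, "==")
  sum((w_case %o% w_ctrl) * conc) / (sum(w_case) * sum(w_ctrl))
}
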
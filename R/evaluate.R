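#' Evaluate a signature on a cohort
#'
#' Runs the majority-vote classifier, compares the two risk groups with
#' Kaplan-Meier curves and the log-rank test, estimates the hazard ratio of
#' low- versus high-risk membership (HR < 1 means the low-risk call is
#' protective), computes IPCW time-dependent AUCs of the vote-fraction score
#' at 3, 5 and 7 years, and fits a multivariate Cox model over the risk label
#' plus whichever of age, stage and grade the cohort records. A horizon with
#' no cases or no controls yields `NA` for that AUC and is excluded from the
#' mean.
#'
#' @param cohort A preprocessed `reo_cohort`.
#' @param sig An `reo_signature`.
#' @param horizons AUC horizons in months (default 36, 60, 84).
#' @return List of class `reo_evaluation`: `cohort`, `n_high`, `n_low`,
#'   `logrank_p`, `hr`, `hr_ci`, `hr_p`, `auc` (named vector), `mean_auc`,
#'   `multivariate` (a `reo_coxfit`), `calls`.
#' @export
evaluate_signature <- function(cohort, sig, horizons = c(36, 60, 84)) {
  stopifnot(inherits(cohort, "reo_cohort"), inherits(sig, "reo_signature"))
  calls <- classify(cohort, sig)
  cl <- cohort$clinical
  tt <- cl$os_time
  ev <- cl$os_event
  n_high <- sum(calls$label == "high")
  n_low <- sum(calls$label == "low")

  if (n_high == 0 || n_low == 0) {
    warning("cohort '", cohort$name, "': all samples fell in one risk group; ",
            "group comparisons unavailable")
    km_p <- NA_real_; hr <- c(NA_real_, NA_real_, NA_real_); hr_p <- NA_real_
  } else {
    km <- km_logrank(tt, ev, calls$label)
    km_p <- km$logrank_p
    f <- cox_fit(as.numeric(calls$label == "low"), tt, ev)
    hr <- c(f$hr[1], f$ci_low[1], f$ci_high[1])
    hr_p <- f$p[1]
  }

  auc <- vapply(horizons, function(h) {
    tryCatch(td_auc(calls$score, tt, ev, h), error = function(e) NA_real_)
  }, numeric(1))
  names(auc) <- paste0(horizons, "m")

  covars <- data.frame(risk_low = as.numeric(calls$label == "low"))
  for (v in c("age", "stage", "grade")) {
    if (!is.null(cl[[v]]) && sum(!is.na(cl[[v]])) >= 2) {
      x <- as.numeric(cl[[v]])
      if (length(unique(x[!is.na(x)])) >= 2) covars[[v]] <- x
    }
  }
  complete <- stats::complete.cases(covars)
  multi <- cox_fit(covars[complete, , drop = FALSE], tt[complete], ev[complete])

  structure(list(cohort = cohort$name, n_high = n_high, n_low = n_low,
                 logrank_p = km_p, hr = hr[1], hr_ci = hr[2:3], hr_p = hr_p,
                 auc = auc,
                 mean_auc = if (all(is.na(auc))) NA_real_
                            else mean(auc, na.rm = TRUE),
                 multivariate = multi, calls = calls),
            class = "reo_evaluation")
}

#' @export
print.reo_evaluation <- function(x, ...) {
  cat(sprintf("<reo_evaluation> cohort %s: %d high-risk / %d low-risk\n",
              x$cohort, x$n_high, x$n_low))
  cat(sprintf("  log-rank p = %.3g | HR (low vs high) = %.3f [%.3f, %.3f]\n",
              x$logrank_p, x$hr, x$hr_ci[1], x$hr_ci[2]))
  cat("  AUC:", paste(sprintf("%s %.3f", names(x$auc), x$auc), collapse = ", "),
      sprintf("| mean %.3f\n", x$mean_auc))
  invisible(x)
}

#' Risk-group versus chemotherapy-response contingency analysis
#'
#' Collapses RECIST categories to chemo-sensitive (CR, PR) versus
#' chemo-resistant (SD, PD), drops samples without a response record,
#' optionally restricts to platinum-treated samples, and tests the 2x2
#' risk-by-response table with the exact Fisher test. The reported odds
#' ratio is for low-risk sensitivity (low-risk odds of being sensitive over
#' high-risk odds); its exact reciprocal is the odds ratio for low-risk
#' resistance.
#'
#' @param calls A [classify()] result.
#' @param clinical Clinical data frame with `sample_id`, `drug_response` and
#'   (if `platinum_only`) `platinum_flag`.
#' @param platinum_only Restrict to samples with `platinum_flag == 1`.
#' @return List of class `reo_drug_response`: `table` (rows high/low, columns
#'   sensitive/resistant), `or_sensitive`, `or_resistant`, `p`, `n`,
#'   `degenerate`.
#' @export
drug_response_analysis <- function(calls, clinical, platinum_only = FALSE) {
  stopifnot(all(c("sample_id", "label") %in% names(calls)),
            all(c("sample_id", "drug_response") %in% names(clinical)))
  df <- merge(calls[, c("sample_id", "label")],
              clinical[, c("sample_id", "drug_response",
                           intersect("platinum_flag", names(clinical))),
                       drop = FALSE],
              by = "sample_id")
  if (platinum_only) {
    if (is.null(df$platinum_flag))
      stop("platinum_only = TRUE requires a platinum_flag column")
    df <- df[!is.na(df$platinum_flag) & df$platinum_flag == 1, , drop = FALSE]
  }
  df <- df[!is.na(df$drug_response) & df$drug_response %in%
             c("CR", "PR", "SD", "PD"), , drop = FALSE]
  if (nrow(df) == 0) stop("no samples with usable drug-response records")
  sensitive <- df$drug_response %in% c("CR", "PR")
  a <- sum(df$label == "high" & sensitive)
  b <- sum(df$label == "high" & !sensitive)
  c_ <- sum(df$label == "low" & sensitive)
  d <- sum(df$label == "low" & !sensitive)
  ft <- fisher_2x2(a, b, c_, d)
  or_sens <- (c_ * b) / (d * a)   # low-risk odds of sensitivity vs high-risk
  structure(list(table = matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                                dimnames = list(c("high", "low"),
                                                c("sensitive", "resistant"))),
                 or_sensitive = or_sens, or_resistant = 1 / or_sens,
                 p = ft$p, n = nrow(df), degenerate = ft$degenerate),
            class = "reo_drug_response")
}

#' @export
print.reo_drug_response <- function(x, ...) {
  cat("Risk group vs chemotherapy response (n =", x$n, ")\n")
  print(x$table)
  cat(sprintf("OR low-risk sensitive = %.3f (resistant %.3f), Fisher p = %.3g\n",
              x$or_sensitive, x$or_resistant, x$p))
  invisible(x)
}
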
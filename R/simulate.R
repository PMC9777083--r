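#' Configuration for the multi-platform survival simulator
#'
#' Defaults emulate a multi-cohort serous ovarian cancer study at desk scale:
#' five cohorts (three training, one test, one validation) of 150 samples,
#' a shared 300-gene universe of which 30 genes carry prognostic signal with
#' fixed hazard directions, proportional-hazards exponential survival with a
#' baseline median of 40 months, a 30% censoring target, and per-cohort
#' strictly increasing distortions plus per-sample positive gains that mimic
#' platform and scaling differences without touching within-sample orderings.
#'
#' @param n_cohorts Total cohorts; roles are assigned as
#'   `n_cohorts - 2` training, then one test, then one validation.
#' @param n_samples Samples per cohort (scalar or length `n_cohorts`).
#' @param n_genes Size of the shared gene universe.
#' @param n_prognostic Number of genes whose expression tracks latent risk
#'   (half up with risk, half down).
#' @param beta Log-hazard per unit latent risk.
#' @param signal Expression shift per unit latent risk for prognostic genes.
#' @param noise_sd Residual expression noise SD.
#' @param baseline_sd SD of gene-specific baseline levels (mean 6, an
#'   intensity-like scale).
#' @param baseline_hazard Event rate per month at zero risk
#'   (default `log(2)/40`: 40-month baseline median survival).
#' @param censor_target Desired fraction of censored samples, in `[0, 1)`.
#' @param distort Apply per-cohort monotone distortions and per-sample gains
#'   (`TRUE`); set `FALSE` for undistorted matrices in invariance tests.
#' @param covariates Generate age/stage/grade columns weakly linked to risk.
#' @param drug_response Generate RECIST responses with sensitivity log-odds
#'   decreasing in latent risk, plus a platinum flag.
#' @param exact_times Keep full-precision survival times; by default times
#'   are rounded to 2 decimals as real clinical tables report them.
#' @param seed Mandatory integer seed.
#' @return A list of class `reo_sim_config`.
#' @export
sim_config <- function(n_cohorts = 5, n_samples = 150, n_genes = 300,
                       n_prognostic = 30, beta = 1, signal = 1,
                       noise_sd = 1, baseline_sd = 2,
                       baseline_hazard = log(2) / 40,
                       censor_target = 0.30, distort = TRUE,
                       covariates = TRUE, drug_response = TRUE,
                       exact_times = FALSE, seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducible simulation")
  stopifnot(n_cohorts >= 1, n_genes >= 2, n_prognostic <= n_genes,
            censor_target >= 0, censor_target < 1, baseline_hazard > 0)
  n_samples <- rep_len(n_samples, n_cohorts)
  structure(as.list(environment()), class = "reo_sim_config")
}

#' Simulate multi-platform cohorts with planted prognostic structure
#'
#' Per sample, a latent risk \eqn{r \sim N(0,1)} drives both expression and
#' survival: prognostic gene g has mean `baseline_g + dir_g * signal * r`
#' (null genes have no risk term), and survival time is exponential with
#' hazard `baseline_hazard * exp(beta * r)`. Censoring is independent
#' exponential with its rate calibrated by root-finding so the expected
#' censored fraction matches `censor_target` given the realized hazards.
#' Each cohort's values then pass through a cohort-specific strictly
#' increasing cubic map and a per-sample positive gain, so cohorts differ in
#' scale and shape while every within-sample ordering is preserved exactly.
#'
#' @param config A [sim_config()].
#' @return List with `cohorts` (list of `reo_cohort`, roles assigned) and
#'   `truth` (planted gene table with directions, per-cohort latent risk and
#'   uncensored event times, and the censoring rate used).
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "reo_sim_config"))
  cf <- config
  set.seed(cf$seed)
  genes <- sprintf("g%04d", seq_len(cf$n_genes))
  prog <- sort(sample(genes, cf$n_prognostic))
  dir <- stats::setNames(rep_len(c(1, -1), cf$n_prognostic), prog)
  baseline <- stats::setNames(stats::rnorm(cf$n_genes, 6, cf$baseline_sd),
                              genes)
  roles <- c(rep("training", max(cf$n_cohorts - 2, 1)),
             if (cf$n_cohorts >= 2) "test", if (cf$n_cohorts >= 3) "validation")
  roles <- roles[seq_len(cf$n_cohorts)]

  cohorts <- vector("list", cf$n_cohorts)
  truth_risk <- vector("list", cf$n_cohorts)
  truth_time <- vector("list", cf$n_cohorts)
  cens_rates <- numeric(cf$n_cohorts)

  for (k in seq_len(cf$n_cohorts)) {
    n <- cf$n_samples[k]
    sid <- sprintf("c%d_s%03d", k, seq_len(n))
    r <- stats::rnorm(n)

    eff <- matrix(0, cf$n_genes, n, dimnames = list(genes, sid))
    eff[prog, ] <- outer(dir * cf$signal, r)
    expr <- baseline + eff +
      matrix(stats::rnorm(cf$n_genes * n, 0, cf$noise_sd), cf$n_genes, n)
    dimnames(expr) <- list(genes, sid)

    haz <- cf$baseline_hazard * exp(cf$beta * r)
    t_event <- stats::rexp(n, rate = haz)
    if (cf$censor_target > 0) {
      # expected censored fraction under exponential censoring at rate c
      target_fn <- function(cc) mean(cc / (cc + haz)) - cf$censor_target
      rate <- tryCatch(
        stats::uniroot(target_fn, lower = 1e-8, upper = 1e4, tol = 1e-10)$root,
        error = function(e)
          stop("censoring target ", cf$censor_target,
               " is infeasible for the realized hazards"))
      t_cens <- stats::rexp(n, rate = rate)
    } else {
      rate <- 0
      t_cens <- rep(Inf, n)
    }
    cens_rates[k] <- rate
    os_time <- pmin(t_event, t_cens)
    os_event <- as.integer(t_event <= t_cens)
    if (!cf$exact_times) os_time <- pmax(round(os_time, 2), 0.01)

    clinical <- data.frame(sample_id = sid, os_time = os_time,
                           os_event = os_event, stringsAsFactors = FALSE)
    if (cf$covariates) {
      clinical$age <- round(pmin(pmax(60 + 3 * r + stats::rnorm(n, 0, 10),
                                      30), 89))
      clinical$stage <- pmin(pmax(round(3 + 0.3 * r +
                                          stats::rnorm(n, 0, 0.7)), 1), 4)
      clinical$grade <- pmin(pmax(round(3 + 0.2 * r +
                                          stats::rnorm(n, 0, 0.8)), 1), 4)
    }
    if (cf$drug_response) {
      p_sens <- stats::plogis(1.5 - 0.8 * r)
      sens <- stats::rbinom(n, 1, p_sens) == 1
      resp <- ifelse(sens,
                     ifelse(stats::runif(n) < 0.6, "CR", "PR"),
                     ifelse(stats::runif(n) < 0.5, "SD", "PD"))
      clinical$drug_response <- resp
      clinical$platinum_flag <- stats::rbinom(n, 1, 0.9)
    }

    # distortion parameters are always drawn so the RNG stream (and hence the
    # underlying data) is identical whether or not the distortion is applied
    a <- stats::runif(1, 0.5, 2)
    d3 <- stats::runif(1, 0, 0.05)
    shift <- stats::rnorm(1, 0, 2)
    gain <- exp(stats::rnorm(n, 0, 0.2))
    if (cf$distort) {
      # strictly increasing cohort map a*x + d*x^3 + shift, then per-sample gain
      expr <- (a * expr + d3 * expr^3 + shift) *
        rep(gain, each = cf$n_genes)
    }

    cohorts[[k]] <- cohort(expr, clinical,
                           name = sprintf("sim%d", k),
                           role = roles[k],
                           platform = sprintf("platform%d", k))
    truth_risk[[k]] <- stats::setNames(r, sid)
    truth_time[[k]] <- stats::setNames(t_event, sid)
  }

  list(cohorts = cohorts,
       truth = list(prognostic_genes = prog, directions = dir,
                    latent_risk = truth_risk, event_times = truth_time,
                    censor_rates = cens_rates, config = cf))
}
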
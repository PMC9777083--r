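# Independent oracles used to cross-check the package's statistics. These are
# deliberately naive (double loops, dense grids, exhaustive enumeration) and
# share no code with the implementation.

# Harrell C-index by explicit double loop over all ordered sample pairs.
oracle_cindex <- function(score, time, event) {
  num <- 0; den <- 0
  n <- length(score)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      if (score[i] > score[j]) num <- num + 1
      else if (score[i] == score[j]) num <- num + 0.5
    }
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

# Step-up BH adjustment straight from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Breslow partial log-likelihood for a single covariate, evaluated on a grid.
breslow_loglik <- function(beta, x, time, event) {
  vapply(beta, function(b) {
    ll <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
    }
    ll
  }, numeric(1))
}

oracle_cox_coef <- function(x, time, event, lo = -5, hi = 5, by = 5e-4) {
  grid <- seq(lo, hi, by = by)
  grid[which.max(breslow_loglik(grid, x, time, event))]
}

# Exhaustive best-subset search over candidate vote indicators: returns the
# maximum C-index of a vote-sum score over all non-empty candidate subsets.
oracle_best_subset <- function(V, time, event) {
  k <- nrow(V)
  best <- -Inf
  for (mask in seq_len(2^k - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) != 0)
    s <- colSums(V[members, , drop = FALSE])
    ci <- oracle_cindex(s, time, event)
    if (ci > best) best <- ci
  }
  best
}

# Small random right-censored survival instance; integer-ish times force ties.
rand_surv <- function(n, tie_times = TRUE, cens_frac = 0.3) {
  time <- if (tie_times) sample(1:8, n, replace = TRUE)
          else round(rexp(n, 0.1), 3)
  event <- rbinom(n, 1, 1 - cens_frac)
  if (sum(event) < 2) event[sample(n, 2)] <- 1
  list(time = time, event = event)
}

# A tiny deterministic cohort for data-model tests.
toy_cohort <- function(n_genes = 6, n_samples = 8, seed = 1, name = "toy",
                       role = "training") {
  set.seed(seed)
  expr <- matrix(rnorm(n_genes * n_samples, 6, 2), n_genes, n_samples,
                 dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                 sprintf("s%02d", seq_len(n_samples))))
  clin <- data.frame(sample_id = colnames(expr),
                     os_time = round(rexp(n_samples, 0.02), 2) + 1,
                     os_event = rbinom(n_samples, 1, 0.7),
                     stringsAsFactors = FALSE)
  cohort(expr, clin, name = name, role = role)
}

# Build an reo_matrix + oriented-pair table directly from a vote matrix so
# greedy/classify tests can plant exact vote patterns. Pair p_k is realized by
# genes a_k (value = vote) and b_k (value = 0.5), so REO = vote exactly.
planted_vote_instance <- function(V, time, event) {
  k <- nrow(V); n <- ncol(V)
  genes <- c(sprintf("a%02d", seq_len(k)), sprintf("b%02d", seq_len(k)))
  expr <- matrix(0.5, 2 * k, n,
                 dimnames = list(genes, sprintf("s%02d", seq_len(n))))
  expr[seq_len(k), ] <- V      # a_k > b_k  iff  vote = 1
  pairs <- data.frame(gene_a = sprintf("a%02d", seq_len(k)),
                      gene_b = sprintf("b%02d", seq_len(k)),
                      risky_state = 1L, stringsAsFactors = FALSE)
  cand <- pairs
  cand$coef <- 1; cand$hr <- exp(1); cand$p <- 0.01; cand$adj_p <- 0.01
  cand$c_index <- vapply(seq_len(k), function(i)
    oracle_cindex(V[i, ], time, event), numeric(1))
  cand <- cand[order(-cand$c_index, cand$gene_a), , drop = FALSE]
  rownames(cand) <- NULL
  list(expr = expr, reo = build_reo_matrix(expr, pairs), candidates = cand)
}
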
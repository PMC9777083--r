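test_that("combination score is the fraction of risky votes", {
  time <- 1:4; event <- rep(1, 4)
  V <- rbind(c(1, 1, 0, 0),
             c(1, 0, 1, 0),
             c(1, 0, 0, 1),
             c(0, 1, 1, 0))
  inst <- planted_vote_instance(V, time, event)
  one <- combination_score(inst$reo, inst$candidates[inst$candidates$gene_a == "a01", ])
  expect_equal(unname(one), c(1, 1, 0, 0))
  all4 <- combination_score(inst$reo, inst$candidates)
  expect_equal(unname(all4), c(3, 2, 2, 1) / 4)

  # combination restricted to pairs absent from the matrix is an error
  ghost <- data.frame(gene_a = "zz1", gene_b = "zz2", risky_state = 1L)
  expect_error(combination_score(inst$reo, ghost), "detected")
})

test_that("greedy accepts a strictly improving second pair (hand-checked instance)", {
  time <- 1:8; event <- rep(1, 8)
  vA <- c(1, 1, 1, 1, 0, 0, 0, 0)
  vB <- c(1, 1, 0, 0, 1, 1, 0, 0)
  # by the O(n^2) oracle the vote-sum of A+B beats either pair alone
  expect_equal(oracle_cindex(vA, time, event), 22 / 28)
  expect_equal(oracle_cindex(vA + vB, time, event), 24 / 28)
  inst <- planted_vote_instance(rbind(vA, vB), time, event)
  combos <- greedy_build(inst$candidates, inst$reo, time, event, n_seeds = 1)
  expect_equal(nrow(combos[[1]]$pairs), 2)
  expect_equal(combos[[1]]$train_c_index, 24 / 28)
})

test_that("greedy objective is bounded by the seed below and brute-force subsets above", {
  set.seed(55)
  for (rep in 1:6) {
    n <- sample(10:14, 1)
    k <- sample(6:9, 1)
    time <- sample(1:10, n, replace = TRUE)
    event <- rbinom(n, 1, 0.8); if (sum(event) < 2) event[1:2] <- 1
    V <- matrix(rbinom(k * n, 1, 0.5), k, n)
    keep <- rowSums(V) > 0 & rowSums(V) < n
    V <- V[keep, , drop = FALSE]
    if (nrow(V) < 2) next
    # orient rows so each has concordance >= 0.5, as screen_pairs guarantees
    for (i in seq_len(nrow(V)))
      if (oracle_cindex(V[i, ], time, event) < 0.5) V[i, ] <- 1 - V[i, ]
    inst <- planted_vote_instance(V, time, event)
    combos <- greedy_build(inst$candidates, inst$reo, time, event,
                           n_seeds = min(3, nrow(V)))
    best_subset <- oracle_best_subset(V, time, event)
    for (cb in combos) {
      expect_gte(cb$train_c_index,
                 max(cb$pairs$c_index[1]) - 1e-12)   # never below its seed
      expect_lte(cb$train_c_index, best_subset + 1e-12)
    }
  }
})

test_that("test-set selection gates on significance before maximizing concordance", {
  # one combo tracks test survival, the other is noise
  set.seed(66)
  n <- 60
  time <- round(rexp(n, 0.05), 2) + 0.01
  event <- rbinom(n, 1, 0.85)
  v_signal <- as.integer(time < stats::median(time))
  flip <- sample(n, 8)
  v_signal[flip] <- 1L - v_signal[flip]   # imperfect marker, finite Cox MLE
  v_noise <- rbinom(n, 1, 0.5)
  inst <- planted_vote_instance(rbind(v_signal, v_noise), time, event)
  test_co <- cohort(inst$expr,
                    data.frame(sample_id = colnames(inst$expr),
                               os_time = time, os_event = event),
                    name = "testset", role = "test")
  mk_combo <- function(g, ci) list(pairs = inst$candidates[
    inst$candidates$gene_a == g, , drop = FALSE],
    train_c_index = ci, seed_rank = 1)
  sig <- select_final(list(mk_combo("a01", 0.9), mk_combo("a02", 0.95)),
                      test_co)
  expect_s3_class(sig, "reo_signature")
  expect_equal(sig$pairs$gene_a, "a01")   # noise combo fails the p < 0.05 gate
  expect_lt(sig$test_cox_p, 0.05)

  # no significant combo at all is a hard error
  expect_error(select_final(list(mk_combo("a02", 0.95)), test_co),
               "no combination is significant")
})

test_that("majority vote labels follow the strict-majority rule with ties called high", {
  n_pairs <- 20
  set.seed(91)
  V <- matrix(rbinom(n_pairs * 3, 1, 0.5), n_pairs, 3)
  V[, 1] <- rep(c(1, 0), c(11, 9))   # 11/20 risky -> high
  V[, 2] <- rep(c(1, 0), c(5, 15))   # 5/20  -> low
  V[, 3] <- rep(c(1, 0), c(10, 10))  # exact tie -> high, flagged
  inst <- planted_vote_instance(V, time = 1:3, event = rep(1, 3))
  sig <- structure(list(pairs = inst$candidates, n_pairs = n_pairs,
                        training_c_index = NA, test_c_index = NA,
                        test_cox_p = NA,
                        provenance = list(test_cohort = "none")),
                   class = "reo_signature")
  co <- cohort(inst$expr,
               data.frame(sample_id = colnames(inst$expr),
                          os_time = c(5, 8, 2), os_event = c(1, 0, 1)),
               name = "v")
  calls <- classify(co, sig)
  expect_equal(as.character(calls$label), c("high", "low", "high"))
  expect_equal(calls$votes_risky, c(11L, 5L, 10L))
  expect_equal(calls$votes_total, rep(20L, 3))
  expect_equal(calls$tie, c(FALSE, FALSE, TRUE))

  # undetected pairs are removed before voting: drop 10 pairs' genes
  co_half <- cohort(co$expr[-(1:10), , drop = FALSE], co$clinical, name = "v2")
  calls_half <- suppressMessages(classify(co_half, sig))
  expect_equal(calls_half$votes_total, rep(10L, 3))

  # no detected pair at all names the platform
  co_none <- cohort(co$expr[21:40, , drop = FALSE] + 0, co$clinical,
                    name = "v3", platform = "weird")
  expect_error(classify(co_none, sig), "weird")
})

test_that("a sample's risk call is independent of the other samples", {
  sim <- simulate_cohorts(sim_config(n_cohorts = 3, n_samples = 40,
                                     n_genes = 40, n_prognostic = 12,
                                     seed = 17))
  tr <- lapply(sim$cohorts[1:2], preprocess_cohort)
  sig <- suppressMessages(build_signature(tr, sim$cohorts[[3]],
                                          alpha = 0.2, alpha_adj = 0.2,
                                          n_seeds = 3))
  co <- sim$cohorts[[3]]
  full <- classify(co, sig)

  # single-sample cohort, shuffled cohort, duplicated-column cohort
  one <- cohort(co$expr[, 5, drop = FALSE], co$clinical[5, , drop = FALSE],
                name = "one")
  expect_equal(classify(one, sig)$votes_risky, full$votes_risky[5])
  expect_equal(as.character(classify(one, sig)$label),
               as.character(full$label[5]))

  perm <- rev(seq_len(ncol(co$expr)))
  shuf <- cohort(co$expr[, perm], co$clinical[perm, ], name = "shuf")
  calls_shuf <- classify(shuf, sig)
  idx <- match(full$sample_id, calls_shuf$sample_id)
  expect_equal(calls_shuf$votes_risky[idx], full$votes_risky)
  expect_equal(as.character(calls_shuf$label[idx]), as.character(full$label))
})

test_that("classification is invariant to strictly monotone per-sample transforms", {
  sim <- simulate_cohorts(sim_config(n_cohorts = 3, n_samples = 40,
                                     n_genes = 40, n_prognostic = 12,
                                     seed = 17))
  tr <- lapply(sim$cohorts[1:2], preprocess_cohort)
  sig <- suppressMessages(build_signature(tr, sim$cohorts[[3]],
                                          alpha = 0.2, alpha_adj = 0.2,
                                          n_seeds = 3))
  co <- sim$cohorts[[3]]
  set.seed(1)
  gains <- runif(ncol(co$expr), 0.2, 4)
  expr2 <- sinh(co$expr / 20) * rep(gains, each = nrow(co$expr)) + 2
  co2 <- cohort(expr2, co$clinical, name = co$name)
  expect_identical(classify(co2, sig), classify(co, sig))
})

test_that("signatures survive a JSON round trip", {
  set.seed(202)
  n <- 40
  time <- seq_len(n); event <- rep(1, n)
  vA <- as.integer(time <= n / 2)
  flipA <- sample(n, 6); vA[flipA] <- 1L - vA[flipA]
  vB <- as.integer(time %% 3 != 0)
  inst <- planted_vote_instance(rbind(vA, vB), time, event)
  combos <- greedy_build(inst$candidates, inst$reo, time, event, n_seeds = 1)
  co <- cohort(inst$expr,
               data.frame(sample_id = colnames(inst$expr),
                          os_time = time, os_event = event), name = "t")
  sig <- select_final(combos, co)
  path <- withr::local_tempfile(fileext = ".json")
  write_signature(sig, path)
  back <- read_signature(path)
  expect_equal(back$pairs, sig$pairs)
  expect_equal(back$test_c_index, sig$test_c_index)
  expect_equal(back$n_pairs, sig$n_pairs)
  expect_identical(classify(co, back), classify(co, sig))
})
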
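test_that("loridp_delta matches the exact rational toy value and its symmetries", {
  # y_i=5, n_i=10, y_j=1, n_j=10, alpha_w=6, alpha_0=20:
  # log(11/19) - log(7/23) = log(253/133)
  expect_equal(loridp_delta(5, 10, 1, 10, 6, 20), log(253 / 133),
               tolerance = 1e-14)
  # identical corpora -> 0
  expect_equal(loridp_delta(4, 12, 4, 12, 8, 24), 0)
  # swapping corpus roles negates the difference of logs
  expect_equal(loridp_delta(5, 10, 1, 10, 6, 20),
               -loridp_delta(1, 10, 5, 10, 6, 20))
  # degenerate one-lemma corpora: the odds denominator hits zero
  expect_error(loridp_delta(10, 10, 5, 5, 15, 15), "denominator")
})

test_that("loridp_variance is the sum of reciprocal smoothed counts", {
  # toy: 1/(5+6) + 1/(1+6) = 1/11 + 1/7 = 18/77
  expect_equal(loridp_variance(5, 1, 6), 18 / 77, tolerance = 1e-14)
  # symmetric in the two corpora
  expect_equal(loridp_variance(5, 1, 6), loridp_variance(1, 5, 6))
  # doubling all counts strictly decreases the variance
  expect_lt(loridp_variance(10, 2, 12), loridp_variance(5, 1, 6))
  expect_error(loridp_variance(0, 5, 0), "positive")
})

test_that("compute_keyness composes delta, variance and z per row", {
  tab <- merge_tables(freq_tab(a = 5, b = 5), freq_tab(a = 1, b = 9))
  res <- compute_keyness(tab)
  row_a <- res[res$lemma == "a", ]
  expect_equal(row_a$delta, log(253 / 133), tolerance = 1e-14)
  expect_equal(row_a$variance, 18 / 77, tolerance = 1e-14)
  expect_equal(row_a$z, log(253 / 133) / sqrt(18 / 77), tolerance = 1e-14)
  # identical corpora -> all z exactly 0
  same <- merge_tables(freq_tab(a = 3, b = 7), freq_tab(a = 3, b = 7))
  expect_true(all(compute_keyness(same)$z == 0))
})

test_that("keyness scores agree with the exact-rational oracle on random tables", {
  set.seed(42)
  for (i in 1:200) {
    pair <- random_count_pair()
    got <- compute_keyness(merge_tables(frequency_table(pair$target),
                                        frequency_table(pair$reference)))
    want <- oracle_keyness_table(pair$target[pair$target > 0],
                                 pair$reference[pair$reference > 0])
    got <- got[order(got$lemma), ]
    expect_equal(got$lemma, want$lemma)
    expect_equal(got$delta, want$delta, tolerance = 1e-12)
    expect_equal(got$variance, want$variance, tolerance = 1e-12)
    expect_equal(got$z, want$z, tolerance = 1e-12)
  }
})

test_that("swapping corpus roles negates every z and swaps the key lists", {
  set.seed(7)
  for (i in 1:20) {
    pair <- random_count_pair(max_lemmas = 8L, max_count = 40L)
    a <- frequency_table(pair$target); b <- frequency_table(pair$reference)
    fwd <- compute_keyness(merge_tables(a, b))
    rev <- compute_keyness(merge_tables(b, a))
    m <- match(fwd$lemma, rev$lemma)
    expect_equal(fwd$z, -rev$z[m], tolerance = 1e-12)
    sel_f <- select_keys(fwd, 1.5)
    sel_r <- select_keys(rev, 1.5)
    expect_equal(sel_f$target_keys$lemma, sel_r$reference_keys$lemma)
    expect_equal(sel_f$reference_keys$lemma, sel_r$target_keys$lemma)
  }
})

test_that("monotonicity: increasing the target count weakly increases delta", {
  n_i <- 100; n_j <- 100; y_j <- 5
  deltas <- vapply(1:40, function(y_i) {
    loridp_delta(y_i, n_i, y_j, n_j, alpha_w = y_i + y_j, alpha_0 = n_i + n_j)
  }, numeric(1))
  expect_true(all(diff(deltas) >= 0))
})

test_that("bonferroni_threshold reproduces the published critical value and quantile identities", {
  # family-wise 0.01 over the 59,190-lemma combined list -> |z| = 5.10
  expect_equal(round(bonferroni_threshold(0.01, 59190, "one-sided"), 2), 5.10)
  expect_equal(bonferroni_threshold(0.5, 1, "one-sided"), 0)
  expect_equal(bonferroni_threshold(0.05, 1, "one-sided"), 1.6449,
               tolerance = 1e-4)
  # two-sided splits alpha across the tails
  expect_equal(bonferroni_threshold(0.05, 10, "two-sided"),
               qnorm(1 - 0.05 / 20), tolerance = 1e-12)
  expect_error(bonferroni_threshold(0, 10), "alpha")
  expect_error(bonferroni_threshold(0.05, 0), "m must")
})

test_that("select_keys splits, ranks and flags by the threshold", {
  res <- tibble::tibble(
    lemma = c("up", "down", "mid"),
    y_target = 1, y_reference = 1,
    delta = c(1, -1, 0.1), variance = 1,
    z = c(6.0, -5.5, 1.0), significant = NA, rank = NA_integer_)
  sel <- select_keys(res, 5.10)
  expect_equal(sel$target_keys$lemma, "up")
  expect_equal(sel$reference_keys$lemma, "down")
  expect_equal(sel$target_keys$rank, 1L)
  expect_equal(sel$results$significant, c(TRUE, TRUE, FALSE))
  # all |z| below threshold -> two empty lists
  sel0 <- select_keys(res, 10)
  expect_equal(nrow(sel0$target_keys), 0L)
  expect_equal(nrow(sel0$reference_keys), 0L)
  # equal z ties break alphabetically
  tie <- res
  tie$z <- c(6, 6, 6)
  expect_equal(select_keys(tie, 5)$target_keys$lemma,
               sort(c("up", "down", "mid")))
})

test_that("top_k_table truncates, ranks and glosses", {
  keys <- tibble::tibble(lemma = paste0("w", 1:60),
                         z = seq(60, 1) / 2, rank = 1:60)
  out <- top_k_table(keys, 50)
  expect_equal(nrow(out), 50L)
  expect_equal(out$abs_z, sort(out$abs_z, decreasing = TRUE))
  expect_equal(out$rank, 1:50)
  # fewer keys than k: no padding
  expect_equal(nrow(top_k_table(keys[1:3, ], 50)), 3L)
  expect_equal(nrow(top_k_table(keys[0, ], 50)), 0L)
  # glosses fill where mapped, blank elsewhere
  g <- top_k_table(keys[1:2, ], 2, gloss_map = c(w1 = "war"))
  expect_equal(g$gloss, c("war", ""))
})

test_that("implied_loridp is the fixed point of the estimator at expected counts", {
  p_ref <- generate_lexicon(50, 1, 0)
  p_tgt <- p_ref; p_tgt[1] <- p_tgt[1] * 2; p_tgt <- p_tgt / sum(p_tgt)
  v <- implied_loridp(p_tgt, p_ref, 1e4, 1e4)
  # plugging expected counts into the package formula gives the same value
  y_i <- 1e4 * p_tgt; y_j <- 1e4 * p_ref
  direct <- loridp_delta(y_i, 1e4, y_j, 1e4, y_i + y_j, 2e4)
  expect_equal(v, direct, tolerance = 1e-14)
  # null probabilities imply zero
  expect_true(all(abs(implied_loridp(p_ref, p_ref, 1e4, 1e4)) < 1e-12))
})
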
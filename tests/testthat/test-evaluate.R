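test_that("first-order entropy matches the closed form", {
  expect_equal(first_order_entropy(c(0.5, 0.5)), 1)
  expect_equal(first_order_entropy(rep(0.25, 4)), 2)
  expect_equal(first_order_entropy(c(0.25, 0.75)),
               -(0.25 * log2(0.25) + 0.75 * log2(0.75)))
  # counts and probabilities agree; zero categories contribute nothing
  expect_equal(first_order_entropy(c(10, 30, 0)), first_order_entropy(c(0.25, 0.75)))
  expect_equal(first_order_entropy(c(1, 0, 0)), 0)
  expect_error(first_order_entropy(c(-1, 2)), "negative")
})

test_that("compression ratio is the exact size quotient", {
  expect_equal(compression_ratio(4200, 420), 10)
  expect_equal(compression_ratio(100, 100), 1)
  expect_error(compression_ratio(0, 10), "positive")
  # dialect arithmetic: 42 bytes/row CSV vs 12 bytes/row binary -> 3.5
  ch <- replicate(6, rand_walk_int16(400), simplify = FALSE)
  expect_equal(compression_ratio(length(write_fixed_csv(ch)),
                                 length(write_binary_int16(ch))), 3.5)
})

test_that("the worked bandwidth example reproduces 2.16 Mbps", {
  expect_equal(raw_stream_bandwidth(500, 15, 9, 32), 2.16)
  expect_equal(raw_stream_bandwidth(60, 6, 6, 16), 60 * 6 * 6 * 16 / 1e6)
})

test_that("the Friedman statistic follows the rank-sum formula", {
  expect_equal(friedman_rank_test(matrix(1, 4, 3))$statistic, 0)
  expect_equal(friedman_rank_test(matrix(1, 4, 3))$p_value, 1)
  # one method always best, one always worst: rank sums (3, 6, 9) -> chi2 = 6
  m <- rbind(c(3, 2, 1), c(30, 20, 10), c(0.3, 0.2, 0.1))
  fr <- friedman_rank_test(m)
  expect_equal(fr$statistic, 6)
  expect_equal(unname(fr$mean_ranks), c(1, 2, 3))
  # cross-check against the reference implementation on tie-free matrices
  set.seed(51)
  for (i in 1:10) {
    m <- matrix(stats::runif(6 * 4), 6, 4)
    fr <- friedman_rank_test(m)
    ref <- stats::friedman.test(m)
    expect_equal(fr$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(fr$p_value, unname(ref$p.value), tolerance = 1e-9)
  }
})

test_that("Nemenyi critical differences match the published table", {
  # q_{0.05, k} for k = 2..10 as tabulated for the Nemenyi test
  q_table <- c(1.960, 2.343, 2.569, 2.728, 2.850, 2.949, 3.031, 3.102, 3.164)
  for (k in 2:10) {
    nem <- nemenyi_posthoc(seq_len(k), N = 20)
    expect_equal(nem$q, q_table[k - 1], tolerance = 2e-3)
    expect_equal(nem$cd, q_table[k - 1] * sqrt(k * (k + 1) / 120),
                 tolerance = 2e-3)
  }
  # CD shrinks to zero as the corpus grows
  expect_lt(nemenyi_posthoc(1:5, N = 1e8)$cd, 1e-3)
  # identical mean ranks flag nothing
  expect_false(any(nemenyi_posthoc(rep(2, 4), N = 10)$significant))
})

test_that("ANOVA plus Tukey flags exactly the separated classes", {
  # identical class means -> F = 0
  res <- anova_tukey(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res$F, 0)
  set.seed(52)
  cr <- c(stats::rnorm(50, 10), stats::rnorm(50, 18))
  cls <- rep(c("active", "stationary"), each = 50)
  res <- anova_tukey(cr, cls)
  expect_lt(res$p_value, 0.05)
  expect_identical(res$significant_pairs, "stationary-active")
  # three classes, one shifted: only the shifted pairs flagged
  cr <- c(stats::rnorm(40, 10), stats::rnorm(40, 10), stats::rnorm(40, 18))
  cls <- rep(c("a", "b", "c"), each = 40)
  res <- anova_tukey(cr, cls)
  expect_setequal(res$significant_pairs, c("c-a", "c-b"))
  expect_error(anova_tukey(c(1, 2), c("a", "b")), "observations")
})

test_that("the benchmark harness ranks methods and separates regimes", {
  corpus <- synth_corpus(12, seed = 61, duration_s = 4)
  bench <- run_benchmark(corpus)
  ranks <- bench$friedman$mean_ranks
  expect_lte(ranks[["delta"]], min(ranks[c("linear", "poly2", "poly3",
                                           "poly4", "poly5")]))
  expect_gt(bench$by_activity[["sitting"]], bench$by_activity[["walking"]])
  # per-row ranks are a permutation with average ties: sums k(k+1)/2
  crmat <- matrix(bench$cases$cr, ncol = 7, byrow = TRUE)
  rowranks <- t(apply(crmat, 1, function(r) rank(-r)))
  expect_true(all(abs(rowSums(rowranks) - 28) < 1e-9))
  # CR accounting: reported bytes match recomputed file sizes
  one <- bench$cases[1, ]
  chans <- corpus[[one$case]]$channels
  expect_identical(one$csv_bytes, length(write_fixed_csv(chans)))
  expect_identical(one$compressed_bytes,
                   length(kc_compress(chans, one$method)))
  expect_warning(run_benchmark(corpus[1]), "single")
})
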
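test_that("Zipf slope hits the analytic anchors exactly", {
  # counts proportional to 1/rank -> slope exactly -1
  z <- zipf_slope(c(a = 12, b = 6, c = 4, d = 3))
  expect_equal(z$slope, -1, tolerance = 1e-12)
  expect_equal(z$r_squared, 1, tolerance = 1e-12)

  # uniform counts -> slope 0
  expect_equal(zipf_slope(c(a = 5, b = 5, c = 5, d = 5))$slope, 0,
               tolerance = 1e-12)

  # zero-count types are excluded; rank ties break alphabetically
  rf <- rank_frequency(c(b = 4, c = 7, a = 4, z = 0))
  expect_identical(names(rf$counts), c("c", "a", "b"))
  expect_identical(zipf_slope(rf)$n_types_used, 3L)

  expect_error(zipf_slope(c(a = 5)), class = "usvrep_insufficient_diversity")
})

test_that("proportion test compares observed counts to the uniform model", {
  expect_equal(proportion_test(c(a = 10, b = 10))$statistic, 0)
  pt <- proportion_test(c(a = 20, b = 0))
  expect_equal(pt$statistic, 20)   # (20-10)^2/10 * 2
  expect_equal(pt$df, 1)
  expect_error(proportion_test(c(a = 5)), class = "usvrep_parameter")
  expect_error(proportion_test(c(a = 0, b = 0)), class = "usvrep_degenerate")
})

test_that("pair tables follow the sliding-window and bout-length rules", {
  pt <- pair_table(list(c("A", "A", "B", "B", "A")))
  expect_identical(pt$total, 4L)
  expect_identical(pt$counts["A", "A"], 1L)
  expect_identical(pt$counts["A", "B"], 1L)
  expect_identical(pt$counts["B", "B"], 1L)
  expect_identical(pt$counts["B", "A"], 1L)

  # bouts of exactly 3 syllables contribute nothing
  expect_error(pair_table(list(c("A", "B", "A"))), class = "usvrep_empty_table")

  # disjoint bouts are additive
  b1 <- list(c("A", "A", "B", "B", "A"))
  b2 <- list(c("B", "A", "A", "B"))
  expect_identical(pair_table(c(b1, b2))$counts,
                   pair_table(b1)$counts + pair_table(b2)$counts)

  # pooled totals conserve sum over qualifying bouts of (len - 1)
  set.seed(5)
  seqs <- replicate(20, sample(c("A", "B", "C"), sample(4:9, 1), replace = TRUE),
                    simplify = FALSE)
  expect_identical(pair_table(seqs)$total, sum(lengths(seqs) - 1L))
})

test_that("pair independence test behaves at its analytic anchors", {
  # perfectly independent table (outer product) -> statistic 0
  pt <- pair_table(list(c("A", "A", "B", "B", "A")))
  pt$counts <- outer(c(A = 30L, B = 10L), c(A = 15L, B = 5L)) / 5L
  pt$total <- sum(pt$counts)
  expect_equal(pair_independence_test(pt)$statistic, 0)

  # deterministic alternation -> maximal association on a 2x2 table
  alt <- pair_table(list(rep(c("A", "B"), 30)))
  it <- pair_independence_test(alt)
  expect_equal(it$statistic, it$n, tolerance = 1e-9)
  expect_identical(it$df, 1L)

  # under the null the statistic has mean ~ df (simulation)
  set.seed(11)
  stats <- replicate(300, {
    seqs <- list(sample(c("A", "B", "C"), 120, replace = TRUE))
    pair_independence_test(pair_table(seqs))$statistic
  })
  expect_equal(mean(stats), 4, tolerance = 0.15)

  # statistic is invariant under relabeling of types
  set.seed(12)
  s <- sample(c("A", "B", "C"), 80, replace = TRUE)
  relab <- c(A = "Q", B = "R", C = "P")[s]
  expect_equal(pair_independence_test(pair_table(list(s)))$statistic,
               pair_independence_test(pair_table(list(unname(relab))))$statistic)

  # independence test agrees with the stats::chisq.test cross-check
  set.seed(13)
  s2 <- sample(c("A", "B", "C"), 200, replace = TRUE,
               prob = c(0.5, 0.3, 0.2))
  m <- pair_table(list(s2))$counts
  ours <- pair_independence_test(pair_table(list(s2)))
  ref <- suppressWarnings(chisq.test(m, correct = FALSE))
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$df, unname(ref$parameter))
})

test_that("switching probability counts repetitions over all pairings", {
  pt <- pair_table(list(c("A", "A", "B", "B", "A")))
  expect_equal(switching_probability(pt), 0.5)
  expect_equal(switching_probability(pair_table(list(rep("A", 6)))), 0)
  expect_gte(switching_probability(pt), 0)
  expect_lte(switching_probability(pt), 1)
})

test_that("initial-syllable probabilities form an empirical distribution", {
  bouts <- c(replicate(10, c("flat", "chevron", "flat"), simplify = FALSE))
  p <- initial_syllable_probs(bouts)
  expect_equal(unname(p["flat"]), 1)
  mixed <- list(c("flat", "flat", "flat"), c("chevron", "flat", "flat"))
  p2 <- initial_syllable_probs(mixed)
  expect_equal(unname(p2[c("chevron", "flat")]), c(0.5, 0.5), ignore_attr = TRUE)
  expect_equal(sum(p2), 1)
})

test_that("audibility census reproduces the worked percentages", {
  mk <- function(n, n_above, age) {
    data.frame(age_group = age,
               dominant_khz = c(rep(110, n_above), rep(70, n - n_above)),
               min_khz = 40)
  }
  cens <- audibility_census(rbind(mk(3145, 946, "p5"),
                                  mk(4560, 629, "p11"),
                                  mk(6963, 43, "adult")))
  got <- setNames(round(cens$frac_dominant_above * 100, 1), cens$age_group)
  expect_equal(unname(got["p5"]), 30.1)
  expect_equal(unname(got["p11"]), 13.8)
  expect_equal(unname(got["adult"]), 0.6)
  expect_equal(cens$frac_all_energy_above, rep(0, 3))
})

test_that("purity census fractions sum to one per age", {
  d <- data.frame(age_group = rep(c("p5", "adult"), each = 10),
                  purity = c(rep("tonal", 9), "nonlinear",
                             rep("tonal", 8), "harmonic", "nonlinear"))
  pc <- purity_census(d)
  expect_equal(pc$frac_tonal + pc$frac_harmonic + pc$frac_nonlinear, c(1, 1))
  expect_equal(pc$frac_nonlinear[pc$age_group == "p5"], 0.1)
})

test_that("descriptive statistics report excess kurtosis honestly", {
  # Bernoulli(1/2) two-point sample: excess kurtosis -2 in closed form
  expect_equal(excess_kurtosis(c(0, 0, 1, 1)), -2)
  # constant sample -> undefined, reported absent
  expect_true(is.na(excess_kurtosis(rep(3, 10))))
  # fewer than 4 observations -> absent
  expect_true(is.na(excess_kurtosis(c(1, 2, 3))))
  # large normal sample -> ~0
  set.seed(21)
  expect_equal(excess_kurtosis(rnorm(50000)), 0, tolerance = 0.1)

  d <- data.frame(age_group = "p5", syll_type = "flat",
                  duration_ms = c(10, 12, 14, 16), dominant_khz = c(70, 72, 74, 76))
  ds <- descriptive_stats(d)
  expect_identical(nrow(ds), 2L)
  dur <- ds[ds$variable == "duration_ms", ]
  expect_equal(dur$mean, 13)
  expect_equal(dur$median, 13)
  expect_lt(dur$ci95_lo, dur$mean)
})
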
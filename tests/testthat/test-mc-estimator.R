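test_that("one subsample experiment reproduces enumerated counts", {
  expect_identical(subsample_counts(toy_series, c(1, 2, 4), 1, 0.5),
                   c(a = 3, b = 1))
  # sampling every template recovers the exact totals
  expect_identical(subsample_counts(toy_series, 1:5, 1, 0.5),
                   c(a = 6, b = 2))
  expect_error(subsample_counts(toy_series, c(1, 6), 1, 0.5), "1..5")
})

test_that("fused subset counting equals two single-length counting passes", {
  set.seed(13)
  for (i in 1:25) {
    n <- sample(15:60, 1)
    m <- sample(1:3, 1)
    r <- runif(1, 0.05, 0.6)
    x <- rnorm(n)
    N <- n - m - 1
    idx <- draw_subset(N, sample(2:N, 1))
    cc <- subsample_counts(x, idx, m, r)
    expect_identical(cc[["a"]], direct_range_count(x, idx, m, r))
    expect_identical(cc[["b"]], direct_range_count(x, idx, m + 1, r))
  }
})

test_that("Monte Carlo estimate with n0 = N equals the exact entropy", {
  f <- sampen(toy_series, m = 1, r = 0.5, normalize = FALSE,
              method = "mc", n0 = 5, n1 = 4, seed = 1)
  expect_equal(f$value, log(3), tolerance = 1e-14)
  expect_false(f$degenerate)

  set.seed(3)
  x <- rnorm(100)
  ex <- sampen(x, m = 2, r = 0.3, normalize = FALSE)
  mc <- sampen(x, m = 2, r = 0.3, normalize = FALSE, method = "mc",
               n0 = 97, n1 = 3, seed = 8)
  expect_equal(mc$value, ex$value, tolerance = 1e-14)
  expect_equal(mc$a_bar, ex$A)
})

test_that("Monte Carlo estimator is deterministic given a seed", {
  x <- mix_process(600, p = 0.4, seed = 5)
  f1 <- sampen(x, m = 2, r = 0.2, method = "mc", n0 = 100, n1 = 10, seed = 4)
  f2 <- sampen(x, m = 2, r = 0.2, method = "mc", n0 = 100, n1 = 10, seed = 4)
  f3 <- sampen(x, m = 2, r = 0.2, method = "mc", n0 = 100, n1 = 10, seed = 5)
  expect_identical(f1$value, f2$value)
  expect_identical(f1$experiments, f2$experiments)
  expect_false(identical(f1$experiments, f3$experiments))
})

test_that("constant series gives zero entropy under the MC estimator", {
  f <- sampen(rep(2, 50), m = 2, r = 0.1, normalize = FALSE,
              method = "mc", n0 = 10, n1 = 5, seed = 1)
  expect_identical(f$value, 0)
})

test_that("zero-match series triggers the degenerate MC fallback", {
  x <- seq(0, 990, by = 10)
  f <- sampen(x, m = 1, r = 0.5, normalize = FALSE,
              method = "mc", n0 = 20, n1 = 5, seed = 2)
  expect_true(f$degenerate)
  expect_equal(f$value, -log(2 / (20 * 19)))
})

test_that("per-experiment counts satisfy their structural bounds", {
  x <- mix_process(2000, p = 0.5, seed = 10)
  f <- sampen(x, m = 2, r = 0.2, method = "mc", n0 = 150, n1 = 20, seed = 6)
  a <- f$experiments[, "a"]; b <- f$experiments[, "b"]
  expect_true(all(b >= 0 & b <= a))
  expect_true(all(a <= 150 * 149 / 2))
  expect_equal(mean(a), f$a_bar)
  expect_equal(mean(b), f$b_bar)
})

test_that("subsample pair rates are unbiased (exhaustive enumeration)", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(8:11, 1)
    x <- rnorm(n)
    m <- 1
    r <- sample(c(0.2, 0.5), 1)
    N <- n - m - 1
    oc <- oracle_counts(x, m, r)
    for (n0 in 2:3) {
      om <- oracle_subsample_moments(x, m, r, n0)
      expect_equal(om$a_mean, rate_expectation(oc$A, N, n0),
                   tolerance = 1e-12)
      expect_equal(om$b_mean, rate_expectation(oc$B, N, n0),
                   tolerance = 1e-12)
    }
  }
})

test_that("parameter strategies return the documented choices", {
  expect_identical(strategy_s1(), list(name = "S1", n0 = 2000L, n1 = 150L))
  expect_identical(strategy_s1(), strategy_s1())

  s <- strategy_s2(2^20)
  expect_identical(s$n0, 1024L)
  expect_identical(s$n1, 25L)

  s <- strategy_s2(2^10)
  expect_identical(s$n0, 1024L)
  expect_identical(s$n1, 1L)

  # the lower bound on n0 engages for every N below 1024^2
  for (N in c(10, 1000, 2^16, 1024^2 - 1)) {
    expect_gte(strategy_s2(N)$n0, 1024L)
  }
  expect_identical(strategy_s2(1024^2 + 2048)$n0, 1024L)
  expect_identical(strategy_s2(2^22)$n0, 2048L)
})

test_that("oversized n0 fails with a pointer to the adaptive strategy", {
  expect_error(
    sampen(toy_series, m = 1, r = 0.5, normalize = FALSE, method = "mc",
           n0 = 10, n1 = 2),
    "strategy_s2"
  )
})

test_that("comparison counting is exact and independent of series length", {
  f <- sampen(toy_series, m = 1, r = 0.5, normalize = FALSE, method = "mc",
              n0 = 3, n1 = 2, seed = 1)
  expect_identical(comparison_count(f), 12)

  x1 <- mix_process(200, 0.5, seed = 1)
  x2 <- mix_process(500, 0.5, seed = 2)
  f1 <- sampen(x1, m = 2, r = 0.2, method = "mc", n0 = 50, n1 = 3, seed = 3)
  f2 <- sampen(x2, m = 2, r = 0.2, method = "mc", n0 = 50, n1 = 3, seed = 3)
  expect_identical(comparison_count(f1), 3 * 50 * 49)
  expect_identical(comparison_count(f1), comparison_count(f2))

  expect_error(sampen(x1, m = 2, r = 0.2, method = "mc", n0 = 50, n1 = 0),
               "n1")
  expect_error(comparison_count(sampen(x1, m = 2, r = 0.2)), "mcsampen")
})
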
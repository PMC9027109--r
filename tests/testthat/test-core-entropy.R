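test_that("Chebyshev distance matches its definition and rejects bad input", {
  expect_identical(chebyshev_dist(c(0, 0), c(0, 0)), 0)
  expect_identical(chebyshev_dist(c(1, 2), c(2, 0)), 2)
  expect_equal(chebyshev_dist(c(0.1, 0.4, 0.2), c(0.1, 0.1, 0.2)), 0.3)
  expect_identical(chebyshev_dist(c(2, 1), c(1, 2)),
                   chebyshev_dist(c(1, 2), c(2, 1)))
  expect_error(chebyshev_dist(1:2, 1:3), "equal length")
})

test_that("unit-SD rescaling divides by sd and rejects constant series", {
  set.seed(11)
  x <- rnorm(200, mean = 5, sd = 3)
  y <- normalize_sd(x)
  expect_equal(sd(y), 1, tolerance = 1e-12)
  expect_equal(y, x / sd(x))              # no centering
  alt <- rep(c(-1, 1), 10)
  expect_equal(normalize_sd(alt), alt / sd(alt))
  expect_error(normalize_sd(rep(2, 10)), "constant")
})

test_that("direct range counting reproduces hand-enumerated pair counts", {
  expect_identical(direct_range_count(toy_series, 1:5, k = 1, r = 0.5), 6)
  expect_identical(direct_range_count(toy_series, 1:5, k = 2, r = 0.5), 2)
  expect_identical(direct_range_count(toy_series, 3, k = 1, r = 0.5), 0)
  expect_error(direct_range_count(toy_series, c(1, 9), k = 2, r = 0.5),
               "indices")
  expect_error(direct_range_count(toy_series, c(1, 1, 2), k = 1, r = 0.5),
               "distinct")
})

test_that("match counts on the toy series equal the enumerated values", {
  mc <- match_counts(toy_series, m = 1, r = 0.5)
  expect_identical(mc$A, 6)
  expect_identical(mc$B, 2)
  expect_identical(mc$A_i, c(3L, 3L, 0L, 3L, 3L))
  expect_identical(mc$B_i, c(1L, 1L, 0L, 1L, 1L))
  expect_identical(mc$N, 5L)
})

test_that("degenerate count patterns behave as defined", {
  # constant series: all templates identical, every pair matches
  mc <- match_counts(rep(1, 10), m = 2, r = 0.1)
  expect_identical(mc$N, 7L)
  expect_identical(mc$A, 7 * 6 / 2)
  expect_identical(mc$B, 7 * 6 / 2)
  expect_equal(sampen(rep(1, 10), m = 2, r = 0.1, normalize = FALSE)$value, 0)

  # strictly increasing with steps > 2r: no matches at all
  x <- seq(0, 90, by = 10)
  mc2 <- match_counts(x, m = 1, r = 0.5)
  expect_identical(mc2$A, 0)
  f <- sampen(x, m = 1, r = 0.5, normalize = FALSE)
  expect_true(f$degenerate)
  expect_equal(f$value, -log(2 / (8 * 7)))

  expect_error(match_counts(c(1, 2, 3), m = 2, r = 0.1), "too short")
})

test_that("exact sample entropy of the toy series is log 3", {
  f <- sampen(toy_series, m = 1, r = 0.5, normalize = FALSE)
  expect_equal(f$value, log(3), tolerance = 1e-14)
  expect_false(f$degenerate)
  expect_identical(f$method, "exact")
  expect_s3_class(f, "sampen")
  expect_equal(as.double(f), f$value)
})

test_that("counting agrees exactly with the all-pairs oracle on random signals", {
  set.seed(42)
  for (i in 1:30) {
    n <- sample(10:60, 1)
    m <- sample(1:3, 1)
    r <- sample(c(0.1, 0.2, 0.5), 1)
    x <- rnorm(n)
    mc <- match_counts(x, m, r)
    oc <- oracle_counts(x, m, r)
    expect_identical(mc$A, oc$A)
    expect_identical(mc$B, oc$B)
    expect_identical(mc$A_i, oc$A_i)
    expect_identical(mc$B_i, oc$B_i)
    # structural invariants
    expect_true(all(mc$A_i >= mc$B_i))
    expect_true(mc$B <= mc$A)
    expect_true(mc$A <= mc$N * (mc$N - 1) / 2)
    expect_identical(sum(mc$A_i) / 2, mc$A)
  }
})

test_that("match totals are nondecreasing in the tolerance r", {
  set.seed(7)
  x <- rnorm(80)
  rs <- c(0.05, 0.1, 0.2, 0.4, 0.8)
  for (m in 1:2) {
    counts <- lapply(rs, function(r) match_counts(x, m, r))
    A <- vapply(counts, `[[`, numeric(1), "A")
    B <- vapply(counts, `[[`, numeric(1), "B")
    expect_true(all(diff(A) >= 0))
    expect_true(all(diff(B) >= 0))
  }
})

test_that("sample entropy is invariant under joint rescaling of series and r", {
  set.seed(9)
  x <- rnorm(60)
  for (cc in c(0.5, 3, 10)) {
    f1 <- sampen(x, m = 2, r = 0.2, normalize = FALSE)
    f2 <- sampen(cc * x, m = 2, r = cc * 0.2, normalize = FALSE)
    expect_equal(f1$value, f2$value, tolerance = 1e-12)
    expect_identical(f1$A, f2$A)
  }
})
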
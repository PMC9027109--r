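#' Subsample pair counts for one Monte Carlo experiment
#'
#' Given a set of sampled template start indices, counts the matched
#' unordered pairs among the length-`m` templates (`a`) and among the
#' length-`m + 1` templates (`b`) at those indices.  This is one
#' experiment of the Monte Carlo estimator; with `idx` equal to the full
#' index set it reproduces the exact counts.
#'
#' @param x Numeric series.
#' @param idx Distinct 1-based template start indices drawn from
#'   `1..(n - m - 1)`.
#' @param m Template length.
#' @param r Tolerance.
#' @return Named numeric vector `c(a = , b = )`.
#' @examples
#' u <- c(0, 0, 1, 0, 0, 1, 0)
#' subsample_counts(u, c(1, 2, 4), m = 1, r = 0.5)  # a = 3, b = 1
#' @export
subsample_counts <- function(x, idx, m, r) {
  check_params(m, r)
  check_series(x, m)
  N <- n_templates(length(x), m)
  idx <- as.integer(idx)
  if (anyNA(idx) || any(idx < 1L) || any(idx > N)) {
    stop("sampled indices must lie in 1..", N)
  }
  if (anyDuplicated(idx)) stop("sampled indices must be distinct")
  cc <- cpp_pair_counts_subset(as.double(x), idx - 1L, as.integer(m),
                               as.double(r))
  c(a = cc[[1]], b = cc[[2]])
}

# Monte Carlo estimation core.  Draws n1 independent index subsets of size
# n0, counts matched pairs in each, averages, and takes -log(b_bar/a_bar).
# Returns the ingredients needed by the "mcsampen" object.
mcsampen_core <- function(x, m, r, n0, n1,
                          sampler = c("hidden_shuffle", "fisher_yates")) {
  sampler <- match.arg(sampler)
  check_params(m, r)
  check_series(x, m)
  N <- n_templates(length(x), m)
  if (n0 < 2) stop("'n0' must be at least 2")
  if (n0 > N) {
    stop("n0 (", n0, ") exceeds the number of templates N = ", N,
         "; use strategy_s2(), which adapts n0 to the series length")
  }
  if (n1 < 1) stop("'n1' must be at least 1")
  xx <- as.double(x)
  a_tilde <- numeric(n1)
  b_tilde <- numeric(n1)
  examined <- 0
  for (k in seq_len(n1)) {
    s <- draw_subset(N, n0, method = sampler)
    cc <- cpp_pair_counts_subset(xx, s - 1L, as.integer(m), as.double(r))
    a_tilde[k] <- cc[[1]]
    b_tilde[k] <- cc[[2]]
    examined <- examined + cc[[3]]
  }
  a_bar <- mean(a_tilde)
  b_bar <- mean(b_tilde)
  if (a_bar > 0 && b_bar > 0) {
    value <- -log(b_bar / a_bar)
    degenerate <- FALSE
  } else {
    # finite fallback mirroring the exact definition's degenerate branch,
    # on the subsample scale
    value <- -log(2 / (n0 * (n0 - 1)))
    degenerate <- TRUE
  }
  list(value = value, a_bar = a_bar, b_bar = b_bar,
       experiments = cbind(a = a_tilde, b = b_tilde),
       n0 = as.integer(n0), n1 = as.integer(n1), N = N,
       sampler = sampler, degenerate = degenerate,
       # each examined pair resolves one m-distance and one (m+1)-distance
       # threshold decision, as in the two range-counting passes of the
       # published procedure: the total is n1 * n0 * (n0 - 1)
       comparisons = 2 * examined)
}

#' Parameter strategy S1: size-independent subsampling
#'
#' Fixed subsample size and repeat count, `n0 = 2000` and `n1 = 150`,
#' making the estimator's cost independent of the series length.
#'
#' @return A list with elements `name`, `n0`, `n1`.
#' @export
strategy_s1 <- function() {
  list(name = "S1", n0 = 2000L, n1 = 150L)
}

#' Parameter strategy S2: length-adaptive subsampling
#'
#' `n0 = max(1024, floor(sqrt(N)))` and
#' `n1 = max(1, min(floor(5 + log2(N)), floor(N / n0)))`, where `N` is the
#' number of templates.  The square-root growth of `n0` and logarithmic
#' growth of `n1` keep the total cost at O(N log N), while the floor of
#' 1024 on `n0` protects accuracy on short series.
#'
#' @param N Number of templates (or series length; any positive integer).
#' @return A list with elements `name`, `n0`, `n1`.
#' @export
strategy_s2 <- function(N) {
  if (length(N) != 1L || !is.finite(N) || N < 2) stop("'N' must be >= 2")
  n0 <- max(1024L, as.integer(floor(sqrt(N))))
  n1 <- max(1L, min(as.integer(floor(5 + log2(N))),
                    as.integer(floor(N / n0))))
  list(name = "S2", n0 = n0, n1 = n1)
}
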
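#' Expected matched-pair rate of a subsample experiment
#'
#' The subsample count estimators are unbiased on the pair-rate scale:
#' `E[a~ / (n0 * (n0 - 1))] = A / (N * (N - 1))`, and identically for the
#' `b` side.  This returns the right-hand side, i.e. the exact expectation
#' of the normalized subsample count for any subsample size `n0 > 1`.
#'
#' @param pairs Total unordered matched-pair count (`A` or `B`, the halved
#'   sums of the per-template counts).
#' @param N Number of templates in the full series.
#' @param n0 Subsample size (enters only through the validity condition
#'   `n0 > 1`; the expectation itself is free of `n0`).
#' @return `pairs / (N * (N - 1))`.
#' @examples
#' rate_expectation(6, N = 5, n0 = 3)  # 0.3
#' @export
rate_expectation <- function(pairs, N, n0) {
  if (n0 <= 1) stop("'n0' must exceed 1 for the pair rate to be defined")
  if (N < 2) stop("'N' must be at least 2")
  if (pairs < 0) stop("'pairs' must be nonnegative")
  pairs / (N * (N - 1))
}

#' Closed-form variance of the subsample matched-pair rate
#'
#' Variance of `b~ / (n0 * (n0 - 1))` (equivalently the `a` side, passing
#' the per-template counts `A_i`) under uniform subsampling of `n0`
#' template indices without replacement:
#' `Var = C_n0 / n0`, where `C_n0` is the sum of four terms built from the
#' total pair count `B = sum(B_l) / 2` and the per-template sum of squares
#' `sum(B_l^2)`:
#' \deqn{C_{n_0} = \frac{B}{(n_0-1)N(N-1)}
#'   + \frac{n_0-2}{(n_0-1)N(N-1)(N-2)}\Big(\sum_l B_l^2 - 2B\Big)
#'   + \frac{(n_0-2)(n_0-3)}{(n_0-1)N(N-1)(N-2)(N-3)}
#'       \Big(B^2 - \sum_l B_l^2 + B\Big)
#'   - \frac{n_0 B^2}{N^2 (N-1)^2}.}
#' `C_n0` is bounded above by `1 + 1 / (2 * (n0 - 1))`, so the variance
#' vanishes at rate `1/n0`.
#'
#' Terms with a zero coefficient are skipped before their denominators are
#' formed, which makes the formula usable at `n0` of 2 or 3 (where the
#' third term drops out) even for `N < 4`.
#'
#' @param per_template Integer vector of per-template match counts
#'   (`B_i` or `A_i`); its sum must be even.
#' @param N Number of templates (defaults to `length(per_template)`).
#' @param n0 Subsample size, `2 <= n0 <= N`.
#' @return An object of class `"sampen_variance"`: list with `c_n0`,
#'   `variance` (`= c_n0 / n0`), `bound` (`1 + 1/(2*(n0-1))`), and the four
#'   additive `terms`.
#' @examples
#' v <- rate_variance(c(3, 3, 0, 3, 3), n0 = 3)
#' v$c_n0                 # 0.08
#' v$variance             # 0.08 / 3
#' @export
rate_variance <- function(per_template, N = length(per_template), n0) {
  if (length(per_template) != N) {
    stop("'per_template' must have one entry per template (length N)")
  }
  if (any(per_template < 0)) stop("per-template counts must be nonnegative")
  tot <- sum(per_template)
  if (tot %% 2 != 0) stop("sum of per-template counts must be even")
  if (n0 < 2 || n0 > N) stop("need 2 <= n0 <= N")
  if (n0 > 3 && N < 4) {
    stop("the four-term variance formula needs N >= 4 when n0 > 3; ",
         "use enumerated_moments() for smaller instances")
  }
  B <- tot / 2
  ssq <- sum(as.numeric(per_template)^2)
  term1 <- B / ((n0 - 1) * N * (N - 1))
  term2 <- if (n0 == 2) 0 else
    (n0 - 2) / ((n0 - 1) * N * (N - 1) * (N - 2)) * (ssq - 2 * B)
  term3 <- if (n0 <= 3) 0 else
    ((n0 - 2) * (n0 - 3)) / ((n0 - 1) * N * (N - 1) * (N - 2) * (N - 3)) *
      (B^2 - ssq + B)
  term4 <- -n0 * B^2 / (N^2 * (N - 1)^2)
  c_n0 <- term1 + term2 + term3 + term4
  structure(
    list(c_n0 = c_n0, variance = c_n0 / n0,
         bound = 1 + 1 / (2 * (n0 - 1)),
         terms = c(term1 = term1, term2 = term2,
                   term3 = term3, term4 = term4),
         N = N, n0 = n0, B = B),
    class = "sampen_variance"
  )
}

#' @export
print.sampen_variance <- function(x, digits = 6, ...) {
  cat("Subsample pair-rate variance (N = ", x$N, ", n0 = ", x$n0, ")\n",
      sep = "")
  cat("  C_n0     =", format(x$c_n0, digits = digits), "\n")
  cat("  variance =", format(x$variance, digits = digits),
      " (C_n0 / n0)\n")
  cat("  bound    =", format(x$bound, digits = digits),
      " (1 + 1/(2(n0-1)))\n")
  if (x$c_n0 == 0) {
    cat("  note: no matches anywhere, C_n0 sits on the lower boundary 0\n")
  }
  invisible(x)
}

#' Exact subsample moments by exhaustive enumeration
#'
#' Brute-force oracle for the closed-form moments: computes the normalized
#' pair counts `a~ / (n0 (n0 - 1))` and `b~ / (n0 (n0 - 1))` for every one
#' of the `choose(N, n0)` index subsets and returns their exact population
#' mean and variance under the uniform measure.
#'
#' @param x Numeric series.
#' @param m Template length.
#' @param r Tolerance.
#' @param n0 Subsample size.
#' @param guard Enumeration guard passed to [enumerate_subsets()].
#' @return A list with `a_mean`, `a_var`, `b_mean`, `b_var`, `n_subsets`.
#' @examples
#' enumerated_moments(c(0, 0, 1, 0, 0, 1, 0), m = 1, r = 0.5, n0 = 3)
#' @export
enumerated_moments <- function(x, m, r, n0, guard = 1e6) {
  check_params(m, r)
  check_series(x, m)
  N <- n_templates(length(x), m)
  subs <- enumerate_subsets(N, n0, guard = guard)
  scale <- n0 * (n0 - 1)
  av <- numeric(ncol(subs))
  bv <- numeric(ncol(subs))
  xx <- as.double(x)
  for (j in seq_len(ncol(subs))) {
    cc <- cpp_pair_counts_subset(xx, subs[, j] - 1L, as.integer(m),
                                 as.double(r))
    av[j] <- cc[[1]] / scale
    bv[j] <- cc[[2]] / scale
  }
  pop_var <- function(v) mean((v - mean(v))^2)
  list(a_mean = mean(av), a_var = pop_var(av),
       b_mean = mean(bv), b_var = pop_var(bv),
       n_subsets = ncol(subs))
}
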
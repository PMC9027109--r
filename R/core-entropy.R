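#' Chebyshev (maximum-norm) distance between two templates
#'
#' The distance used throughout sample-entropy computation:
#' `max(abs(a - b))` over the template coordinates.
#'
#' @param a,b Numeric vectors of equal length.
#' @return A single nonnegative number.
#' @examples
#' chebyshev_dist(c(1, 2), c(2, 0))  # 2
#' @export
chebyshev_dist <- function(a, b) {
  if (length(a) != length(b)) {
    stop("'a' and 'b' must have equal length (got ", length(a), " and ",
         length(b), ")")
  }
  if (length(a) < 1L) stop("templates must have length >= 1")
  max(abs(a - b))
}

#' Rescale a series to unit standard deviation
#'
#' Divides the series by its sample standard deviation so that the tolerance
#' `r` can be read on the conventional unit-SD scale.  The mean is left
#' untouched: Chebyshev distances between templates are translation
#' invariant, so centering would not change any match count.
#'
#' @param x Numeric vector.
#' @return `x / sd(x)`.
#' @export
normalize_sd <- function(x) {
  check_series(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s <= 0) {
    stop("cannot normalize a constant (or degenerate) series: sd is ", s)
  }
  x / s
}

# shared validation: finite numeric series, long enough for template length m
check_series <- function(x, m = NULL) {
  if (!is.numeric(x)) stop("the series must be numeric")
  if (anyNA(x) || any(!is.finite(x))) stop("the series contains NA/non-finite values")
  if (!is.null(m)) {
    if (length(x) < m + 3) {
      stop("series too short: need n >= m + 3 (n = ", length(x),
           ", m = ", m, ") so that at least 2 templates exist")
    }
  }
  invisible(x)
}

check_params <- function(m, r) {
  if (length(m) != 1L || !is.finite(m) || m < 1 || m != floor(m)) {
    stop("'m' must be a positive integer")
  }
  if (length(r) != 1L || !is.finite(r) || r < 0) stop("'r' must be >= 0")
  invisible(NULL)
}

# number of templates; both the length-m and length-(m+1) template sets have
# N = n - m - 1 members (the final sample is unused), following the
# convention under which A and B are counted over equally sized sets
n_templates <- function(n, m) n - m - 1

#' Count matched template pairs over a set of template start indices
#'
#' Direct range counting: the number of unordered index pairs \{i, j\} in
#' `idx` whose length-`k` templates lie within Chebyshev distance `r`
#' (comparison is `<= r`).
#'
#' @param x Numeric series.
#' @param idx Integer vector of distinct 1-based template start indices.
#' @param k Template length.
#' @param r Tolerance.
#' @return Number of matched unordered pairs.
#' @examples
#' u <- c(0, 0, 1, 0, 0, 1, 0)
#' direct_range_count(u, 1:5, k = 1, r = 0.5)  # 6
#' direct_range_count(u, 1:5, k = 2, r = 0.5)  # 2
#' @export
direct_range_count <- function(x, idx, k, r) {
  check_series(x)
  check_params(k, r)
  idx <- as.integer(idx)
  if (anyNA(idx) || any(idx < 1L) || any(idx > length(x) - k + 1L)) {
    stop("template start indices must lie in 1..", length(x) - k + 1L,
         " for template length ", k)
  }
  if (anyDuplicated(idx)) stop("template start indices must be distinct")
  cpp_range_count(as.double(x), idx - 1L, as.integer(k), as.double(r))
}

#' Per-template and total match counts
#'
#' Computes, for every template index `i` in `1..N` with `N = n - m - 1`,
#' the number `A_i` of length-`m` templates (self excluded) within
#' tolerance `r` of template `i`, and likewise `B_i` for length `m + 1`.
#' The totals are the unordered pair counts `A = sum(A_i) / 2` and
#' `B = sum(B_i) / 2`.
#'
#' @param x Numeric series (already normalized if `r` is meant on the
#'   unit-SD scale).
#' @param m Template length.
#' @param r Tolerance.
#' @return An object of class `"sampen_counts"`: a list with elements
#'   `A`, `B`, `A_i`, `B_i`, `N`, `m`, `r`.
#' @examples
#' match_counts(c(0, 0, 1, 0, 0, 1, 0), m = 1, r = 0.5)
#' @export
match_counts <- function(x, m, r) {
  check_params(m, r)
  check_series(x, m)
  cc <- cpp_pair_counts_full(as.double(x), as.integer(m), as.double(r))
  structure(
    list(A = cc$A, B = cc$B, A_i = cc$A_i, B_i = cc$B_i,
         N = as.integer(cc$N), m = as.integer(m), r = r),
    class = "sampen_counts"
  )
}

#' @export
print.sampen_counts <- function(x, ...) {
  cat("Template match counts (m = ", x$m, ", r = ", format(x$r), ")\n",
      sep = "")
  cat("  N templates:", x$N, "\n")
  cat("  A (m-matched pairs):    ", format(x$A), "\n")
  cat("  B ((m+1)-matched pairs):", format(x$B), "\n")
  invisible(x)
}

# exact sample entropy core: -log(B/A) with the finite fallback
# -log(2 / (N (N - 1))) when either count is zero
sampen_exact_core <- function(x, m, r) {
  mc <- match_counts(x, m, r)
  N <- mc$N
  if (mc$A > 0 && mc$B > 0) {
    list(value = -log(mc$B / mc$A), A = mc$A, B = mc$B, N = N,
         degenerate = FALSE)
  } else {
    list(value = -log(2 / (N * (N - 1))), A = mc$A, B = mc$B, N = N,
         degenerate = TRUE)
  }
}
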
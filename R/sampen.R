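#' Sample entropy of a time series, exact or by Monte Carlo subsampling
#'
#' Sample entropy (SampEn) measures the irregularity of a univariate series
#' as `-log(B/A)`, where `A` counts unordered pairs of length-`m` templates
#' within Chebyshev tolerance `r` and `B` the corresponding pairs of length
#' `m + 1`.  Both template families have `N = n - m - 1` members.  When
#' either count is zero the finite fallback `-log(2 / (N * (N - 1)))` is
#' returned and flagged as degenerate.
#'
#' `method = "exact"` counts every template pair directly, at O(N^2) cost.
#' `method = "mc"` runs the Monte Carlo estimator (MCSampEn): it draws `n1`
#' uniform subsets of `n0` template indices (Hidden Shuffle sampling),
#' counts matched pairs within each subset, averages the per-experiment
#' counts `A~` and `B~`, and returns `-log(b_bar / a_bar)`.  Its cost,
#' O(`n1 * n0^2`), does not depend on the series length, and the estimate
#' converges to the exact value as `n0` or `n1` grows.
#'
#' @param x Numeric series of length at least `m + 3`.
#' @param m Template length (default 4, a common operating point for long
#'   physiological recordings).
#' @param r Tolerance (default 0.15).  With `normalize = TRUE` it is read
#'   on the unit-standard-deviation scale.
#' @param method `"exact"` or `"mc"`.
#' @param normalize If `TRUE` (default) divide `x` by its standard
#'   deviation before counting.
#' @param n0,n1 Monte Carlo subsample size and number of repeated
#'   experiments.  Ignored for `method = "exact"`; mutually exclusive with
#'   `strategy`.
#' @param strategy `"s1"` (fixed `n0 = 2000`, `n1 = 150`) or `"s2"`
#'   (length-adaptive); used when `n0`/`n1` are not given.  Defaults to
#'   `"s1"` when nothing is specified.
#' @param seed Optional integer; when given, the RNG state is set locally
#'   (and restored on exit) so the estimate is reproducible.
#' @param sampler Index sampler passed to [draw_subset()].
#' @return An object of class `"sampen"` (and `"mcsampen"` for
#'   `method = "mc"`).  Key elements: `value` (the entropy), `A`/`B` or
#'   `a_bar`/`b_bar`, `N`, `degenerate`, and for Monte Carlo fits the
#'   per-experiment counts `experiments`, `n0`, `n1`, `seed`, and the
#'   instrumented number of template-pair distance `comparisons`.
#' @examples
#' u <- c(0, 0, 1, 0, 0, 1, 0)
#' sampen(u, m = 1, r = 0.5, normalize = FALSE)         # log(3)
#'
#' x <- mix_process(2^11, p = 0.3, seed = 7)
#' fit <- sampen(x, m = 2, r = 0.15, method = "mc",
#'               n0 = 500, n1 = 30, seed = 1)
#' fit
#' summary(fit)
#' @export
sampen <- function(x, m = 4, r = 0.15, method = c("exact", "mc"),
                   normalize = TRUE, n0 = NULL, n1 = NULL,
                   strategy = NULL, seed = NULL,
                   sampler = c("hidden_shuffle", "fisher_yates")) {
  method <- match.arg(method)
  sampler <- match.arg(sampler)
  cl <- match.call()
  check_params(m, r)
  check_series(x, m)
  if (normalize) x <- normalize_sd(x)
  N <- n_templates(length(x), m)

  if (method == "exact") {
    core <- sampen_exact_core(x, m, r)
    out <- c(core, list(n = length(x), m = m, r = r, normalized = normalize,
                        method = "exact", call = cl))
    class(out) <- "sampen"
    return(out)
  }

  if (!is.null(strategy) && (!is.null(n0) || !is.null(n1))) {
    stop("give either 'n0'/'n1' or 'strategy', not both")
  }
  if (is.null(n0) || is.null(n1)) {
    st <- if (is.null(strategy) || identical(tolower(strategy), "s1")) {
      strategy_s1()
    } else if (identical(tolower(strategy), "s2")) {
      strategy_s2(N)
    } else {
      stop("unknown strategy '", strategy, "' (use \"s1\" or \"s2\")")
    }
    if (is.null(n0)) n0 <- st$n0
    if (is.null(n1)) n1 <- st$n1
  }

  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  core <- mcsampen_core(x, m, r, n0, n1, sampler = sampler)
  out <- c(core, list(n = length(x), m = m, r = r, normalized = normalize,
                      method = "mc", seed = seed, call = cl))
  class(out) <- c("mcsampen", "sampen")
  out
}

#' @export
print.sampen <- function(x, digits = max(4L, getOption("digits") - 3L), ...) {
  lab <- if (inherits(x, "mcsampen")) "Monte Carlo sample entropy (MCSampEn)"
         else "Sample entropy (exact direct counting)"
  cat(lab, "\n", sep = "")
  cat("  m = ", x$m, ", r = ", format(x$r),
      if (isTRUE(x$normalized)) " (unit-SD scale)", ", n = ", x$n,
      ", N = ", x$N, " templates\n", sep = "")
  if (inherits(x, "mcsampen")) {
    cat("  n0 = ", x$n0, " sampled templates, n1 = ", x$n1,
        " experiments", if (!is.null(x$seed)) paste0(", seed = ", x$seed),
        "\n", sep = "")
  }
  cat("  SampEn = ", format(x$value, digits = digits),
      if (isTRUE(x$degenerate)) "  [degenerate: a zero match count]",
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.sampen <- function(object, ...) {
  structure(object, class = c("summary.sampen", class(object)))
}

#' @export
print.summary.sampen <- function(x, digits = 6, ...) {
  class(x) <- setdiff(class(x), "summary.sampen")
  print(x, digits = digits)
  if (inherits(x, "mcsampen")) {
    rate_a <- x$a_bar / (x$n0 * (x$n0 - 1))
    rate_b <- x$b_bar / (x$n0 * (x$n0 - 1))
    cat("  mean subsample counts: a_bar = ", format(x$a_bar, digits = digits),
        ", b_bar = ", format(x$b_bar, digits = digits), "\n", sep = "")
    cat("  matched-pair rates:    a = ", format(rate_a, digits = digits),
        ", b = ", format(rate_b, digits = digits), "\n", sep = "")
    cat("  per-experiment entropy spread (finite cases): ",
        paste(format(stats::quantile(per_experiment_entropy(x),
                                     c(0.25, 0.5, 0.75), na.rm = TRUE),
                     digits = digits), collapse = " / "),
        " (quartiles)\n", sep = "")
    cat("  template-pair comparisons performed: ",
        format(x$comparisons, big.mark = ","), "\n", sep = "")
  } else {
    cat("  A = ", format(x$A), ", B = ", format(x$B), ", B/A = ",
        format(x$B / x$A, digits = digits), "\n", sep = "")
  }
  invisible(x)
}

# entropy each single experiment would give on its own (NA when a count is 0)
per_experiment_entropy <- function(fit) {
  a <- fit$experiments[, "a"]
  b <- fit$experiments[, "b"]
  ifelse(a > 0 & b > 0, -log(b / a), NA_real_)
}

#' @export
as.double.sampen <- function(x, ...) x$value

#' Convergence diagnostics plot for a Monte Carlo sample-entropy fit
#'
#' Plots the running estimate `-log(cummean(b) / cummean(a))` against the
#' experiment index, with the final estimate as a horizontal line, plus the
#' spread of single-experiment entropies.
#'
#' @param x An `"mcsampen"` object.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.mcsampen <- function(x, ...) {
  a <- cumsum(x$experiments[, "a"]) / seq_len(x$n1)
  b <- cumsum(x$experiments[, "b"]) / seq_len(x$n1)
  running <- ifelse(a > 0 & b > 0, -log(b / a), NA_real_)
  graphics::plot(seq_len(x$n1), running, type = "l",
                 xlab = "experiment k", ylab = "running MCSampEn estimate",
                 main = sprintf("MCSampEn convergence (n0 = %d, n1 = %d)",
                                x$n0, x$n1), ...)
  graphics::abline(h = x$value, lty = 2)
  pe <- per_experiment_entropy(x)
  graphics::points(seq_len(x$n1), pe, pch = 16,
                   col = grDevices::adjustcolor("grey40", 0.4), cex = 0.5)
  invisible(x)
}
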
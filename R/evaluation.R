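#' Repeated-run error metrics against an exact reference value
#'
#' Summarizes a batch of Monte Carlo entropy estimates against the exact
#' sample entropy of the same series: `mean_err` is the magnitude of the
#' mean signed error (a bias measure), `rmse` the root mean squared error,
#' and `relative_error` the ratio `rmse / |truth|` (only defined for a
#' nonzero reference).
#'
#' @param estimates Numeric vector of repeated estimates.
#' @param truth The exact reference value.
#' @return An object of class `"sampen_errors"`: list with `mean_err`,
#'   `mean_signed`, `rmse`, `relative_error`, `n_runs`, `truth`,
#'   `estimates`.
#' @examples
#' error_metrics(c(1, 3), truth = 1)  # mean_err 1, rmse sqrt(2)
#' @export
error_metrics <- function(estimates, truth) {
  if (length(estimates) < 1) stop("'estimates' must be nonempty")
  if (length(truth) != 1L || !is.finite(truth)) {
    stop("'truth' must be a single finite number")
  }
  err <- estimates - truth
  structure(
    list(mean_err = abs(mean(err)),
         mean_signed = mean(err),
         rmse = sqrt(mean(err^2)),
         relative_error = if (truth != 0) sqrt(mean(err^2)) / abs(truth)
                          else NA_real_,
         n_runs = length(estimates),
         truth = truth,
         estimates = estimates),
    class = "sampen_errors"
  )
}

#' @export
print.sampen_errors <- function(x, digits = 6, ...) {
  cat("Repeated-run error metrics (", x$n_runs, " runs, truth = ",
      format(x$truth, digits = digits), ")\n", sep = "")
  cat("  MeanErr     =", format(x$mean_err, digits = digits), "\n")
  cat("  RMeanSqErr  =", format(x$rmse, digits = digits), "\n")
  if (is.finite(x$relative_error)) {
    cat("  rel. error  =", format(x$relative_error, digits = digits),
        " (RMeanSqErr / truth)\n")
  }
  invisible(x)
}

# run the MC estimator `runs` times with per-run seeds derived from the
# caller's stream, returning the vector of entropy estimates
repeated_mcsampen <- function(x, m, r, n0, n1, runs,
                              normalize = FALSE) {
  vapply(seq_len(runs), function(i) {
    sampen(x, m = m, r = r, method = "mc", normalize = normalize,
           n0 = n0, n1 = n1)$value
  }, numeric(1))
}

#' Error surface of the Monte Carlo estimator over an (n0, n1) grid
#'
#' For every grid cell, runs the Monte Carlo estimator `runs` times against
#' the exact sample entropy of the same (already prepared) series and
#' records the repeated-run error metrics.  Cells with `n0` exceeding the
#' number of templates are skipped with a warning.
#'
#' @param x Numeric series (pass it already normalized if `r` is on the
#'   unit-SD scale; no normalization is applied here).
#' @param m,r Entropy parameters.
#' @param n0_grid,n1_grid Integer vectors of subsample sizes and repeat
#'   counts.
#' @param runs Repeated runs per cell (default 50).
#' @param seed Optional integer seed for the whole experiment.
#' @return A data frame with columns `n0`, `n1`, `mean_err`, `rmse`,
#'   `runs`, and attribute `truth`.
#' @export
convergence_surface <- function(x, m, r, n0_grid, n1_grid, runs = 50,
                                seed = NULL) {
  if (length(n0_grid) < 1 || length(n1_grid) < 1) {
    stop("both grids must be nonempty")
  }
  truth <- sampen(x, m = m, r = r, method = "exact", normalize = FALSE)$value
  N <- n_templates(length(x), m)
  keep <- n0_grid <= N
  if (!all(keep)) {
    warning("skipping n0 cells exceeding the template count N = ", N, ": ",
            paste(n0_grid[!keep], collapse = ", "))
    n0_grid <- n0_grid[keep]
  }
  grid <- expand.grid(n0 = n0_grid, n1 = n1_grid)
  res <- with_seed(seed, {
    lapply(seq_len(nrow(grid)), function(i) {
      est <- repeated_mcsampen(x, m, r, grid$n0[i], grid$n1[i], runs)
      em <- error_metrics(est, truth)
      data.frame(n0 = grid$n0[i], n1 = grid$n1[i],
                 mean_err = em$mean_err, rmse = em$rmse, runs = runs)
    })
  })
  out <- do.call(rbind, res)
  attr(out, "truth") <- truth
  out
}

#' Relative estimation error across the MIX(p) randomness scale
#'
#' For each mixing probability `p`, generates one MIX(p) realization,
#' computes its exact sample entropy as the reference, then runs the Monte
#' Carlo estimator `runs` times with the randomness-adaptive parameters
#' `n0 = round(1000 + 3000 p)` and `n1 = round(80 + 70 p)` and reports the
#' ratio of the root mean squared error to the exact entropy.
#'
#' @param p_grid Mixing probabilities in `[0, 1]`.
#' @param n Series length for each realization.
#' @param m,r Entropy parameters (defaults 4 and 0.15; the series is
#'   normalized to unit SD before counting).
#' @param runs Repeated estimator runs per `p` (default 50).
#' @param seed Optional integer seed governing both the realizations and
#'   the estimator runs.
#' @return Data frame with columns `p`, `n0`, `n1`, `truth`, `mean_err`,
#'   `rmse`, `relative_error`, `runs`, `degenerate_truth`.
#' @export
relative_error_vs_p <- function(p_grid, n, m = 4, r = 0.15, runs = 50,
                                seed = NULL) {
  if (any(p_grid < 0 | p_grid > 1)) stop("'p_grid' must lie in [0, 1]")
  res <- with_seed(seed, {
    lapply(p_grid, function(p) {
      x <- normalize_sd(mix_process(n, p))
      ex <- sampen(x, m = m, r = r, method = "exact", normalize = FALSE)
      n0 <- round(1000 + 3000 * p)
      n1 <- round(80 + 70 * p)
      est <- repeated_mcsampen(x, m, r, n0, n1, runs)
      em <- error_metrics(est, ex$value)
      degenerate <- ex$degenerate || ex$value <= 0
      data.frame(p = p, n0 = n0, n1 = n1, truth = ex$value,
                 mean_err = em$mean_err, rmse = em$rmse,
                 relative_error = if (degenerate) NA_real_
                                  else em$relative_error,
                 runs = runs, degenerate_truth = degenerate)
    })
  })
  do.call(rbind, res)
}

#' Number of template-pair comparisons performed by a Monte Carlo fit
#'
#' The instrumented count of template-pair distance evaluations: every one
#' of the `n0 * (n0 - 1) / 2` index pairs in each of the `n1` experiments
#' is resolved against the tolerance at template length `m` and at
#' `m + 1`, giving `n1 * n0 * (n0 - 1)` in total — independent of the
#' series length.
#'
#' @param fit An `"mcsampen"` object.
#' @return The comparison count (numeric, exact).
#' @export
comparison_count <- function(fit) {
  if (!inherits(fit, "mcsampen")) {
    stop("'fit' must be an \"mcsampen\" object (method = \"mc\")")
  }
  fit$comparisons
}

#' Write an evaluation table to CSV
#'
#' Plain-text export of the tables produced by [convergence_surface()] and
#' [relative_error_vs_p()].
#'
#' @param table A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
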
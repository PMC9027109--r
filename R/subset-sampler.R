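#' Draw a uniform random subset of template indices
#'
#' Samples `n0` distinct indices from `1..n_pop`, each of the
#' `choose(n_pop, n0)` subsets being equally likely, emitted in ascending
#' order.  The default `"hidden_shuffle"` method is a sequential sampler
#' that needs only O(`n0`) expected arithmetic operations and O(`n0`)
#' memory, independent of `n_pop`; `"fisher_yates"` is base R's partial
#' shuffle (`sample.int`), kept behind the same interface as a
#' cross-validation reference.
#'
#' Both methods consume R's global random number stream, so draws are
#' reproducible under [set.seed()].
#'
#' @param n_pop Population size (N).
#' @param n0 Sample size, `1 <= n0 <= n_pop`.
#' @param method `"hidden_shuffle"` (default) or `"fisher_yates"`.
#' @return Sorted integer vector of `n0` distinct indices in `1..n_pop`.
#' @examples
#' set.seed(1)
#' draw_subset(100, 5)
#' @export
draw_subset <- function(n_pop, n0, method = c("hidden_shuffle", "fisher_yates")) {
  method <- match.arg(method)
  if (length(n_pop) != 1L || length(n0) != 1L || n_pop < 1 || n0 < 1 ||
      n0 != floor(n0) || n_pop != floor(n_pop)) {
    stop("'n_pop' and 'n0' must be positive integers")
  }
  if (n0 > n_pop) {
    stop("sample size n0 (", n0, ") exceeds the number of available ",
         "templates (", n_pop, "); for short series use strategy_s2(), ",
         "which caps n0 by the series length")
  }
  switch(method,
    hidden_shuffle = cpp_hidden_shuffle(as.double(n_pop), as.integer(n0)),
    fisher_yates = sort(sample.int(n_pop, n0))
  )
}

#' Enumerate all subsets of a given size
#'
#' Exhaustive companion to [draw_subset()], used to verify the sampler's
#' uniformity and the closed-form moments of the subsample pair counts by
#' brute force.
#'
#' @param n_pop Population size.
#' @param n0 Subset size.
#' @param guard Maximum number of subsets allowed (default `1e6`).
#' @return An integer matrix with `n0` rows; each column is one subset in
#'   ascending order.
#' @examples
#' enumerate_subsets(5, 3)  # 10 columns
#' @export
enumerate_subsets <- function(n_pop, n0, guard = 1e6) {
  if (n0 < 1 || n0 > n_pop) stop("need 1 <= n0 <= n_pop")
  n_sub <- choose(n_pop, n0)
  if (n_sub > guard) {
    stop("choose(", n_pop, ", ", n0, ") = ", format(n_sub),
         " subsets exceeds the enumeration guard (", format(guard), ")")
  }
  m <- utils::combn(n_pop, n0)
  storage.mode(m) <- "integer"
  m
}
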
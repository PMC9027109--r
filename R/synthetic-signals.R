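#' MIX(p) benchmark process
#'
#' A classic surrogate for studying regularity statistics: a deterministic
#' 12-periodic sine of unit variance is replaced, at each position
#' independently with probability `p`, by an i.i.d. uniform noise draw of
#' unit variance.  `p = 0` gives the pure sine, `p = 1` pure noise, and
#' intermediate `p` interpolates the randomness of the series.
#'
#' The deterministic part is `x_j = alpha^(-1/2) * sin(2*pi*j/12)` with
#' `alpha = mean(sin(2*pi*(1:12)/12)^2) = 1/2` (so the amplitude is
#' `sqrt(2)` and the variance over a period is 1).  The noise is uniform
#' on `[-sqrt(3), sqrt(3)]`, also unit variance.  Both the harmonic of the
#' sine and the noise half-width can be overridden for compatibility with
#' other renderings of the process.
#'
#' @param n Series length.
#' @param p Mixing probability in `[0, 1]`.
#' @param seed Optional integer seed (RNG state restored on exit).
#' @param noise_halfwidth Half-width of the uniform noise support
#'   (default `sqrt(3)` for unit variance).
#' @param harmonic Integer harmonic `h` in `sin(2*pi*h*j/12)` (default 1).
#' @return Numeric vector of length `n`.
#' @examples
#' mix_process(24, p = 0, seed = 1)     # sqrt(2) * sin(2*pi*j/12)
#' @export
mix_process <- function(n, p, seed = NULL, noise_halfwidth = sqrt(3),
                        harmonic = 1) {
  if (n < 1) stop("'n' must be >= 1")
  if (length(p) != 1L || !is.finite(p) || p < 0 || p > 1) {
    stop("'p' must be a probability in [0, 1]")
  }
  alpha <- mean(sin(2 * pi * harmonic * (1:12) / 12)^2)
  if (alpha <= 1e-12) {
    stop("degenerate harmonic: the sine component vanishes identically")
  }
  j <- seq_len(n)
  x <- alpha^(-1 / 2) * sin(2 * pi * harmonic * j / 12)
  with_seed(seed, {
    z <- stats::rbinom(n, 1L, p)
    y <- stats::runif(n, -noise_halfwidth, noise_halfwidth)
    (1 - z) * x + z * y
  })
}

#' 1/f (pink) noise by spectral synthesis
#'
#' White Gaussian noise is transformed to the frequency domain, each
#' component is scaled by `f^(-1/2)` (so the power spectrum decays as
#' `1/f`), the zero-frequency term is removed, and the inverse transform is
#' rescaled to unit standard deviation.  For `n >= 2^14` the fitted
#' log-log periodogram slope is close to -1.
#'
#' @param n Series length (at least 2).
#' @param seed Optional integer seed (RNG state restored on exit).
#' @return Numeric vector of length `n` with standard deviation 1.
#' @examples
#' x <- pink_noise(1024, seed = 1)
#' sd(x)  # 1
#' @export
pink_noise <- function(n, seed = NULL) {
  if (n < 2) stop("'n' must be >= 2")
  w <- with_seed(seed, stats::rnorm(n))
  sp <- stats::fft(w)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) / n       # two-sided frequency magnitude
  scale <- c(0, f[-1]^(-1 / 2)) # zero out DC
  x <- Re(stats::fft(sp * scale, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Small named reference signals
#'
#' Deterministic signals used throughout the examples and tests: the
#' 7-point toy series whose match counts are known by hand, a constant
#' series (entropy exactly 0), a monotone series with steps far larger
#' than any reasonable tolerance (degenerate: no matches), and a seeded
#' MIX(0.3) draw.
#'
#' @return Named list of numeric vectors: `toy`, `constant`, `bigstep`,
#'   `mix03`.
#' @export
demo_signals <- function() {
  list(
    toy = c(0, 0, 1, 0, 0, 1, 0),
    constant = rep(1, 10),
    bigstep = seq(0, 90, by = 10),
    mix03 = mix_process(4096, p = 0.3, seed = 20220408)
  )
}

# evaluate `expr` under a locally seeded RNG, restoring the caller's state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
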
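# Independent brute-force oracles, deliberately coded over a different route
# than the package internals: templates are materialized as matrix rows and
# all pairwise Chebyshev distances come from stats::dist(method = "maximum").

template_matrix <- function(x, k, N) {
  m <- vapply(seq_len(N), function(i) x[i:(i + k - 1)], numeric(k))
  if (k == 1) matrix(m, ncol = 1) else t(m)
}

oracle_counts <- function(x, m, r) {
  n <- length(x)
  N <- n - m - 1
  count_side <- function(k) {
    Tm <- template_matrix(x, k, N)
    D <- as.matrix(stats::dist(Tm, method = "maximum"))
    diag(D) <- Inf
    per <- rowSums(D <= r)
    list(total = sum(per) / 2, per = as.integer(per))
  }
  a <- count_side(m)
  b <- count_side(m + 1)
  list(A = a$total, B = b$total, A_i = a$per, B_i = b$per, N = N)
}

oracle_sampen <- function(x, m, r) {
  oc <- oracle_counts(x, m, r)
  if (oc$A > 0 && oc$B > 0) -log(oc$B / oc$A)
  else -log(2 / (oc$N * (oc$N - 1)))
}

# exact population moments of the normalized subsample pair counts over all
# choose(N, n0) index subsets, via the same dist-based counting
oracle_subsample_moments <- function(x, m, r, n0) {
  n <- length(x)
  N <- n - m - 1
  Dm <- as.matrix(stats::dist(template_matrix(x, m, N), method = "maximum"))
  Dm1 <- as.matrix(stats::dist(template_matrix(x, m + 1, N),
                               method = "maximum"))
  subs <- utils::combn(N, n0)
  scale <- n0 * (n0 - 1)
  a <- apply(subs, 2, function(s) {
    D <- Dm[s, s, drop = FALSE]
    sum(D[upper.tri(D)] <= r) / scale
  })
  b <- apply(subs, 2, function(s) {
    D <- Dm1[s, s, drop = FALSE]
    sum(D[upper.tri(D)] <= r) / scale
  })
  pop_var <- function(v) mean((v - mean(v))^2)
  list(a_mean = mean(a), a_var = pop_var(a),
       b_mean = mean(b), b_var = pop_var(b))
}

toy_series <- c(0, 0, 1, 0, 0, 1, 0)

`%||%` <- function(a, b) if (is.null(a)) b else a

# least-squares slope of the log binned periodogram, for 1/f checks
periodogram_slope <- function(x, bins = 30) {
  n <- length(x)
  pg <- Mod(stats::fft(x))^2 / n
  k <- 2:(floor(n / 2))
  f <- (k - 1) / n
  lf <- log10(f)
  cut_pts <- seq(min(lf), max(lf), length.out = bins + 1)
  grp <- cut(lf, cut_pts, include.lowest = TRUE)
  mx <- tapply(lf, grp, mean)
  my <- tapply(log10(pg[k]), grp, mean)
  ok <- is.finite(mx) & is.finite(my)
  unname(stats::coef(stats::lm(my[ok] ~ mx[ok]))[2])
}
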
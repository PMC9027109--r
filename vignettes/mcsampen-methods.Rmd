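---
title: "Monte Carlo estimation of sample entropy: model, assumptions, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo estimation of sample entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcsampen)
```

## The statistic

Sample entropy (SampEn) quantifies the irregularity of a univariate time
series $u = (u_1, \dots, u_n)$. Fix a template length $m \ge 1$ and a
tolerance $r \ge 0$. A template is a length-$m$ window
$x_i = (u_i, \dots, u_{i+m-1})$; its $(m{+}1)$-length counterpart is
$y_i = (u_i, \dots, u_{i+m})$. Both families are indexed by
$i = 1, \dots, N$ with

$$N = n - m - 1,$$

so the two sets have equal size (the final sample is unused). This is the
convention adopted throughout this package. Some published SampEn codes use
$N = n - m$ templates at length $m$; the difference is $O(1/N)$ in the
counts and vanishes for long series, but exact results here follow the
$n - m - 1$ convention, so small-$n$ comparisons against other codes should
expect off-by-one count differences.

Two templates match when their Chebyshev distance
$\rho(a, b) = \max_\ell |a_\ell - b_\ell|$ is at most $r$ (the comparison
is $\le r$, not strict). With

$$A = \tfrac12 \sum_i A_i, \qquad B = \tfrac12 \sum_i B_i$$

counting matched unordered pairs at lengths $m$ and $m+1$,

$$\mathrm{SampEn}(u, m, r) = -\log\frac{B}{A}, \qquad A, B > 0,$$

and $-\log\bigl(2 / (N (N-1))\bigr)$ otherwise (the largest value
expressible with a single matched pair — a finite stand-in for "no
repetition observed"). `sampen()` flags this branch with
`degenerate = TRUE`. Logarithms are natural throughout, the dominant
convention in the SampEn literature.

`B/A` is a conditional probability: given that two length-$m$ templates
match, the probability that extending both by one sample preserves the
match. Regular signals keep matches when extended (ratio near 1, entropy
near 0); unpredictable signals lose them (small ratio, large entropy).

### Normalization and the meaning of r

`sampen(..., normalize = TRUE)` (the default) divides the series by its
sample standard deviation, so `r = 0.15` means "0.15 standard deviations".
The mean is not subtracted: Chebyshev distances between templates are
invariant under adding a constant to the whole series, so centering cannot
change any count. Tolerances quoted in the literature (typically
$0.1$–$0.25$) assume this unit-SD scale; `r` values on raw physical units
require `normalize = FALSE`.

### Parameter defaults

* `m = 4`: for long recordings ($n \gtrsim 10^4$) longer templates
  discriminate structure better than the classic `m = 2`; `m = 2` remains
  sensible for series of a few thousand samples.
* `r = 0.15` on the unit-SD scale.
* Exact counting costs $O(N^2)$ template-pair tests and is practical to
  roughly $n = 10^5$–$10^6$ at desk scale.

## The Monte Carlo estimator

The expensive objects are the pair counts. Normalized as rates,
$A / (N(N-1))$ is (half) the probability that two randomly chosen distinct
templates match. MCSampEn estimates these rates by subsampling: draw a
uniform random subset $s$ of $n_0$ template indices (without replacement),
count matched pairs $\tilde A(s)$, $\tilde B(s)$ among the sampled
templates only, repeat $n_1$ times independently, and average:

$$\bar A = \frac{1}{n_1}\sum_{k=1}^{n_1} \tilde A(s_k), \qquad
  \widehat{\mathrm{SampEn}} = -\log \frac{\bar B}{\bar A}.$$

The subsample rates are exactly unbiased,
$E[\tilde A / (n_0 (n_0 - 1))] = A / (N (N - 1))$, and their variance has
the closed form $C_{n_0} / n_0$ with $C_{n_0}$ given by four explicit terms
in the per-template counts (`rate_variance()`), bounded above by
$1 + 1/(2(n_0 - 1))$. Both facts are verified in the test suite by
exhaustive enumeration over all $\binom{N}{n_0}$ subsets on small
instances; the enumeration (`enumerated_moments()`) is the authority used
to pin down the exact grouping of the four variance terms, which is easy
to mis-transcribe. Averaging over $n_1$ experiments divides the variance
by $n_1$, so the estimate converges to the exact value as $n_0$ or $n_1$
grows, while the cost $O(n_1 n_0^2)$ never depends on the series length.
That independence is what makes the method attractive for very long
recordings, and is checked by an instrumented comparison counter
(`comparison_count()`), which always equals $n_1 \, n_0 (n_0 - 1)$: each
examined pair resolves one $m$- and one $(m{+}1)$-distance decision. The
implementation fuses the two passes (an $(m{+}1)$-match requires an
$m$-match of its prefix), which changes the arithmetic performed but not
the set of decisions resolved.

If $\bar A$ or $\bar B$ is zero the estimator mirrors the exact
definition's fallback on the subsample scale, returning
$-\log(2 / (n_0 (n_0 - 1)))$ with `degenerate = TRUE`. The published
procedure leaves this case undefined; mirroring the exact convention keeps
the output finite and comparable.

### Drawing subsets: Hidden Shuffle

Uniform sampling of $n_0$ distinct indices from $1..N$ must not cost
$O(N)$, or it would erase the point of subsampling. `draw_subset()`
implements the Hidden Shuffle sequential sampler: it emits a sorted uniform
subset in $O(n_0)$ expected arithmetic operations and $O(n_0)$ memory. The
construction views a partial Fisher–Yates shuffle abstractly: (1) the
number of "high" source positions hit is simulated from independent
Bernoulli trials with decreasing success probabilities via geometric skips
with thinning; (2) those positions are realized as descending order
statistics of i.i.d. uniforms, a duplicated discrete position handing its
slot to an unspecified low item; (3) the remaining items form a uniform
subset of the low range, drawn by sequential inclusion. Output order is
ascending; pair counting is order-invariant, so no post-shuffle is applied.
Uniformity is tested two ways: exact chi-square over all 20 subsets of
$\binom{6}{3}$ at $2\times10^5$ draws, and marginal inclusion frequencies
at $N = 50$, $n_0 = 7$. A reference sampler (`method = "fisher_yates"`,
base R's `sample.int`) sits behind the same interface for
cross-validation. Both consume R's global RNG stream, so `set.seed()`
makes every estimate reproducible; `sampen(..., seed = )` sets and
restores the stream locally.

### Choosing n0 and n1

Two stock strategies are provided:

* **S1** (`strategy_s1()`): $n_0 = 2000$, $n_1 = 150$, independent of the
  series length — constant cost, and accurate enough that repeated-run
  errors are small compared to typical entropy values for $m = 4$.
* **S2** (`strategy_s2(N)`): $n_0 = \max(1024, \lfloor\sqrt N\rfloor)$,
  $n_1 = \max(1, \min(\lfloor 5 + \log_2 N\rfloor, \lfloor N/n_0\rfloor))$
  — total cost $O(N \log N)$, trading some accuracy on short series for
  scalability. The floor of 1024 on $n_0$ protects short series from
  under-sampling; the floor of 1 on $n_1$ guarantees at least one
  experiment.

For MIX($p$) benchmarks (below) a randomness-adaptive rule
$n_0 = 1000 + 3000p$, $n_1 = 80 + 70p$ keeps the relative error of the
estimate within about 2% across the whole $p$ range
(`relative_error_vs_p()`): more random series need more sampling because
their match counts are smaller and relatively noisier.

## Synthetic benchmarks

`mix_process(n, p)` generates the MIX($p$) family: a deterministic
12-periodic sine $x_j = \alpha^{-1/2}\sin(2\pi j/12)$ with
$\alpha = \frac{1}{12}\sum_{j=1}^{12}\sin^2(2\pi j/12) = \tfrac12$ (unit
variance over a period, amplitude $\sqrt 2$), an i.i.d. uniform noise
sequence $y_j$ on $[-\sqrt 3, \sqrt 3]$ (unit variance), and an
independent Bernoulli($p$) mask $z_j$:

$$m_j = (1 - z_j)\, x_j + z_j\, y_j.$$

$p$ tunes the series continuously from fully regular to fully random, which
makes MIX the standard stress test for regularity statistics. The noise
support and sine harmonic are arguments (`noise_halfwidth`, `harmonic`) so
alternative renderings of the process — e.g. a noise support of
$[-3, 3]$ — can be reproduced; the defaults keep both components at unit
variance, which is what makes a single $r$ on the unit-SD scale comparable
across $p$.

`pink_noise(n)` synthesizes $1/f$ noise spectrally: a white Gaussian
spectrum is scaled by $f^{-1/2}$, the DC term zeroed, inverse-transformed,
and rescaled to unit SD. Any synthesis with the right spectral slope would
do — only the entropy statistics of the signal matter here — and the test
suite checks the fitted log–log periodogram slope at $n = 2^{16}$ lies in
$[-1.2, -0.8]$.

What these generators deliberately do not emulate: nonstationarity,
measurement artifacts, missing samples, and the autocorrelation structure
of real physiological signals. Passing tests on MIX and $1/f$ noise
demonstrates correctness of the estimator and its error behaviour as
randomness varies, not clinical performance on any particular recording
type.

## The evaluation protocol

Because the estimator is randomized, accuracy is summarized over repeated
runs (default 50, configurable) against the exact value of the same
realization: `MeanErr` (the magnitude of the mean signed error — the signed
mean is retained in the report for inspection), `RMeanSqErr` (root mean
squared error), and the relative error `RMeanSqErr / SampEn`.
`convergence_surface()` maps these metrics over an $(n_0, n_1)$ grid; both
metrics shrink toward zero as either parameter grows, and the package's
acceptance checks assert a strict decrease from light $(400, 20)$ to heavy
$(4000, 250)$ sampling on a MIX(0.3) series of $n = 2^{14}$.

Problem sizes used in the shipped checks: the convergence and
randomness-ordering experiments run at $n = 2^{14}$ and the
relative-error experiment at $n = 2^{16}$, where exact ground truth is
computed by direct counting in seconds; these sizes exercise the same
estimator configurations that apply unchanged to $10^6$-sample recordings
(the estimator's cost does not grow with $n$, only the ground-truth
computation does). Output tables carry the series length used.

## Numerical and design choices

* **Tie-breaking at the tolerance**: matches use $\le r$ exactly; no
  epsilon is added. Counts are integers and are exact; the only floating
  arithmetic is the subtraction in the distance, so oracle comparisons in
  the tests demand bit-exact equality.
* **Degenerate inputs**: constant series have entropy 0 (all templates
  match); series with no matches return the degenerate fallback rather
  than `Inf`; constant series cannot be normalized (error, since `r` on
  the unit-SD scale is meaningless).
* **Variance formula domain**: the four-term closed form divides by
  $(N-2)(N-3)$; terms are skipped when their coefficient vanishes, which
  makes $n_0 \in \{2, 3\}$ usable (the third term drops) even when
  $N < 4$. The no-match boundary case $C_{n_0} = 0$ is reported with a
  note instead of violating the strict positivity bound, which presumes
  at least one match.
* **Seeds**: nothing draws from wall-clock entropy; every stochastic
  function either uses the ambient RNG stream or takes an explicit `seed`
  and restores the stream afterwards.
* **Counting kernels** are small C++ routines (the usual practice for
  SampEn tooling): sampled templates are gathered into a contiguous
  coordinate-major buffer so the pair loop streams through memory, and the
  first coordinate is screened before the full Chebyshev test. Exact
  counting of a $2^{16}$-sample series takes a few seconds; one MCSampEn
  run at S1 settings takes well under a second.

## Limitations

* Exact ground truth by direct counting is the only exact method shipped;
  tree- or box-assisted exact algorithms are out of scope.
* The estimator assumes a fixed, fully observed series; no streaming or
  multiscale variants.
* For highly regular series ($p \to 0$ in MIX terms) the exact entropy
  approaches 0 and the *relative* error of any estimator degrades even
  while absolute errors stay tiny; `relative_error_vs_p()` flags
  non-positive or degenerate ground truth instead of reporting a ratio.
* File input is plain text or CSV; physiological container formats (WFDB,
  EDF) should be converted externally, e.g. with the standard `rdsamp`
  tool, to one-value-per-line text.
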
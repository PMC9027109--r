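# mcsampen

Exact and Monte Carlo estimation of **sample entropy** (SampEn) for
univariate time series, aimed at the long recordings common in
physiological signal analysis (ECG, EEG, RR-interval series) where direct
computation is prohibitively slow.

## What it computes

For a series $u_1,\dots,u_n$, template length $m$ and tolerance $r$,
sample entropy is

$$\mathrm{SampEn}(u, m, r) \;=\; -\log\frac{B}{A},$$

where $A$ and $B$ count the unordered pairs of length-$m$ and
length-$(m{+}1)$ templates whose Chebyshev distance is at most $r$, over
the $N = n - m - 1$ templates of each length (when a count is zero, the
finite fallback $-\log(2/(N(N-1)))$ is returned and flagged). Small
values mean a regular, self-similar signal; large values an irregular one.

Exact counting costs $O(N^2)$. The package's core is **MCSampEn**, a Monte
Carlo estimator: draw $n_1$ uniform random subsets of $n_0$ template
indices (without replacement, via the $O(n_0)$ Hidden Shuffle sequential
sampler), count matched pairs inside each subset, average the counts, and
return $-\log(\bar B/\bar A)$. The subsample pair *rates* are exactly
unbiased and their variance is $C_{n_0}/n_0$ with a closed-form
$C_{n_0} < 1 + \tfrac{1}{2(n_0-1)}$ (implemented in `rate_variance()` and
verified by exhaustive enumeration), so the estimate converges as $n_0$ or
$n_1$ grows — at a cost $O(n_1 n_0^2)$ that is **independent of the series
length**.

Also included: the MIX($p$) and $1/f$-noise benchmark generators, a
repeated-run error-evaluation protocol (`error_metrics()`,
`convergence_surface()`, `relative_error_vs_p()`), an exhaustive subset
enumerator and closed-form moment formulas for verification, plain-text /
CSV readers, and a command-line front end (`inst/cli/mcsampen.R`).

## Worked example

```r
library(mcsampen)

x <- mix_process(2^14, p = 0.3, seed = 42)   # 30% noise / 70% periodic

exact <- sampen(x, m = 4, r = 0.15)          # direct O(N^2) counting
exact
#> Sample entropy (exact direct counting)
#>   m = 4, r = 0.15 (unit-SD scale), n = 16384, N = 16379 templates
#>   SampEn = 0.6334

mc <- sampen(x, m = 4, r = 0.15, method = "mc", seed = 1)  # strategy S1
summary(mc)
#> Monte Carlo sample entropy (MCSampEn)
#>   m = 4, r = 0.15 (unit-SD scale), n = 16384, N = 16379 templates
#>   n0 = 2000 sampled templates, n1 = 150 experiments, seed = 1
#>   SampEn = 0.626785
#>   mean subsample counts: a_bar = 13464.2, b_bar = 7194
#>   matched-pair rates:    a = 0.00336773, b = 0.0017994
#>   per-experiment entropy spread (finite cases): 0.601425 / 0.627367 / 0.655204 (quartiles)
#>   template-pair comparisons performed: 599,700,000
```

The exact value 0.6334 says this mixed signal sits between a pure sine
(entropy near 0) and pure noise (entropy well above 2 at these settings).
The Monte Carlo estimate 0.6268 agrees to within 0.007, and its cost —
the reported $150 \times 2000 \times 1999 \approx 6\times10^8$
template-pair comparisons — is *fixed*: it would be identical for a
series a thousand times longer, while exact counting grows quadratically
(about $5.5\times10^{11}$ pairs at $n = 2^{20}$). `plot(mc)` shows the
running estimate stabilizing across the 150 experiments.

From a shell:

```sh
Rscript inst/cli/mcsampen.R --input series.txt --m 4 --r 0.15 \
    --method mc --strategy s1 --seed 7
```

prints the entropy estimate on stdout; `--runs 50 --with-truth` adds
repeated-run error metrics against the exact value, and `--output
report.csv` writes a per-run provenance table.

## License

MIT.
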
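#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Chebyshev match test for two templates of length k starting at a and b.
// Early exit on the first coordinate exceeding r.
static inline bool cheb_match(const double* a, const double* b, int k, double r) {
    for (int l = 0; l < k; ++l) {
        double d = a[l] - b[l];
        if (d < 0) d = -d;
        if (d > r) return false;
    }
    return true;
}

// Unordered matched pairs among templates of length k starting at the given
// 0-based positions (Algorithm-style double loop, j > i).
// [[Rcpp::export]]
double cpp_range_count(NumericVector u, IntegerVector starts0, int k, double r) {
    const double* p = REAL(u);
    const int L = starts0.size();
    double count = 0;
    for (int i = 0; i < L; ++i) {
        const double* a = p + starts0[i];
        for (int j = i + 1; j < L; ++j) {
            if (cheb_match(a, p + starts0[j], k, r)) count += 1;
        }
    }
    return count;
}

// Fused pair counting for template lengths m and m+1 over a subset of start
// positions.  An (m+1)-match requires an m-match of the prefix, so the
// (m+1)-th coordinate only decides B after the m-prefix matches; both
// threshold decisions are resolved for every pair.  Returns
// (A, B, pairs_examined).
//
// The sampled templates are gathered into a contiguous coordinate-major
// buffer first: the double loop then streams sequentially through memory
// instead of chasing n0 random positions in a long series, and the first
// two coordinates are screened with a branch-light test the compiler can
// vectorize.
// [[Rcpp::export]]
NumericVector cpp_pair_counts_subset(NumericVector u, IntegerVector starts0,
                                     int m, double r) {
    const double* p = REAL(u);
    const int L = starts0.size();
    const int k = m + 1;
    // coordinate-major: coord[l * L + i] = u[starts0[i] + l]
    std::vector<double> coord((size_t)k * L);
    for (int l = 0; l < k; ++l) {
        double* cl = coord.data() + (size_t)l * L;
        for (int i = 0; i < L; ++i) cl[i] = p[starts0[i] + l];
    }
    const double* c0 = coord.data();
    double A = 0, B = 0;
    double examined = (double)L * (L - 1) / 2;  // every pair is examined
    for (int i = 0; i < L; ++i) {
        const double a0 = c0[i];
        for (int j = i + 1; j < L; ++j) {
            double d = a0 - c0[j];
            if (d < 0) d = -d;
            if (d > r) continue;
            bool ok = true;
            for (int l = 1; l < m; ++l) {
                double dl = coord[(size_t)l * L + i] - coord[(size_t)l * L + j];
                if (dl < 0) dl = -dl;
                if (dl > r) { ok = false; break; }
            }
            if (ok) {
                ++A;
                double dm = coord[(size_t)m * L + i] - coord[(size_t)m * L + j];
                if (dm < 0) dm = -dm;
                if (dm <= r) ++B;
            }
        }
        if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
    }
    return NumericVector::create(A, B, examined);
}

// Full-series counting over all N = n - m - 1 templates, with per-template
// tallies.  A_i/B_i count matches of template i (self excluded); totals are
// the halved sums, accumulated directly as unordered pairs.
// [[Rcpp::export]]
List cpp_pair_counts_full(NumericVector u, int m, double r) {
    const double* p = REAL(u);
    const R_xlen_t n = u.size();
    const R_xlen_t N = n - m - 1;
    IntegerVector Ai(N), Bi(N);
    int* ai = INTEGER(Ai);
    int* bi = INTEGER(Bi);
    double A = 0, B = 0;
    for (R_xlen_t i = 0; i < N; ++i) {
        const double* a = p + i;
        const double a0 = a[0];
        for (R_xlen_t j = i + 1; j < N; ++j) {
            const double* b = p + j;
            double d = a0 - b[0];
            if (d < 0) d = -d;
            if (d > r) continue;
            if (cheb_match(a + 1, b + 1, m - 1, r)) {
                ++A; ++ai[i]; ++ai[j];
                double dm = a[m] - b[m];
                if (dm < 0) dm = -dm;
                if (dm <= r) { ++B; ++bi[i]; ++bi[j]; }
            }
        }
        if ((i & 255) == 0) Rcpp::checkUserInterrupt();
    }
    return List::create(_["A"] = A, _["B"] = B, _["A_i"] = Ai, _["B_i"] = Bi,
                        _["N"] = (double)N);
}

// Hidden Shuffle: sequential uniform sampling of n distinct items from
// {1..N} in O(n) expected arithmetic operations, emitted ascending.
// Three phases over a conceptual partial Fisher-Yates shuffle:
//   1. count the "low picks" among independent Bernoulli trials with
//      p_i = (n-i)/(N-i) via geometric skips with thinning (p_i decreases
//      in i, so the current p is a valid envelope for later trials);
//   2. map descending order statistics of iid uniforms to discrete high
//      positions; a repeated position hands its slot to a hidden low item;
//   3. draw the remaining L items as a uniform L-subset of the n low
//      positions by sequential inclusion.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector cpp_hidden_shuffle(double N, int n) {
    std::vector<int> out;
    out.reserve(n);
    int H = 0;
    double i = 0;
    if (N > n) {
        H = n;
        while (i < n) {
            double q = 1.0 - (N - n) / (N - i);
            i += std::floor(std::log(unif_rand()) / std::log(1.0 - q));
            if (i < n) {
                double pi = 1.0 - (N - n) / (N - i);
                if (unif_rand() < pi / q) --H;  // low pick confirmed
            }
            i += 1;
        }
    }
    int L = n - H;
    double a = 1.0;
    while (H > 0) {
        double S_old = n + std::floor(a * (N - n));
        a *= std::pow(unif_rand(), 1.0 / H);
        double S = n + std::floor(a * (N - n));
        --H;
        if (S < S_old) {
            out.push_back((int)(N - 1 - S) + 1);  // fresh high item, 1-based
        } else {
            ++L;  // duplicate position: one more low item instead
        }
    }
    int nn = n;
    while (L > 0) {
        double u = unif_rand();
        int s = 0;
        double F = (double)L / nn;
        while (F < u && s < nn - L) {
            F = 1.0 - (1.0 - (double)L / (nn - s - 1)) * (1.0 - F);
            ++s;
        }
        --L;
        nn = nn - s - 1;
        out.push_back((int)(N - 1 - nn) + 1);
    }
    return IntegerVector(out.begin(), out.end());
}
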
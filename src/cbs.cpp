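#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Circular binary segmentation kernel.
//
// For an ordered vector x[0..m-1], a circular arc (i, j] (0 <= i < j <= m,
// excluding the full circle) is compared against its complement with a
// pooled-variance two-sample t statistic.  For a fixed data set the squared
// t is a strictly increasing function of the between-group sum of squares
//
//   B(i, j) = (R_j - R_i)^2 * m / (k * (m - k)),   k = j - i,
//
// where R_l is the partial-sum bridge R_l = S_l - l * S_m / m, because
// t^2 = B * (m - 2) / (C - B) with C = total centred sum of squares, and C
// is invariant under permutation.  The search and the permutation test are
// therefore carried out on B.
//
// min_width is the minimal number of markers any resulting linear piece may
// have; pieces of size zero (i == 0 or j == m) are allowed.

static inline void bridge(const std::vector<double> &x, std::vector<double> &R) {
    const int m = (int)x.size();
    double S = 0.0;
    for (int l = 0; l < m; ++l) S += x[l];
    const double mu = S / m;
    R[0] = 0.0;
    for (int l = 1; l <= m; ++l) R[l] = R[l - 1] + x[l - 1] - mu;
}

// Max of B over valid (i, j); returns best B, writes arc bounds.
// If stop_at > 0, the scan aborts early as soon as the running max exceeds
// stop_at (used inside the permutation loop: the permutation is already an
// exceedance).
static inline double scan_width(const std::vector<double> &R, int m, int k,
                                int min_width, double w, double best,
                                int *best_i, int *best_j) {
    for (int i = 0; i + k <= m; ++i) {
        if (i > 0 && i < min_width) continue;
        const int j = i + k;
        if (j < m && (m - j) < min_width) continue;
        const double d = R[j] - R[i];
        const double B = d * d * w;
        if (B > best) { best = B; *best_i = i; *best_j = j; }
    }
    return best;
}

// Exact max of B over valid (i, j).  Widths are visited from the edges of
// the admissible range inward, i.e. in non-increasing order of
// w(k) = m / (k (m - k)); since (R_j - R_i)^2 <= range(R)^2 for every pair,
// the scan stops exactly when range^2 * w(k) can no longer beat the
// current best (or, inside the permutation loop, the observed statistic
// `stop_at`: the remaining widths cannot change the exceedance verdict).
static double max_arc_B(const std::vector<double> &x, int min_width,
                        int *best_i, int *best_j, double stop_at,
                        std::vector<double> &R) {
    const int m = (int)x.size();
    *best_i = -1; *best_j = -1;
    if (m < 2 * min_width) return -1.0;
    bridge(x, R);
    double mx = R[0], mn = R[0];
    for (int l = 1; l <= m; ++l) {
        if (R[l] > mx) mx = R[l];
        if (R[l] < mn) mn = R[l];
    }
    const double range2 = (mx - mn) * (mx - mn);
    double best = -1.0;
    int klo = min_width, khi = m - min_width;
    while (klo <= khi) {
        const double wlo = (double)m / ((double)klo * (double)(m - klo));
        const double whi = (double)m / ((double)khi * (double)(m - khi));
        const int k = (wlo >= whi) ? klo : khi;
        const double w = (wlo >= whi) ? wlo : whi;
        // no remaining width can beat the current best (observed mode) or
        // reach the exceedance threshold (permutation mode): stop
        const double target = (stop_at > 0.0) ? stop_at : best;
        if (target >= 0.0 && range2 * w < target) break;
        best = scan_width(R, m, k, min_width, w, best, best_i, best_j);
        if (stop_at > 0.0 && best >= stop_at) return best;  // exceedance decided
        if (k == klo) ++klo; else --khi;
    }
    return best;
}

static double centred_ss(const std::vector<double> &x) {
    const int m = (int)x.size();
    double S = 0.0;
    for (int l = 0; l < m; ++l) S += x[l];
    const double mu = S / m;
    double C = 0.0;
    for (int l = 0; l < m; ++l) C += (x[l] - mu) * (x[l] - mu);
    return C;
}

// [[Rcpp::export(name = ".cbs_max_stat_cpp")]]
List cbs_max_stat_cpp(NumericVector x, int min_width) {
    const int m = x.size();
    std::vector<double> v(x.begin(), x.end());
    std::vector<double> R(m + 1);
    int bi, bj;
    double B = max_arc_B(v, min_width, &bi, &bj, -1.0, R);
    if (bi < 0)
        return List::create(_["i"] = -1, _["j"] = -1, _["B"] = NA_REAL,
                            _["t"] = NA_REAL);
    const double C = centred_ss(v);
    // signed pooled-variance t from B
    double S_arc = 0.0;
    for (int l = bi; l < bj; ++l) S_arc += v[l];
    double S_all = 0.0;
    for (int l = 0; l < m; ++l) S_all += v[l];
    const int k = bj - bi;
    const double m1 = S_arc / k, m2 = (S_all - S_arc) / (m - k);
    double t;
    const double W = C - B;                      // within-group SS
    if (W <= 1e-12 * std::max(C, 1.0)) {
        t = (m1 >= m2) ? R_PosInf : R_NegInf;
    } else {
        t = (m1 - m2 >= 0 ? 1.0 : -1.0) * std::sqrt(B * (m - 2) / W);
    }
    return List::create(_["i"] = bi, _["j"] = bj, _["B"] = B, _["t"] = t);
}

// Sequential permutation p-value for the max arc statistic.
//
// Stops as soon as the outcome is decided:
//  * non-significant: exceedances reach n_stop = ceil(alpha * (nperm + 1)),
//    after which the final p-value (exceed + 1) / (nperm + 1) cannot fall
//    below alpha;
//  * significant: after at least min_perm permutations, the conf_level
//    Clopper-Pearson upper bound on p is below alpha.
// With early = false all nperm permutations are always run.
// Uses R's RNG stream (so set.seed() governs reproducibility).
// [[Rcpp::export(name = ".cbs_perm_pvalue_cpp")]]
List cbs_perm_pvalue_cpp(NumericVector x, int min_width, double obs_B,
                         int nperm, double alpha, bool early,
                         int min_perm, double conf_level) {
    const int m = x.size();
    std::vector<double> v(x.begin(), x.end());
    std::vector<double> R(m + 1);
    RNGScope scope;
    const double thresh = obs_B * (1.0 - 1e-9);
    const int n_stop = (int)std::ceil(alpha * (nperm + 1));
    int exceed = 0, done = 0;
    bool decided = false, significant = false;
    for (int p = 0; p < nperm; ++p) {
        // Fisher-Yates shuffle
        for (int l = m - 1; l > 0; --l) {
            int idx = (int)(unif_rand() * (l + 1));
            if (idx > l) idx = l;
            std::swap(v[l], v[idx]);
        }
        int bi, bj;
        double B = max_arc_B(v, min_width, &bi, &bj, thresh, R);
        ++done;
        if (B >= thresh) ++exceed;
        if (early) {
            if (exceed >= n_stop) { decided = true; significant = false; break; }
            if (done >= min_perm && done % 100 == 0) {
                double ub = R::qbeta(conf_level, exceed + 1.0,
                                     (double)(done - exceed), 1, 0);
                if (ub < alpha) { decided = true; significant = true; break; }
            }
        }
    }
    double pval = (exceed + 1.0) / (done + 1.0);
    if (!decided) significant = (pval < alpha);
    return List::create(_["p"] = pval, _["nperm_done"] = done,
                        _["exceed"] = exceed, _["significant"] = significant);
}

// Exact permutation p-value by full enumeration of all m! orderings
// (m <= 9).  Returns the proportion of orderings whose max arc B reaches
// the observed one; the observed arrangement is included, so p >= 1/m!.
// [[Rcpp::export(name = ".cbs_exact_pvalue_cpp")]]
double cbs_exact_pvalue_cpp(NumericVector x, int min_width, double obs_B) {
    const int m = x.size();
    if (m > 9) stop("exact enumeration limited to m <= 9");
    std::vector<double> v(x.begin(), x.end());
    std::vector<int> idx(m);
    for (int l = 0; l < m; ++l) idx[l] = l;
    std::sort(idx.begin(), idx.end());
    std::vector<double> R(m + 1), w(m);
    const double thresh = obs_B * (1.0 - 1e-9);
    double total = 0.0, hits = 0.0;
    do {
        for (int l = 0; l < m; ++l) w[l] = v[idx[l]];
        int bi, bj;
        double B = max_arc_B(w, min_width, &bi, &bj, thresh, R);
        total += 1.0;
        if (B >= thresh) hits += 1.0;
    } while (std::next_permutation(idx.begin(), idx.end()));
    return hits / total;
}
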
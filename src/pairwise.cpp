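#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Weighted pairwise dissimilarities between the rows of x.
// kind: 0 = none (uniform), 1 = logarithm, 2 = threshold.
// metric: 0 = euclidean, 1 = squared_euclidean, 2 = cityblock.
// Weight normalization happens per pair (num / den); a pair whose raw
// weights are all zero falls back to uniform weights. The uniform and
// threshold raw weights use the exact constants 1.0 and beta so that
// degenerate parameter choices (threshold 0, beta = 1) reproduce the
// unweighted matrix bit for bit.
// [[Rcpp::export(name = ".pairwiseCoreCpp")]]
NumericMatrix pairwise_core_cpp(NumericMatrix x, NumericMatrix v,
                                int kind, double thr, double beta,
                                int metric) {
    int n = x.nrow(), S = x.ncol();
    NumericMatrix d(n, n);
    for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
            double num = 0.0, den = 0.0, plain = 0.0;
            for (int s = 0; s < S; ++s) {
                double diff = x(i, s) - x(j, s);
                double dev = (metric == 2) ? std::fabs(diff) : diff * diff;
                double r;
                if (kind == 0) {
                    r = 1.0;
                } else if (kind == 1) {
                    r = std::log(v(i, s) + v(j, s) + 1.0);
                } else {
                    r = (v(i, s) + v(j, s) >= thr) ? 1.0 : beta;
                }
                num += r * dev;
                den += r;
                plain += dev;
            }
            double val = (den > 0.0) ? num / den : plain / S;
            if (metric == 0) val = std::sqrt(val > 0.0 ? val : 0.0);
            d(i, j) = val;
            d(j, i) = val;
        }
    }
    return d;
}

// All upper-triangle pair coverage sums, per column: the empirical
// distribution the threshold quantile is resolved against.
// [[Rcpp::export(name = ".pairSumsCpp")]]
NumericVector pair_sums_cpp(NumericMatrix v) {
    int n = v.nrow(), S = v.ncol();
    R_xlen_t m = (R_xlen_t)n * (n - 1) / 2 * S;
    NumericVector out(m);
    R_xlen_t k = 0;
    for (int s = 0; s < S; ++s)
        for (int j = 1; j < n; ++j)
            for (int i = 0; i < j; ++i)
                out[k++] = v(i, s) + v(j, s);
    return out;
}
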
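#include <Rcpp.h>
using namespace Rcpp;

//' Permutation null of mean z for one gene-size class
//'
//' Draws \code{nperm} subsets of \code{size} values without replacement
//' from \code{pool} (partial Fisher-Yates) and returns the subset means.
//' Uses R's RNG, so results are reproducible under \code{set.seed()}.
//'
//' @param pool Numeric pool of guide z-values.
//' @param size Gene size (guides per draw).
//' @param nperm Number of permutation draws.
//' @return Numeric vector of \code{nperm} null means.
//' @export
// [[Rcpp::export]]
NumericVector perm_null_means(NumericVector pool, int size, int nperm) {
    int n = pool.size();
    if (size < 1 || size > n)
        stop("size must lie in [1, length(pool)]");
    if (nperm < 1)
        stop("nperm must be >= 1");
    std::vector<double> p(pool.begin(), pool.end());
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    NumericVector out(nperm);
    for (int k = 0; k < nperm; ++k) {
        double sum = 0.0;
        for (int j = 0; j < size; ++j) {
            // unif_rand() < 1, so pick lies in [j, n-1]
            int pick = j + (int)(unif_rand() * (n - j));
            std::swap(idx[j], idx[pick]);
            sum += p[idx[j]];
        }
        out[k] = sum / size;
    }
    return out;
}
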
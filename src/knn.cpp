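#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Exact k-nearest neighbors by blocked pairwise Euclidean distances.
//
// Rows of X are aggregated into blocks of `blockSize` rows; for each block Q
// the distance block is obtained from the expansion
//   d(q, x)^2 = ||q||^2 + ||x||^2 - 2 q.x
// so the dominant cost is one dense matrix product Q X^T per block and peak
// memory stays O(blockSize * n).  Negative round-off is clamped at zero.
// Ties are broken deterministically by the lower row index; self is excluded.
//
// Returns 1-based neighbor indices (n x k) and distances (n x k), each row
// sorted by increasing (distance, index).
// [[Rcpp::export(".knnBlockedCpp")]]
List knnBlockedCpp(const arma::mat& X, const int k, const int blockSize) {
    const arma::uword n = X.n_rows;
    if (X.n_cols == 0) stop("X must have at least one column");
    if (k < 1 || (arma::uword)k > n - 1) stop("k must satisfy 1 <= k <= n-1");
    if (blockSize < 1) stop("blockSize must be >= 1");

    arma::vec sq = arma::sum(arma::square(X), 1);
    IntegerMatrix idx(n, k);
    NumericMatrix dst(n, k);

    // running best-k per row, kept sorted ascending by (d2, index);
    // lexicographic comparison makes ties deterministic (lower index wins)
    std::vector<double> bd(k);
    std::vector<arma::uword> bi(k);

    for (arma::uword start = 0; start < n; start += (arma::uword)blockSize) {
        arma::uword end = std::min(n, start + (arma::uword)blockSize) - 1;
        // n x b orientation: one contiguous column per block row
        arma::mat Gt = X * X.rows(start, end).t();
        for (arma::uword r = start; r <= end; ++r) {
            const double* col = Gt.colptr(r - start);
            const double sqr = sq[r];
            int filled = 0;
            double worst = R_PosInf;
            arma::uword worstIdx = 0;
            for (arma::uword j = 0; j < n; ++j) {
                if (j == r) continue;
                double d2 = sqr + sq[j] - 2.0 * col[j];
                if (d2 < 0.0) d2 = 0.0;
                if (filled == k &&
                    (d2 > worst || (d2 == worst && j > worstIdx))) continue;
                // insert (d2, j) into the sorted best-k arrays
                int p = filled < k ? filled : k - 1;
                while (p > 0 && (bd[p - 1] > d2 ||
                                 (bd[p - 1] == d2 && bi[p - 1] > j))) {
                    bd[p] = bd[p - 1];
                    bi[p] = bi[p - 1];
                    --p;
                }
                bd[p] = d2;
                bi[p] = j;
                if (filled < k) ++filled;
                if (filled == k) { worst = bd[k - 1]; worstIdx = bi[k - 1]; }
            }
            for (int s = 0; s < k; ++s) {
                idx(r, s) = (int)bi[s] + 1;
                dst(r, s) = std::sqrt(bd[s]);
            }
        }
    }
    return List::create(_["idx"] = idx, _["dist"] = dst);
}

// One row block of the full pairwise Euclidean distance matrix, same
// expansion as above.  rows are 1-based and define the block Q.
// [[Rcpp::export(".distBlockCpp")]]
arma::mat distBlockCpp(const arma::mat& X, const arma::uvec& rows) {
    if (X.n_cols == 0) stop("X must have at least one column");
    arma::vec sq = arma::sum(arma::square(X), 1);
    arma::uvec r0 = rows - 1;
    arma::mat D2 = -2.0 * (X.rows(r0) * X.t());
    D2.each_row() += sq.t();
    D2.each_col() += sq(r0);
    D2.transform([](double v) { return v < 0.0 ? 0.0 : std::sqrt(v); });
    return D2;
}
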
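#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Exact k-nearest-neighbour search (Euclidean), chunked over query rows so
// that the full distance matrix is never materialized. Selection uses a
// bounded max-heap of (distance, index) pairs per query row.
// Returns 1-based indices into the reference rows, ordered by distance
// (ties broken by smaller index).
// [[Rcpp::export(name = ".knn_index_cpp")]]
IntegerMatrix knn_index_cpp(const arma::mat& query, const arma::mat& ref,
                            int k, int chunk = 1024) {
  const arma::uword nq = query.n_rows, nr = ref.n_rows;
  if ((arma::uword)k > nr) stop("k exceeds the number of reference points");
  IntegerMatrix out(nq, k);
  arma::vec ref_sq = arma::sum(arma::square(ref), 1);
  typedef std::pair<double, arma::uword> DI;  // (distance, index)
  std::vector<DI> heap;
  heap.reserve(k);
  for (arma::uword s = 0; s < nq; s += chunk) {
    arma::uword e = std::min(s + (arma::uword)chunk, nq) - 1;
    // squared distance up to the per-query constant: ||r||^2 - 2 q.r,
    // stored reference-major so each query's distances are contiguous
    arma::mat D = -2.0 * ref * query.rows(s, e).t();
    D.each_col() += ref_sq;
    for (arma::uword i = 0; i < D.n_cols; ++i) {
      const double* d = D.colptr(i);
      heap.clear();
      for (arma::uword j = 0; j < nr; ++j) {
        double dj = d[j];
        if ((int)heap.size() < k) {
          heap.emplace_back(dj, j);
          if ((int)heap.size() == k)
            std::make_heap(heap.begin(), heap.end());
        } else if (dj < heap.front().first ||
                   (dj == heap.front().first && j < heap.front().second)) {
          std::pop_heap(heap.begin(), heap.end());
          heap.back() = DI(dj, j);
          std::push_heap(heap.begin(), heap.end());
        }
      }
      std::sort(heap.begin(), heap.end());
      for (int j = 0; j < (int)heap.size(); ++j)
        out(s + i, j) = heap[j].second + 1;
    }
  }
  return out;
}
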
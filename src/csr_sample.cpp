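// Categorical sampling from the rows of a CSR similarity graph, used to
// draw positive partners proportional to mu[i, ]. Uses R's RNG so draws
// are reproducible under set.seed().
#include <Rcpp.h>

// row_ptr: 0-based offsets of length n+1 into col_idx/cumprob
// cumprob: within-row cumulative weights, last entry = row total
// anchors: 1-based row indices, possibly repeated
// returns 1-based sampled column index per anchor (0 if row empty) and
// the weight mu of the sampled edge
// [[Rcpp::export]]
Rcpp::List cpp_sample_positive(Rcpp::IntegerVector row_ptr,
                               Rcpp::IntegerVector col_idx,
                               Rcpp::NumericVector cumprob,
                               Rcpp::IntegerVector anchors,
                               int per_anchor) {
  int m = anchors.size();
  Rcpp::IntegerVector out(m * per_anchor);
  Rcpp::NumericVector w(m * per_anchor);
  int k = 0;
  for (int ai = 0; ai < m; ++ai) {
    int row = anchors[ai] - 1;
    int lo = row_ptr[row], hi = row_ptr[row + 1];
    for (int p = 0; p < per_anchor; ++p, ++k) {
      if (hi <= lo) {
        out[k] = 0;  // isolated anchor, caller filters
        w[k] = 0.0;
        continue;
      }
      double total = cumprob[hi - 1];
      double u = R::unif_rand() * total;
      // binary search for first cumprob >= u within [lo, hi)
      int l = lo, r = hi - 1;
      while (l < r) {
        int mid = (l + r) / 2;
        if (cumprob[mid] >= u)
          r = mid;
        else
          l = mid + 1;
      }
      out[k] = col_idx[l] + 1;
      w[k] = cumprob[l] - (l > lo ? cumprob[l - 1] : 0.0);
    }
  }
  return Rcpp::List::create(Rcpp::Named("idx") = out, Rcpp::Named("mu") = w);
}
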
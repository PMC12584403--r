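#include <Rcpp.h>
using namespace Rcpp;

// Monte Carlo sampler for absorbing random walks on a sparse row-stochastic
// chain stored in CSR form. Probabilities arrive pre-accumulated per row so a
// step is a single uniform draw plus a binary search. Uses R's RNG so that
// set.seed() in the calling R code makes ensembles bit-reproducible.
//
// rowptr:  length n+1, 0-based offsets into colind/cumprob
// colind:  0-based destination states
// cumprob: cumulative transition probabilities within each row (last == 1)
// fate:    per-state fate id, 0 for transient states, 1..K for absorbing
// starts:  0-based start states to sample uniformly
// [[Rcpp::export]]
List cpp_simulate_walks(IntegerVector rowptr, IntegerVector colind,
                        NumericVector cumprob, IntegerVector fate,
                        IntegerVector starts, int n_iter, int max_steps,
                        bool keep_paths) {
  int n_start = starts.size();
  IntegerVector out_fate(n_iter), out_steps(n_iter), out_start(n_iter);
  IntegerVector out_last(n_iter);
  List paths(keep_paths ? n_iter : 0);
  std::vector<int> buf;

  for (int w = 0; w < n_iter; ++w) {
    int s = starts[(int)(unif_rand() * n_start) % n_start];
    int cur = s;
    if (keep_paths) { buf.clear(); buf.push_back(cur + 1); }
    int step = 0;
    while (fate[cur] == 0 && step < max_steps) {
      int lo = rowptr[cur], hi = rowptr[cur + 1];
      double u = unif_rand();
      // binary search for first cumprob >= u in [lo, hi)
      int a = lo, b = hi - 1;
      while (a < b) {
        int mid = (a + b) / 2;
        if (cumprob[mid] < u) a = mid + 1; else b = mid;
      }
      cur = colind[a];
      ++step;
      if (keep_paths) buf.push_back(cur + 1);
    }
    out_fate[w] = fate[cur];  // 0 => unabsorbed (hit max_steps)
    out_steps[w] = step;
    out_start[w] = s + 1;
    out_last[w] = cur + 1;
    if (keep_paths) paths[w] = IntegerVector(buf.begin(), buf.end());
  }
  List res = List::create(_["fate"] = out_fate, _["steps"] = out_steps,
                          _["start"] = out_start, _["last"] = out_last);
  if (keep_paths) res["paths"] = paths;
  return res;
}
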
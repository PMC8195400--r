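#include <Rcpp.h>
using namespace Rcpp;

// Permutation engine shared by the permutation-based tests.
//
// For each of n_perm random permutations of the sample labels, accumulates,
// per variant, the sum of a value vector over carrier samples (indicator
// sums) and the dosage-weighted sum (for burden-style statistics). Carriers
// are sparse for rare variants, so each permutation costs O(N) for the
// shuffle plus O(nnz) for the accumulation, instead of O(N * k).
//
// carrier_idx: list of integer vectors, 0-based sample indices with dosage>0
// carrier_dos: list of numeric vectors, dosages at those samples
// values:      N x V matrix of value vectors (e.g. centered phenotype,
//              centered ranks); one shared permutation per replicate is
//              applied to every column so statistics computed from different
//              columns see the same relabelling
// returns list with elements ind[[v]] and dos[[v]], each k x n_perm
//
// Uses R's RNG (unif_rand), so results are reproducible under set.seed().

// [[Rcpp::export(name = ".perm_carrier_sums", rng = false)]]
List perm_carrier_sums(List carrier_idx, List carrier_dos,
                       NumericMatrix values, int n_perm) {
  GetRNGstate();
  const int N = values.nrow();
  const int V = values.ncol();
  const int k = carrier_idx.size();

  std::vector<std::vector<int> > idx(k);
  std::vector<std::vector<double> > dos(k);
  for (int i = 0; i < k; ++i) {
    IntegerVector ii = carrier_idx[i];
    NumericVector dd = carrier_dos[i];
    idx[i].assign(ii.begin(), ii.end());
    dos[i].assign(dd.begin(), dd.end());
  }

  List ind_out(V), dos_out(V);
  std::vector<NumericMatrix> S(V), D(V);
  for (int v = 0; v < V; ++v) {
    S[v] = NumericMatrix(k, n_perm);
    D[v] = NumericMatrix(k, n_perm);
  }

  std::vector<int> perm(N);
  for (int j = 0; j < N; ++j) perm[j] = j;

  for (int b = 0; b < n_perm; ++b) {
    // Fisher-Yates shuffle with R's RNG
    for (int j = N - 1; j > 0; --j) {
      int u = (int)(unif_rand() * (j + 1));
      if (u > j) u = j;
      std::swap(perm[j], perm[u]);
    }
    for (int v = 0; v < V; ++v) {
      const double *val = &values(0, v);
      double *Scol = &S[v](0, b);
      double *Dcol = &D[v](0, b);
      for (int i = 0; i < k; ++i) {
        double si = 0.0, di = 0.0;
        const std::vector<int> &ci = idx[i];
        const std::vector<double> &gi = dos[i];
        for (size_t t = 0; t < ci.size(); ++t) {
          double x = val[perm[ci[t]]];
          si += x;
          di += gi[t] * x;
        }
        Scol[i] = si;
        Dcol[i] = di;
      }
    }
  }

  PutRNGstate();
  for (int v = 0; v < V; ++v) {
    ind_out[v] = S[v];
    dos_out[v] = D[v];
  }
  return List::create(_["ind"] = ind_out, _["dos"] = dos_out);
}
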
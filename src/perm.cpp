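#include <Rcpp.h>
using namespace Rcpp;

// Permutation null for the genotypic-LD G-test. Genotype dosages are in
// {0,1,2}; margins (and hence expected counts) are invariant under
// permutation of one locus's labels, so expecteds are precomputed once.
// Uses R's RNG (seeded by the caller) for reproducibility.
// [[Rcpp::export]]
List g_test_perm_cpp(IntegerVector a, IntegerVector b, int n_perm) {
  const int n = a.size();
  if (b.size() != n) stop("length mismatch");
  int ra[3] = {0, 0, 0}, cb[3] = {0, 0, 0};
  for (int i = 0; i < n; ++i) {
    if (a[i] < 0 || a[i] > 2 || b[i] < 0 || b[i] > 2) stop("dosages must be 0, 1 or 2");
    ++ra[a[i]];
    ++cb[b[i]];
  }
  double e[9];
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c) e[3 * r + c] = (double)ra[r] * cb[c] / n;

  int obs[9] = {0};
  for (int i = 0; i < n; ++i) ++obs[3 * a[i] + b[i]];
  double g_obs = 0.0;
  for (int j = 0; j < 9; ++j)
    if (obs[j] > 0) g_obs += obs[j] * std::log(obs[j] / e[j]);
  g_obs *= 2.0;

  std::vector<int> perm(b.begin(), b.end());
  const double thr = g_obs - 1e-9;  // count ties as exceedances
  int count = 0;
  for (int s = 0; s < n_perm; ++s) {
    for (int i = n - 1; i > 0; --i) {  // Fisher-Yates
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    int cnt[9] = {0};
    for (int i = 0; i < n; ++i) ++cnt[3 * a[i] + perm[i]];
    double g = 0.0;
    for (int j = 0; j < 9; ++j)
      if (cnt[j] > 0) g += cnt[j] * std::log(cnt[j] / e[j]);
    g *= 2.0;
    if (g >= thr) ++count;
  }
  return List::create(_["g_obs"] = g_obs, _["count"] = count);
}

// Sums of uniformly random k-subsets (without replacement) of w, via
// partial Fisher-Yates. Null distribution for the module-score
// normalization.
// [[Rcpp::export]]
NumericVector subset_sums_cpp(NumericVector w, int k, int n_perm) {
  const int n = w.size();
  if (k < 1 || k > n) stop("k out of range");
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  NumericVector out(n_perm);
  for (int s = 0; s < n_perm; ++s) {
    double sum = 0.0;
    for (int i = 0; i < k; ++i) {
      int j = i + (int)(unif_rand() * (n - i));
      if (j >= n) j = n - 1;
      std::swap(idx[i], idx[j]);
      sum += w[idx[i]];
    }
    out[s] = sum;
  }
  return out;
}
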
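#include <Rcpp.h>
using namespace Rcpp;

// Pairwise r2 between 0/1 marker vectors and permutation significance.
// r2 is the squared Pearson correlation over genotypes non-missing at
// both markers; permutations shuffle one marker's complete-case calls.

static inline double r2_from_counts(long n, long na, long nb, long n11) {
  double num = (double)n * n11 - (double)na * nb;
  double den = (double)na * (n - na) * (double)nb * (n - nb);
  if (den <= 0.0) return NA_REAL;   // monomorphic column
  return (num * num) / den;
}

// [[Rcpp::export(name = ".pair_r2_perm")]]
List pair_r2_perm(IntegerMatrix x, IntegerVector ia, IntegerVector ib,
                  int n_perm) {
  const int n = x.nrow();
  const int np = ia.size();
  NumericVector r2(np), pval(np);
  IntegerVector ncomp(np);
  std::vector<int> a(n), b(n);

  for (int t = 0; t < np; ++t) {
    const int ca = ia[t] - 1, cb = ib[t] - 1;
    int m = 0;
    long na = 0, nb = 0, n11 = 0;
    for (int i = 0; i < n; ++i) {
      int xa = x(i, ca), xb = x(i, cb);
      if (xa == NA_INTEGER || xb == NA_INTEGER) continue;
      a[m] = xa; b[m] = xb; ++m;
      na += xa; nb += xb;
      if (xa == 1 && xb == 1) ++n11;
    }
    ncomp[t] = m;
    double obs = m >= 2 ? r2_from_counts(m, na, nb, n11) : NA_REAL;
    r2[t] = obs;
    if (!R_finite(obs) || n_perm <= 0) { pval[t] = NA_REAL; continue; }

    int ge = 0;
    for (int s = 0; s < n_perm; ++s) {
      // Fisher-Yates shuffle of a[0..m-1]
      for (int i = m - 1; i > 0; --i) {
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(a[i], a[j]);
      }
      long p11 = 0;
      for (int i = 0; i < m; ++i)
        if (a[i] == 1 && b[i] == 1) ++p11;
      double rp = r2_from_counts(m, na, nb, p11);
      if (rp >= obs - 1e-12) ++ge;
    }
    pval[t] = (1.0 + ge) / (1.0 + n_perm);
  }
  return List::create(_["r2"] = r2, _["p"] = pval, _["n"] = ncomp);
}
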
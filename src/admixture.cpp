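#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the admixture model on haploid-scored dominant markers.
//
// Data model, per genotype i and marker l (missing cells skipped):
//   z_il | q_i        ~ Categorical(q_i)          latent population of origin
//   x_il | z_il = k   ~ Bernoulli(p_kl)           band presence
//   p_kl              ~ Beta(1, 1)
//   q_i               ~ Dirichlet(alpha, ..., alpha)
//   alpha             ~ Uniform(0, alpha_max], updated by a reflected
//                       Metropolis random walk (normal proposal).
//
// Recorded per kept iteration: the data log-likelihood with the latent
// origins integrated out, sum_il log sum_k q_ik Pr(x_il | p_kl) (the
// quantity STRUCTURE reports as Ln Like), the alpha value, and running
// sums of q and p for posterior means.

// [[Rcpp::export(name = ".admixture_gibbs")]]
List admixture_gibbs(IntegerMatrix x, int K, int burnin, int iters, int thin,
                     double alpha_init, double alpha_sd, double alpha_max) {
  const int n = x.nrow(), L = x.ncol();
  if (K < 1) stop("K must be >= 1");

  RNGScope scope;

  NumericMatrix q(n, K);
  NumericMatrix p(K, L);
  IntegerMatrix z(n, L);
  std::fill(q.begin(), q.end(), 1.0 / K);
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l) p(k, l) = R::rbeta(1.0, 1.0);

  double alpha = alpha_init;
  int n_rec = iters / thin;
  if (n_rec < 1) n_rec = 1;
  NumericVector loglik_rec(n_rec), alpha_rec(n_rec);
  NumericMatrix q_sum(n, K);
  NumericMatrix p_sum(K, L);
  int rec = 0, alpha_acc = 0, alpha_try = 0;

  std::vector<double> w(K);
  std::vector<int> n1(K * L), n0(K * L), m(n * K);

  const int total = burnin + iters;
  for (int it = 0; it < total; ++it) {
    // --- z update (and sufficient statistics for p, q) ---
    std::fill(n1.begin(), n1.end(), 0);
    std::fill(n0.begin(), n0.end(), 0);
    std::fill(m.begin(), m.end(), 0);
    for (int i = 0; i < n; ++i) {
      for (int l = 0; l < L; ++l) {
        int xi = x(i, l);
        if (xi == NA_INTEGER) { z(i, l) = NA_INTEGER; continue; }
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          double lik = xi == 1 ? p(k, l) : 1.0 - p(k, l);
          w[k] = q(i, k) * lik;
          tot += w[k];
        }
        int zk = K - 1;
        if (tot > 0.0) {
          double u = unif_rand() * tot, cum = 0.0;
          for (int k = 0; k < K; ++k) {
            cum += w[k];
            if (u <= cum) { zk = k; break; }
          }
        } else {
          zk = (int)(unif_rand() * K);
          if (zk >= K) zk = K - 1;
        }
        z(i, l) = zk;
        if (xi == 1) n1[zk * L + l]++; else n0[zk * L + l]++;
        m[i * K + zk]++;
      }
    }

    // --- p update: Beta(1 + n1, 1 + n0) ---
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l)
        p(k, l) = R::rbeta(1.0 + n1[k * L + l], 1.0 + n0[k * L + l]);

    // --- q update: Dirichlet(alpha + m_i) ---
    if (K == 1) {
      for (int i = 0; i < n; ++i) q(i, 0) = 1.0;
    } else {
      for (int i = 0; i < n; ++i) {
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          double g = R::rgamma(alpha + m[i * K + k], 1.0);
          q(i, k) = g;
          tot += g;
        }
        if (tot <= 0.0) {
          for (int k = 0; k < K; ++k) q(i, k) = 1.0 / K;
        } else {
          for (int k = 0; k < K; ++k) q(i, k) /= tot;
        }
      }

      // --- alpha update: reflected Metropolis random walk ---
      alpha_try++;
      double prop = alpha + norm_rand() * alpha_sd;
      if (prop < 0.0) prop = -prop;            // reflect at 0
      if (prop > 0.0 && prop <= alpha_max) {
        double slogq = 0.0;
        for (int i = 0; i < n; ++i)
          for (int k = 0; k < K; ++k)
            slogq += std::log(std::max(q(i, k), 1e-300));
        double lr = n * (R::lgammafn(K * prop) - K * R::lgammafn(prop))
                  - n * (R::lgammafn(K * alpha) - K * R::lgammafn(alpha))
                  + (prop - alpha) * slogq;
        if (std::log(unif_rand()) < lr) { alpha = prop; alpha_acc++; }
      }
    }

    // --- record ---
    if (it >= burnin) {
      int post = it - burnin;
      if ((post + 1) % thin == 0 && rec < n_rec) {
        double ll = 0.0;
        for (int i = 0; i < n; ++i)
          for (int l = 0; l < L; ++l) {
            int xi = x(i, l);
            if (xi == NA_INTEGER) continue;
            double lik = 0.0;
            for (int k = 0; k < K; ++k)
              lik += q(i, k) * (xi == 1 ? p(k, l) : 1.0 - p(k, l));
            ll += std::log(std::max(lik, 1e-300));
          }
        loglik_rec[rec] = ll;
        alpha_rec[rec] = alpha;
        for (int i = 0; i < n; ++i)
          for (int k = 0; k < K; ++k) q_sum(i, k) += q(i, k);
        for (int k = 0; k < K; ++k)
          for (int l = 0; l < L; ++l) p_sum(k, l) += p(k, l);
        rec++;
      }
    }
  }

  if (rec == 0) stop("no iterations recorded; increase iters or lower thin");
  for (int i = 0; i < n; ++i) {
    double tot = 0.0;
    for (int k = 0; k < K; ++k) tot += q_sum(i, k);
    for (int k = 0; k < K; ++k) q_sum(i, k) /= tot;
  }
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l) p_sum(k, l) /= rec;

  return List::create(_["q"] = q_sum, _["p"] = p_sum,
                      _["loglik"] = loglik_rec[Range(0, rec - 1)],
                      _["alpha"] = alpha_rec[Range(0, rec - 1)],
                      _["alpha_accept"] =
                        alpha_try > 0 ? (double)alpha_acc / alpha_try : NA_REAL);
}
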
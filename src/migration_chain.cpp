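// MCMC kernel for the first-generation-migrant assignment model.
// Latent origins are updated by random-scan collapsed Gibbs under the
// leave-one-out Dirichlet-multinomial predictive likelihood; migrant-rate
// rows by conjugate Dirichlet Gibbs (with the Rao-Blackwellized conditional
// mean accumulated for the posterior mean); per-population inbreeding F by
// random-walk Metropolis on the logit scale with a Beta(1,5) prior.
// Uses R's RNG so chains are reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static inline double geno_loglik(int a1, int a2, double p1, double p2, double f) {
  if (a1 == a2) return std::log(p1 * p1 * (1.0 - f) + p1 * f);
  return std::log(2.0 * p1 * p2 * (1.0 - f));
}

// [[Rcpp::export(name = ".migration_chain_cpp")]]
List migration_chain_cpp(IntegerMatrix flat1, IntegerMatrix flat2,
                         IntegerVector n_alleles, IntegerVector home,
                         int R, int jmax, int n_samples, int burnin, int thin) {
  const int n = flat1.nrow(), L = flat1.ncol();
  const int ncell = L * jmax;  // flat indices are 1-based into (L*jmax)

  std::vector<std::vector<int>> C(R, std::vector<int>(ncell, 0));
  std::vector<std::vector<int>> T(R, std::vector<int>(L, 0));
  std::vector<int> origin(n);
  for (int i = 0; i < n; ++i) origin[i] = home[i] - 1;

  auto bump = [&](int i, int s, int d) {
    for (int l = 0; l < L; ++l) {
      int f1 = flat1(i, l);
      if (f1 == NA_INTEGER) continue;
      C[s][f1 - 1] += d;
      C[s][flat2(i, l) - 1] += d;
      T[s][l] += 2 * d;
    }
  };
  for (int i = 0; i < n; ++i) bump(i, origin[i], 1);

  std::vector<double> F(R, 0.1);
  NumericMatrix m(R, R), mrb(R, R);
  std::fill(m.begin(), m.end(), 1.0 / R);
  std::fill(mrb.begin(), mrb.end(), 1.0 / R);
  NumericMatrix logm(R, R);
  for (int j = 0; j < R * R; ++j) logm[j] = std::log(m[j]);

  const int total = burnin + n_samples;
  std::vector<int> keep;
  for (int sw = burnin; sw < total; sw += thin) keep.push_back(sw);
  NumericMatrix traces(keep.size(), R * R);
  NumericMatrix rb_sum(R, R);
  std::vector<double> f_sum(R, 0.0);
  int kept = 0;
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::vector<double> lp(R), w(R);

  for (int sw = 0; sw < total; ++sw) {
    // random scan order (Fisher-Yates with R's RNG)
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(ord[i], ord[j]);
    }
    for (int k = 0; k < n; ++k) {
      const int i = ord[k];
      bump(i, origin[i], -1);
      double mx = -1e300;
      for (int s = 0; s < R; ++s) {
        double ll = logm(home[i] - 1, s);
        const double f = F[s];
        for (int l = 0; l < L; ++l) {
          const int f1 = flat1(i, l);
          if (f1 == NA_INTEGER) continue;
          const int f2 = flat2(i, l);
          const double den = n_alleles[l] + T[s][l];
          const double p1 = (1.0 + C[s][f1 - 1]) / den;
          const double p2 = (1.0 + C[s][f2 - 1]) / den;
          ll += geno_loglik(f1, f2, p1, p2, f);
        }
        lp[s] = ll;
        if (ll > mx) mx = ll;
      }
      double tot = 0.0;
      for (int s = 0; s < R; ++s) { w[s] = std::exp(lp[s] - mx); tot += w[s]; }
      double u = unif_rand() * tot, cum = 0.0;
      int news = R - 1;
      for (int s = 0; s < R; ++s) { cum += w[s]; if (u <= cum) { news = s; break; } }
      origin[i] = news;
      bump(i, news, 1);
    }
    // m rows: conjugate Gibbs + Rao-Blackwellized conditional mean
    for (int r = 0; r < R; ++r) {
      std::vector<int> cnt(R, 0);
      int nr = 0;
      for (int i = 0; i < n; ++i) if (home[i] - 1 == r) { cnt[origin[i]]++; nr++; }
      double tot = 0.0;
      std::vector<double> g(R);
      for (int s = 0; s < R; ++s) { g[s] = R::rgamma(1.0 + cnt[s], 1.0); tot += g[s]; }
      for (int s = 0; s < R; ++s) {
        m(r, s) = g[s] / tot;
        logm(r, s) = std::log(m(r, s));
        mrb(r, s) = (1.0 + cnt[s]) / (double)(R + nr);
      }
    }
    // F: random-walk Metropolis on logit scale, Beta(1,5) prior
    for (int s = 0; s < R; ++s) {
      bool any = false;
      for (int i = 0; i < n; ++i) if (origin[i] == s) { any = true; break; }
      if (!any) { F[s] = R::rbeta(1.0, 5.0); continue; }
      const double cur = F[s];
      const double lo = std::log(cur / (1.0 - cur)) + norm_rand() * 0.5;
      const double prop = 1.0 / (1.0 + std::exp(-lo));
      double dll = 4.0 * (std::log(1.0 - prop) - std::log(1.0 - cur));
      for (int i = 0; i < n; ++i) {
        if (origin[i] != s) continue;
        for (int l = 0; l < L; ++l) {
          const int f1 = flat1(i, l);
          if (f1 == NA_INTEGER) continue;
          const int f2 = flat2(i, l);
          const double den = n_alleles[l] + T[s][l];
          const double p1 = (1.0 + C[s][f1 - 1]) / den;
          const double p2 = (1.0 + C[s][f2 - 1]) / den;
          dll += geno_loglik(f1, f2, p1, p2, prop) - geno_loglik(f1, f2, p1, p2, cur);
        }
      }
      const double jac = std::log(prop * (1.0 - prop)) - std::log(cur * (1.0 - cur));
      if (std::log(unif_rand()) < dll + jac) F[s] = prop;
    }
    // record
    if (sw >= burnin && ((sw - burnin) % thin == 0)) {
      for (int j = 0; j < R * R; ++j) {
        traces(kept, j) = m[j];
        rb_sum[j] += mrb[j];
      }
      for (int s = 0; s < R; ++s) f_sum[s] += F[s];
      kept++;
    }
  }
  for (int j = 0; j < R * R; ++j) rb_sum[j] /= kept;
  NumericVector fm(R);
  for (int s = 0; s < R; ++s) fm[s] = f_sum[s] / kept;
  return List::create(_["m_mean"] = rb_sum, _["traces"] = traces,
                      _["F_mean"] = fm, _["n_kept"] = kept);
}
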
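#include <Rcpp.h>
using namespace Rcpp;

// One collapsed Gibbs chain over per-read source assignments for a
// single sink sample.
//
// x: 0-based taxon index of each sink read (length N)
// m: V x T training counts of the known source environments; the
//    Unknown environment is component V (no training counts).
// Per-read full conditional for environment v given all other reads:
//   p(v | ...) ~ p(x_i | v) * (n^-i[v] + beta)
// with p(x_i | v) = (m[v,t] + n^-i[v,t] + alpha1) /
//                   (m[v]   + n^-i[v]   + T*alpha1)   for known v
// (training counts only if training_only), and the same form with
// m = 0, alpha2 for Unknown.
//
// Uses R's RNG: the caller controls determinism through set.seed().
// Returns an ndraws x (V+1) matrix of assigned-read counts per
// environment, recorded after `burnin` full sweeps and then every
// `thin` sweeps.
// [[Rcpp::export]]
IntegerMatrix gibbs_chain_cpp(IntegerVector x, NumericMatrix m,
                              double alpha1, double alpha2, double beta,
                              int burnin, int ndraws, int thin,
                              bool training_only) {
  const int N = x.size();
  const int V = m.nrow();
  const int T = m.ncol();
  const int E = V + 1;

  std::vector<double> mv(V, 0.0);
  for (int v = 0; v < V; ++v)
    for (int t = 0; t < T; ++t) mv[v] += m(v, t);

  std::vector<int> z(N);
  std::vector<int> n(E * T, 0);   // n[v + E*t]
  std::vector<double> nv(E, 0.0);
  for (int i = 0; i < N; ++i) {
    int v = (int)(unif_rand() * E);
    if (v >= E) v = E - 1;
    z[i] = v;
    n[v + E * x[i]] += 1;
    nv[v] += 1.0;
  }

  IntegerMatrix draws(ndraws, E);
  std::vector<double> p(E);
  int drawn = 0;
  const double Ta1 = T * alpha1, Ta2 = T * alpha2;

  for (int sweep = 0; drawn < ndraws; ++sweep) {
    for (int i = 0; i < N; ++i) {
      const int t = x[i];
      const int vz = z[i];
      n[vz + E * t] -= 1;
      nv[vz] -= 1.0;
      double tot = 0.0;
      for (int v = 0; v < V; ++v) {
        double num = m(v, t) + alpha1;
        double den = mv[v] + Ta1;
        if (!training_only) {
          num += n[v + E * t];
          den += nv[v];
        }
        p[v] = num / den * (nv[v] + beta);
        tot += p[v];
      }
      p[V] = (n[V + E * t] + alpha2) / (nv[V] + Ta2) * (nv[V] + beta);
      tot += p[V];
      double u = unif_rand() * tot;
      int vnew = 0;
      double acc = p[0];
      while (u > acc && vnew < E - 1) acc += p[++vnew];
      z[i] = vnew;
      n[vnew + E * t] += 1;
      nv[vnew] += 1.0;
    }
    const int s1 = sweep + 1;
    const int b = burnin > 0 ? burnin : 1;
    if (s1 >= b && (s1 - b) % thin == 0) {
      for (int v = 0; v < E; ++v) draws(drawn, v) = (int)nv[v];
      ++drawn;
    }
  }
  return draws;
}
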
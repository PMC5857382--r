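#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <utility>
using namespace Rcpp;

// Coordinate-descent core of the joint sparse partial-correlation
// regression, for a fixed precision-diagonal estimate sii. Operates on the
// Gram matrix G = X X' of standardized gene rows; M[i][k] tracks
// <sum_j beta_ij x_j, x_k> and is updated rank-one per accepted move.
// Active shooting: full sweeps over all pairs alternate with cheap sweeps
// over the currently nonzero pairs.

// When support_only is true the sweep is restricted to the pairs nonzero in
// rho_init (used for the relaxed, debiasing refit at lambda = 0).

// [[Rcpp::export(name = ".space_cd")]]
List space_cd(const NumericMatrix& G, const NumericVector& sii,
              const NumericVector& w, double lambda,
              const NumericMatrix& rho_init, double tol,
              int max_full_sweeps, bool support_only) {
  const int p = G.nrow();
  NumericMatrix rho = clone(rho_init);
  std::vector<double> M((size_t) p * p, 0.0);

  // initialise M from rho_init (beta_ij = rho_ij sqrt(sii_j / sii_i))
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j) {
      if (i == j || rho(i, j) == 0.0) continue;
      double b = rho(i, j) * std::sqrt(sii[j] / sii[i]);
      for (int k = 0; k < p; ++k) M[(size_t) i * p + k] += b * G(j, k);
    }

  typedef std::pair<int, int> ij;
  std::vector<ij> all;
  all.reserve((size_t) p * (p - 1) / 2);
  for (int i = 0; i < p - 1; ++i)
    for (int j = i + 1; j < p; ++j)
      if (!support_only || rho_init(i, j) != 0.0) all.push_back(ij(i, j));
  if (all.empty()) {
    NumericVector rss0(p);
    for (int i = 0; i < p; ++i) rss0[i] = G(i, i);
    return List::create(_["rho"] = rho, _["rss"] = rss0,
                        _["n_full_sweeps"] = 0);
  }

  auto sweep = [&](const std::vector<ij>& idx) -> double {
    double dmax = 0.0;
    for (size_t r = 0; r < idx.size(); ++r) {
      const int i = idx[r].first, j = idx[r].second;
      const double a_ij = std::sqrt(sii[j] / sii[i]), a_ji = 1.0 / a_ij;
      const double cur = rho(i, j);
      const double ri = G(i, j) - M[(size_t) i * p + j] + cur * a_ij * G(j, j);
      const double rj = G(j, i) - M[(size_t) j * p + i] + cur * a_ji * G(i, i);
      const double S = w[i] * a_ij * ri + w[j] * a_ji * rj;
      const double D = w[i] * a_ij * a_ij * G(j, j) +
                       w[j] * a_ji * a_ji * G(i, i);
      double nv = 0.0;
      const double soft = std::fabs(S) - lambda;
      if (soft > 0.0) nv = (S > 0.0 ? soft : -soft) / D;
      if (nv != cur) {
        rho(i, j) = nv;
        rho(j, i) = nv;
        const double di = (nv - cur) * a_ij, dj = (nv - cur) * a_ji;
        double* Mi = &M[(size_t) i * p];
        double* Mj = &M[(size_t) j * p];
        for (int k = 0; k < p; ++k) {
          Mi[k] += di * G(j, k);
          Mj[k] += dj * G(i, k);
        }
        const double d = std::fabs(nv - cur);
        if (d > dmax) dmax = d;
      }
    }
    return dmax;
  };

  int full = 0;
  double d_full = R_PosInf;
  while (true) {
    if (++full > max_full_sweeps)
      stop("SPACE did not converge after %d full sweeps (last max change %g)",
           max_full_sweeps, d_full);
    d_full = sweep(all);
    long act_iter = 0;
    while (true) {
      std::vector<ij> act;
      for (int i = 0; i < p - 1; ++i)
        for (int j = i + 1; j < p; ++j)
          if (rho(i, j) != 0.0) act.push_back(ij(i, j));
      if (act.empty()) break;
      if (++act_iter > 1000000L)
        stop("SPACE active-set sweeps did not converge (max change %g)",
             d_full);
      if (sweep(act) < tol) break;
      Rcpp::checkUserInterrupt();
    }
    if (d_full < tol) break;
  }

  // residual sums of squares under the final rho (beta recomputed clean)
  NumericVector rss(p);
  for (int i = 0; i < p; ++i) {
    std::vector<double> Mi(p, 0.0);
    for (int j = 0; j < p; ++j) {
      if (i == j || rho(i, j) == 0.0) continue;
      const double b = rho(i, j) * std::sqrt(sii[j] / sii[i]);
      for (int k = 0; k < p; ++k) Mi[k] += b * G(j, k);
    }
    double cross = 0.0;
    for (int j = 0; j < p; ++j) {
      if (i == j || rho(i, j) == 0.0) continue;
      const double b = rho(i, j) * std::sqrt(sii[j] / sii[i]);
      cross += b * Mi[j];
    }
    rss[i] = G(i, i) - 2.0 * Mi[i] + cross;
  }

  return List::create(_["rho"] = rho, _["rss"] = rss,
                      _["n_full_sweeps"] = full);
}
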
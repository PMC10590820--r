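#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Hit-and-run chain over {v : v = NB*alpha (null space of S), lb <= v <= ub}.
// Directions alternate between artificial-centering moves (towards a stored
// point) and range-scaled random directions projected on the null space.
// Uses R's RNG so runs are reproducible under set.seed().
// [[Rcpp::export(name = ".achr_chain_cpp")]]
List achr_chain_cpp(const arma::mat &NB, const arma::vec &lb, const arma::vec &ub,
                    const arma::vec &x0, const arma::mat &warmup,
                    const arma::vec &range, int n_points, int thin, int burn_in) {
  const int n = NB.n_rows;
  const int maxpool = 4 * warmup.n_cols;
  arma::mat pool(n, maxpool);
  pool.cols(0, warmup.n_cols - 1) = warmup;
  int npool = warmup.n_cols;

  arma::vec x = x0, center = arma::mean(warmup, 1);
  arma::mat out(n, n_points);
  int kept = 0, it = 0, rejects = 0;
  const int total = burn_in + n_points * thin;
  const int itmax = 50 * total + 1000;

  RNGScope scope;
  while (kept < n_points) {
    if (++it > itmax) stop("sampler failed to advance");
    arma::vec d(n);
    if (unif_rand() < 0.5) {
      int j = (int)std::floor(unif_rand() * npool);
      d = pool.col(j) - center;
    } else {
      arma::vec g(n);
      for (int i = 0; i < n; ++i) g[i] = norm_rand() * range[i];
      d = NB * (NB.t() * g);
    }
    double nrm = arma::norm(d);
    if (nrm < 1e-12) continue;
    d /= nrm;

    double tmin = -arma::datum::inf, tmax = arma::datum::inf;
    for (int i = 0; i < n; ++i) {
      if (std::abs(d[i]) <= 1e-10) continue;
      double t1 = (lb[i] - x[i]) / d[i];
      double t2 = (ub[i] - x[i]) / d[i];
      if (t1 > t2) std::swap(t1, t2);
      if (t1 > tmin) tmin = t1;
      if (t2 < tmax) tmax = t2;
    }
    if (!std::isfinite(tmin) || !std::isfinite(tmax) || tmax - tmin < 1e-12)
      continue;
    double step = tmin + unif_rand() * (tmax - tmin);
    arma::vec xn = x + step * d;
    if (it % 25 == 0) xn = NB * (NB.t() * xn);   // drift control
    bool ok = true;
    for (int i = 0; i < n; ++i)
      if (xn[i] < lb[i] - 1e-9 || xn[i] > ub[i] + 1e-9) { ok = false; break; }
    if (!ok) { ++rejects; continue; }
    x = xn;
    for (int i = 0; i < n; ++i) center[i] += (x[i] - center[i]) / (npool + it);
    if (it % 10 == 0 && npool < maxpool) pool.col(npool++) = x;
    if (it > burn_in && (it - burn_in) % thin == 0) out.col(kept++) = x;
  }
  return List::create(_["points"] = out, _["rejects"] = rejects);
}
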
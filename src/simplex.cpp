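#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Bounded-variable two-phase primal simplex for
//   max c'x  s.t.  A x = b,  lb <= x <= ub
// All bounds must be finite (callers substitute a large box).
// Metabolic LPs are small and well-scaled, so a dense implementation with
// periodic refactorisation-by-solve is adequate and keeps the code auditable.
//
// status codes: 0 optimal, 1 infeasible, 2 unbounded, 3 iteration limit

static const double DTOL  = 1e-9;   // reduced-cost tolerance
static const double PTOL  = 1e-10;  // pivot tolerance
static const double FTOL  = 1e-7;   // phase-1 feasibility tolerance

struct SimplexState {
  arma::mat A;          // m x N
  arma::vec b, lb, ub, x;
  arma::ivec basis;     // length m, column indices
  arma::ivec instat;    // 0 = nonbasic at lb, 1 = nonbasic at ub, 2 = basic
};

// one simplex phase; returns status
static int simplex_iterate(SimplexState &S, const arma::vec &c, int max_iter) {
  const int m = S.A.n_rows, N = S.A.n_cols;
  bool bland = false;
  int degen_run = 0;

  arma::mat B(m, m);
  for (int it = 0; it < max_iter; ++it) {
    for (int i = 0; i < m; ++i) B.col(i) = S.A.col(S.basis[i]);

    // periodic resync of basic values against accumulated drift
    if (it % 60 == 0) {
      arma::vec rhs = S.b;
      for (int j = 0; j < N; ++j)
        if (S.instat[j] != 2) rhs -= S.A.col(j) * S.x[j];
      arma::vec xb;
      if (!arma::solve(xb, B, rhs)) return 3;
      for (int i = 0; i < m; ++i) S.x[S.basis[i]] = xb[i];
    }

    arma::vec cB(m);
    for (int i = 0; i < m; ++i) cB[i] = c[S.basis[i]];
    arma::vec y;
    if (!arma::solve(y, B.t(), cB)) return 3;

    // entering variable
    int enter = -1;
    double best = DTOL;
    for (int j = 0; j < N; ++j) {
      if (S.instat[j] == 2) continue;
      if (S.ub[j] - S.lb[j] < 1e-14) continue;   // fixed
      double d = c[j] - arma::dot(y, S.A.col(j));
      double gain = (S.instat[j] == 0) ? d : -d;
      if (gain > (bland ? DTOL : best)) {
        enter = j;
        if (bland) break;
        best = gain;
      }
    }
    if (enter < 0) return 0;  // optimal

    int sigma = (S.instat[enter] == 0) ? 1 : -1;
    arma::vec w;
    if (!arma::solve(w, B, S.A.col(enter))) return 3;

    // ratio test
    double tmax = S.ub[enter] - S.lb[enter];
    int leave = -1, leave_bound = 0;   // 0 -> lower, 1 -> upper
    for (int i = 0; i < m; ++i) {
      double delta = -sigma * w[i];    // rate of change of basic i
      int bi = S.basis[i];
      double t;
      int hb;
      if (delta > PTOL)      { t = (S.ub[bi] - S.x[bi]) / delta; hb = 1; }
      else if (delta < -PTOL){ t = (S.lb[bi] - S.x[bi]) / delta; hb = 0; }
      else continue;
      if (t < -1e-9) t = 0;
      if (t < tmax - 1e-12 ||
          (t < tmax + 1e-12 && leave >= 0 && bland && bi < S.basis[leave])) {
        tmax = t; leave = i; leave_bound = hb;
      }
    }
    if (!std::isfinite(tmax)) return 2;
    if (tmax < 0) tmax = 0;

    if (tmax < 1e-11) { if (++degen_run > 40) bland = true; }
    else degen_run = 0;

    // update solution
    S.x[enter] += sigma * tmax;
    for (int i = 0; i < m; ++i) S.x[S.basis[i]] -= sigma * tmax * w[i];

    if (leave < 0) {
      // bound flip
      S.instat[enter] = 1 - S.instat[enter];
      S.x[enter] = (S.instat[enter] == 0) ? S.lb[enter] : S.ub[enter];
    } else {
      int out = S.basis[leave];
      S.instat[out] = leave_bound;
      S.x[out] = leave_bound ? S.ub[out] : S.lb[out];
      S.basis[leave] = enter;
      S.instat[enter] = 2;
    }
  }
  return 3;
}

// [[Rcpp::export(name = ".simplex_cpp")]]
List simplex_cpp(const arma::mat &A, const arma::vec &b, const arma::vec &c,
                 const arma::vec &lb, const arma::vec &ub, int max_iter = 0) {
  const int m = A.n_rows, n = A.n_cols;
  if (max_iter <= 0) max_iter = 2000 + 60 * (n + m);

  SimplexState S;
  S.A = arma::join_rows(A, arma::eye(m, m));   // artificials
  S.b = b;
  S.lb = arma::vec(n + m);
  S.ub = arma::vec(n + m);
  S.x  = arma::vec(n + m);
  S.instat = arma::ivec(n + m);
  S.basis  = arma::ivec(m);

  for (int j = 0; j < n; ++j) {
    S.lb[j] = lb[j]; S.ub[j] = ub[j];
    // nonbasic variables must sit exactly on a bound
    if (std::abs(lb[j]) <= std::abs(ub[j])) { S.x[j] = lb[j]; S.instat[j] = 0; }
    else                                    { S.x[j] = ub[j]; S.instat[j] = 1; }
  }
  arma::vec r = b - A * S.x.head(n);
  arma::vec c1 = arma::zeros(n + m);
  for (int i = 0; i < m; ++i) {
    int j = n + i;
    S.lb[j] = std::min(0.0, r[i]);
    S.ub[j] = std::max(0.0, r[i]);
    S.x[j]  = r[i];
    S.basis[i] = j;
    S.instat[j] = 2;
    c1[j] = (r[i] >= 0) ? -1.0 : 1.0;   // maximize -|a|
  }

  int st = simplex_iterate(S, c1, max_iter);
  if (st == 3) return List::create(_["status"] = 3);
  double infeas = 0.0;
  for (int i = 0; i < m; ++i) infeas += std::abs(S.x[n + i]);
  if (infeas > FTOL) return List::create(_["status"] = 1);

  // pin artificials to zero and optimise the real objective
  for (int i = 0; i < m; ++i) {
    int j = n + i;
    S.lb[j] = S.ub[j] = 0.0;
    S.x[j] = 0.0;
    if (S.instat[j] != 2) S.instat[j] = 0;
  }
  arma::vec c2 = arma::zeros(n + m);
  c2.head(n) = c;
  st = simplex_iterate(S, c2, max_iter);
  if (st != 0) return List::create(_["status"] = st);

  arma::vec xs = S.x.head(n);
  return List::create(_["status"] = 0,
                      _["objective"] = arma::dot(c, xs),
                      _["x"] = NumericVector(xs.begin(), xs.end()));
}
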
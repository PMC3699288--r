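// Dense bounded-variable two-phase revised simplex.
//
// Solves   max  c'x   s.t.  A x {<=,=,>=} b,   l <= x <= u
// with l, u possibly infinite.  Written for the moderate problem sizes of
// core metabolic networks (tens to a few hundred variables); maintains an
// explicit basis inverse with periodic refactorisation, uses Dantzig pricing
// with a Bland's-rule fallback to guarantee termination.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double INF = 1e30;
static const double PIV_TOL = 1e-9;   // pivot / reduced-cost tolerance
static const double FEAS_TOL = 1e-9;  // bound / phase-1 feasibility tolerance

struct Simplex {
  mat A;          // m x n (structural + slack + artificial columns)
  vec b, c, lb, ub;
  int m, n;
  std::vector<int> basis;      // size m, column index basic in row i
  std::vector<int> vstat;      // 0 = nonbasic at lb, 1 = nonbasic at ub,
                               // 2 = basic, 3 = nonbasic free (value 0)
  vec x;                       // current values, size n
  mat Binv;                    // m x m
  int iter_count = 0;
  bool bland = false;

  void refactor() {
    mat B(m, m);
    for (int i = 0; i < m; ++i) B.col(i) = A.col(basis[i]);
    bool ok = inv(Binv, B);
    if (!ok) Rcpp::stop("simplex: singular basis during refactorisation");
  }

  void recompute_basics() {
    vec rhs = b;
    for (int j = 0; j < n; ++j)
      if (vstat[j] != 2 && x[j] != 0.0) rhs -= A.col(j) * x[j];
    vec xb = Binv * rhs;
    for (int i = 0; i < m; ++i) x[basis[i]] = xb[i];
  }

  // one simplex phase on objective obj; returns status:
  // 0 optimal, 1 unbounded
  int iterate(const vec& obj, int max_iter) {
    int stalled = 0;
    for (int it = 0; it < max_iter; ++it) {
      ++iter_count;
      if (iter_count % 200 == 0) { refactor(); recompute_basics(); }
      // duals and reduced costs
      vec cb(m);
      for (int i = 0; i < m; ++i) cb[i] = obj[basis[i]];
      vec y = Binv.t() * cb;
      // pricing
      int enter = -1, dir = 0;      // dir +1 increase, -1 decrease
      double best = bland ? 0.0 : PIV_TOL;
      for (int j = 0; j < n; ++j) {
        if (vstat[j] == 2) continue;
        if (lb[j] == ub[j]) continue;           // fixed
        double dj = obj[j] - dot(y, A.col(j));
        bool up = (vstat[j] == 0 || vstat[j] == 3) && dj > PIV_TOL;
        bool dn = (vstat[j] == 1 || vstat[j] == 3) && dj < -PIV_TOL;
        if (!up && !dn) continue;
        if (bland) { enter = j; dir = up ? 1 : -1; break; }
        double mag = std::fabs(dj);
        if (mag > best) { best = mag; enter = j; dir = up ? 1 : -1; }
      }
      if (enter < 0) return 0;                  // optimal
      vec t = Binv * A.col(enter);              // basic direction
      // ratio test
      double theta = (ub[enter] - lb[enter]);   // bound-flip distance
      if (theta >= INF) theta = datum::inf;
      int leave = -1; int leave_to = 0;         // 0 -> lb, 1 -> ub
      double best_piv = 0.0;
      for (int i = 0; i < m; ++i) {
        double ti = dir * t[i];
        int bi = basis[i];
        double lim; int to;
        if (ti > PIV_TOL) {                     // basic decreases
          if (lb[bi] <= -INF) continue;
          lim = (x[bi] - lb[bi]) / ti; to = 0;
        } else if (ti < -PIV_TOL) {             // basic increases
          if (ub[bi] >= INF) continue;
          lim = (ub[bi] - x[bi]) / (-ti); to = 1;
        } else {
          continue;
        }
        // among (near-)ties, prefer the largest pivot magnitude for
        // numerical stability of the basis update
        double tie_tol = 1e-7 * (1.0 + std::fabs(theta));
        if (lim < theta - tie_tol ||
            (lim < theta + tie_tol && std::fabs(ti) > best_piv)) {
          theta = std::min(theta, lim);
          leave = i; leave_to = to; best_piv = std::fabs(ti);
        }
      }
      if (!std::isfinite(theta)) return 1;      // unbounded
      if (theta < 0) theta = 0;
      if (theta < 1e-12) { if (++stalled > 400) bland = true; }
      else stalled = 0;
      // apply step
      x[enter] += dir * theta;
      for (int i = 0; i < m; ++i) x[basis[i]] -= dir * theta * t[i];
      if (leave < 0) {
        // bound flip of entering variable
        vstat[enter] = (dir > 0) ? 1 : 0;
        x[enter] = (dir > 0) ? ub[enter] : lb[enter];
      } else {
        int out = basis[leave];
        vstat[out] = leave_to;
        x[out] = (leave_to == 0) ? lb[out] : ub[out];
        basis[leave] = enter;
        vstat[enter] = 2;
        // update Binv: pivot on row `leave` of t
        double piv = t[leave];
        rowvec br = Binv.row(leave) / piv;
        for (int i = 0; i < m; ++i) {
          if (i == leave) continue;
          Binv.row(i) -= t[i] * br;
        }
        Binv.row(leave) = br;
      }
    }
    Rcpp::stop("simplex: iteration limit reached");
    return 0;
  }
};

// [[Rcpp::export(name = ".simplex_solve")]]
Rcpp::List simplex_solve(const arma::mat& Amat,
                         const arma::vec& rhs,
                         const arma::ivec& rel,     // -1 <=, 0 =, +1 >=
                         const arma::vec& cvec,
                         const arma::vec& lower,
                         const arma::vec& upper,
                         bool maximize = true,
                         int max_iter = 50000) {
  int m = Amat.n_rows, ns = Amat.n_cols;
  // slacks: one per row; artificials: one per row
  int n = ns + m + m;
  Simplex S;
  S.m = m; S.n = n;
  S.A.zeros(m, n);
  S.A.cols(0, ns - 1) = Amat;
  S.b = rhs;
  S.lb.set_size(n); S.ub.set_size(n);
  for (int j = 0; j < ns; ++j) {
    S.lb[j] = std::max(lower[j], -INF);
    S.ub[j] = std::min(upper[j], INF);
    if (S.lb[j] > S.ub[j] + FEAS_TOL)
      Rcpp::stop("simplex: variable %d has lower bound above upper bound", j + 1);
  }
  for (int i = 0; i < m; ++i) {
    int j = ns + i;
    S.A(i, j) = 1.0;
    if (rel[i] < 0)      { S.lb[j] = 0;    S.ub[j] = INF; }  // Ax + s = b, s >= 0
    else if (rel[i] > 0) { S.lb[j] = -INF; S.ub[j] = 0;   }
    else                 { S.lb[j] = 0;    S.ub[j] = 0;   }
  }
  S.c.zeros(n);
  for (int j = 0; j < ns; ++j) S.c[j] = maximize ? cvec[j] : -cvec[j];

  // initial nonbasic values for structural + slack columns
  S.x.zeros(n);
  S.vstat.assign(n, 0);
  for (int j = 0; j < ns + m; ++j) {
    if (S.lb[j] <= -INF && S.ub[j] >= INF) { S.vstat[j] = 3; S.x[j] = 0.0; }
    else if (S.lb[j] <= -INF)              { S.vstat[j] = 1; S.x[j] = S.ub[j]; }
    else if (S.ub[j] >= INF)               { S.vstat[j] = 0; S.x[j] = S.lb[j]; }
    else {
      // finite range: start at the bound of smaller magnitude
      if (std::fabs(S.lb[j]) <= std::fabs(S.ub[j])) { S.vstat[j] = 0; S.x[j] = S.lb[j]; }
      else                                          { S.vstat[j] = 1; S.x[j] = S.ub[j]; }
    }
  }
  // artificial basis
  vec resid = S.b;
  for (int j = 0; j < ns + m; ++j)
    if (S.x[j] != 0.0) resid -= S.A.col(j) * S.x[j];
  S.basis.resize(m);
  vec phase1 = zeros<vec>(n);
  for (int i = 0; i < m; ++i) {
    int j = ns + m + i;
    S.A(i, j) = (resid[i] >= 0) ? 1.0 : -1.0;
    S.lb[j] = 0; S.ub[j] = INF;
    S.x[j] = std::fabs(resid[i]);
    S.basis[i] = j;
    S.vstat[j] = 2;
    phase1[j] = -1.0;   // maximize -(sum of artificials)
  }
  S.Binv.eye(m, m);
  for (int i = 0; i < m; ++i) if (S.A(i, ns + m + i) < 0) S.Binv(i, i) = -1.0;

  // Phase 1
  S.iterate(phase1, max_iter);
  double infeas = 0.0;
  for (int i = 0; i < m; ++i) infeas += S.x[ns + m + i];
  std::string status;
  vec xs(ns, fill::zeros);
  double objval = NA_REAL;
  if (infeas > 1e-7) {
    status = "infeasible";
  } else {
    // freeze artificials at zero
    for (int i = 0; i < m; ++i) { S.lb[ns + m + i] = 0; S.ub[ns + m + i] = 0; }
    for (int j = ns + m; j < n; ++j) if (S.vstat[j] != 2) S.x[j] = 0.0;
    S.bland = false;
    int st = S.iterate(S.c, max_iter);
    if (st == 1) {
      status = "unbounded";
    } else {
      status = "optimal";
      S.refactor();
      S.recompute_basics();
      for (int j = 0; j < ns; ++j) xs[j] = S.x[j];
      objval = dot(cvec, xs);
      // clip round-off at the bounds
      for (int j = 0; j < ns; ++j) {
        if (lower[j] > -INF && xs[j] < lower[j]) xs[j] = lower[j];
        if (upper[j] <  INF && xs[j] > upper[j]) xs[j] = upper[j];
      }
    }
  }
  // row duals at the final basis (meaningful for status == "optimal")
  vec cb(m);
  for (int i = 0; i < m; ++i) cb[i] = S.c[S.basis[i]];
  vec y = S.Binv.t() * cb;
  if (!maximize) y = -y;
  return Rcpp::List::create(
    Rcpp::Named("status") = status,
    Rcpp::Named("objective") = maximize ? objval : (std::isnan(objval) ? objval : objval),
    Rcpp::Named("x") = xs,
    Rcpp::Named("duals") = y,
    Rcpp::Named("iterations") = S.iter_count);
}
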
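#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using namespace Rcpp;

// Bounded-variable two-phase primal simplex with Bland's rule.
//
//   max c'x   s.t.   A x = b,   l <= x <= u      (all bounds finite)
//
// Determinism: the entering variable is the smallest eligible index and
// ratio-test ties are broken by the smallest basic variable index, so two
// calls with identical inputs always return the same vertex.  Bland's rule
// also guarantees termination under degeneracy.  Artificial variables are
// given upper bound |r_i| (their starting value), so every variable is
// boxed and the LP can never be unbounded.

static const double PIV_TOL = 1e-9;
static const double FEAS_TOL = 1e-7;

struct SimplexState {
  mat A;                 // m x N (structurals then artificials)
  vec b, lb, ub, x;
  uvec basis;            // m basic variable indices
  std::vector<bool> in_basis;
  std::vector<bool> at_upper;   // meaningful for nonbasic only
  int m, n, N;
};

// One simplex run for a given cost vector. Returns 0 ok, 2 numerical.
static int simplex_iterate(SimplexState &S, const vec &cost, int max_iter) {
  for (int iter = 0; iter < max_iter; ++iter) {
    mat B(S.m, S.m);
    for (int i = 0; i < S.m; ++i) B.col(i) = S.A.col(S.basis[(uword)i]);
    vec cB(S.m);
    for (int i = 0; i < S.m; ++i) cB[i] = cost[S.basis[(uword)i]];
    vec y;
    if (!solve(y, B.t(), cB, solve_opts::no_approx)) return 2;

    // entering: smallest index with favourable reduced cost (Bland)
    int enter = -1, dir = 0;
    for (int j = 0; j < S.N; ++j) {
      if (S.in_basis[j]) continue;
      if (S.ub[j] - S.lb[j] <= PIV_TOL) continue;   // fixed, cannot move
      double d = cost[j] - dot(y, S.A.col(j));
      if (!S.at_upper[j] && d > PIV_TOL) { enter = j; dir = +1; break; }
      if (S.at_upper[j] && d < -PIV_TOL) { enter = j; dir = -1; break; }
    }
    if (enter < 0) return 0;                        // optimal

    vec w;
    if (!solve(w, B, S.A.col(enter), solve_opts::no_approx)) return 2;
    vec h = -double(dir) * w;                       // d x_B / d t

    double tmax = S.ub[enter] - S.lb[enter];        // bound-to-bound flip
    int leave = -1;
    for (int i = 0; i < S.m; ++i) {
      uword bi = S.basis[(uword)i];
      double cap;
      if (h[i] > PIV_TOL)       cap = (S.ub[bi] - S.x[bi]) / h[i];
      else if (h[i] < -PIV_TOL) cap = (S.x[bi] - S.lb[bi]) / (-h[i]);
      else continue;
      if (cap < -1e-12) cap = 0.0;
      if (cap < tmax - 1e-12) { tmax = cap; leave = i; }
      else if (cap <= tmax + 1e-12 && leave >= 0 &&
               S.basis[(uword)i] < S.basis[(uword)leave]) { leave = i; }
    }
    if (tmax < 0) tmax = 0;

    // update primal values
    S.x[enter] += dir * tmax;
    for (int i = 0; i < S.m; ++i) S.x[S.basis[(uword)i]] += tmax * h[i];

    if (leave < 0) {
      S.at_upper[enter] = !S.at_upper[enter];       // flipped bound
    } else {
      uword out = S.basis[(uword)leave];
      // leaving variable rests on the bound it ran into
      bool out_upper = h[leave] > 0;
      S.x[out] = out_upper ? S.ub[out] : S.lb[out];
      S.at_upper[out] = out_upper;
      S.in_basis[out] = false;
      S.basis[(uword)leave] = (uword)enter;
      S.in_basis[enter] = true;
    }
  }
  return 2;                                         // iteration limit
}

// refresh basic values from the nonbasic assignment for accuracy
static bool refresh_basics(SimplexState &S) {
  vec rhs = S.b;
  for (int j = 0; j < S.N; ++j)
    if (!S.in_basis[j] && S.x[j] != 0.0) rhs -= S.A.col(j) * S.x[j];
  mat B(S.m, S.m);
  for (int i = 0; i < S.m; ++i) B.col(i) = S.A.col(S.basis[(uword)i]);
  vec xb;
  if (!solve(xb, B, rhs, solve_opts::no_approx)) return false;
  for (int i = 0; i < S.m; ++i) S.x[S.basis[(uword)i]] = xb[i];
  return true;
}

// [[Rcpp::export(name = ".lp_simplex_cpp")]]
List lp_simplex_cpp(const arma::mat &A, const arma::vec &b,
                    const arma::vec &c, const arma::vec &l,
                    const arma::vec &u, bool maximize = true) {
  int m = (int)A.n_rows, n = (int)A.n_cols, N = n + m;
  if ((int)b.n_elem != m || (int)c.n_elem != n ||
      (int)l.n_elem != n || (int)u.n_elem != n)
    stop("inconsistent LP dimensions");
  for (int j = 0; j < n; ++j) {
    if (!std::isfinite(l[j]) || !std::isfinite(u[j]))
      stop("all bounds must be finite");
    if (l[j] > u[j] + 1e-12) stop("lower bound exceeds upper bound");
  }

  SimplexState S;
  S.m = m; S.n = n; S.N = N;
  S.A.zeros(m, N);
  S.A.cols(0, n - 1) = A;
  S.b = b;
  S.lb.zeros(N); S.ub.zeros(N); S.x.zeros(N);
  S.lb.subvec(0, n - 1) = l;
  S.ub.subvec(0, n - 1) = u;
  S.in_basis.assign(N, false);
  S.at_upper.assign(N, false);

  // structurals start at their lower bound; artificials absorb the residual
  for (int j = 0; j < n; ++j) S.x[j] = l[j];
  vec r = b - A * S.lb.subvec(0, n - 1);
  S.basis.set_size(m);
  for (int i = 0; i < m; ++i) {
    int a = n + i;
    S.A(i, a) = (r[i] >= 0) ? 1.0 : -1.0;
    S.x[a] = std::fabs(r[i]);
    S.lb[a] = 0.0;
    S.ub[a] = std::fabs(r[i]) + 1.0;   // never needs to grow
    S.basis[(uword)i] = (uword)a;
    S.in_basis[a] = true;
  }

  int max_iter = 2000 * (N + 1);
  vec sense_c = maximize ? vec(c) : vec(-c);

  // phase 1: drive artificials to zero
  vec c1 = zeros<vec>(N);
  for (int i = 0; i < m; ++i) c1[n + i] = -1.0;
  int st = simplex_iterate(S, c1, max_iter);
  if (st != 0)
    return List::create(_["status"] = "numerical", _["objective"] = NA_REAL,
                        _["fluxes"] = NumericVector(n));
  double art = 0;
  for (int i = 0; i < m; ++i) art += S.x[n + i];
  double scale = 1.0 + norm(b, "inf");
  if (art > FEAS_TOL * scale)
    return List::create(_["status"] = "infeasible", _["objective"] = NA_REAL,
                        _["fluxes"] = NumericVector(n));

  // phase 2: artificials pinned to zero, optimise the real objective
  for (int i = 0; i < m; ++i) {
    S.lb[n + i] = 0.0; S.ub[n + i] = 0.0;
    if (S.x[n + i] < FEAS_TOL) S.x[n + i] = 0.0;
  }
  vec c2 = zeros<vec>(N);
  c2.subvec(0, n - 1) = sense_c;
  st = simplex_iterate(S, c2, max_iter);
  if (st != 0)
    return List::create(_["status"] = "numerical", _["objective"] = NA_REAL,
                        _["fluxes"] = NumericVector(n));
  if (!refresh_basics(S))
    return List::create(_["status"] = "numerical", _["objective"] = NA_REAL,
                        _["fluxes"] = NumericVector(n));

  NumericVector fx(n);
  double obj = 0;
  for (int j = 0; j < n; ++j) {
    double v = S.x[j];
    if (v < l[j]) v = l[j];
    if (v > u[j]) v = u[j];
    fx[j] = v;
    obj += c[j] * v;
  }
  return List::create(_["status"] = "optimal", _["objective"] = obj,
                      _["fluxes"] = fx);
}
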
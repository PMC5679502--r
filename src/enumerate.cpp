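#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using namespace Rcpp;

// Exhaustive vertex enumeration for   max c'x,  A x = 0,  l <= x <= u.
//
// Every vertex of the (bounded) feasible polytope is a basic solution: m
// variables solve A_B x_B = -A_N x_N with each of the n-m nonbasic
// variables pinned at one of its bounds.  We enumerate all m-subsets with
// nonsingular A_B and all 2^(n-m) bound patterns, keep the feasible points
// and return the best objective.  Completely independent of the simplex
// implementation; intended as a brute-force oracle on small (presolved)
// systems only.

// [[Rcpp::export(name = ".lp_enum_cpp")]]
List lp_enum_cpp(const arma::mat &A, const arma::vec &l, const arma::vec &u,
                 const arma::vec &c, double feas_tol = 1e-7) {
  int m = (int)A.n_rows, n = (int)A.n_cols;
  if (m >= n) stop("enumeration oracle needs more variables than constraints");
  int k = n - m;
  if (k > 20) stop("too many degrees of freedom for exhaustive enumeration");
  double ncomb = 1.0;
  for (int i = 0; i < m; ++i) ncomb = ncomb * (n - i) / (i + 1);
  if (ncomb > 5e5) stop("too many basis candidates for exhaustive enumeration");

  const int np = 1 << k;
  // pattern matrix: P(i, p) = 1 if nonbasic i sits at its upper bound
  mat P(k, np);
  for (int p = 0; p < np; ++p)
    for (int i = 0; i < k; ++i) P(i, p) = (p >> i) & 1 ? 1.0 : 0.0;

  double best = -datum::inf;
  vec best_x;
  bool any_feasible = false;

  std::vector<int> comb(m);
  for (int i = 0; i < m; ++i) comb[i] = i;
  uvec bidx(m), nidx(k);

  double bscale = 1.0 + std::max(norm(l, "inf"), norm(u, "inf"));
  double eps = feas_tol * bscale;

  while (true) {
    for (int i = 0; i < m; ++i) bidx[(uword)i] = (uword)comb[i];
    // complement
    {
      int pos = 0, ci = 0;
      for (int j = 0; j < n; ++j) {
        if (ci < m && comb[ci] == j) { ++ci; continue; }
        nidx[(uword)pos++] = (uword)j;
      }
    }
    mat AB = A.cols(bidx);
    if (rcond(AB) > 1e-10) {
      mat M;
      if (solve(M, AB, A.cols(nidx), solve_opts::no_approx)) {
        vec lN = l(nidx), uN = u(nidx), lB = l(bidx), uB = u(bidx);
        vec cN = c(nidx), cB = c(bidx);
        // X_N = lN + (uN - lN) .* pattern   (k x np)
        mat XN = repmat(lN, 1, np) + diagmat(uN - lN) * P;
        mat XB = -M * XN;                                   // m x np
        for (int p = 0; p < np; ++p) {
          bool ok = true;
          for (int i = 0; i < m; ++i) {
            double v = XB(i, p);
            if (v < lB[i] - eps || v > uB[i] + eps) { ok = false; break; }
          }
          if (!ok) continue;
          any_feasible = true;
          double obj = dot(cN, XN.col(p)) + dot(cB, XB.col(p));
          if (obj > best + 1e-12) {
            best = obj;
            best_x.set_size(n);
            for (int i = 0; i < k; ++i) best_x[nidx[(uword)i]] = XN(i, p);
            for (int i = 0; i < m; ++i) best_x[bidx[(uword)i]] = XB(i, p);
          }
        }
      }
    }
    // next combination (odometer)
    int i = m - 1;
    while (i >= 0 && comb[i] == n - m + i) --i;
    if (i < 0) break;
    ++comb[i];
    for (int j = i + 1; j < m; ++j) comb[j] = comb[j - 1] + 1;
  }

  if (!any_feasible)
    return List::create(_["status"] = "infeasible", _["objective"] = NA_REAL,
                        _["x"] = NumericVector(0));
  return List::create(_["status"] = "optimal", _["objective"] = best,
                      _["x"] = NumericVector(best_x.begin(), best_x.end()));
}
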
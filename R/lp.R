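# Linear-programming backends.
#
# solve_lp() is the production solver: a deterministic bounded-variable
# two-phase simplex (Bland's rule) implemented in C++.  lp_vertex_oracle()
# is an independent exhaustive vertex enumerator used only for validation;
# it presolves chains of degree-2 balanced metabolites so that the
# combinatorial enumeration stays tractable on the toy network.

#' Solve a bounded linear programme
#'
#' Maximises (or minimises) `c'x` subject to `A x = b` and `l <= x <= u`.
#' All bounds must be finite; with a fully boxed feasible region the LP can
#' never be unbounded.  Deterministic: repeated calls return the same
#' vertex.
#'
#' @param A constraint matrix (m x n)
#' @param b right-hand side (length m)
#' @param c objective coefficients (length n)
#' @param l,u variable bounds (length n, finite)
#' @param maximize direction
#' @return list with `status` ("optimal"/"infeasible"/"numerical"),
#'   `objective`, `fluxes`
#' @export
solve_lp <- function(A, b, c, l, u, maximize = TRUE) {
  .lp_simplex_cpp(as.matrix(A), as.numeric(b), as.numeric(c),
                  as.numeric(l), as.numeric(u), isTRUE(maximize))
}

# eliminate balanced rows touched by exactly two reactions: a*v1 + b*v2 = 0
# implies v2 = -(a/b) v1, so the pair collapses to one variable with
# intersected (transformed) bounds.  Returns NULL if the intersection is
# empty (infeasible by presolve).
presolve_chains <- function(A, l, u, c) {
  repeat {
    nz <- abs(A) > 1e-12
    deg <- rowSums(nz)
    A <- A[deg > 0, , drop = FALSE]
    nz <- nz[deg > 0, , drop = FALSE]
    deg <- deg[deg > 0]
    row <- which(deg == 2)[1]
    if (is.na(row)) break
    js <- which(nz[row, ])
    j1 <- js[1]; j2 <- js[2]
    g <- -A[row, j1] / A[row, j2]          # v2 = g * v1
    if (g > 0) { lo2 <- l[j2] / g; hi2 <- u[j2] / g }
    else       { lo2 <- u[j2] / g; hi2 <- l[j2] / g }
    lo <- max(l[j1], lo2); hi <- min(u[j1], hi2)
    if (lo > hi + 1e-9) return(NULL)
    A[, j1] <- A[, j1] + g * A[, j2]
    c[j1] <- c[j1] + g * c[j2]
    l[j1] <- lo; u[j1] <- min(hi, max(lo, hi))
    u[j1] <- hi
    keep <- seq_len(ncol(A)) != j2
    A <- A[-row, keep, drop = FALSE]
    l <- l[keep]; u <- u[keep]; c <- c[keep]
  }
  list(A = A, l = l, u = u, c = c)
}

#' Exhaustive LP oracle by vertex enumeration
#'
#' Independent reference for [solve_lp()] on homogeneous problems
#' (`A x = 0`): every vertex of the boxed polytope is enumerated as a basic
#' solution and the best feasible objective returned.  Only the objective
#' value and status are comparable with the simplex (alternate optimal
#' vertices may differ).  Intended for small systems; errors out if the
#' combinatorics get out of hand.
#'
#' @param A constraint matrix (rows must be balanced species, rhs 0)
#' @param l,u finite bounds
#' @param c objective (maximised)
#' @return list with `status` and `objective`
#' @export
lp_vertex_oracle <- function(A, l, u, c) {
  pre <- presolve_chains(as.matrix(A), as.numeric(l), as.numeric(u),
                         as.numeric(c))
  if (is.null(pre)) return(list(status = "infeasible", objective = NA_real_))
  A <- pre$A
  if (nrow(A) > 0) {
    qrA <- qr(t(A))
    if (qrA$rank < nrow(A)) {
      keep <- sort(qrA$pivot[seq_len(qrA$rank)])
      A <- A[keep, , drop = FALSE]
    }
  }
  if (nrow(A) == 0) {
    # pure box problem: optimum at the favourable bound of each variable
    x <- ifelse(pre$c > 0, pre$u, pre$l)
    return(list(status = "optimal", objective = sum(pre$c * x)))
  }
  res <- .lp_enum_cpp(A, pre$l, pre$u, pre$c)
  list(status = res$status, objective = res$objective)
}
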
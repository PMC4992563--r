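# Thin R wrapper around the compiled bounded-variable simplex.
#
# A workspace holds the (fixed) constraint matrix of one FBA problem and the
# cached optimal bases used for warm starts; it lives in an environment slot
# of the problem object so that it is rebuilt lazily in fresh sessions.

lp_new <- function(A, b) {
  lp_workspace_new(A, b)
}

#' Solve a bounded linear program
#'
#' Solves `max/min c'x` subject to `A x = b` and `lb <= x <= ub` with the
#' package's two-phase revised simplex. Exposed mainly for testing; FBA users
#' should call [solve_fba()].
#'
#' @param A constraint matrix (dense, rows = equality constraints).
#' @param b right-hand side.
#' @param c objective coefficients.
#' @param lb,ub variable bounds (finite).
#' @param maximize logical; maximize (`TRUE`) or minimize.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"failed"`), `obj` and `x`.
#' @export
lp_solve <- function(A, b, c, lb, ub, maximize = TRUE) {
  res <- lp_solve_dense(as.matrix(A), as.numeric(b), as.numeric(c),
                        as.numeric(lb), as.numeric(ub), isTRUE(maximize))
  res$status <- c("optimal", "infeasible", "unbounded", "failed")[res$status + 1L]
  res
}
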
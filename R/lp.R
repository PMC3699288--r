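#' Solve a bounded linear program
#'
#' Low-level interface to the package's dense bounded-variable two-phase
#' revised simplex. Solves `max (or min) c'x` subject to `A x (rel) b` and
#' `lb <= x <= ub`. Infinite bounds are allowed.
#'
#' This is the numerical core behind [solve_fba()] and friends; it is exported
#' mainly so that solutions can be cross-checked against independent solvers.
#'
#' @param A constraint matrix (dense or `Matrix` sparse), one row per
#'   constraint, one column per variable.
#' @param rel character vector of constraint senses, one of `"<="`, `"="`,
#'   `">="` per row.
#' @param rhs numeric right-hand sides.
#' @param objective numeric objective coefficients (length `ncol(A)`).
#' @param lower,upper numeric variable bounds; `-Inf`/`Inf` allowed.
#' @param maximize logical; maximize (default) or minimize.
#'
#' @return A list with elements `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"`), `objective`, `x` (primal values), and `duals`
#'   (row duals at the final basis).
#' @export
lp_solve <- function(A, rel, rhs, objective, lower, upper, maximize = TRUE) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  n <- ncol(A)
  m <- nrow(A)
  stopifnot(length(rhs) == m, length(rel) == m,
            length(objective) == n, length(lower) == n, length(upper) == n)
  rel_code <- match(rel, c("<=", "=", ">=")) - 2L
  if (anyNA(rel_code)) stop("constraint senses must be one of '<=', '=', '>='")
  res <- .simplex_solve(A, as.numeric(rhs), rel_code, as.numeric(objective),
                        as.numeric(lower), as.numeric(upper),
                        maximize = maximize)
  res$x <- as.numeric(res$x)
  res$duals <- as.numeric(res$duals)
  res
}
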
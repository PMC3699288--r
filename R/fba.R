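#' Linear constraint over reaction fluxes
#'
#' A single extra row for the flux-balance linear program:
#' `sum(coefficients * v) relation rhs`.
#'
#' @param coefficients named numeric vector (names are reaction ids).
#' @param relation one of `"<="`, `"="`, `">="`.
#' @param rhs right-hand side (default 0).
#' @return A `linear_constraint` object.
#' @export
linear_constraint <- function(coefficients, relation = "<=", rhs = 0) {
  stopifnot(length(coefficients) > 0, !is.null(names(coefficients)),
            relation %in% c("<=", "=", ">="))
  if (all(coefficients == 0)) stop("constraint has no nonzero coefficient")
  structure(list(coefficients = coefficients, relation = relation, rhs = rhs),
            class = "linear_constraint")
}

#' Objective specification for flux optimization
#'
#' @param coefficients named numeric vector of objective coefficients over
#'   reaction ids, or a single reaction id string (coefficient 1).
#' @param direction `"maximize"` or `"minimize"`.
#' @return An `objective_spec` object.
#' @export
objective_spec <- function(coefficients, direction = "maximize") {
  if (is.character(coefficients) && length(coefficients) == 1 &&
      is.null(names(coefficients)))
    coefficients <- setNames(1, coefficients)
  stopifnot(length(coefficients) > 0, !is.null(names(coefficients)))
  if (all(coefficients == 0)) stop("empty objective")
  direction <- match.arg(direction, c("maximize", "minimize"))
  structure(list(coefficients = coefficients, direction = direction),
            class = "objective_spec")
}

# assemble the LP for a model + extra constraint rows
fba_lp <- function(model, extra = list()) {
  S <- as.matrix(stoichiometric_matrix(model))
  rxn <- model$reactions
  n <- nrow(rxn)
  A <- S
  rel <- rep("=", nrow(S))
  rhs <- rep(0, nrow(S))
  for (con in extra) {
    stopifnot(inherits(con, "linear_constraint"))
    missing <- setdiff(names(con$coefficients), rxn$id)
    if (length(missing))
      stop("constraint references unknown reaction: ", missing[1])
    row <- rep(0, n)
    row[match(names(con$coefficients), rxn$id)] <- con$coefficients
    A <- rbind(A, row)
    rel <- c(rel, con$relation)
    rhs <- c(rhs, con$rhs)
  }
  list(A = A, rel = rel, rhs = rhs,
       lower = rxn$lower_bound, upper = rxn$upper_bound, ids = rxn$id)
}

resolve_objective <- function(model, objective) {
  if (is.null(objective)) objective <- objective_spec(model$objective_id)
  if (is.character(objective)) objective <- objective_spec(objective)
  stopifnot(inherits(objective, "objective_spec"))
  missing <- setdiff(names(objective$coefficients), model$reactions$id)
  if (length(missing)) stop("objective references unknown reaction: ", missing[1])
  objective
}

#' Flux balance analysis
#'
#' Maximizes (or minimizes) a linear flux objective subject to steady state
#' (`S v = 0`), the model's flux bounds, and any extra linear constraints
#' (e.g. flux-ratio couplings from [add_ratio_constraint()]).
#'
#' The returned optimum is one vertex of the optimal face; claims about
#' uniqueness of individual fluxes should be made with
#' [flux_variability()], not from the vertex.
#'
#' @param model a `metabolic_model`.
#' @param objective an [objective_spec()], a reaction id, or `NULL` for the
#'   model's default objective.
#' @param extra list of [linear_constraint()] rows.
#' @return A `flux_solution`: list with `status` (`"optimal"`,
#'   `"infeasible"`, `"unbounded"`), `objective_value`, and `fluxes`, a
#'   named numeric vector in mmol gDW^-1 h^-1.
#' @export
#' @examples
#' m <- example_toy_model()
#' sol <- solve_fba(m)
#' sol$objective_value
solve_fba <- function(model, objective = NULL, extra = list()) {
  objective <- resolve_objective(model, objective)
  lp <- fba_lp(model, extra)
  cc <- rep(0, length(lp$ids))
  cc[match(names(objective$coefficients), lp$ids)] <- objective$coefficients
  res <- lp_solve(lp$A, lp$rel, lp$rhs, cc, lp$lower, lp$upper,
                  maximize = objective$direction == "maximize")
  fluxes <- setNames(res$x, lp$ids)
  structure(list(status = res$status,
                 objective_value = if (res$status == "optimal") res$objective else NA_real_,
                 fluxes = fluxes,
                 objective = objective,
                 duals = res$duals),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status: ", x$status,
      ", objective: ", format(x$objective_value, digits = 8), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a flux solution into a tibble
#'
#' @param x a `flux_solution`.
#' @param nonzero keep only fluxes with magnitude above `tol`.
#' @param tol zero threshold (default 1e-9).
#' @param ... unused.
#' @return Tibble with columns `reaction`, `flux`.
#' @export
tidy.flux_solution <- function(x, nonzero = FALSE, tol = 1e-9, ...) {
  out <- tibble::tibble(reaction = names(x$fluxes), flux = unname(x$fluxes))
  if (nonzero) out <- out[abs(out$flux) > tol, ]
  out
}

#' @rdname tidy.flux_solution
#' @return For `glance()`: a one-row tibble with `status`,
#'   `objective_value`, `n_active` (fluxes above `tol`).
#' @export
glance.flux_solution <- function(x, tol = 1e-9, ...) {
  tibble::tibble(status = x$status, objective_value = x$objective_value,
                 n_active = sum(abs(x$fluxes) > tol))
}

#' Flux variability analysis
#'
#' For each reaction, the minimum and maximum flux compatible with
#' attaining at least `fraction` of the optimal objective (at most, for a
#' minimization objective). Used to characterize alternative optima: a
#' reaction with `max == 0` at `fraction = 1` carries no flux in any
#' optimal solution.
#'
#' @inheritParams solve_fba
#' @param fraction fraction of the optimal objective to retain, in (0, 1].
#' @param reactions reaction ids to scan (default: all).
#' @return Tibble with columns `reaction`, `min`, `max`.
#' @export
flux_variability <- function(model, objective = NULL, fraction = 1.0,
                             extra = list(), reactions = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  objective <- resolve_objective(model, objective)
  base <- solve_fba(model, objective, extra)
  if (base$status != "optimal")
    stop("base FBA problem is ", base$status)
  z <- base$objective_value
  lock <- if (objective$direction == "maximize") {
    linear_constraint(objective$coefficients, ">=",
                      fraction * z - 1e-9 * max(1, abs(z)))
  } else {
    linear_constraint(objective$coefficients, "<=",
                      fraction * z + 1e-9 * max(1, abs(z)))
  }
  lp <- fba_lp(model, c(extra, list(lock)))
  if (is.null(reactions)) reactions <- lp$ids
  n <- length(lp$ids)
  out <- purrr::map_dfr(reactions, function(rx) {
    cc <- rep(0, n); cc[match(rx, lp$ids)] <- 1
    lo <- lp_solve(lp$A, lp$rel, lp$rhs, cc, lp$lower, lp$upper, maximize = FALSE)
    hi <- lp_solve(lp$A, lp$rel, lp$rhs, cc, lp$lower, lp$upper, maximize = TRUE)
    tibble::tibble(reaction = rx, min = lo$objective, max = hi$objective)
  })
  out
}

#' Flux-ratio coupling constraint
#'
#' Builds the linear row `v_target - ratio * v_reference {relation} 0`,
#' used for couplings such as "terminal oxidase consumes 10% of the oxygen
#' evolved by photosystem II" or "oxygenase flux at least 3% of carboxylase
#' flux". Implemented as an extra matrix row (not a bound substitution) so
#' it composes with FVA.
#'
#' @param target_rxn,reference_rxn reaction ids.
#' @param ratio non-negative finite ratio.
#' @param relation `">="`, `"="`, or `"<="`.
#' @param model optional; when supplied, warns if the reference reaction can
#'   carry negative flux (the constraint's meaning then changes sign).
#' @return A [linear_constraint()].
#' @export
add_ratio_constraint <- function(target_rxn, reference_rxn, ratio,
                                 relation = ">=", model = NULL) {
  stopifnot(is.finite(ratio), ratio >= 0)
  if (!is.null(model)) {
    i <- match(reference_rxn, model$reactions$id)
    if (!is.na(i) && model$reactions$lower_bound[i] < 0)
      warning("reference reaction ", reference_rxn,
              " is reversible; the ratio constraint changes meaning for negative flux")
  }
  coefs <- setNames(c(1, -ratio), c(target_rxn, reference_rxn))
  if (target_rxn == reference_rxn)
    coefs <- setNames(1 - ratio, target_rxn)
  linear_constraint(coefs, relation, 0)
}

#' Forced-flux scan
#'
#' Re-optimizes the objective while forcing a reaction's flux to at least
#' each value of an ascending grid (a lower-bound sweep). For a
#' maximization objective the resulting objective sequence is
#' non-increasing; forcing flux through an energetically wasteful cycle
#' shows an immediate growth reduction, while forcing a reaction below its
#' optimal flux leaves the objective unchanged.
#'
#' @inheritParams solve_fba
#' @param rxn reaction id to force.
#' @param values ascending numeric grid of forced lower bounds.
#' @return Tibble with columns `forced`, `status`, `objective` (`NA` where
#'   infeasible).
#' @export
forced_flux_scan <- function(model, objective = NULL, rxn, values,
                             extra = list()) {
  stopifnot(!is.unsorted(values))
  purrr::map_dfr(values, function(v) {
    con <- linear_constraint(setNames(1, rxn), ">=", v)
    sol <- solve_fba(model, objective, c(extra, list(con)))
    tibble::tibble(forced = v, status = sol$status,
                   objective = sol$objective_value)
  })
}

#' Parsimonious flux distribution at the optimum
#'
#' Fixes the objective at (a fraction of) its optimal value and minimizes
#' the total absolute flux, yielding a representative flux map free of
#' arbitrary internal cycles that a plain simplex vertex may carry. The
#' objective value is unchanged; only the flux vector is cleaned up.
#'
#' @inheritParams flux_variability
#' @return A `flux_solution` whose `objective_value` equals the original
#'   optimum and whose `fluxes` have minimal total magnitude.
#' @export
parsimonious_fba <- function(model, objective = NULL, extra = list(),
                             fraction = 1.0) {
  objective <- resolve_objective(model, objective)
  base <- solve_fba(model, objective, extra)
  if (base$status != "optimal") return(base)
  z <- base$objective_value
  slack <- 1e-9 * max(1, abs(z))
  lock <- if (objective$direction == "maximize") {
    linear_constraint(objective$coefficients, ">=", fraction * z - slack)
  } else {
    linear_constraint(objective$coefficients, "<=", fraction * z + slack)
  }
  lp <- fba_lp(model, c(extra, list(lock)))
  n <- length(lp$ids)
  # split v = p - n with p, n >= 0; minimize sum(p + n)
  A2 <- cbind(lp$A, -lp$A)
  lower <- c(pmax(lp$lower, 0), pmax(-lp$upper, 0))
  upper <- c(pmax(lp$upper, 0), pmax(-lp$lower, 0))
  res <- lp_solve(A2, lp$rel, lp$rhs, rep(1, 2 * n), lower, upper,
                  maximize = FALSE)
  if (res$status != "optimal") return(base) # fall back to the plain vertex
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  out <- base
  out$fluxes <- setNames(v, lp$ids)
  out$objective_value <- sum(objective$coefficients *
                               v[match(names(objective$coefficients), lp$ids)])
  out
}
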
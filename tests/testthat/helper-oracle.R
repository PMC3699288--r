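# Brute-force LP oracle: enumerates all basic solutions of
#   { S v = 0 (+ extra equality rows), lb <= v <= ub }
# by fixing every choice of n - rank(S) variables at a bound and solving for
# the rest. Independent of the simplex implementation. Only for tiny models.

enumerate_vertices <- function(model, extra_eq = NULL) {
  S <- as.matrix(cyanoflux::stoichiometric_matrix(model))
  if (!is.null(extra_eq)) S <- rbind(S, extra_eq$row)
  b <- c(rep(0, nrow(S) - length(extra_eq$rhs)), extra_eq$rhs)
  if (is.null(extra_eq)) b <- rep(0, nrow(S))
  n <- ncol(S)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  r <- qr(S)$rank
  nfix <- n - r
  verts <- list()
  if (nfix == 0) {
    sol <- tryCatch(qr.solve(S, b), error = function(e) NULL)
    if (!is.null(sol) && all(sol >= lb - 1e-8 & sol <= ub + 1e-8))
      verts[[1]] <- sol
  } else {
    for (fix_idx in utils::combn(n, nfix, simplify = FALSE)) {
      free_idx <- setdiff(seq_len(n), fix_idx)
      Sf <- S[, free_idx, drop = FALSE]
      if (qr(Sf)$rank < length(free_idx)) next
      bounds <- expand.grid(rep(list(c("lb", "ub")), nfix),
                            stringsAsFactors = FALSE)
      for (k in seq_len(nrow(bounds))) {
        vfix <- ifelse(unlist(bounds[k, ]) == "lb", lb[fix_idx], ub[fix_idx])
        if (any(!is.finite(vfix))) next
        rhs <- b - S[, fix_idx, drop = FALSE] %*% vfix
        vfree <- tryCatch(qr.solve(Sf, rhs), error = function(e) NULL)
        if (is.null(vfree)) next
        v <- numeric(n)
        v[fix_idx] <- vfix
        v[free_idx] <- vfree
        if (all(v >= lb - 1e-8 & v <= ub + 1e-8))
          verts[[length(verts) + 1L]] <- v
      }
    }
  }
  if (!length(verts)) return(NULL)
  out <- do.call(rbind, verts)
  colnames(out) <- model$reactions$id
  out
}

oracle_optimum <- function(model, objective_id) {
  V <- enumerate_vertices(model)
  stopifnot(!is.null(V))
  max(V[, objective_id])
}

# FVA oracle: vertices of the optimal face (objective locked by an extra
# equality row), then per-reaction min/max over them
oracle_fva <- function(model, objective_id) {
  z <- oracle_optimum(model, objective_id)
  row <- as.numeric(model$reactions$id == objective_id)
  V <- enumerate_vertices(model, extra_eq = list(row = row, rhs = z))
  stopifnot(!is.null(V))
  tibble::tibble(reaction = colnames(V),
                 min = unname(apply(V, 2, min)),
                 max = unname(apply(V, 2, max)))
}
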
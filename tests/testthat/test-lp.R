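test_that("simplex agrees with an independent solver on random LPs", {
  skip_if_not_installed("pracma")
  set.seed(101)
  for (k in 1:40) {
    n <- sample(3:10, 1); m <- sample(2:6, 1)
    A <- matrix(round(rnorm(m * n), 2), m, n)
    rel <- sample(c("<=", "=", ">="), m, replace = TRUE, prob = c(.5, .2, .3))
    x0 <- runif(n, 0, 5)
    b <- as.numeric(A %*% x0)
    b[rel == "<="] <- b[rel == "<="] + runif(sum(rel == "<="), 0, 2)
    b[rel == ">="] <- b[rel == ">="] - runif(sum(rel == ">="), 0, 2)
    cc <- round(rnorm(n), 2)
    r1 <- lp_solve(A, rel, b, cc, rep(0, n), rep(10, n))
    A1 <- rbind(A[rel == "<=", , drop = FALSE],
                -A[rel == ">=", , drop = FALSE], diag(n))
    b1 <- c(b[rel == "<="], -b[rel == ">="], rep(10, n))
    Aeq <- A[rel == "=", , drop = FALSE]
    beq <- b[rel == "="]
    if (nrow(Aeq) == 0) { Aeq <- NULL; beq <- NULL }
    r2 <- tryCatch(pracma::linprog(-cc, A = A1, b = b1, Aeq = Aeq, beq = beq,
                                   maxiter = 2000),
                   error = identity, warning = identity)
    if (inherits(r2, c("error", "warning"))) next
    expect_equal(r1$status, "optimal")
    expect_equal(r1$objective, -r2$fval, tolerance = 1e-6)
  }
})

test_that("simplex detects infeasible and unbounded problems", {
  r <- lp_solve(matrix(c(1, 1), 1), "<=", -1, c(1, 1), c(0, 0), c(10, 10))
  expect_equal(r$status, "infeasible")
  r <- lp_solve(matrix(c(1, -1), 1), "=", 0, c(1, 0), c(0, 0), c(Inf, Inf))
  expect_equal(r$status, "unbounded")
})

test_that("free and upper-bounded variables are handled", {
  r <- lp_solve(matrix(c(1, 1), 1), "=", 5, c(1, 2),
                c(-Inf, -Inf), c(Inf, 2))
  expect_equal(r$objective, 7, tolerance = 1e-8)
  expect_equal(r$x, c(3, 2), tolerance = 1e-8)
})

test_that("FBA objective matches exhaustive vertex enumeration on all fixtures", {
  for (nm in c("chain", "branch", "parallel", "wasteful_cycle")) {
    fx <- make_lp_fixture(nm)
    sol <- solve_fba(fx$model)
    expect_equal(sol$status, "optimal", info = nm)
    expect_equal(sol$objective_value, fx$optimum, tolerance = 1e-6, info = nm)
    expect_equal(sol$objective_value,
                 oracle_optimum(fx$model, fx$model$objective_id),
                 tolerance = 1e-6, info = nm)
  }
})

test_that("FVA ranges match vertex enumeration of the optimal face", {
  for (nm in c("chain", "branch", "parallel", "wasteful_cycle")) {
    fx <- make_lp_fixture(nm)
    fva <- flux_variability(fx$model, fraction = 1.0)
    oracle <- oracle_fva(fx$model, fx$model$objective_id)
    got <- fva[match(oracle$reaction, fva$reaction), ]
    expect_equal(got$min, oracle$min, tolerance = 1e-6, info = nm)
    expect_equal(got$max, oracle$max, tolerance = 1e-6, info = nm)
    known <- fx$fva
    got2 <- fva[match(known$reaction, fva$reaction), ]
    expect_equal(got2$min, known$min, tolerance = 1e-6, info = nm)
    expect_equal(got2$max, known$max, tolerance = 1e-6, info = nm)
  }
})

test_that("optimal solutions satisfy steady state and bounds", {
  m <- core_default()
  sc <- apply_scenario(m, scenario_config(light_limit = 20))
  sol <- solve_fba(sc$model, sc$objective, sc$constraints)
  expect_equal(sol$status, "optimal")
  S <- stoichiometric_matrix(sc$model)
  expect_lt(max(abs(as.numeric(S %*% sol$fluxes))), 1e-6)
  expect_true(all(sol$fluxes >= sc$model$reactions$lower_bound - 1e-8))
  expect_true(all(sol$fluxes <= sc$model$reactions$upper_bound + 1e-8))
})

test_that("scale invariance: scaling bounds scales the objective", {
  fx <- make_lp_fixture("branch")
  base <- solve_fba(fx$model)$objective_value
  for (k in c(0.5, 3)) {
    m2 <- fx$model
    m2$reactions$lower_bound <- m2$reactions$lower_bound * k
    m2$reactions$upper_bound <- m2$reactions$upper_bound * k
    expect_equal(solve_fba(m2)$objective_value, k * base, tolerance = 1e-8)
  }
})

test_that("random optima lie within their own fraction-1 FVA ranges", {
  fx <- make_lp_fixture("parallel")
  set.seed(7)
  for (k in 1:25) {
    cc <- setNames(rnorm(4), fx$model$reactions$id)
    obj <- objective_spec(cc)
    sol <- solve_fba(fx$model, obj)
    if (sol$status != "optimal") next
    fva <- flux_variability(fx$model, obj, fraction = 1.0)
    expect_true(all(sol$fluxes >= fva$min[match(names(sol$fluxes),
                                                fva$reaction)] - 1e-6))
    expect_true(all(sol$fluxes <= fva$max[match(names(sol$fluxes),
                                                fva$reaction)] + 1e-6))
  }
})

test_that("FVA ranges widen monotonically as the fraction is relaxed", {
  m <- core_default()
  sc <- apply_scenario(m, scenario_config(light_limit = 20))
  ids <- c("RBC", "PGAM", "ICD")
  f10 <- flux_variability(sc$model, sc$objective, 1.0, sc$constraints, ids)
  f09 <- flux_variability(sc$model, sc$objective, 0.9, sc$constraints, ids)
  expect_true(all(f09$min <= f10$min + 1e-6))
  expect_true(all(f09$max >= f10$max - 1e-6))
})

test_that("ratio constraints bind as written", {
  con <- add_ratio_constraint("RBO", "RBC", 0.03, ">=")
  expect_s3_class(con, "linear_constraint")
  expect_equal(unname(con$coefficients), c(1, -0.03))
  # ratio 0 with >= leaves the optimum unchanged
  fx <- make_lp_fixture("branch")
  con0 <- add_ratio_constraint("R_lo", "R_hi", 0, ">=")
  expect_equal(solve_fba(fx$model, extra = list(con0))$objective_value,
               solve_fba(fx$model)$objective_value, tolerance = 1e-9)
  # reversible reference triggers a warning
  m <- example_toy_model()
  expect_warning(add_ratio_constraint("R1", "R3", 0.1, model = m),
                 "reversible")
})

test_that("forced-flux scans are monotone and record infeasibility", {
  fx <- make_lp_fixture("wasteful_cycle")
  scan <- forced_flux_scan(fx$model, NULL, "CYC", c(0, 1, 2, 5, 1e5))
  expect_true(all(diff(scan$objective[scan$status == "optimal"]) < 1e-9))
  expect_gt(scan$objective[1] - scan$objective[2], 0.1) # immediate reduction
  expect_equal(scan$status[5], "infeasible")
  # forcing below the optimal flux leaves the objective unchanged
  scan2 <- forced_flux_scan(fx$model, NULL, "GEN_E", c(0, 1, 3))
  expect_equal(scan2$objective, rep(20 / 3, 3), tolerance = 1e-8)
})

test_that("parsimonious FBA preserves the optimum and removes loops", {
  m <- core_default()
  sc <- apply_scenario(m, scenario_config(light_limit = 20))
  plain <- solve_fba(sc$model, sc$objective, sc$constraints)
  pars <- parsimonious_fba(sc$model, sc$objective, sc$constraints)
  expect_equal(pars$objective_value, plain$objective_value, tolerance = 1e-6)
  expect_lte(sum(abs(pars$fluxes)), sum(abs(plain$fluxes)) + 1e-6)
})
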
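#' Scenario configuration for constraint-based analyses
#'
#' Collects every tunable constraint parameter and topology toggle that
#' defines one analysis condition. Defaults encode the phototrophic
#' reference: a 24 h doubling time (growth rate ln 2 / 24 per hour), carbon
#' taken up only as bicarbonate, nitrogen as nitrate, residual respiratory
#' activity in the light (terminal oxidase and Mehler-like reaction each
#' taking up 10% of the oxygen evolved by photosystem II), superoxide
#' formation at 0.5% of PSII and PSI electron flow, and RuBisCO oxygenase
#' forced to at least 3% of the carboxylase flux.
#'
#' @param growth_rate_target target growth rate, h^-1 (default `log(2)/24`).
#' @param carbon_source `"bicarbonate"`, `"acetate"` or `"none"`.
#' @param nitrogen_source logical; nitrate uptake open.
#' @param maintenance_atp growth-independent ATP hydrolysis,
#'   mmol gDW^-1 h^-1.
#' @param oxidase_fraction terminal-oxidase O2 uptake as a fraction of PSII
#'   O2 evolution (equality coupling; 0 disables).
#' @param mehler_like_fraction Mehler-like (flavodiiron) O2 uptake as a
#'   fraction of PSII O2 evolution.
#' @param ros_fraction fraction of PSII and PSI electron flow diverted to
#'   superoxide.
#' @param oxygenase_min_ratio lower bound on oxygenase:carboxylase flux.
#' @param storage_flux required glycogen synthesis in the light,
#'   mmol gDW^-1 h^-1.
#' @param phosphoserine_present,glyoxylate_shunt_present,tca_variant
#'   topology toggles, see [core_model_toggles()].
#' @param transhydrogenase_mode `"reversible"`, `"NADPH_to_NADH_only"` or
#'   `"absent"`.
#' @param ndh1_substrate `"NADPH_only"` or `"both"` (whether the
#'   proton-pumping NDH-1 complex also accepts NADH).
#' @param gdh_irreversible keep glutamate dehydrogenase irreversible in the
#'   deaminating direction (avoids cycles that substitute for the
#'   transhydrogenase).
#' @param glycogen_cap maximal glycogen mobilisation for dark scenarios,
#'   mmol gDW^-1 h^-1; `NA` = derive as (1 + eps) times the maintenance
#'   requirement, see [dark_metabolism()].
#' @param dcmu block photosystem II (the inhibitor DCMU).
#' @param light_limit photon uptake bound; `NA` = uncapped, or calibrated by
#'   the scenario functions to reach `growth_rate_target`.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(growth_rate_target = log(2) / 24,
                            carbon_source = c("bicarbonate", "acetate", "none"),
                            nitrogen_source = TRUE,
                            maintenance_atp = 0.15,
                            oxidase_fraction = 0.10,
                            mehler_like_fraction = 0.10,
                            ros_fraction = 0.005,
                            oxygenase_min_ratio = 0.03,
                            storage_flux = 0.05,
                            phosphoserine_present = TRUE,
                            glyoxylate_shunt_present = FALSE,
                            tca_variant = c("bypass", "OGDH", "GABA",
                                            "glyoxylate", "open", "all"),
                            transhydrogenase_mode = c("reversible",
                                                      "NADPH_to_NADH_only",
                                                      "absent"),
                            ndh1_substrate = c("NADPH_only", "both"),
                            gdh_irreversible = TRUE,
                            glycogen_cap = NA_real_,
                            dcmu = FALSE,
                            light_limit = NA_real_) {
  carbon_source <- match.arg(carbon_source)
  tca_variant <- match.arg(tca_variant)
  transhydrogenase_mode <- match.arg(transhydrogenase_mode)
  ndh1_substrate <- match.arg(ndh1_substrate)
  fr <- c(oxidase_fraction, mehler_like_fraction, ros_fraction)
  stopifnot(all(fr >= 0 & fr <= 1), oxygenase_min_ratio >= 0,
            maintenance_atp >= 0, storage_flux >= 0)
  structure(as.list(environment()), class = "scenario_config")
}

set_bounds <- function(model, id, lb = NULL, ub = NULL) {
  i <- match(id, model$reactions$id)
  if (is.na(i)) stop("no such reaction: ", id)
  if (!is.null(lb)) model$reactions$lower_bound[i] <- lb
  if (!is.null(ub)) model$reactions$upper_bound[i] <- ub
  model
}

remove_reactions <- function(model, ids) {
  ids <- intersect(ids, model$reactions$id)
  if (!length(ids)) return(model)
  model$reactions <- model$reactions[!model$reactions$id %in% ids, ]
  model$stoichiometry <-
    model$stoichiometry[!model$stoichiometry$reaction %in% ids, ]
  roles <- attr(model, "roles")
  if (!is.null(roles)) attr(model, "roles") <- roles[!roles %in% ids]
  model
}

role_id <- function(roles, role, required = TRUE) {
  if (role %in% names(roles)) return(unname(roles[[role]]))
  if (required) stop("model exposes no reaction for role '", role, "'")
  NA_character_
}

#' Apply a scenario configuration to a model
#'
#' Toggles pathway reactions on or off, sets exchange and directionality
#' bounds, builds the flux-ratio coupling rows, and returns the configured
#' problem. Reactions are addressed through the model's role mapping
#' ([core_model_roles()]), so the suite is model-agnostic.
#'
#' @param model a `metabolic_model` exposing the required roles.
#' @param config a [scenario_config()].
#' @param roles optional role mapping overriding the model's own.
#' @return A list with elements `model` (bounds set, toggled reactions
#'   removed), `constraints` (list of [linear_constraint()] coupling rows)
#'   and `objective` (an [objective_spec()] maximizing the biomass
#'   objective function).
#' @export
apply_scenario <- function(model, config, roles = core_model_roles(model)) {
  stopifnot(inherits(config, "scenario_config"))
  # --- topology: remove closure variants not selected -----------------------
  rid <- function(r) role_id(roles, r, required = FALSE)
  closure_roles <- list(
    OGDH = c("ogdh", "scs"), bypass = c("ogdc", "ssadh"),
    GABA = c("gad", "gabat", "ssadh"), glyoxylate = c("icl", "mals"))
  to_ids <- function(rr) {
    ids <- vapply(rr, rid, character(1))
    # fall back to canonical ids for roles the mapping does not carry
    ids[is.na(ids)] <- core_roles_all[rr[is.na(ids)]]
    ids
  }
  keep_roles <- switch(config$tca_variant,
                       all = unlist(closure_roles), open = character(0),
                       closure_roles[[config$tca_variant]])
  if (config$glyoxylate_shunt_present) keep_roles <- c(keep_roles, "icl", "mals")
  keep <- to_ids(unique(keep_roles))
  drop <- setdiff(to_ids(unique(unlist(closure_roles))), keep)
  if (config$tca_variant != "open") {
    need <- setdiff(keep, model$reactions$id)
    if (length(need))
      stop("configuration requires reaction(s) absent from the model: ",
           paste(need, collapse = ", "),
           " (tca_variant ", config$tca_variant, ")")
  }
  model <- remove_reactions(model, drop)
  if (!config$phosphoserine_present)
    model <- remove_reactions(model, c("PGCD", "PSAT", "PSP"))
  roles <- roles[roles %in% model$reactions$id]

  # --- exchange bounds ------------------------------------------------------
  ex_hco3 <- role_id(roles, "bicarbonate_exchange")
  ex_ac <- role_id(roles, "acetate_exchange")
  model <- set_bounds(model, ex_hco3,
                      lb = if (config$carbon_source == "bicarbonate") -1000 else 0)
  # acetate can be a carbon source but is never secreted (fermentative
  # export is outside the modelled physiology)
  model <- set_bounds(model, ex_ac, ub = 0,
                      lb = if (config$carbon_source == "acetate") -1000 else 0)
  if ("EX_no3" %in% model$reactions$id)
    model <- set_bounds(model, "EX_no3",
                        lb = if (config$nitrogen_source) -1000 else 0)
  pho <- role_id(roles, "photon_uptake")
  if (!is.na(config$light_limit))
    model <- set_bounds(model, pho, ub = config$light_limit)
  if (config$dcmu)
    model <- set_bounds(model, role_id(roles, "psii"), lb = 0, ub = 0)

  # --- directionality toggles ----------------------------------------------
  th <- role_id(roles, "transhydrogenase", required = FALSE)
  if (!is.na(th)) {
    model <- switch(config$transhydrogenase_mode,
      reversible = set_bounds(model, th, lb = -1000, ub = 1000),
      NADPH_to_NADH_only = set_bounds(model, th, lb = 0, ub = 1000),
      absent = set_bounds(model, th, lb = 0, ub = 0))
  }
  ndh1n <- role_id(roles, "ndh1_nadh", required = FALSE)
  if (!is.na(ndh1n))
    model <- set_bounds(model, ndh1n, lb = 0,
                        ub = if (config$ndh1_substrate == "both") 1000 else 0)
  gdh <- role_id(roles, "gdh", required = FALSE)
  if (!is.na(gdh))
    model <- set_bounds(model, gdh,
                        lb = if (config$gdh_irreversible) 0 else -1000)

  # --- maintenance and storage ---------------------------------------------
  model <- set_bounds(model, role_id(roles, "maintenance"),
                      lb = config$maintenance_atp)
  model <- set_bounds(model, role_id(roles, "glycogen_sink"),
                      lb = config$storage_flux)
  if (!is.na(config$glycogen_cap))
    model <- set_bounds(model, role_id(roles, "glycogen_source"),
                        ub = config$glycogen_cap)

  # --- coupling rows --------------------------------------------------------
  psii <- role_id(roles, "psii")
  cons <- list()
  if (config$oxidase_fraction > 0)
    cons <- c(cons, list(add_ratio_constraint(
      role_id(roles, "terminal_oxidase"), psii,
      config$oxidase_fraction, "=")))
  if (config$mehler_like_fraction > 0)
    cons <- c(cons, list(add_ratio_constraint(
      role_id(roles, "mehler_like"), psii,
      config$mehler_like_fraction, "=")))
  if (config$ros_fraction > 0) {
    # PSII: 4 electrons per reaction unit; ROS1 diverts 2 electrons per unit
    cons <- c(cons, list(
      add_ratio_constraint(role_id(roles, "ros_psii"), psii,
                           config$ros_fraction * 4 / 2, "="),
      add_ratio_constraint(role_id(roles, "ros_psi"), role_id(roles, "psi"),
                           config$ros_fraction, "=")))
  }
  if (config$oxygenase_min_ratio > 0)
    cons <- c(cons, list(add_ratio_constraint(
      role_id(roles, "oxygenase"), role_id(roles, "carboxylase"),
      config$oxygenase_min_ratio, ">=")))

  list(model = model,
       constraints = cons,
       objective = objective_spec(role_id(roles, "biomass")),
       roles = roles)
}

#' Calibrate the photon bound to a target growth rate
#'
#' Growth is light-limited in the reference condition; this finds the photon
#' uptake bound at which the optimized growth rate equals
#' `config$growth_rate_target` (bisection on a monotone function).
#'
#' @inheritParams apply_scenario
#' @return The calibrated photon flux bound.
#' @export
calibrate_light_limit <- function(model, config = scenario_config(),
                                  roles = core_model_roles(model)) {
  growth_at <- function(L) {
    cfg <- config; cfg$light_limit <- L
    sc <- apply_scenario(model, cfg, roles)
    sol <- solve_fba(sc$model, sc$objective, sc$constraints)
    if (sol$status != "optimal") -Inf else sol$objective_value
  }
  target <- config$growth_rate_target
  hi <- 1
  while (growth_at(hi) < target && hi < 1e5) hi <- hi * 4
  if (growth_at(hi) < target)
    stop("growth target unreachable at any photon flux")
  lo <- 0
  for (k in 1:40) {
    mid <- (lo + hi) / 2
    if (growth_at(mid) < target) lo <- mid else hi <- mid
  }
  hi
}

scenario_result <- function(config, solution, roles, fva = NULL) {
  structure(list(config = config, solution = solution,
                 indicators = scenario_indicators(solution, roles),
                 fva = fva, roles = roles),
            class = "scenario_result")
}

scenario_indicators <- function(solution, roles) {
  v <- function(role) {
    id <- if (role %in% names(roles)) roles[[role]] else NA_character_
    if (is.na(id) || !id %in% names(solution$fluxes)) return(NA_real_)
    unname(solution$fluxes[[id]])
  }
  carb <- v("carboxylase"); oxy <- v("oxygenase")
  closure <- sum(c(v("ssadh"), max(v("scs"), 0, na.rm = TRUE), v("icl")),
                 na.rm = TRUE)
  cyc <- min(closure, v("citrate_synthase"), v("sdh"), na.rm = TRUE)
  tibble::tibble(
    growth_rate = unname(solution$objective_value),
    photorespiration_rate = if (!is.na(carb) && carb > 1e-9)
      100 * oxy / carb else 0,
    pgk_pgm_ratio = if (!is.na(v("pgam")) && abs(v("pgam")) > 1e-9)
      v("pgk_cbb") / abs(v("pgam")) else NA_real_,
    tca_cyclic_flux = max(cyc, 0),
    opp_flux = v("opp"),
    net_o2_evolution = v("o2_exchange")) # exchange flux: positive = export
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result> status: ", x$solution$status, "\n", sep = "")
  print(x$indicators)
  invisible(x)
}

#' @export
tidy.scenario_result <- function(x, ...) tidy(x$solution, ...)

#' @export
glance.scenario_result <- function(x, ...) x$indicators

#' Phototrophic reference scenario
#'
#' Maximizes the biomass objective under the light-limited reference
#' constraints (bicarbonate-only carbon, nitrate nitrogen, maintenance ATP,
#' residual light respiration couplings, glycogen storage flux). When
#' `config$light_limit` is `NA` the photon bound is first calibrated so the
#' growth rate meets `config$growth_rate_target`.
#'
#' @inheritParams apply_scenario
#' @param fva_roles roles whose flux-variability ranges (at objective
#'   fraction 1) are reported alongside the vertex solution; fluxes that are
#'   not unique must be judged by these ranges.
#' @return A `scenario_result`: the configuration used, the `flux_solution`,
#'   derived indicators (growth rate, photorespiration rate as
#'   100 x oxygenase/carboxylase, PGK/PGM branchpoint ratio, cyclic TCA
#'   flux, OPP flux) and any FVA ranges requested.
#' @export
phototrophic_reference <- function(model, config = scenario_config(),
                                   roles = core_model_roles(model),
                                   fva_roles = character()) {
  if (is.na(config$light_limit))
    config$light_limit <- calibrate_light_limit(model, config, roles)
  sc <- apply_scenario(model, config, roles)
  sol <- parsimonious_fba(sc$model, sc$objective, sc$constraints)
  fva <- NULL
  if (length(fva_roles) && sol$status == "optimal") {
    ids <- unname(sc$roles[intersect(fva_roles, names(sc$roles))])
    fva <- flux_variability(sc$model, sc$objective, 1.0, sc$constraints,
                            reactions = ids)
  }
  scenario_result(config, sol, sc$roles, fva)
}

#' Dark metabolism scenario
#'
#' Photon uptake is zero and metabolism runs on stored glycogen. The
#' mobilisation cap follows the rule "only slightly above the maintenance
#' requirement": glycogen uptake is first minimized subject to the
#' maintenance ATP demand alone, and the cap is set to `(1 + eps)` times
#' that minimum. The biomass objective (residual growth / cellular
#' turnover) is then maximized under the cap.
#'
#' The redox routing of the optimum depends on `transhydrogenase_mode` and
#' `ndh1_substrate`: with a reversible transhydrogenase (or an NDH-1
#' accepting NADH), respiratory reducing power comes from cyclic TCA flux;
#' with neither, it comes from the oxidative pentose phosphate pathway.
#'
#' @inheritParams apply_scenario
#' @param eps headroom of the glycogen cap above the maintenance-only
#'   requirement (default 0.1).
#' @return A `scenario_result`; `indicators$tca_cyclic_flux` and
#'   `indicators$opp_flux` summarise the redox routing.
#' @export
dark_metabolism <- function(model, config = scenario_config(),
                            roles = core_model_roles(model), eps = 0.1) {
  config$light_limit <- 0
  config$oxidase_fraction <- 0
  config$mehler_like_fraction <- 0
  config$ros_fraction <- 0
  config$storage_flux <- 0
  if (is.na(config$glycogen_cap)) {
    cfg0 <- config; cfg0$glycogen_cap <- 1000
    sc0 <- apply_scenario(model, cfg0, roles)
    src <- role_id(sc0$roles, "glycogen_source")
    msol <- solve_fba(sc0$model, objective_spec(src, "minimize"),
                      sc0$constraints)
    if (msol$status != "optimal")
      stop("maintenance demand infeasible even with unlimited glycogen")
    config$glycogen_cap <- (1 + eps) * msol$objective_value
  }
  sc <- apply_scenario(model, config, roles)
  sol <- parsimonious_fba(sc$model, sc$objective, sc$constraints)
  scenario_result(config, sol, sc$roles)
}

#' Compare TCA-cycle closure variants
#'
#' Optimizes the same scenario under each of the four closure topologies
#' (OGDH complex, the decarboxylase/SSADH bypass, the GABA shunt, the
#' glyoxylate shunt) plus the open cycle, holding all remaining constraints
#' identical. The model must contain all variant reactions (build with
#' `tca_variant = "all"`).
#'
#' @inheritParams apply_scenario
#' @param scenario `"phototrophic"` or `"dark"`.
#' @param variants variants to compare.
#' @return Tibble with columns `variant`, `status`, `objective`.
#' @export
compare_tca_variants <- function(model, config = scenario_config(),
                                 scenario = c("phototrophic", "dark"),
                                 roles = core_model_roles(model),
                                 variants = c("OGDH", "bypass", "GABA",
                                              "open")) {
  scenario <- match.arg(scenario)
  if (scenario == "phototrophic" && is.na(config$light_limit))
    config$light_limit <- calibrate_light_limit(
      model, { c <- config; c$tca_variant <- "open"; c }, roles)
  if (scenario == "dark" && is.na(config$glycogen_cap)) {
    cfg <- config; cfg$tca_variant <- "open"
    config$glycogen_cap <- dark_metabolism(model, cfg, roles)$config$glycogen_cap
  }
  purrr::map_dfr(variants, function(vr) {
    cfg <- config; cfg$tca_variant <- vr
    res <- if (scenario == "phototrophic") {
      sc <- apply_scenario(model, cfg, roles)
      solve_fba(sc$model, sc$objective, sc$constraints)
    } else {
      dark_metabolism(model, cfg, roles)$solution
    }
    tibble::tibble(variant = vr, status = res$status,
                   objective = res$objective_value)
  })
}

#' Photorespiration scenarios
#'
#' The three serine/glycine provisioning scenarios: (1) no phosphoserine
#' pathway — serine, glycine and cysteine derive from glyoxylate, so a
#' nonzero photorespiratory flux emerges from the optimization itself;
#' (2) phosphoserine pathway present — photorespiration ceases and the
#' oxygenase leaves the optimal solution; (3) phosphoserine pathway present
#' with the oxygenase forced to at least 3% of carboxylase flux — the bound
#' binds, and flux variability shows the two stoichiometrically equivalent
#' fates of glyoxylate (to glycine, or recycled to the CBB cycle via
#' glycerate).
#'
#' @inheritParams phototrophic_reference
#' @param scenario_id 1, 2 or 3.
#' @return A `scenario_result`; `indicators$photorespiration_rate` is
#'   100 x oxygenase/carboxylase at the optimum, and `fva` carries ranges
#'   for the oxygenase and the two glyoxylate routes.
#' @export
photorespiration_analysis <- function(model, config = scenario_config(),
                                      scenario_id = 1,
                                      roles = core_model_roles(model)) {
  stopifnot(scenario_id %in% 1:3)
  config$phosphoserine_present <- scenario_id >= 2
  config$oxygenase_min_ratio <- if (scenario_id == 3) 0.03 else 0
  phototrophic_reference(model, config, roles,
                         fva_roles = c("oxygenase", "glyoxylate_to_glycine",
                                       "glyoxylate_to_glycerate"))
}

#' Photoheterotrophic acetate + DCMU growth test
#'
#' The in-silico counterpart of the spot assay on acetate in the presence of
#' the PSII inhibitor DCMU: water splitting and linear electron transport
#' are blocked (PSI cyclic electron flow and ATP generation are not),
#' bicarbonate exchange is closed to net uptake, and acetate is the sole
#' carbon source. With a glyoxylate shunt the network can form C4 skeletons
#' from acetate and grows; without it, net anaplerosis from C2 units is
#' impossible and maximal growth is zero.
#'
#' @inheritParams apply_scenario
#' @param glyoxylate_shunt_present include isocitrate lyase + malate
#'   synthase.
#' @param control run the photomixotrophic control instead (acetate + light
#'   + bicarbonate, no DCMU), where growth is positive regardless of the
#'   shunt.
#' @return The maximal growth rate (0 when photoheterotrophic growth is
#'   impossible).
#' @export
acetate_dcmu_test <- function(model, glyoxylate_shunt_present,
                              config = scenario_config(),
                              roles = core_model_roles(model),
                              control = FALSE) {
  config$glyoxylate_shunt_present <- glyoxylate_shunt_present
  config$dcmu <- !control
  config$carbon_source <- "acetate"
  config$oxidase_fraction <- 0
  config$mehler_like_fraction <- 0
  config$ros_fraction <- 0
  config$oxygenase_min_ratio <- 0
  config$storage_flux <- 0
  config$light_limit <- 1000
  sc <- apply_scenario(model, config, roles)
  if (control)
    sc$model <- set_bounds(sc$model, role_id(roles, "bicarbonate_exchange"),
                           lb = -1000)
  sol <- solve_fba(sc$model, sc$objective, sc$constraints)
  if (sol$status != "optimal") return(0)
  max(sol$objective_value, 0)
}
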
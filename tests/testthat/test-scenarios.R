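test_that("scenario toggles edit the model as configured", {
  m <- core_all()
  cfg <- scenario_config(tca_variant = "open", dcmu = TRUE,
                         phosphoserine_present = FALSE)
  sc <- apply_scenario(m, cfg)
  expect_false(any(c("OGDH", "SCS", "OGDC", "SSADH", "GAD", "GABAT",
                     "ICL", "MALS", "PGCD", "PSAT", "PSP") %in%
                     sc$model$reactions$id))
  i <- match("PSII", sc$model$reactions$id)
  expect_equal(sc$model$reactions$upper_bound[i], 0)
  # zero fractions add no coupling rows
  cfg0 <- scenario_config(oxidase_fraction = 0, mehler_like_fraction = 0,
                          ros_fraction = 0, oxygenase_min_ratio = 0)
  expect_length(apply_scenario(m, cfg0)$constraints, 0)
  # default fractions: oxidase + mehler + 2 ROS + oxygenase floor
  expect_length(apply_scenario(m, scenario_config())$constraints, 5)
})

test_that("phototrophic reference meets the growth target and couplings", {
  res <- reference_run()
  expect_equal(res$solution$status, "optimal")
  expect_equal(res$indicators$growth_rate, log(2) / 24, tolerance = 1e-3)
  v <- res$solution$fluxes
  # residual respiration and Mehler-like activity at 10% of PSII O2, ROS at
  # 0.5% of electron flow (coupling rows hold exactly)
  expect_equal(v[["COX"]], 0.10 * v[["PSII"]], tolerance = 1e-8)
  expect_equal(v[["FDP"]], 0.10 * v[["PSII"]], tolerance = 1e-8)
  expect_equal(v[["ROS1"]], 0.01 * v[["PSII"]], tolerance = 1e-8)
  expect_equal(v[["ROS2"]], 0.005 * v[["PSI"]], tolerance = 1e-8)
  # oxygenase floor binds (photorespiration is yield-costly)
  expect_equal(v[["RBO"]], 0.03 * v[["RBC"]], tolerance = 1e-8)
  # net oxygen evolution in the light
  expect_gt(res$indicators$net_o2_evolution, 0)
})

test_that("phototrophic flux map is non-cyclic with active phosphoketolase", {
  res <- reference_run()
  v <- res$solution$fluxes
  expect_gt(v[["PHK1"]] + v[["PHK2"]], 1e-4) # PHK shortcut carries flux
  expect_lt(abs(v[["PDH"]]), 1e-8)           # bypassing the CO2-releasing PDH
  expect_lt(abs(v[["SSADH"]]), 1e-8)
  expect_equal(res$indicators$tca_cyclic_flux, 0, tolerance = 1e-8)
  expect_lt(abs(res$indicators$opp_flux), 1e-8)
})

test_that("TCA shortcuts carry no flux in any phototrophic optimum (FVA)", {
  m <- core_all()
  cfg <- scenario_config(tca_variant = "all")
  cfg$light_limit <- calibrate_light_limit(m, cfg)
  sc <- apply_scenario(m, cfg)
  fva <- flux_variability(sc$model, sc$objective, 1.0, sc$constraints,
                          reactions = c("SSADH", "OGDH", "OGDC"))
  expect_true(all(fva$max <= 1e-6))
  expect_true(all(fva$min >= -1e-6))
})

test_that("flux direction is invariant over a 10x light range", {
  m <- build_core_model(core_model_toggles(include_phk = FALSE))
  cfg <- scenario_config(maintenance_atp = 0, storage_flux = 0,
                         oxygenase_min_ratio = 0)
  sols <- lapply(c(5, 50), function(L) {
    cfg$light_limit <- L
    sc <- apply_scenario(m, cfg)
    parsimonious_fba(sc$model, sc$objective, sc$constraints)$fluxes
  })
  cs <- sum(sols[[1]] * sols[[2]]) /
    sqrt(sum(sols[[1]]^2) * sum(sols[[2]]^2))
  expect_equal(cs, 1, tolerance = 1e-6)
})

test_that("dark redox routing follows transhydrogenase and NDH-1 assumptions", {
  m <- core_default()
  # reversible transhydrogenase: respiration via cyclic TCA, OPP negligible
  d1 <- dark_metabolism(m, scenario_config(transhydrogenase_mode = "reversible"))
  expect_gt(d1$indicators$tca_cyclic_flux, 1e-4)
  expect_lt(d1$indicators$opp_flux, 0.05 * d1$indicators$tca_cyclic_flux)
  # no transhydrogenase, NADPH-specific NDH-1: OPP takes over, no cyclic flux
  d2 <- dark_metabolism(m, scenario_config(transhydrogenase_mode = "absent"))
  expect_equal(d2$indicators$tca_cyclic_flux, 0, tolerance = 1e-8)
  expect_gt(d2$indicators$opp_flux, 1e-4)
  # NDH-1 accepting NADH restores the cyclic TCA solution
  d3 <- dark_metabolism(m, scenario_config(transhydrogenase_mode = "absent",
                                           ndh1_substrate = "both"))
  expect_gt(d3$indicators$tca_cyclic_flux, 1e-4)
  expect_lt(d3$indicators$opp_flux, 0.05 * d3$indicators$tca_cyclic_flux)
})

test_that("dark glycogen cap slightly exceeds the maintenance requirement", {
  m <- core_default()
  d <- dark_metabolism(m, scenario_config(), eps = 0.1)
  expect_equal(d$solution$status, "optimal")
  expect_gt(d$indicators$growth_rate, 0) # residual growth fits in the slack
  # a cap below the maintenance requirement is infeasible
  tight <- scenario_config()
  tight$glycogen_cap <- d$config$glycogen_cap / (1.1 * 2)
  d2 <- dark_metabolism(m, tight)
  expect_equal(d2$solution$status, "infeasible")
})

test_that("TCA closure variants rank as stoichiometry dictates", {
  m <- core_all()
  dark <- compare_tca_variants(m, scenario = "dark")
  obj <- setNames(dark$objective, dark$variant)
  expect_equal(obj[["GABA"]], obj[["bypass"]], tolerance = 1e-6)
  expect_gt(obj[["OGDH"]], obj[["bypass"]] + 1e-6)
  expect_gt(obj[["bypass"]], obj[["open"]])
  photo <- compare_tca_variants(m, scenario = "phototrophic")
  expect_lt(diff(range(photo$objective)), 1e-6) # closure unused in the light
})

test_that("photorespiration scenarios reproduce the three regimes", {
  m <- core_default()
  r1 <- photorespiration_analysis(m, scenario_config(), 1)
  expect_gt(r1$indicators$photorespiration_rate, 1) # emerges from optimality
  oxy1 <- r1$fva[r1$fva$reaction == "RBO", ]
  expect_gt(oxy1$min, 0)
  r2 <- photorespiration_analysis(m, scenario_config(), 2)
  expect_equal(r2$indicators$photorespiration_rate, 0, tolerance = 1e-6)
  oxy2 <- r2$fva[r2$fva$reaction == "RBO", ]
  expect_lt(oxy2$max, 1e-6) # ceases in every optimum
  r3 <- photorespiration_analysis(m, scenario_config(), 3)
  expect_equal(r3$indicators$photorespiration_rate, 3, tolerance = 1e-6)
  # both glyoxylate fates are optimal alternatives
  gly <- r3$fva[r3$fva$reaction == "GGAT", ]
  glr <- r3$fva[r3$fva$reaction == "GCL", ]
  expect_gt(gly$max, 1e-6)
  expect_gt(glr$max, 1e-6)
  # an extra pathway can only help
  expect_gte(r2$indicators$growth_rate,
             r1$indicators$growth_rate - 1e-9)
})

test_that("acetate + DCMU growth requires the glyoxylate shunt", {
  m <- core_shunt()
  expect_gt(acetate_dcmu_test(m, TRUE), 1e-6)
  expect_lt(abs(acetate_dcmu_test(m, FALSE)), 1e-9)
  # photomixotrophic control grows regardless of the shunt
  expect_gt(acetate_dcmu_test(m, TRUE, control = TRUE), 1e-6)
  expect_gt(acetate_dcmu_test(m, FALSE, control = TRUE), 1e-6)
})

test_that("added constraints never increase the optimum (monotone burden)", {
  m <- core_default()
  cfg <- scenario_config(light_limit = 20)
  sc <- apply_scenario(m, cfg)
  base <- solve_fba(sc$model, sc$objective, sc$constraints)$objective_value
  for (con in list(add_ratio_constraint("RBO", "RBC", 0.10, ">="),
                   linear_constraint(c(ZWF = 1), ">=", 0.01))) {
    v <- solve_fba(sc$model, sc$objective, c(sc$constraints, list(con)))
    expect_lte(v$objective_value, base + 1e-9)
  }
})

test_that("forcing flux through the OGDH shortcut cuts phototrophic growth", {
  m <- core_all()
  cfg <- scenario_config(tca_variant = "all", light_limit = 20)
  sc <- apply_scenario(m, cfg)
  scan <- forced_flux_scan(sc$model, sc$objective, "OGDH",
                           c(0, 0.05, 0.1), extra = sc$constraints)
  expect_true(all(diff(scan$objective) < -1e-6)) # immediate, strong reduction
})
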
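# memoized fixtures shared across test files (built once per test run)
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixtures)) assign(key, force(expr), .fixtures)
  get(key, .fixtures)
}

core_default <- function() memo("core_default", build_core_model())

core_all <- function()
  memo("core_all", build_core_model(core_model_toggles(tca_variant = "all")))

core_shunt <- function()
  memo("core_shunt",
       build_core_model(core_model_toggles(glyoxylate_shunt_present = TRUE)))

reference_run <- function()
  memo("reference_run", phototrophic_reference(core_default(), scenario_config()))

diurnal_run <- function()
  memo("diurnal_run", run_diurnal(core_default(), diurnal_config()))

design12 <- function() rep(circadian_design_times(), 2)
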
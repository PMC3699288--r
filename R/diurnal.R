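#' Configuration of the diurnal dynamic-FBA simulation
#'
#' Defines the 24 h light/dark cycle, the time-varying biomass objective and
#' the storage dynamics. The day starts at circadian time (CT) 0 (sunrise);
#' light follows a triangular profile peaking at CT `day_length / 2` and is
#' zero through the night. Per-step synthesis of the biomass components
#' follows the window rules: DNA and inorganic ions at a constant rate over
#' the full cycle; protein, RNA, cell wall and lipid only during the light
#' phase, in proportion to light availability; pigments from two hours
#' before sunrise until two hours before dusk (plateau with linear ramps);
#' glycogen storage accumulates only from mid-day onward and is the
#' optimization objective of the light phase, while dark steps maximize ATP
#' production subject to maintenance.
#'
#' @param n_steps steps per 24 h (default 48, i.e. 30 min).
#' @param day_length light-phase duration, h (default 12).
#' @param light_peak photon flux at the apex of the triangle; `NA` = five
#'   times the constant-light photon bound calibrated to the reference
#'   growth rate (enough to meet the compressed daytime synthesis demand
#'   with headroom for storage).
#' @param smoothing_steps steps over which window transitions are ramped
#'   linearly (default 4).
#' @param dark_respiration_fraction night terminal-oxidase cap as a fraction
#'   of the light-phase oxidase level at peak light (default 0.1).
#' @param pigment_lead_h hours before sunrise at which pigment synthesis
#'   starts (and before dusk at which it ends; default 2).
#' @param daily_totals named vector of per-component 24 h synthesis targets
#'   (mmol gDW^-1 d^-1); `NULL` = the amounts implied by integrating the
#'   reference biomass composition over one doubling-time day
#'   (`log(2) * BOF weight` per component).
#' @param scenario a [scenario_config()] providing the remaining constraint
#'   parameters (maintenance ATP, coupling fractions, redox toggles).
#' @return A `diurnal_config` list.
#' @export
diurnal_config <- function(n_steps = 48, day_length = 12,
                           light_peak = NA_real_, smoothing_steps = 4,
                           dark_respiration_fraction = 0.1,
                           pigment_lead_h = 2,
                           daily_totals = NULL,
                           scenario = scenario_config()) {
  stopifnot(n_steps >= 4, day_length > 0, day_length < 24,
            dark_respiration_fraction >= 0, dark_respiration_fraction <= 1,
            smoothing_steps >= 0)
  if ((n_steps * day_length) %% 24 != 0)
    stop("n_steps must place a step boundary at dusk ",
         "(n_steps * day_length divisible by 24)")
  if (!is.null(daily_totals) && any(daily_totals < 0))
    stop("daily_totals must be non-negative")
  structure(list(n_steps = n_steps, day_length = day_length,
                 light_peak = light_peak, smoothing_steps = smoothing_steps,
                 dark_respiration_fraction = dark_respiration_fraction,
                 pigment_lead_h = pigment_lead_h,
                 daily_totals = daily_totals, scenario = scenario),
            class = "diurnal_config")
}

#' Triangular diurnal light profile
#'
#' Zero at and after dusk and before sunrise; linear from 0 at sunrise
#' (CT 0) to `light_peak` at CT `day_length / 2`, back to 0 at dusk. Times
#' outside \[0, 24) are wrapped.
#'
#' @param t circadian time, h (vectorised).
#' @param config a [diurnal_config()] (its `light_peak` must be set).
#' @return Photon flux at `t`.
#' @export
light_profile <- function(t, config) {
  t <- t %% 24
  peak <- config$light_peak
  if (is.na(peak)) stop("light_peak is not set; run build_schedule() first")
  half <- config$day_length / 2
  ifelse(t >= config$day_length, 0, peak * (1 - abs(t - half) / half))
}

# components synthesised through DM_* demand reactions
diurnal_components <- c("protein", "dna", "rna", "lipid", "pigment",
                        "cellwall", "ion")

default_daily_totals <- function(model) {
  # 24 h at the reference growth rate ln2/24 drains log(2) x BOF weight
  bof <- model$stoichiometry[model$stoichiometry$reaction == "BOF", ]
  w <- -bof$coefficient[match(diurnal_components, bof$metabolite)]
  setNames(log(2) * w, diurnal_components)
}

#' Build the per-step diurnal schedule
#'
#' Resolves the light profile and the per-step biomass-component weight
#' vectors. Weights are synthesis-rate requirements (mmol gDW^-1 h^-1)
#' scaled so that each component's rates integrate to its 24 h daily total:
#' constant for DNA and ions, proportional to light for protein / RNA /
#' cell wall / lipid, and a ramped plateau over the pigment window. Dark
#' steps carry objective mode `"ATP"`, light steps `"biomass"`.
#'
#' @param config a [diurnal_config()].
#' @param model the model to be simulated (used for default daily totals);
#'   `NULL` uses [build_core_model()] defaults.
#' @param reference optional precomputed [phototrophic_reference()] result
#'   used to calibrate `light_peak`; computed on demand when absent.
#' @return A list of class `diurnal_schedule`: `steps` (tibble with step,
#'   time, mid-point time, light, mode), `weights` (tibble step x component
#'   with the required synthesis rate) and the resolved `config`.
#' @export
build_schedule <- function(config, model = NULL, reference = NULL) {
  if (is.null(model)) model <- build_core_model()
  if (is.na(config$light_peak)) {
    if (is.null(reference))
      reference <- phototrophic_reference(model, config$scenario)
    config$light_peak <- 5 * reference$config$light_limit
    attr(config, "reference") <- reference
  }
  n <- config$n_steps
  dt <- 24 / n
  t0 <- (seq_len(n) - 1) * dt
  mid <- t0 + dt / 2
  light <- light_profile(mid, config)
  dark <- t0 >= config$day_length | t0 + dt <= 1e-9 # step fully after dusk
  mode <- ifelse(light > 0, "biomass", "ATP")

  totals <- config$daily_totals
  if (is.null(totals)) totals <- default_daily_totals(model)
  missing <- setdiff(diurnal_components, names(totals))
  if (length(missing)) stop("daily_totals lacks component: ", missing[1])

  # window shapes, normalised so sum(shape * dt) == 1
  shape_const <- rep(1 / 24, n)
  shape_light <- light / sum(light * dt)
  ramp_w <- config$smoothing_steps * dt
  pig_start <- 24 - config$pigment_lead_h
  pig_end <- config$day_length - config$pigment_lead_h
  pig_raw <- vapply(mid, function(tt) {
    # window wraps midnight: [pig_start, 24) U [0, pig_end)
    inside <- tt >= pig_start | tt < pig_end
    if (!inside) return(0)
    since <- (tt - pig_start) %% 24        # hours since window opened
    until <- (pig_end - tt) %% 24          # hours until window closes
    min(1, if (ramp_w > 0) min(since / ramp_w, until / ramp_w) else 1)
  }, numeric(1))
  shape_pig <- pig_raw / sum(pig_raw * dt)

  weights <- tibble::tibble(step = rep(seq_len(n), length(diurnal_components)),
                            component = rep(diurnal_components, each = n),
                            rate = c(totals[["protein"]] * shape_light,
                                     totals[["dna"]] * shape_const,
                                     totals[["rna"]] * shape_light,
                                     totals[["lipid"]] * shape_light,
                                     totals[["pigment"]] * shape_pig,
                                     totals[["cellwall"]] * shape_light,
                                     totals[["ion"]] * shape_const))
  steps <- tibble::tibble(step = seq_len(n), time = t0, mid = mid,
                          light = light, mode = mode,
                          storage_window = mid >= config$day_length / 2 &
                            mid < config$day_length)
  structure(list(steps = steps, weights = weights, config = config,
                 daily_totals = totals),
            class = "diurnal_schedule")
}

#' Run the diurnal dynamic-FBA simulation
#'
#' Static-optimization dynamic FBA: each step solves one FBA problem with
#' that step's light bound, synthesis requirements and objective mode, then
#' updates the glycogen pool and the cumulative amount of each synthesized
#' component. Light steps carry the residual-respiration, Mehler-like and
#' superoxide couplings relative to PSII and maximize net glycogen storage
#' (bounded to the second half of the day); dark steps cap the terminal
#' oxidase at `dark_respiration_fraction` of its peak-light level and
#' maximize ATP production subject to maintenance. Glycogen degradation is
#' bounded by the current pool content, which therefore never goes
#' negative.
#'
#' @param model a core model from [build_core_model()].
#' @param config a [diurnal_config()].
#' @param pool0 initial glycogen pool, mmol glucosyl units gDW^-1; `NA`
#'   starts with the amount needed to reach dawn (one full night of the
#'   dark-phase demand, estimated from the schedule).
#' @return A `diurnal_trajectory`: `steps` (per-step tibble with time,
#'   light, mode, status, objective, glycogen pool and net O2 exchange),
#'   `fluxes` (steps x reactions matrix), `cumulative` (long tibble of
#'   cumulative synthesized amounts), `schedule`, and `status` ("complete"
#'   or a diagnostic if a step was infeasible and the trajectory was
#'   truncated).
#' @export
run_diurnal <- function(model, config = diurnal_config(), pool0 = NA_real_) {
  sched <- build_schedule(config, model)
  config <- sched$config
  cfg <- config$scenario
  ref <- attr(config, "reference")
  if (is.null(ref)) ref <- phototrophic_reference(model, cfg)
  roles <- core_model_roles(model)
  rid <- function(r) role_id(roles, r)

  # peak-light PSII estimate scales linearly from the calibrated reference
  psii_ref <- ref$solution$fluxes[[rid("psii")]]
  psii_peak <- psii_ref * config$light_peak / ref$config$light_limit
  night_cox <- config$dark_respiration_fraction *
    cfg$oxidase_fraction * psii_peak

  base_cfg <- cfg
  base_cfg$storage_flux <- 0
  base_cfg$light_limit <- NA_real_ # photon bound set per step
  sc <- apply_scenario(model, base_cfg, roles)
  m0 <- sc$model
  m0 <- set_bounds(m0, rid("biomass"), lb = 0, ub = 0) # DM_* replace the BOF
  day_cons <- sc$constraints

  n <- config$n_steps
  dt <- 24 / n
  dm_ids <- paste0("DM_", diurnal_components)
  pool <- if (is.na(pool0)) {
    # one night of respiration plus dark synthesis, with 50% headroom
    1.5 * (24 - config$day_length) *
      (night_cox + sum(sched$daily_totals[c("dna", "ion", "pigment")]) / 24)
  } else {
    pool0
  }

  flux_mat <- matrix(NA_real_, n, nrow(m0$reactions),
                     dimnames = list(NULL, m0$reactions$id))
  pool_series <- numeric(n)
  obj_series <- numeric(n)
  status <- "complete"
  cum <- matrix(0, n, length(diurnal_components),
                dimnames = list(NULL, diurnal_components))
  cum_now <- setNames(rep(0, length(diurnal_components)), diurnal_components)

  wt <- tidyr::pivot_wider(sched$weights, names_from = "component",
                           values_from = "rate")
  wt <- wt[order(wt$step), ]

  for (k in seq_len(n)) {
    st <- sched$steps[k, ]
    mk <- m0
    mk <- set_bounds(mk, rid("photon_uptake"), ub = max(st$light, 0))
    # synthesis requirements: equality bounds on the demand reactions
    for (comp in diurnal_components) {
      rr <- wt[[comp]][k]
      mk <- set_bounds(mk, paste0("DM_", comp), lb = rr, ub = rr)
    }
    # glycogen pool draw limited by current content
    mk <- set_bounds(mk, rid("glycogen_source"), lb = 0, ub = pool / dt)
    if (st$mode == "biomass") {
      mk <- set_bounds(mk, rid("glycogen_sink"), lb = 0,
                       ub = if (st$storage_window) 1000 else 0)
      cons <- day_cons
      objective <- objective_spec(setNames(
        c(1, -1), c(rid("glycogen_sink"), rid("glycogen_source"))))
    } else {
      mk <- set_bounds(mk, rid("glycogen_sink"), lb = 0, ub = 0)
      mk <- set_bounds(mk, rid("terminal_oxidase"), ub = night_cox)
      # night O2 uptake capped at the scaled-down respiration rate; this
      # paces glycogen consumption through the night
      mk <- set_bounds(mk, rid("o2_exchange"), lb = -night_cox)
      cons <- list() # PSII-relative couplings are moot without light
      objective <- objective_spec(rid("maintenance"))
    }
    sol <- parsimonious_fba(mk, objective, cons)
    if (sol$status != "optimal") {
      status <- sprintf(paste0("infeasible at step %d (CT %.2f h, mode %s, ",
                               "glycogen pool %.4f); trajectory truncated"),
                        k, st$mid, st$mode, pool)
      warning(status)
      break
    }
    flux_mat[k, ] <- sol$fluxes
    obj_series[k] <- sol$objective_value
    pool <- pool + (sol$fluxes[[rid("glycogen_sink")]] -
                      sol$fluxes[[rid("glycogen_source")]]) * dt
    pool <- max(pool, 0)
    pool_series[k] <- pool
    cum_now <- cum_now + sol$fluxes[dm_ids] * dt
    cum[k, ] <- cum_now
  }
  done <- if (status == "complete") n else k - 1
  steps <- sched$steps
  steps$status <- c(rep("optimal", done), rep("infeasible", n - done))
  steps$objective <- c(obj_series[seq_len(done)], rep(NA, n - done))
  steps$glycogen <- c(pool_series[seq_len(done)], rep(NA, n - done))
  ex_o2 <- rid("o2_exchange")
  steps$net_o2_evolution <- flux_mat[, ex_o2]
  cumulative <- tibble::as_tibble(cum[seq_len(done), , drop = FALSE])
  cumulative$step <- seq_len(done)
  cumulative <- tidyr::pivot_longer(cumulative, -"step",
                                    names_to = "component",
                                    values_to = "cumulative")
  structure(list(steps = steps, fluxes = flux_mat, cumulative = cumulative,
                 schedule = sched, status = status, dt = dt,
                 roles = roles, night_cox = night_cox),
            class = "diurnal_trajectory")
}

#' @export
print.diurnal_trajectory <- function(x, ...) {
  cat("<diurnal_trajectory> ", nrow(x$steps), " steps of ",
      format(x$dt, digits = 3), " h; status: ", x$status, "\n", sep = "")
  invisible(x)
}

#' Tidy a diurnal trajectory into a long flux table
#'
#' @param x a `diurnal_trajectory`.
#' @param reactions optional reaction ids to keep.
#' @param ... unused.
#' @return Tibble with columns `step`, `time`, `reaction`, `flux`.
#' @export
tidy.diurnal_trajectory <- function(x, reactions = NULL, ...) {
  df <- tibble::as_tibble(x$fluxes)
  df$step <- x$steps$step
  df$time <- x$steps$mid
  out <- tidyr::pivot_longer(df, c(-"step", -"time"),
                             names_to = "reaction", values_to = "flux")
  if (!is.null(reactions)) out <- out[out$reaction %in% reactions, ]
  out
}

#' Integrate component synthesis over the full cycle
#'
#' Left-Riemann sums of the per-step synthesis fluxes times the step width;
#' equal by construction to the final values of the cumulative series.
#'
#' @param trajectory a complete `diurnal_trajectory`.
#' @return Tibble with columns `component`, `total` (mmol gDW^-1 per 24 h).
#' @export
integrate_components <- function(trajectory) {
  if (trajectory$status != "complete")
    stop("trajectory incomplete: ", trajectory$status)
  dm_ids <- paste0("DM_", diurnal_components)
  tot <- colSums(trajectory$fluxes[, dm_ids, drop = FALSE]) * trajectory$dt
  tibble::tibble(component = diurnal_components, total = unname(tot))
}

#' Carbon closure of a diurnal trajectory
#'
#' Balances the carbon taken up over 24 h (bicarbonate minus released CO2
#' and any acetate exchange) against the carbon accumulated in biomass
#' components and the net change of the glycogen pool.
#'
#' @param trajectory a complete `diurnal_trajectory`.
#' @param model the simulated model (for component carbon contents).
#' @return A one-row tibble with `carbon_in`, `carbon_stored`,
#'   `relative_gap`.
#' @export
carbon_balance <- function(trajectory, model) {
  stopifnot(trajectory$status == "complete")
  dt <- trajectory$dt
  fx <- trajectory$fluxes
  roles <- trajectory$roles
  uptake <- function(role) -sum(fx[, roles[[role]]]) * dt
  c_in <- uptake("bicarbonate_exchange") + uptake("co2_exchange") +
    2 * uptake("acetate_exchange")
  carbon_of <- function(ids)
    element_count(model$metabolites$formula[match(ids, model$metabolites$id)], "C")
  comp_c <- carbon_of(diurnal_components)
  totals <- integrate_components(trajectory)$total
  pool0 <- trajectory$steps$glycogen[1] -
    (fx[1, roles[["glycogen_sink"]]] - fx[1, roles[["glycogen_source"]]]) * dt
  dpool <- trajectory$steps$glycogen[nrow(trajectory$steps)] - pool0
  c_stored <- sum(totals * comp_c) + 6 * dpool
  tibble::tibble(carbon_in = c_in, carbon_stored = c_stored,
                 relative_gap = (c_in - c_stored) / max(c_in, 1e-12))
}

#' Plot a diurnal trajectory
#'
#' Four panels against circadian time: light, glycogen pool, net O2
#' exchange, and selected fluxes.
#'
#' @param object a `diurnal_trajectory`.
#' @param reactions reaction ids for the flux panel.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.diurnal_trajectory <- function(object,
                                        reactions = c("RBC", "SSADH", "GPM"),
                                        ...) {
  st <- object$steps
  top <- tibble::tibble(time = st$mid,
                        light = st$light, glycogen = st$glycogen,
                        net_o2 = st$net_o2_evolution)
  top <- tidyr::pivot_longer(top, -"time", names_to = "panel",
                             values_to = "value")
  fl <- tidy(object, reactions = reactions)
  fl$panel <- paste0("flux: ", fl$reaction)
  df <- dplyr::bind_rows(top,
                         tibble::tibble(time = fl$time, panel = fl$panel,
                                        value = fl$flux))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, linewidth = 0.3) +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 2) +
    ggplot2::labs(x = "circadian time (h)", y = NULL,
                  title = "Diurnal simulation") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
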
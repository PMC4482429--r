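#' Simulation configuration
#'
#' Builds the full parameter set for one simulation. Every argument has a
#' calibrated default; the defaults describe healthy vascularised soft tissue
#' over a bony prominence subjected to alternating 2 h pressure cycles (the
#' clinical turning convention). Concentrations and rates are in arbitrary
#' model units; lengths are in grid cells; one tick is one simulated hour.
#'
#' The tunable groups are:
#' \describe{
#'   \item{geometry/vasculature}{`grid_width`, `grid_height`, `vessel_density`
#'     (vessels per cell, placed on a jittered regular lattice),
#'     `vessel_size_min`/`vessel_size_max` (sizes are drawn uniformly and the
#'     largest must stay below twice the smallest).}
#'   \item{oxygen}{vessels release `oxygen_production_rate` scaled by their
#'     current/mean size; living tissue consumes `oxygen_consumption_rate`
#'     per tick; below `oxygen_ischemia_threshold` a cell is ischemic
#'     (oxygen exactly at threshold counts as perfused).}
#'   \item{layers}{each diffusible species has a `<layer>_diffusion_fraction`
#'     (mass-conserving 8-neighbour spread, applied `diffusion_substeps`
#'     times per tick) and a `<layer>_degradation_rate` (fraction lost per
#'     tick); layers are `oxygen, damp, tnf, il1, tgf, ros, steroid,
#'     antidamp, antiox`.}
#'   \item{ischemia/reperfusion}{ischemic cells gain
#'     `oxidase_accumulation_rate` of xanthine oxidase and lose
#'     `ischemia_penalty * oxygen_sensitivity` life; perfused cells heal at
#'     `heal_rate * oxygen_sensitivity`; on reperfusion a fraction
#'     `reperfusion_conversion_fraction` of the stored oxidase converts to
#'     ROS at `reperfusion_ros_coeff` per unit (debiting
#'     `reperfusion_oxygen_cost` oxygen); local ROS above
#'     `ros_event_threshold / ros_sensitivity` adds one insult, and every
#'     `ros_insult_limit` insults cost `ros_insult_penalty` life at once.}
#'   \item{inflammation}{TNF damages (`tnf_sensitivity * tnf_damage_coeff`)
#'     and TGF heals (`tgf_sensitivity * tgf_heal_coeff`) tissue; stressed
#'     cells release DAMPs scaled by the life drop; thresholds
#'     (`thr_damp_activate_N`, `thr_tnf_to_M1`, `thr_il1_to_M1`,
#'     `thr_il1_to_M2`, `thr_tgf_to_M2`, `thr_direct_damage_activation`)
#'     gate probabilistic state changes (`p_activate_N`, `p_switch_M1`,
#'     `p_switch_M2`); lifespans are drawn uniformly from the configured
#'     ranges and activation extends a neutrophil's lifespan.}
#'   \item{pressure}{`pressure_intensity` applied on a central plateau of
#'     radius `pressure_plateau_radius`, decaying (linearly by default) to
#'     zero at `pressure_falloff_radius`, alternating on/off every
#'     `pressure_half_period` ticks (or following the explicit
#'     `pressure_on_ticks` list); vessels shrink by
#'     `pressure_constriction_coeff * pressure` of their base size.}
#'   \item{treatments}{`treatment_agent` (`"none"`, `"steroid"` = IV,
#'     `"antidamp"` = topical), `treatment_dose`, `treatment_onset_tick`,
#'     plus the steroid kill rule (`steroid_mode`, `steroid_threshold`,
#'     `steroid_neutrophil_ros_burst`, `steroid_delivery`) and the anti-DAMP
#'     quenching coefficient `antidamp_quench_coeff`.}
#' }
#'
#' @param ... named parameter overrides; unknown names are an error.
#' @return an object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(grid_width = 50, grid_height = 50)
#' cfg$pressure_intensity
#' @export
sim_config <- function(...) {
  cfg <- default_config_values()
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all configuration overrides must be named")
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  validate_config(cfg)
}

default_config_values <- function() {
  list(
    grid_width = 100L, grid_height = 100L,
    tick_hours = 1, n_ticks = 1000L, seed = 1L,
    vessel_density = 0.04, vessel_size_min = 1.0, vessel_size_max = 1.5,

    oxygen_production_rate = 100, oxygen_consumption_rate = 1.5,
    oxygen_ischemia_threshold = 2.0, oxygen_sensitivity = 1,

    oxygen_diffusion_fraction = 0.9,  oxygen_degradation_rate = 0.2,
    damp_diffusion_fraction = 0.05,   damp_degradation_rate = 0.10,
    tnf_diffusion_fraction = 0.15,    tnf_degradation_rate = 0.15,
    il1_diffusion_fraction = 0.05,    il1_degradation_rate = 0.10,
    tgf_diffusion_fraction = 0.05,    tgf_degradation_rate = 0.10,
    ros_diffusion_fraction = 0.4,     ros_degradation_rate = 0.30,
    steroid_diffusion_fraction = 0.1, steroid_degradation_rate = 0.10,
    antidamp_diffusion_fraction = 0,  antidamp_degradation_rate = 0.01,
    antiox_diffusion_fraction = 0.05, antiox_degradation_rate = 0.10,
    diffusion_substeps = 16L,

    heal_rate = 0.04, ischemia_penalty = 0.309,
    oxidase_accumulation_rate = 1.0, reperfusion_ros_coeff = 1.5,
    reperfusion_conversion_fraction = 1.0, reperfusion_oxygen_cost = 0.1,
    ros_event_threshold = 2.5, ros_insult_limit = 12L,
    ros_insult_penalty = 0.6, ros_sensitivity = 1,

    tnf_sensitivity = 1, tgf_sensitivity = 1,
    tnf_damage_coeff = 0.30, tnf_damage_saturation = 1.2, tgf_heal_coeff = 0.02,
    damp_secretion_rate = 800, tissue_death_damp_burst = 30,
    tnf_secretion_rate = 4.0,
    il1_secretion_rate = 1.0, tgf_secretion_rate = 1.0,

    thr_damp_activate_N = 45, thr_tnf_to_M1 = 3.0,
    thr_il1_to_M1 = 2.0, thr_il1_to_M2 = 6.0, thr_tgf_to_M2 = 8.0,
    thr_direct_damage_activation = 55,
    p_activate_N = 0.0092, p_switch_M1 = 0.5, p_switch_M2 = 0.5,
    o2_activation_threshold = 4.5,

    neutrophil_lifespan_min = 10L, neutrophil_lifespan_max = 20L,
    neutrophil_activated_lifespan_bonus = 70L,
    neutrophil_death_ros_burst = 0,
    macrophage_lifespan_min = 100L, macrophage_lifespan_max = 150L,
    recruitment_rate_N = 0.15, recruitment_rate_M = 0.02,
    chemotaxis_floor = 0.05,
    leukocyte_site_capacity = 1L,

    pressure_intensity = 1, pressure_half_period = 2L,
    pressure_plateau_radius = 10, pressure_falloff_radius = 25,
    pressure_constriction_coeff = 1, pressure_profile = "linear",
    pressure_on_ticks = NULL,

    initial_injury_fraction = 0, initial_injury_radius = 10,
    stress_mode = "decreasing",

    steroid_threshold = 0.5, steroid_neutrophil_ros_burst = 2,
    steroid_mode = "kill_all", steroid_delivery = "infusion",
    antidamp_quench_coeff = 0.5,
    antiox_production_rate = 0, antiox_quench_coeff = 0.5,

    treatment_agent = "none", treatment_dose = 0, treatment_onset_tick = 0L
  )
}

validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  num1 <- function(nm) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v))
      stop("configuration field '", nm, "' must be a single number")
    v
  }
  if (num1("grid_width") < 1 || num1("grid_height") < 1)
    stop("grid dimensions must be positive")
  if (num1("vessel_size_max") >= 2 * num1("vessel_size_min"))
    stop("vessel_size_max must be smaller than twice vessel_size_min ",
         "(vessel sizes span a narrow uniform range)")
  if (num1("thr_il1_to_M2") <= num1("thr_il1_to_M1"))
    stop("thr_il1_to_M2 must exceed thr_il1_to_M1 (the M2-inducing IL-1 ",
         "level is the higher one)")
  if (num1("pressure_falloff_radius") < num1("pressure_plateau_radius"))
    stop("pressure_falloff_radius must be >= pressure_plateau_radius")
  probs <- c("p_activate_N", "p_switch_M1", "p_switch_M2",
             "recruitment_rate_N", "recruitment_rate_M",
             "initial_injury_fraction", "reperfusion_conversion_fraction")
  for (nm in probs) {
    v <- num1(nm)
    if (v < 0 || v > 1)
      stop("configuration field '", nm, "' must lie in [0, 1]")
  }
  fr <- grep("_diffusion_fraction$|_degradation_rate$", names(cfg),
             value = TRUE)
  for (nm in fr) {
    v <- num1(nm)
    if (v < 0 || v > 1)
      stop("configuration field '", nm, "' must lie in [0, 1]")
  }
  nonneg <- c("vessel_density", "oxygen_production_rate",
              "oxygen_consumption_rate", "oxygen_ischemia_threshold",
              "oxygen_sensitivity", "tnf_sensitivity", "tgf_sensitivity",
              "ros_sensitivity", "heal_rate", "ischemia_penalty",
              "oxidase_accumulation_rate", "reperfusion_ros_coeff",
              "reperfusion_oxygen_cost", "ros_event_threshold",
              "ros_insult_penalty", "damp_secretion_rate",
              "tnf_secretion_rate", "il1_secretion_rate",
              "tgf_secretion_rate", "tnf_damage_coeff", "tnf_damage_saturation", "tgf_heal_coeff",
              "tissue_death_damp_burst",
              "thr_damp_activate_N", "thr_tnf_to_M1", "thr_il1_to_M1",
              "thr_il1_to_M2", "thr_tgf_to_M2",
              "thr_direct_damage_activation", "pressure_intensity",
              "pressure_plateau_radius", "pressure_falloff_radius",
              "pressure_constriction_coeff", "initial_injury_radius",
              "steroid_threshold", "steroid_neutrophil_ros_burst",
              "antidamp_quench_coeff", "antiox_production_rate", "o2_activation_threshold",
              "antiox_quench_coeff", "treatment_dose", "chemotaxis_floor",
              "neutrophil_death_ros_burst")
  for (nm in nonneg) if (num1(nm) < 0)
    stop("configuration field '", nm, "' must be non-negative")
  ints <- c("grid_width", "grid_height", "n_ticks", "diffusion_substeps",
            "leukocyte_site_capacity",
            "neutrophil_lifespan_min", "neutrophil_lifespan_max",
            "neutrophil_activated_lifespan_bonus", "macrophage_lifespan_min",
            "macrophage_lifespan_max", "pressure_half_period",
            "treatment_onset_tick", "ros_insult_limit")
  for (nm in ints) cfg[[nm]] <- as.integer(num1(nm))
  if (cfg$neutrophil_lifespan_max < cfg$neutrophil_lifespan_min ||
      cfg$macrophage_lifespan_max < cfg$macrophage_lifespan_min)
    stop("lifespan ranges must have max >= min")
  if (!cfg$pressure_profile %in% c("linear", "gaussian"))
    stop("pressure_profile must be 'linear' or 'gaussian'")
  if (!cfg$stress_mode %in% c("decreasing", "below_max"))
    stop("stress_mode must be 'decreasing' or 'below_max'")
  if (!cfg$steroid_mode %in% c("kill_all", "kill_activated", "disable"))
    stop("invalid steroid_mode")
  if (!cfg$steroid_delivery %in% c("infusion", "bolus"))
    stop("invalid steroid_delivery")
  if (!cfg$treatment_agent %in% c("none", "steroid", "antidamp"))
    stop("treatment_agent must be 'none', 'steroid' or 'antidamp'")
  if (!is.null(cfg$pressure_on_ticks))
    cfg$pressure_on_ticks <- as.integer(cfg$pressure_on_ticks)
  class(cfg) <- "sim_config"
  cfg
}

#' Scenario shortcuts
#'
#' `config_pressure()` is the default pressure-cycling scenario;
#' `config_acute()` is the acute-inflammation scenario (no pressure, a
#' central initial injury); `config_unperturbed()` is the negative control
#' (no pressure, no injury).
#'
#' @param injury_fraction multiplicative life reduction on the central disc
#'   (0.3 = cells start at life 70).
#' @param ... further overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
config_pressure <- function(...) sim_config(...)

#' @rdname config_pressure
#' @export
config_acute <- function(injury_fraction = 0.3, ...) {
  sim_config(pressure_intensity = 0,
             initial_injury_fraction = injury_fraction, ...)
}

#' @rdname config_pressure
#' @export
config_unperturbed <- function(...) {
  sim_config(pressure_intensity = 0, initial_injury_fraction = 0, ...)
}

#' Read a configuration file
#'
#' Reads a flat YAML or JSON mapping whose keys are `sim_config` field names.
#' Unknown keys are an error; omitted keys keep their defaults.
#'
#' @param path file path (`.json` is parsed as JSON, anything else as YAML).
#' @return a `sim_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(vals)) stop("config file must contain a mapping")
  do.call(sim_config, vals)
}

#' Write a configuration (or any manifest) as JSON
#'
#' @param cfg a `sim_config`.
#' @param path output path.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$grid_width, "x", x$grid_height,
      " grid, ", x$n_ticks, " ticks\n", sep = "")
  cat("  pressure: intensity ", x$pressure_intensity,
      ", half-period ", x$pressure_half_period, " h\n", sep = "")
  cat("  initial injury: ", 100 * x$initial_injury_fraction, "% (radius ",
      x$initial_injury_radius, ")\n", sep = "")
  cat("  treatment: ", x$treatment_agent,
      if (x$treatment_agent != "none")
        paste0(" dose ", x$treatment_dose, " from tick ",
               x$treatment_onset_tick), "\n", sep = "")
  invisible(x)
}
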
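#' Run a seeded ensemble
#'
#' Runs `n` independent simulations with consecutive seeds and collects
#' per-run outcomes. Ensemble experiments at desk scale typically use a
#' reduced lattice (see the methods vignette); mechanism parameters are
#' unchanged.
#'
#' @param config a `sim_config`.
#' @param n number of runs.
#' @param seed seed of the first run; run `i` uses `seed + i - 1`.
#' @param n_ticks override of `config$n_ticks`.
#' @param keep_trajectories keep the full per-tick tables (needed for
#'   classifier experiments; costs memory).
#' @return a list with `summary` (data frame: `run`, `seed`,
#'   `final_damage`, `ulceration_tick`, `ulcerated`) and, if kept,
#'   `trajectories`.
#' @export
run_ensemble <- function(config, n, seed = 1L, n_ticks = config$n_ticks,
                         keep_trajectories = FALSE) {
  seeds <- as.integer(seed) + seq_len(n) - 1L
  trajs <- if (keep_trajectories) vector("list", n) else NULL
  final_damage <- numeric(n)
  ulc <- integer(n)
  for (i in seq_len(n)) {
    tr <- run_sim(config, seed = seeds[i], n_ticks = n_ticks)
    final_damage[i] <- tr[["total-damage"]][nrow(tr)]
    u <- attr(tr, "ulceration_tick")
    ulc[i] <- if (is.na(u)) NA_integer_ else u
    if (keep_trajectories) trajs[[i]] <- tr
  }
  out <- list(summary = data.frame(
    run = seq_len(n), seed = seeds, final_damage = final_damage,
    ulceration_tick = ulc, ulcerated = !is.na(ulc)))
  if (keep_trajectories) out$trajectories <- trajs
  out
}

#' Find seeds whose runs reach a given outcome
#'
#' Scans consecutive seeds until `n_each` ulcerating and `n_each`
#' resolving runs are found (used to pick the source runs of the restart
#' experiment).
#'
#' @param config a `sim_config`.
#' @param n_each number of seeds of each outcome to collect.
#' @param n_ticks run length used to decide the outcome.
#' @param start_seed first seed scanned.
#' @param max_scan give up after this many seeds.
#' @return list with integer vectors `ulcerated` and `resolved`.
#' @export
find_outcome_seeds <- function(config, n_each, n_ticks = config$n_ticks,
                               start_seed = 1L, max_scan = 50L * n_each) {
  ulc <- integer(0); res <- integer(0)
  s <- as.integer(start_seed)
  for (i in seq_len(max_scan)) {
    if (length(ulc) >= n_each && length(res) >= n_each) break
    tr <- run_sim(config, seed = s, n_ticks = n_ticks)
    if (is.na(attr(tr, "ulceration_tick"))) {
      if (length(res) < n_each) res <- c(res, s)
    } else {
      if (length(ulc) < n_each) ulc <- c(ulc, s)
    }
    s <- s + 1L
  }
  if (length(ulc) < n_each || length(res) < n_each)
    stop("could not find ", n_each, " seeds of each outcome within ",
         max_scan, " runs")
  list(ulcerated = ulc, resolved = res)
}

#' Checkpoint-restart commitment-time experiment
#'
#' For each source run, the full state is checkpointed every
#' `checkpoint_interval` ticks up to `checkpoint_max`; the source then
#' continues for `horizon` further ticks to fix its own outcome
#' (ulcerated = any tissue-cell death). From every checkpoint,
#' `n_restarts` re-simulations are launched with fresh random seeds and
#' run for `horizon` ticks; the per-checkpoint disagreement rate is the
#' fraction of restarts whose outcome differs from their source's. A
#' disagreement rate that falls to zero marks the tick by which the
#' outcome was already committed in the saved state.
#'
#' @param config a `sim_config`.
#' @param source_seeds seeds of the source runs (mix of outcomes, e.g.
#'   from [find_outcome_seeds()]).
#' @param checkpoint_interval,checkpoint_max checkpoint schedule (ticks).
#' @param n_restarts restarts per checkpoint per source.
#' @param horizon additional ticks run after each checkpoint.
#' @param restart_seed base seed for the fresh restart streams.
#' @return list with `rates` (data frame: `checkpoint_tick`, `n`,
#'   `disagreement`), `detail` (per restart) and `sources` (per source
#'   seed and outcome).
#' @export
restart_experiment <- function(config, source_seeds,
                               checkpoint_interval = 25L,
                               checkpoint_max = 200L,
                               n_restarts = 20L, horizon = 500L,
                               restart_seed = 10000L) {
  ticks <- seq(checkpoint_interval, checkpoint_max, by = checkpoint_interval)
  detail <- list()
  sources <- list()
  rseed <- as.integer(restart_seed)
  for (ss in source_seeds) {
    state <- init_state(config, ss)
    checkpoints <- vector("list", length(ticks))
    t_done <- 0L
    dead_seen <- FALSE
    for (j in seq_along(ticks)) {
      st <- step_sim(state, config, ticks[j] - t_done, record = FALSE)
      state <- st
      t_done <- ticks[j]
      checkpoints[[j]] <- state
    }
    out <- step_sim(state, config, horizon, record = TRUE)
    src_ulc <- sum(out$state$alive == 0L) > 0
    sources[[length(sources) + 1]] <- data.frame(
      seed = ss, ulcerated = src_ulc)
    for (j in seq_along(ticks)) {
      for (r in seq_len(n_restarts)) {
        st2 <- reseed_state(checkpoints[[j]], rseed)
        rseed <- rseed + 1L
        fin <- step_sim(st2, config, horizon, record = FALSE)
        re_ulc <- sum(fin$alive == 0L) > 0
        detail[[length(detail) + 1]] <- data.frame(
          source_seed = ss, checkpoint_tick = ticks[j], restart = r,
          source_ulcerated = src_ulc, restart_ulcerated = re_ulc,
          disagree = re_ulc != src_ulc)
      }
    }
  }
  detail <- do.call(rbind, detail)
  rates <- do.call(rbind, lapply(ticks, function(tk) {
    d <- detail[detail$checkpoint_tick == tk, ]
    data.frame(checkpoint_tick = tk, n = nrow(d),
               disagreement = mean(d$disagree))
  }))
  list(rates = rates, detail = detail,
       sources = do.call(rbind, sources))
}

#' Override one configuration parameter by name
#'
#' @param config a `sim_config`.
#' @param param parameter name (unknown names are an error).
#' @param value new value.
#' @return a validated `sim_config`.
#' @export
config_update <- function(config, param, value) {
  if (!param %in% names(config))
    stop("unknown configuration parameter: ", param)
  cfg <- unclass(config)
  cfg[[param]] <- value
  validate_config(cfg)
}

#' Global three-mechanism sensitivity analysis
#'
#' The model has three direct sources of tissue damage: lack of oxygen,
#' TNF and ROS. Each is controlled by one broadly effective sensitivity
#' parameter; setting it to zero removes that damage source entirely.
#' This runs all 8 default/zero combinations and reports mean damage and
#' ulceration at the snapshot tick.
#'
#' @param config base `sim_config`.
#' @param reps replicates per combination.
#' @param t_snap snapshot tick.
#' @param seed ensemble base seed.
#' @return data frame: `oxygen_sensitivity`, `tnf_sensitivity`,
#'   `ros_sensitivity` (logical "at default"), `mean_damage`,
#'   `ulceration_fraction`.
#' @export
sensitivity_global <- function(config, reps = 20, t_snap = 400L, seed = 1L) {
  combos <- expand.grid(oxy = c(FALSE, TRUE), tnf = c(FALSE, TRUE),
                        ros = c(FALSE, TRUE))
  out <- list()
  for (i in seq_len(nrow(combos))) {
    cfg <- config
    if (!combos$oxy[i]) cfg <- config_update(cfg, "oxygen_sensitivity", 0)
    if (!combos$tnf[i]) cfg <- config_update(cfg, "tnf_sensitivity", 0)
    if (!combos$ros[i]) cfg <- config_update(cfg, "ros_sensitivity", 0)
    ens <- run_ensemble(cfg, reps, seed = seed, n_ticks = t_snap)
    out[[i]] <- data.frame(
      oxygen_sensitivity = combos$oxy[i], tnf_sensitivity = combos$tnf[i],
      ros_sensitivity = combos$ros[i],
      mean_damage = mean(ens$summary$final_damage),
      ulceration_fraction = mean(ens$summary$ulcerated))
  }
  do.call(rbind, out)
}

#' Two-parameter sensitivity sweep
#'
#' Mean end-point damage over the cross product of two parameter value
#' grids, the module-level analysis behind the pairwise sensitivity
#' panels.
#'
#' @param config base `sim_config`.
#' @param param_x,values_x,param_y,values_y swept parameters and values.
#' @param t_snap snapshot tick.
#' @param reps replicates per grid cell.
#' @param seed base seed.
#' @return data frame: `param_x`/`param_y` values, `mean_damage`,
#'   `ulceration_fraction`.
#' @export
sensitivity_grid <- function(config, param_x, values_x, param_y, values_y,
                             t_snap = 400L, reps = 10, seed = 1L) {
  out <- list()
  for (vx in values_x) for (vy in values_y) {
    cfg <- config_update(config_update(config, param_x, vx), param_y, vy)
    ens <- run_ensemble(cfg, reps, seed = seed, n_ticks = t_snap)
    out[[length(out) + 1]] <- data.frame(
      x = vx, y = vy, mean_damage = mean(ens$summary$final_damage),
      ulceration_fraction = mean(ens$summary$ulcerated))
  }
  res <- do.call(rbind, out)
  names(res)[1:2] <- c(param_x, param_y)
  res
}

#' Sensitivity index of a parameter
#'
#' The ratio of the change in mean end-point damage to the change in
#' parameter value between two parameter settings.
#'
#' @param config base `sim_config`.
#' @param param parameter name.
#' @param v1,v2 the two values (must differ).
#' @param reps replicates per value.
#' @param t_snap snapshot tick.
#' @param seed base seed.
#' @return a number: `(mean_damage(v2) - mean_damage(v1)) / (v2 - v1)`.
#' @export
sensitivity_index <- function(config, param, v1, v2, reps = 10,
                              t_snap = 400L, seed = 1L) {
  if (v1 == v2) stop("sensitivity index needs two distinct values")
  m <- vapply(c(v1, v2), function(v) {
    cfg <- config_update(config, param, v)
    mean(run_ensemble(cfg, reps, seed = seed,
                      n_ticks = t_snap)$summary$final_damage)
  }, numeric(1))
  (m[2] - m[1]) / (v2 - v1)
}

#' In-silico treatment trial grid
#'
#' Runs replicate simulations over a dose-by-onset grid of one treatment
#' under either the default pressure-cycling scenario or a 40% acute
#' initial injury without pressure, plus the untreated arm (dose 0).
#'
#' @param treatment `"steroid"` or `"antidamp"`.
#' @param doses,onsets numeric grids; the untreated arm is added
#'   automatically.
#' @param scenario `"pressure"` or `"acute_injury_40"`.
#' @param config base `sim_config` (scenario fields are overridden).
#' @param t_end ticks per run.
#' @param reps replicates per arm.
#' @param seed base seed.
#' @return data frame: `dose`, `onset`, `ulceration_fraction`,
#'   `mean_damage`, `mean_ulceration_tick`.
#' @export
trial_grid <- function(treatment, doses, onsets,
                       scenario = c("pressure", "acute_injury_40"),
                       config = sim_config(), t_end = 700L, reps = 50,
                       seed = 1L) {
  scenario <- match.arg(scenario)
  treatment <- match.arg(treatment, c("steroid", "antidamp"))
  base <- if (scenario == "pressure") {
    config_update(config_update(config, "initial_injury_fraction", 0),
                  "pressure_intensity",
                  max(config$pressure_intensity, 1))
  } else {
    config_update(config_update(config, "initial_injury_fraction", 0.4),
                  "pressure_intensity", 0)
  }
  arms <- rbind(data.frame(dose = 0, onset = 0),
                expand.grid(dose = doses, onset = onsets))
  out <- list()
  for (i in seq_len(nrow(arms))) {
    cfg <- base
    if (arms$dose[i] > 0) {
      cfg <- config_update(cfg, "treatment_agent", treatment)
      cfg <- config_update(cfg, "treatment_dose", arms$dose[i])
      cfg <- config_update(cfg, "treatment_onset_tick",
                           as.integer(arms$onset[i]))
    }
    ens <- run_ensemble(cfg, reps, seed = seed, n_ticks = t_end)
    s <- ens$summary
    out[[i]] <- data.frame(
      dose = arms$dose[i], onset = arms$onset[i],
      ulceration_fraction = mean(s$ulcerated),
      mean_damage = mean(s$final_damage),
      mean_ulceration_tick = if (any(s$ulcerated))
        mean(s$ulceration_tick[s$ulcerated]) else NA_real_)
  }
  do.call(rbind, out)
}

#' Write an experiment table with its reproducibility manifest
#'
#' Emits the tidy result table as CSV and a JSON manifest (fully resolved
#' configuration, seeds, package version) next to it, so every output
#' artifact can be regenerated from its manifest alone.
#'
#' @param df result data frame.
#' @param path CSV output path (the manifest replaces the extension with
#'   `.manifest.json`).
#' @param config the `sim_config` used.
#' @param seed the base seed used.
#' @param extra optional named list merged into the manifest.
#' @export
write_results <- function(df, path, config, seed, extra = list()) {
  write.csv(df, path, row.names = FALSE)
  man <- c(list(config = unclass(config), seed = seed,
                package_version = as.character(utils::packageVersion("pressim")),
                created = format(Sys.time(), tz = "UTC")),
           extra)
  jsonlite::write_json(man, sub("\\.csv$", ".manifest.json", path),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}
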
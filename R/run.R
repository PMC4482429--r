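#' Advance a simulation
#'
#' Executes `n` ticks of the model. Each tick applies, in order: pressure
#' update and vessel constriction; vessel oxygen release and leukocyte
#' recruitment; layer diffusion then degradation; the tissue-cell rule
#' (oxygen consumption, ischemia or healing, reperfusion ROS, stepwise ROS
#' insults, TNF damage, TGF healing, DAMP release); leukocyte movement,
#' activation and secretion; treatment effects; aging and death; feature
#' recording.
#'
#' @param state a `sim_state`.
#' @param config the `sim_config` the state was built with.
#' @param n number of ticks to execute.
#' @param record if `TRUE`, also return the per-tick feature table.
#' @return if `record`, a list with elements `state` and `features`
#'   (a data frame, one row per executed tick); otherwise the new state.
#' @export
step_sim <- function(state, config, n = 1L, record = TRUE) {
  stopifnot(inherits(state, "sim_state"), inherits(config, "sim_config"))
  out <- cpp_run(state, config, as.integer(n), record)
  if (!record) return(out$state)
  list(state = out$state, features = as.data.frame(out$features,
                                                   check.names = FALSE))
}

#' Run a complete simulation
#'
#' Composition of [init_state()] and `config$n_ticks` ticks with per-tick
#' feature recording; the trajectory's `ulceration_tick` attribute is the
#' first tick at which any tissue cell died (the opening of the ulcer), or
#' `NA` if none died.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @param n_ticks number of ticks (defaults to `config$n_ticks`).
#' @param keep_state if `TRUE`, attach the final `sim_state` as an
#'   attribute (costs memory across large ensembles).
#' @return a `sim_trajectory`: a data frame with columns `tick`, the 13
#'   whole-field features and `dead-cells`, plus attributes
#'   `ulceration_tick`, `seed` and (optionally) `final_state`.
#' @export
run_sim <- function(config, seed = config$seed, n_ticks = config$n_ticks,
                    keep_state = FALSE) {
  state <- init_state(config, seed)
  out <- cpp_run(state, config, as.integer(n_ticks), TRUE)
  traj <- as.data.frame(out$features, check.names = FALSE)
  class(traj) <- c("sim_trajectory", "data.frame")
  attr(traj, "ulceration_tick") <- ulceration_from_deaths(traj[["dead-cells"]],
                                                          traj[["tick"]])
  attr(traj, "seed") <- as.integer(seed)
  if (keep_state) attr(traj, "final_state") <- out$state
  traj
}

ulceration_from_deaths <- function(dead, tick) {
  i <- which(dead > 0)
  if (!length(i)) NA_integer_ else as.integer(tick[i[1]])
}

#' First tissue-cell death in a trajectory
#'
#' The opening of a pressure ulcer is defined as the first instance of
#' tissue-cell death.
#'
#' @param trajectory a `sim_trajectory` (or any data frame with `tick` and
#'   `dead-cells` columns).
#' @return the earliest tick with at least one dead cell, or `NA_integer_`.
#' @export
detect_ulceration <- function(trajectory) {
  ulceration_from_deaths(trajectory[["dead-cells"]], trajectory[["tick"]])
}

#' @export
print.sim_trajectory <- function(x, ...) {
  ut <- attr(x, "ulceration_tick")
  fd <- if (nrow(x)) format(x[["total-damage"]][nrow(x)]) else "NA"
  cat("<sim_trajectory> ", nrow(x), " ticks; final damage ", fd,
      "; ulceration ",
      if (is.null(ut) || !length(ut) || is.na(ut)) "none"
      else paste0("at tick ", ut), "\n", sep = "")
  invisible(x)
}

#' Export a trajectory as CSV
#'
#' One row per tick; columns are `tick`, the 13 feature names and the
#' cumulative `dead-cells` count. Column order is stable.
#'
#' @param trajectory a `sim_trajectory`.
#' @param path output file.
#' @export
write_trajectory <- function(trajectory, path) {
  write.csv(trajectory, path, row.names = FALSE)
  invisible(path)
}
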
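#' Pressure at a position
#'
#' During the "on" phase of the cycle, pressure equals `intensity` on the
#' central plateau and decays (linearly by default; optionally as a
#' Gaussian shoulder) to zero at the falloff radius; during the "off"
#' phase it is zero everywhere. The schedule alternates every
#' `pressure_half_period` ticks starting "on", unless an explicit
#' `pressure_on_ticks` list is configured.
#'
#' @param r radial distance(s) from the pressure centre, in cells.
#' @param tick tick at which to evaluate the schedule.
#' @param config a `sim_config` (uses its pressure fields).
#' @return pressure value(s), same length as `r`.
#' @export
pressure_at <- function(r, tick, config) {
  cpp_pressure_at(as.numeric(r), config$pressure_intensity,
                  config$pressure_plateau_radius,
                  config$pressure_falloff_radius,
                  pressure_phase_on(tick, config), config$pressure_profile)
}

#' @rdname pressure_at
#' @export
pressure_phase_on <- function(tick, config) {
  if (config$pressure_intensity <= 0) return(FALSE)
  if (!is.null(config$pressure_on_ticks))
    return(tick %in% config$pressure_on_ticks)
  if (config$pressure_half_period <= 0) return(TRUE)
  (((tick - 1) %/% config$pressure_half_period) %% 2) == 0
}

#' Vessel constriction under pressure
#'
#' `current_size = base_size * max(0, 1 - c * pressure)`: strictly
#' decreasing in local pressure until full occlusion, and equal to the base
#' size when pressure is zero.
#'
#' @param base_size vessel base sizes.
#' @param pressure local pressure values (recycled if scalar).
#' @param config a `sim_config` (uses `pressure_constriction_coeff`).
#' @return constricted sizes.
#' @export
constrict_vessels <- function(base_size, pressure, config) {
  n <- max(length(base_size), length(pressure))
  cpp_vessel_size(rep_len(as.numeric(base_size), n),
                  rep_len(as.numeric(pressure), n),
                  config$pressure_constriction_coeff)
}

#' Single-cell tissue rule
#'
#' Applies one tick of the tissue-cell rule to one cell: oxygen
#' consumption; ischemia (oxidase accumulation and life penalty) below the
#' oxygen threshold, healing at or above it; reperfusion conversion of
#' stored oxidase to a ROS burst; the stepwise ROS insult counter; the TNF
#' damage and TGF healing terms; clamping of life to `[0, 100]` and death
#' at 0; and stress-scaled DAMP release. This calls the same compiled
#' kernel the simulation loop runs.
#'
#' @param life,oxidase,insults current cell fields.
#' @param oxygen,tnf,tgf,ros local concentrations at the cell's site.
#' @param config a `sim_config`.
#' @return a list: `life`, `oxidase`, `insults`, `oxygen_after` (local
#'   oxygen after consumption and any reperfusion debit), `ros_add` and
#'   `damp_add` (amounts deposited at the site), `died`.
#' @export
tissue_cell_update <- function(life, oxidase = 0, insults = 0L, oxygen,
                               tnf = 0, tgf = 0, ros = 0, config) {
  cpp_tissue_kernel(life, oxidase, as.integer(insults), oxygen, tnf, tgf,
                    ros, config)
}

#' Chemotactic move choice
#'
#' Given the eight Moore-neighbourhood attractant sums (in row order
#' NW, N, NE, W, E, SW, S, SE), returns the index of the chosen neighbour:
#' the argmax when the strongest signal exceeds the sensing floor (ties
#' broken uniformly at random), otherwise a uniformly random neighbour.
#'
#' @param neighbours numeric vector of 8 attractant sums.
#' @param floor sensing floor below which movement is undirected.
#' @param seed integer seed for the draw.
#' @return neighbour index in 1..8.
#' @export
chemotax_choice <- function(neighbours, floor = 0, seed = 1L) {
  cpp_chemotax_pick(as.numeric(neighbours), floor, as.integer(seed))
}

#' Mass-conserving lattice diffusion
#'
#' Each cell keeps `1 - fraction` of its content and distributes
#' `fraction/8` to each of its eight toroidal neighbours, `substeps` times.
#'
#' @param mat a numeric matrix (a concentration layer).
#' @param fraction diffusion fraction in `[0, 1]`.
#' @param substeps number of passes.
#' @return the diffused matrix.
#' @export
diffuse_layer <- function(mat, fraction, substeps = 1L) {
  cpp_diffuse(mat, fraction, as.integer(substeps))
}

#' Oxygen released by vessels in one tick
#'
#' Each vessel deposits `oxygen_production_rate * current_size /
#' mean(base_size)` at its own site; a fully occluded vessel releases
#' nothing.
#'
#' @param state a `sim_state`.
#' @param config a `sim_config`.
#' @return numeric vector of per-vessel release amounts.
#' @export
vessel_oxygen_release <- function(state, config) {
  v <- state$vessels
  config$oxygen_production_rate * v$current_size / mean(v$base_size)
}
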
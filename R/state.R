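#' Initialise a simulation state
#'
#' Lays one tissue cell per grid site at full health (life = 100), places
#' blood vessels on a jittered regular lattice with uniformly drawn sizes
#' (the largest below twice the smallest), applies the optional central
#' initial injury, pre-equilibrates the oxygen field to its fixed point so
#' that healthy tissue is oxygen-stable from the first tick, and seeds the
#' simulation's Mersenne-twister stream.
#'
#' @param config a [sim_config()].
#' @param seed integer seed for the simulation's random stream (defaults to
#'   `config$seed`).
#' @return a `sim_state`: tick counter, tissue matrices (`life`,
#'   `prev_life`, `oxidase`, `insults`, `alive`), the nine concentration
#'   layers, the vessel and leukocyte tables, and the serialized RNG state.
#' @export
init_state <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  cpp_init_state(config, as.integer(seed))
}

#' Total tissue damage
#'
#' The scalar outcome measure: the sum over all tissue sites of
#' `100 - life`, with dead cells contributing 100.
#'
#' @param state a `sim_state`.
#' @return non-negative number.
#' @export
total_tissue_damage <- function(state) {
  sum(100 - state$life)
}

#' @export
print.sim_state <- function(x, ...) {
  cat("<sim_state> tick ", x$tick, ", ", x$width, "x", x$height,
      " grid\n", sep = "")
  cat("  total damage: ", format(total_tissue_damage(x)),
      " (", sum(x$alive == 0L), " dead cells)\n", sep = "")
  cat("  vessels: ", length(x$vessels$x), "; leukocytes: ",
      length(x$leukocytes$kind), "\n", sep = "")
  invisible(x)
}

CHECKPOINT_VERSION <- 1L

#' Checkpointing
#'
#' `save_checkpoint()` writes the complete simulation state (including the
#' random-stream state) to a versioned container; `load_checkpoint()`
#' restores it bit-exactly, so a resumed run with the same stream is
#' identical to an uninterrupted one. Supplying `seed` replaces only the
#' RNG state with a freshly seeded stream (used by the restart
#' commitment-time experiments).
#'
#' @param state a `sim_state`.
#' @param path file path for the checkpoint container.
#' @param seed optional replacement seed; `NULL` keeps the saved stream.
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   returns a `sim_state`.
#' @export
save_checkpoint <- function(state, path) {
  stopifnot(inherits(state, "sim_state"))
  saveRDS(list(magic = "pressim-checkpoint", version = CHECKPOINT_VERSION,
               state = state), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path, seed = NULL) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read checkpoint '", path, "': ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$magic, "pressim-checkpoint"))
    stop("not a pressim checkpoint: ", path)
  if (!identical(obj$version, CHECKPOINT_VERSION))
    stop("checkpoint version ", obj$version, " not supported")
  state <- obj$state
  if (!inherits(state, "sim_state")) stop("corrupt checkpoint payload")
  if (!is.null(seed)) state$rng_state <- cpp_rng_state(as.integer(seed))
  state
}

#' Reseed a state's random stream in place
#'
#' @param state a `sim_state`.
#' @param seed integer seed.
#' @return the modified state.
#' @export
reseed_state <- function(state, seed) {
  stopifnot(inherits(state, "sim_state"))
  state$rng_state <- cpp_rng_state(as.integer(seed))
  state
}
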
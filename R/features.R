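#' Feature names recorded each tick
#'
#' The 13 whole-field totals recorded at the end of every tick: total
#' tissue damage, each mediator, oxygen, blood flow (the summed current
#' vessel sizes) and counts of each activated cell type.
#'
#' @return character vector of the 13 feature names.
#' @export
feature_names <- function() {
  c("total-damage", "total-danger", "total-tnf", "total-il1", "total-tgf",
    "total-radical", "total-oxidase", "total-antiox", "total-oxygen",
    "blood-flow", "activated-neutrophils", "m1-count", "m2-count")
}

#' Record the feature vector of a state
#'
#' Deterministic summary of a `sim_state`: the 13 features plus the
#' cumulative dead-cell count, identical to the row the simulation loop
#' records at the end of a tick.
#'
#' @param state a `sim_state`.
#' @return named numeric vector.
#' @export
record_features <- function(state) {
  cpp_features(state)
}

#' Euclidean-norm series normalisation
#'
#' Divides a per-tick series by its Euclidean norm so that population
#' curves of different cell types can be compared on relative timing; an
#' all-zero series is returned unchanged.
#'
#' @param series numeric vector.
#' @return normalised vector with unit Euclidean norm (or all zeros).
#' @export
normalize_series <- function(series) {
  stopifnot(length(series) > 0)
  nrm <- sqrt(sum(series^2))
  if (nrm == 0) return(series)
  series / nrm
}
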
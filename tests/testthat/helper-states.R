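# Shared fixtures: all built in code at test time.
# Coordinates in sim_state tables are 0-based (engine convention).

tiny_config <- function(...) {
  sim_config(grid_width = 20L, grid_height = 20L, n_ticks = 50L, ...)
}

# a quiet world: no pressure, no injury, no recruitment, no sources/sinks
# unless switched back on
inert_config <- function(...) {
  tiny_config(pressure_intensity = 0, initial_injury_fraction = 0,
              recruitment_rate_N = 0, recruitment_rate_M = 0,
              oxygen_production_rate = 0, oxygen_consumption_rate = 0,
              oxygen_sensitivity = 0, ...)
}

# drop a leukocyte into an existing state (kind: 1 = neutrophil,
# 2 = macrophage; state: 0 resting, 1 activated/M1, 2 M2)
place_leukocyte <- function(st, kind, state = 0L, x, y, lifespan = 1000L,
                            age = 0L) {
  lk <- st$leukocytes
  st$leukocytes <- list(
    kind = c(lk$kind, as.integer(kind)),
    state = c(lk$state, as.integer(state)),
    age = c(lk$age, as.integer(age)),
    lifespan = c(lk$lifespan, as.integer(lifespan)),
    x = c(lk$x, as.integer(x)), y = c(lk$y, as.integer(y)))
  st
}

set_layer <- function(st, layer, value) {
  st$layers[[layer]][] <- value
  st
}

leuko_df <- function(st) as.data.frame(st$leukocytes)
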
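# pressim

An agent-based simulator of pressure ulcer (PU) formation in vascularised
soft tissue, together with the analysis suite used to interrogate it.

Pressure ulcers in people with impaired mobility (for example after spinal
cord injury) arise from two coupled insults: ischemia while tissue is
compressed over a bony prominence, reperfusion injury when pressure is
relieved, and a self-amplifying inflammatory response to the resulting
damage. `pressim` models a 2-D lattice of tissue cells fed by blood
vessels. Each cell carries a *life* score in [0, 100]; the scalar outcome is
the total tissue damage

    D = sum over cells of (100 - life),

with dead cells contributing 100, and the opening of an ulcer defined as the
first tissue-cell death. One tick is one simulated hour.

Cyclic pressure (default: the 2 h clinical turning interval) constricts
vessels on a central plateau. Occluded tissue becomes hypoxic, loses life,
and accumulates xanthine oxidase; on reperfusion the stored oxidase converts
to reactive oxygen species (ROS) that injure cells stepwise through an
insult counter. Stressed and dying cells release danger signals (DAMPs) that
chemoattract and activate neutrophils; activated neutrophils secrete TNF-α,
which damages tissue; TNF-α and IL-1β polarise macrophages to the
pro-inflammatory M1 state, while higher IL-1β and TGF-β1 levels induce the
reparative M2 state whose TGF-β1 heals tissue. All state changes are
threshold-gated, probabilistic and reversible. In-silico trials administer
an intravascular corticosteroid (kills leukocytes above a threshold; dying
neutrophils release extra ROS) or a topical anti-DAMP antibody (quenches
DAMPs in proportion to the smaller local concentration).

The analysis layer implements the accompanying experiments: per-tick
13-feature trajectory recording, Gaussian-mixture discovery of bimodal
damage outcomes (EM, AIC/BIC order selection), 1-nearest-neighbour
classification of trajectory prefixes, checkpoint-restart commitment-time
experiments, parameter sensitivity sweeps, and treatment dose-by-onset
trial grids.

## A worked example

```r
library(pressim)

## default pressure-cycling scenario on a 50x50 lattice
cfg <- sim_config(grid_width = 50L, grid_height = 50L)
tr  <- run_sim(cfg, seed = 1, n_ticks = 600)
tr
#> <sim_trajectory> 600 ticks; final damage 33216.12; ulceration at tick 395
```

The ulcer opens at tick 395 — after roughly 16.5 simulated days of pressure
cycling — and by tick 600 the field carries about 33,000 damage units
(roughly 13% of the theoretical maximum on this lattice), concentrated in
and around the occluded plateau.

```r
## acute inflammation after a 30% central injury, no pressure
acute <- config_acute(0.3, grid_width = 50L, grid_height = 50L)
ens   <- run_ensemble(acute, 40, seed = 1, n_ticks = 600)
mean(ens$summary$ulcerated)
#> [1] 0.55

fit_gmm(ens$summary$final_damage, 2)
#> <outcome_gmm> k = 2, n = 40
#>   weights:   0.45, 0.55
#>   means:     2385.5, 51529
#>   sd:        479.7, 5260
#>   logLik -383.891; AIC 777.783; BIC 786.227
```

The same 30% injury either resolves (low-damage component near 2,400 —
the tissue heals) or ignites self-sustaining inflammation that opens an
ulcer (component near 52,000), here in 55% of 40 runs. The fitted
two-component mixture separates the outcomes cleanly, and its posterior
labels feed the 1NN trajectory classifier (`nn1_train()`,
`nn1_classify()`, `error_curve()`) and the restart experiments
(`restart_experiment()`).

A command-line interface wrapping the same functions is installed at
`inst/cli/pressim` (subcommands `run`, `ensemble`, `gmm`, `classify`,
`restart`, `sweep`, `trial`).

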
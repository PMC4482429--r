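---
title: "Modelling pressure ulcer formation with pressim: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pressure ulcer formation with pressim: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pressim)
```

## The model

`pressim` simulates a two-dimensional field of vascularised soft tissue over
a bony prominence. Each lattice site holds one tissue cell with an intrinsic
*life* score from 0 (dead) to 100 (perfect health); the whole-field outcome
measure is the total tissue damage

$$D = \sum_{i \in \text{cells}} \bigl(100 - \mathrm{life}_i\bigr),$$

with dead cells contributing 100 each. The opening of an ulcer is defined as
the first tissue-cell death. One tick represents one hour; agent lifespans
anchor this timescale (neutrophils survive 10–20 ticks, macrophages 100–150).

Blood vessels sit on a jittered regular lattice with base sizes drawn
uniformly from a narrow range (the largest below twice the smallest). Each
tick they release oxygen in proportion to their current size. Diffusible
species — oxygen, DAMPs, TNF-α, IL-1β, TGF-β1, ROS, and the two drug layers —
live on concentration layers with toroidal, mass-conserving 8-neighbour
diffusion followed by first-order degradation.

External pressure is applied maximally on a central circular plateau and
decays (linearly by default) to zero at a falloff radius, alternating on/off
every `pressure_half_period` ticks (default 2 h, the clinical turning
interval). Pressure constricts vessels,
`current = base · max(0, 1 − c·p)`, throttling oxygen, leukocyte
recruitment and intravascular drug delivery together.

The injury mechanisms are:

* **Ischemia** — below an oxygen threshold a cell loses
  `ischemia_penalty · oxygen_sensitivity` life per tick and accumulates
  xanthine oxidase; at or above the threshold it heals at
  `heal_rate · oxygen_sensitivity`.
* **Reperfusion injury** — when oxygen returns, stored oxidase converts to a
  proportional ROS burst. ROS injures stepwise: each above-threshold exposure
  adds one insult, and every `ros_insult_limit` insults cost
  `ros_insult_penalty` life at once.
* **Inflammation** — stressed cells (life falling this tick) release DAMPs
  scaled by the drop; dying cells additionally release a necrotic DAMP
  burst. DAMPs chemoattract and (above a threshold, with probability
  `p_activate_N`) activate neutrophils; severely damaged adjacent tissue can
  activate them directly. Activated neutrophils secrete TNF-α, which damages
  tissue; TNF-α and IL-1β polarise macrophages to M1 (which secrete IL-1β);
  higher IL-1β or TGF-β1 levels induce the reparative M2 state (which
  secretes TGF-β1, healing tissue). All polarisation is threshold-gated,
  probabilistic and reversible.

Within a tick the phases run in a fixed order: pressure and constriction;
oxygen release and recruitment; diffusion then degradation; the tissue-cell
rule; leukocyte movement, activation and secretion; treatment effects; aging
and death; feature recording. Sources precede transport, transport precedes
consumers, so single-tick behaviour stays interpretable and testable.

Thirteen whole-field features are recorded at the end of every tick
(`total-damage`, each mediator total, `total-oxygen`, `blood-flow`,
`activated-neutrophils`, `m1-count`, `m2-count`), plus the cumulative dead
cell count.

## Design choices in the rule set

Several mechanisms are deliberate modelling decisions, each exposed in the
configuration:

* **Excluded volume** (`leukocyte_site_capacity`, default 1): a site holds at
  most one leukocyte of a kind. Without it, chemotaxis stacks entire cohorts
  on the argmax cell of the DAMP field and their co-located TNF-α destroys
  tissue within hours, which is neither biological nor compatible with the
  multi-day course of ulceration.
* **TNF-α damage saturation** (`tnf_damage_saturation`): the damage term is
  `tnf_sensitivity · tnf_damage_coeff · min(TNF, sat)`. Receptor-mediated
  cytotoxicity saturates; the cap bounds local kill rates so that acute
  ulcers open on the multi-day timescale rather than within the first two
  simulated days.
* **Necrotic DAMP burst** (`tissue_death_damp_burst`): cell death releases a
  large one-off danger signal, the canonical origin of DAMPs.
* **Vascular destruction**: when the tissue cell at a vessel's site dies,
  that vessel is destroyed. Open ulcers therefore do not re-perfuse from
  within, and blood flow falls as the wound grows.
* **Oxygen-gated contact activation** (`o2_activation_threshold`): the
  contact route of neutrophil activation (by severely damaged neighbours)
  requires an oxygenated site — the oxidative burst needs oxygen — whereas
  DAMP-receptor activation works in hypoxia. Consequently the ischemic core
  of a pressure ulcer does not recruit a TNF-α storm before the ulcer opens,
  and time-to-ulceration is governed by the ischemia/reperfusion clock.
* **Boundary conventions**: oxygen exactly at the ischemia threshold counts
  as perfused; simultaneous M1/M2 eligibility is resolved M2-first; distance
  ties in chemotaxis are broken uniformly at random; dead cells neither act,
  secrete, consume nor heal, and render white.
* **Stress definition**: "stressed" means life fell this tick (the
  alternative, any damaged cell, is selectable via `stress_mode`).
* **IL-1β** has no direct tissue-damage term; it acts only through
  macrophage polarisation.
* **Neutrophil death ROS** is configurable but zero by default: with
  continuous baseline recruitment, resting neutrophils die everywhere all
  the time, and any default burst destabilises healthy tissue and makes the
  ROS total an outcome-correlated feature, contrary to its inert role.
* The **antioxidant layer** is recordable but inert by default (production
  zero); when produced it quenches ROS like the anti-DAMP antibody quenches
  DAMPs.

## Calibration

The defaults were calibrated, in the spirit of the original workflow, by
adjusting parameters one at a time until the qualitative rules behaved
correctly and the headline behaviours emerged:

* *Healthy stability.* Oxygen economy (production 100/vessel/tick,
  consumption 1.5/cell/tick, diffusion fraction 0.9 applied in 16 sub-passes,
  degradation 0.2) keeps every cell's oxygen well above the ischemia
  threshold indefinitely in undisturbed tissue, and responds on the tick
  scale when vessels constrict. The high sub-pass count flattens the field
  between vessels; vessel density 0.04 per cell makes the capillary spacing
  commensurate with the achievable diffusion length.
* *Time to ulceration.* Under default 2 h pressure cycling, plateau cells
  share a synchronised limit cycle of two ischemic and two perfused ticks,
  with one reperfusion ROS insult per cycle. The resulting first death
  occurs at 405 ± ~10 h, driven almost deterministically by the
  ischemia/reperfusion clock; the remaining variance comes from the vessel
  layout draw.
* *Acute bistability.* A central initial injury (fraction `f`, radius 10)
  releases a DAMP pulse proportional to `f`. The pulse seeds a small,
  Poisson-distributed number of neutrophil activations; each long-lived
  activated cohort pushes its patch toward the contact-activation damage
  threshold before dying. Whether any patch completes this bootstrap — and
  hands off to self-sustaining contact-driven inflammation — is the
  stochastic gate. At 30% injury roughly half of the runs ignite; at 25%
  almost none; at 35% nearly all; 40% always. Ignition is decided within the
  first ~125 ticks, while the first death follows only after 200+ ticks.

Problem sizes for the ensemble experiments are a deliberate desk-scale
choice: a 50×50 lattice for ensembles of 100–300 runs, the default 100×100
for single-run experiments such as the 5000-tick stability control. Grid
size is geometry, not mechanism; the pressure-zone dynamics are identical on
both lattices because the profile radii are fixed in cell units.

## Numerical choices

* Diffusion uses `diffusion_substeps` sub-passes per tick of the
  mass-conserving kernel (keep `1−f`, send `f/8` to each Moore neighbour).
* The oxygen field is pre-equilibrated at initialisation to a fixed point
  (max absolute change below 1e-6) so healthy tissue is stable from tick 0.
* One Mersenne-twister stream per simulation; every draw is uniform; the
  serialized generator state travels inside checkpoints, so resuming a run
  with the same stream is bit-exact, and restart experiments replace only
  the stream.
* EM for the damage mixture runs 20 random restarts to a 1e-8 log-likelihood
  tolerance with a variance floor of 1e-6 times the sample variance;
  `AIC = 2p − 2\ln L`, `BIC = p\ln n − 2\ln L` with `p = 3k − 1`.
* 1NN distances use per-feature division by the training-set maximum; the
  per-simulation Euclidean-norm normalisation is reserved for comparing the
  relative timing of cell-population curves.

## What the simulations do and do not show

The generator emulates the study conditions: unperturbed controls, cyclic
and scheduled pressure, central acute injuries of varying depth, and the two
treatment regimes (intravascular corticosteroid that kills leukocytes above
a threshold, with a ROS burst from dying neutrophils; a topical anti-DAMP
antibody applied as a uniform layer that quenches DAMPs in proportion to the
smaller of the two concentrations). It does not model deformation damage,
platelets or mast cells, three-dimensional tissue, individual-patient
calibration, or skin-tone rendering differences.

Known limitations of the present calibration:

* End-point damage under default pressure cycling is narrowly distributed:
  post-opening inflammation smoulders in every run instead of splitting into
  distinct high- and low-damage modes. The saturation cap that keeps acute
  ulceration on the multi-day timescale also caps the inflammatory chain
  reaction in the hypoxic annulus, and we did not find a parameterisation
  that exhibits both behaviours at once. The mixture-model machinery is
  implemented and tested on synthetic mixtures regardless.
* The damage jump at ulceration grows with cycle length rather than with
  reperfusion frequency, because the per-event ROS penalty is small in this
  parameterisation.
* Commitment of acute outcomes happens early (restarts reproduce source
  outcomes from the first checkpoints onward), a sharper version of the
  committed-before-125-ticks behaviour.

## Worked example

```{r example}
library(pressim)

cfg <- sim_config(grid_width = 50L, grid_height = 50L)   # pressure cycling
tr <- run_sim(cfg, seed = 1, n_ticks = 600)
attr(tr, "ulceration_tick")

acute <- config_acute(0.3, grid_width = 50L, grid_height = 50L)
ens <- run_ensemble(acute, 100, seed = 1, n_ticks = 600)
mean(ens$summary$ulcerated)

fit <- fit_gmm(ens$summary$final_damage, 2)
label_outcomes(ens$summary$final_damage, fit)[1:5]
```
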
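---
title: "Modelling plasmodium network plasticity under point stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling plasmodium network plasticity under point stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

The package simulates the *Physarum polycephalum* plasmodium as a fixed
population of very simple mobile particles, indirectly coupled through a
shared chemoattractant field on a 2D lattice. Each particle carries three
forward sensors — one straight ahead and one rotated by the sensor angle SA
to either side, all at sensor-offset distance SO — and turns by the rotation
angle RA toward the strongest reading. It then tries to advance one cell
along its heading; a successful move deposits a fixed quantum of
chemoattractant into the new cell, while a blocked move (the target cell is
occupied or off the lattice) leaves the particle in place with a fresh
random heading. At most one particle inhabits a lattice cell, so crowding
and jamming are part of the dynamics. The field diffuses once per scheduler
step by a 5×5 mean filter whose result is multiplied by a damping factor of
0.9, and external stimuli are projected into the same field as real-valued
point weights — positive values attract, negative values repel, and nothing
is clamped, so a repellent carves a negative well that diffuses like any
other mass.

Collective particle positions are the body plan of the virtual plasmodium;
collective motion is its flux. At the default density the population
spontaneously organises into reticulated transport networks that coarsen
slowly, which is the behaviour all of the stimulation protocols act upon.

One scheduler step is: project active stimuli, update every particle once
(sense → orient → move) in a fresh uniformly random order, then diffuse.
All randomness flows through R's RNG, so a run is a pure function of
(configuration, seed), bit-for-bit.

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| SA (`sensor_angle`) | 60 | degrees | angular offset of the side sensors |
| RA (`rotation_angle`) | 60 | degrees | turn per orientation update |
| SO (`sensor_offset`) | 9 | cells | sensor distance; sets network scale |
| `deposition` | 5 | units/move | trail laid by a successful move |
| `population_size` | 8000 | particles | fixed; no birth or death |
| `damping` | 0.9 | — | field retention per diffusion step |
| `kernel_size` | 5 | cells | mean-filter width |
| `baseline_weight` | 5 | units/cell/step | node attractant after warm-up |
| `stimulus_footprint` | 1 | cells (radius) | node sources project over 3×3 |
| `spacing` | 45 | cells | node separation of the 5×5 array |
| `window_half_width` | 6 | cells | 13×13 measurement windows |
| `mask_thickness` | 13 | cells | inoculation-grid segment width |
| `warmup_steps` | 500 | steps | confinement on the grid mask |
| `stabilize_steps` | 3000 | steps | baseline-only settling before t = 0 |

The sensory parameters, deposition level, population size, damping, kernel
size, 500-unit strong stimuli, 1-unit relative-negative level, −500-unit
repellent level and 13×13 windows are the reference configuration for this
model family; the remaining geometry and timing values are package choices
discussed below.

## Geometry: why spacing 45 and a 3×3 source footprint

Two design choices matter far more than any other and both were settled by
watching the baseline (no-protocol) runs.

**Array spacing.** With 8000 particles on a 200×200 lattice, the array
footprint sets the local particle density the network must live at. A
spacing of 30 cells confines the 5×5 array to a 120×120 region, about 55%
cell occupancy, and at that density the population abandons the network
regime entirely: it contracts into a solid central mass whose interior node
windows saturate at their geometric capacity of 169 particles. A spacing of
45 (array footprint 180×180, ~25% local density) keeps the population in
the reticulated-network regime for the full length of every protocol, which
is the regime all of the stimulation phenomena live in.

**Source footprint.** A node source projected into a single cell at the
5-unit baseline level cannot anchor the network: trails deposited by a
passing tube outweigh it by more than an order of magnitude, the network
coarsens away from the array within a few hundred steps, and most node
windows read zero. Projecting each node over a 3×3 footprint at the same
per-cell level (45 units/step per node in total) pins the network to the
array: every node window stays occupied, the unstimulated baseline is
quasi-stationary, and no window saturates. A 5×5 footprint over-anchors —
windows fill to 110–140 of their 169-cell capacity, which destroys the
headroom that attraction experiments need. The footprint radius is exposed
as `stimulus_footprint` (0 recovers pure point sources).

## Run protocol

`run_experiment()` drives three phases:

1. **Warm-up (500 steps).** The population is inoculated on a grid-shaped
   mask of 13-cell-thick segments connecting adjacent nodes (20,721 cells,
   so 8000 particles sit at ~39% density — confined but able to rearrange)
   and held there by 500 units/step of attractant at every mask cell.
2. **Stabilization (3000 steps).** The mask vanishes; only the node
   baseline remains. The released population relaxes into its stabilized
   network. The slow drift of window occupancies dies out after roughly
   2500–3000 steps, so 3000 is the default; protocols started earlier have
   their pre-stimulus windows contaminated by the relaxation transient.
3. **The run clock.** Scheduled stimuli are expressed on this clock, and
   occupancy of each 13×13 node window is recorded every
   `sampling_interval` (default 10) steps.

The built-in protocols, as deviations from the 5-unit baseline:

```{r}
library(physarum)
cfg <- experiment_config(seed = 1)
pos <- positive_experiment(cfg)            # nodes 7, 23 at 500 over [500, 2500)
rep <- repeated_stimulus_experiment(cfg)   # node 7, 4 cycles of 500 on / 500 off
rel <- relative_negative_experiment(cfg)   # nodes 16, 17 at 1 over [500, 2500)
neg <- repellent_experiment(cfg)           # nodes 16, 17 at -500 over [500, 2500)
run <- run_experiment(pos)
plot(run)
```

The negative protocols' timing is not fixed by the phenomena themselves;
the package mirrors the positive protocol's 2000-step window and leaves
2000 steps of recovery.

## What the runs show — and on what timescale

At full scale the simulations reproduce the qualitative stimulation
phenomenology: strong attractants draw particles from nearby nodes until
the stimulated windows approach saturation; removal produces an efflux with
redistribution toward neighbouring nodes; repeated stimulation of one node
leaves a rising off-period baseline (a spatially implemented memory of the
stimulus); relatively lowered stimuli cause a gradual decline with a slow
recovery after reset; and strong repellents empty the target windows within
a few dozen steps.

Two effects run on slower clocks than one might expect. First, a stimulated
window that has filled to near its 169-cell capacity is a jam: it disperses
from its rim only, so after stimulus removal the occupancy needs on the
order of 2000 steps to fall below three quarters of its stimulated level,
settling near half — the retained half being the same spatial memory seen
in the repeated-stimulation runs. Second, after a repellent is lifted and
the baseline restored, the restored attractant actively recruits the
network back, so target nodes adjacent to surviving tubes are sometimes
re-invaded within ~1000 steps even though truly abandoned nodes stay empty
indefinitely. Both behaviours are density effects of the desk-scale
configuration (8000 particles on 200×200), not numerical artifacts.
Likewise, unstimulated nodes keep a nonzero intrinsic count variance from
slow tube rearrangement, so variance does not always localize strictly to
the stimulated nodes on every seed.

## Resistance analysis

The companion analyzer treats wet-lab-style records: a 4×4 electrode
pairing grid (left X1..X4 against right Y1..Y4, 16 pairs per experiment,
exactly one pair stimulated). The readout per pair is the relative
resistance change r_end/r_start — a ratio, because outcomes are compared as
fold-levels and the ratio is invariant to the scale of the meter.

`analyze_experiment_set()` compares stimulated against unstimulated changes
with an exact two-tailed Mann–Whitney U test: U is computed from midranks,
and for combined samples of up to 25 observations the two-tailed p is
obtained by full enumeration of all choose(n_a+n_b, n_a) labelings as
P(min(U_a, U_b) ≤ observed). Ties are handled by midranks throughout, and
identical samples give p = 1 exactly. Larger samples fall back to the
normal approximation with tie and continuity corrections, and the report
says which path was used. Two pooling rules are provided: one value per
experiment per group (the stimulated pair's change against the mean of its
15 unstimulated pairs; default) or pooling every unstimulated pair
individually.

The synthetic generator emulates the observed outcome structure rather than
any electrical mechanism. Under HAHF stimulation (high amplitude, high
frequency: 2.5 Vpp at 1000 Hz) 80% of experiments respond, with the
stimulated pair's relative change drawn at twice the unstimulated level
(log-normal noise, σ_log = 0.05 on the stimulated draw and 0.08 on the
baseline); the rest are indistinguishable from baseline. Under LALF (0.5
Vpp at 10 Hz) 70% respond with every unstimulated pair's change drawn
log-uniformly at 3–16 times the stimulated pair's, 10% show no differences,
and 20% show a general increase. Baseline changes drift slightly above 1
(default 1.1) to reflect tube aging affecting all pairs. Every probability
and distribution parameter is exposed in `resistance_sim_control()`.

What passing the generator-based tests shows is internal consistency — the
analyzer detects the structure the generator plants, at the fold-levels and
responder fractions observed in the wet lab. It does not validate the
electrical model of real protoplasmic tubes, and the original experiments'
raw resistances (and hence their exact p-values) are not reproducible from
published information.

## Numerical choices

- **Boundary.** Diffusion uses an absorbing boundary: out-of-bounds cells
  contribute zero to the kernel mean but still count in the 25-cell
  divisor, so attractant mass is lost at the dish edge. Sensors hanging
  over the edge read 0, and an off-lattice move candidate counts as
  blocked.
- **Coordinates.** Cells are 0-based (x, y) = (column, row); particle
  positions are continuous and cell membership is by flooring. Inoculated
  particles start at cell centres.
- **Orientation ties.** An exact FL = FR tie (when the forward sensor does
  not win outright) keeps the current heading — deterministic and testable.
  Only the both-sides-stronger case consumes randomness.
- **Deposition.** Only successful moves deposit, so jammed clusters do not
  self-reinforce while stationary.
- **Diffusion cadence.** Once per scheduler step, after the motor stage.
- **Settling margin.** Baseline-activity traces discard the first 20% of
  each on/off phase by default so switching transients do not contaminate
  phase means; off-phases shorter than the margin are dropped with a
  warning.
- **Exact-test tie comparison.** Enumerated U values are compared with a
  1e-9 slack so midrank halves are robust to floating-point representation.

## Problem sizes

Full-scale runs (the study conditions) use the 200×200 lattice with 8000
particles for 8000–8500 total steps; one run takes a handful of seconds in
the compiled core, and the acceptance checks replicate each protocol over
five seeds. Unit and property tests run the same code on a 100×100 lattice
with 800 particles and a 3×3 array, where every structural property
(conservation, exclusion, determinism, schedule levels) is scale-free.

## Known limitations

- The lattice size the original experiments used is not published; the
  desk-scale geometry chosen here reproduces the phenomena qualitatively
  but its density effects (jam-release lag, occasional re-invasion of
  reset repellent nodes, nonzero unstimulated variance) mean the sharper
  quantitative forms of some figure-level claims do not hold on every seed.
- Particles have no oscillatory/shuttle-streaming dynamics, no growth or
  death, and the model does not represent electrical stimulation itself —
  stimuli act only through the generic attractant field.
- The resistance generator models outcome statistics, not tube impedance;
  it is a stand-in for unpublished raw data, and is labelled synthetic
  wherever it appears.
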
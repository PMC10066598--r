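# thalamosim

Desk-scale reconstruction and simulation of a mouse thalamoreticular
microcircuit in R.

## The problem

The thalamic reticular nucleus (Rt) is a shell of GABAergic neurons
wrapped around the thalamus. Its reciprocal loop with thalamocortical
relay cells of the ventral posterolateral nucleus (VPL) gates sensory
transmission in wakefulness and generates sleep spindles — waxing-and-
waning 7–15 Hz oscillations — through "ping-pong" interaction: a burst
of reticular firing inhibits relay cells, whose low-threshold calcium
rebound bursts re-excite the Rt, and so on. `thalamosim` is for
computational neuroscientists who want a complete, inspectable,
constraint-driven model of this loop that builds and runs on a laptop:

- **geometry & placement** — a hexagonal-prism volume (side 323 µm,
  VPL 550 µm + Rt 250 µm ≈ 0.22 mm³) populated by Poisson-disc sampling
  at measured densities (68,750 and 57,467 cells/mm³);
- **morphologies** — synthetic SWC-style arbors per m-type
  (Rt_RC, VPL_TC, VPL_IN) plus the standard processing pipeline
  (unraveling, cut detection, statistical repair, diversification,
  ±2.5 % vertical scaling);
- **connectome** — apposition ("touch") detection at a 1 µm surface
  gap, pathway filtering, three-step pruning to the measured bouton
  densities (0.124 and 0.102 boutons/µm) at a synapses-per-connection
  CV of 0.9, dendro-dendritic gap junctions (0.2 nS) and ML/CT afferent
  fibers with Gaussian spatial mapping (σ = 25 µm);
- **physiology** — stochastic Tsodyks–Markram synapses
  (per-site 2-state release; U/D/F; depressing intrathalamic & lemniscal
  pathways, facilitating corticothalamic ones), AMPA/NMDA/GABA_A
  kinetics, calcium-dependent release, 0.01 Hz minis, and
  two-compartment conductance-based neurons with low-threshold calcium
  bursting;
- **experiments & analysis** — wakefulness / anesthetized / in-vitro /
  up-down protocols, sensory trains, reticular current pulses,
  population polarization, and spike statistics (burst detection,
  oscillation frequency / duration / strength, spectrograms, per-cycle
  recruitment).

The core statistic of the oscillation analysis: the oscillation
frequency is `1/lag*` where `lag*` is the first non-zero peak of the
normalized autocorrelation of the population firing-rate histogram
(5 ms bins); bursts are spike runs with ISI ≤ 15 ms preceded by ≥ 50 ms
of silence.

## Worked example

```r
library(thalamosim)

# a complete miniature circuit (10% of the measured densities)
fx <- make_fixture_circuit(density_scale = 0.1, seed = 1)
bouton_density(fx$synapses, fx$segments$axon_length)
#>    Rt_RC   VPL_IN   VPL_TC
#> 0.124006 1.371281 0.102001

# wakefulness-like state: ML 25 Hz, CT 4 Hz, Ca 1.2 mM
cfg <- protocol_wakefulness(sim_config(duration = 3000, seed = 1))
sim <- run_simulation(fx$network, cfg)
population_rate(sim, "VPL_TC", 500, 3000)  #> ~2 Hz
population_rate(sim, "Rt_RC", 500, 3000)   #> ~8 Hz

# 20-ms pulse into the central 10% of reticular cells
cfg <- stimulus_rt_pulse(cfg, fx$network, fraction = 0.1,
                         amplitude_nA = 0.4, t0 = 1000)
sim <- run_simulation(fx$network, cfg)
tc <- subset(sim$spikes, mtype == "VPL_TC" & time >= 1000 & time <= 1500)
h <- rate_histogram(tc$time - 1000, 500, 5,
                    n_cells = sim$mtype_counts$VPL_TC)
oscillation_frequency(h)
#> ~10.5 Hz   (spindle-band ping-pong evoked by reticular activation)
```

The first two rates say the model is in the quiet-wakefulness regime
(both populations under 10 Hz, firing asynchronously); the last number
is the dominant frequency of the evoked thalamic oscillation, the
model's signature spindle-band rhythm.

## Layout

- `R/` — geometry/placement, morphology generation + processing,
  connectome, synapse physiology, e-models, network engine driver,
  analysis, I/O (SWC, SONATA-convention CSV tables).
- `src/` — Rcpp: Poisson-disc sampler, grid-based touch detection, the
  conductance-based network integrator (lookup-table exponential Euler,
  event-driven stochastic synapses, gap junctions).
- `vignettes/thalamoreticular-methods.Rmd` — the model, its
  assumptions, parameter provenance (measured vs surrogate), numerical
  choices and known limitations.
- `tests/testthat/` — unit + property suites per module and
  `test-acceptance.R` with the acceptance criteria.
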
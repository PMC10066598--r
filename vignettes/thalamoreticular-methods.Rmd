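---
title: "Methods: a desk-scale thalamoreticular microcircuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a desk-scale thalamoreticular microcircuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`thalamosim` reconstructs and simulates a microcircuit spanning the
thalamic reticular nucleus (Rt) and the ventral posterolateral nucleus
(VPL) of the mouse somatosensory thalamus. The pipeline is
constraint-driven: anatomy (densities, neurite overlap, bouton
densities) determines connectivity, and physiology (stochastic
short-term-plastic synapses, conductance-based bursting neurons)
determines dynamics. Network phenomena — asynchronous wakefulness-like
firing, sensory responses, and spindle-band oscillations sustained by
reticular–thalamic "ping-pong" — are emergent, not scripted.

The package operates at *desk scale*: a `density_scale` configuration
(default 0.1 for network experiments) uniformly scales cell densities
and afferent fiber counts so that a complete circuit of ~1,200
two-compartment neurons builds in minutes and simulates seconds of
activity on one CPU. Two structural facts make the subsampling benign:
synapses per axon are pinned by the bouton-density constraint, and
afferent synapse counts scale with the same factor as the cell count, so
*per-cell* synaptic input is density-invariant. For this reason the
conductance-compensation factor that would restore full-scale input is
exactly one; the `g_compensation` flag is retained in the API but is a
no-op for constraint-based builds (we verified that a 1/density_scale
factor, the naive choice, drives the network into seizure-like states).

# Geometry and cell placement

The volume is a hexagonal prism whose cross-section has the same area as
a circle of radius 294 um (side ~323 um, vertex-to-vertex 646 um); the
VPL occupies the bottom 550 um and the Rt the top 250 um (~0.22 mm^3).
Somata are placed by dart-throwing Poisson-disc sampling at the measured
densities (68,750/mm^3 Rt, 57,467/mm^3 VPL), with the minimum distance
derived from the density d as (0.5/d)^(1/3) — a one-parameter rule that
prevents clustering without starving the target counts. Densities are
jittered by +/-5% per circuit instance. Identities: all Rt cells are
reticular (Rt_RC, 57% cAD_ltb / 43% cNAD_ltb), 0.5% of VPL cells are
local interneurons (VPL_IN, bAC), the rest relay cells (VPL_TC, 64%/36%).

# Synthetic morphologies

Real reconstructions are replaced by a stochastic arbor generator with
per-m-type shape profiles: Rt_RC dendrites form laterally elongated
discs (lateral reach 190 um) and the axon descends into the VPL where
its densest arbor lies, with a small local collateral field inside the
Rt (the substrate of intra-reticular inhibition); VPL_TC dendrites form
a compact bush and the axon ascends, giving off a collateral band in the
Rt; VPL_IN arbors are local and confined to the VPL. Arbor tips that
leave their allowed extent are redirected rather than killed, so
realized lengths track the length budgets (a detail that matters:
stochastic tip extinction otherwise makes apposition statistics
erratic). Generator lengths and radii were set so that downstream
apposition densities comfortably exceed the experimental bouton-density
targets — the non-degeneracy requirement — and are realistic in order of
magnitude (several mm of dendrite per cell, ~1 um neurite calibers).

The processing pipeline mirrors what is applied to real reconstructions:
`unravel()` (sliding-window principal-component straightening, window 5
points, section lengths preserved exactly), `detect_cut_points()`
(terminals within 15 um of the top slice plane), `repair_dendrites()`
(continuation/bifurcation/termination sampled per branch order x 20-um
radial shell from reference statistics; regrown diameters equal the last
intact section's mean), `diversify()` (section lengths x (1+N(0,0.2)),
branch rotations N(0, 20 deg), topology untouched), and
`scale_vertical()` (+/-2.5%). Annotations (collateral and dense-arbor
node sets) are carried through every step.

# Connectivity

Touches are segment pairs whose *surface* gap (centerline distance minus
both radii, clamped at zero) is at most 1 um (chemical) or 0 um
(dendrodendritic gap-junction candidates); the surface convention is
what makes a 0-um threshold meaningful. Forbidden pathways (IN-Rt in
either direction; TC-TC) are removed; interneurons connect through
presynaptic dendrites. Pruning is three-step: the coefficient of
variation of synapses per connection is brought to 0.9 by capping the
largest connections (the cap is the largest one achieving the target,
i.e. minimal pruning — a vectorized equivalent of one-at-a-time
removal), then whole (preferentially multi-synaptic) connections are
removed until the mean axonal bouton density matches the measured
0.124/um (Rt) and 0.102/um (TC). Every surviving apposition is a
functional synapse (N_func = 1 x N_app); the resulting N_func
distribution is approximately geometric.

Gap junctions: the reference procedure keeps 30% of dendrodendritic
appositions, a fraction that matched measured divergence *for real
morphologies*. Because the synthetic generator yields a different
apposition count, the fixture tunes the retention to the divergence
midpoint of the measured range (11 coupled partners per cell, of 2–20);
`predict_gap_junctions()` still defaults to 0.30. Each junction is an
ohmic 0.2 nS coupling; per-cell leak conductances are then re-solved so
input resistances return to their pre-junction values. Cells with heavy
junction loads would need a negative leak for exact restoration; the
compensation is clamped at 80% of the original leak because cutting leak
further destabilizes the active models (full restoration is achieved for
lightly coupled cells and in the passive unit tests). Coupled-partner
distances concentrate at ~60–250 um — somewhat wider than the measured
40–120 um band, a direct consequence of the synthetic discs' uniform
overlap (see the dye-injection test).

Afferents: ML (lemniscal) fibers enter from the bottom face and target
the VPL; CT (corticothalamic) fibers enter from the top and target both
nuclei. Synapse counts are volumetric-density x volume; synapses land on
dendrites proportionally to local dendritic length and are assigned to
fibers with probability proportional to exp(-d^2 / (2 sigma^2)), sigma =
25 um, d the lateral fiber–synapse distance (the Gaussian 2-sigma^2
reading of the mapping formula; a `kernel_exponent` switch selects the
alternative). The CT volumetric density default reproduces the order of
the published full-scale CT synapse count; the ML default is set ~3x
higher than the published lemniscal count would imply, because at the
printed density a relay cell receives only ~2 driver synapses and the
desk-scale network is then bistable (relay cells fire only on rebound).
Both densities are explicit configuration, not measurements.

# Synapse physiology

Release is a per-site two-state (recovered/unrecovered) Markov process:
at a presynaptic event a recovered site releases with probability u
(facilitation variable, increment U, recovery time constant F) and then
recovers exponentially with time constant D. The recovery clock is
memoryless: a site that fails a recovery check restarts its exponential
clock (an early implementation that measured time since release
overestimated recovery; the ensemble-mean test against the deterministic
Tsodyks–Markram recursion caught it). Receptor kinetics are
double-exponential conductances: AMPA 0.2/1.74 ms (1.58 ms onto Rt from
TC, 2.74 ms from CT), NMDA 0.29/43 ms with Jahr–Stevens magnesium block
at 1 mM, GABA_A 0.2/8.3 ms with reversal -82 mV (-94 mV onto relay
cells). All intrathalamic and lemniscal pathways are depressing (I2/E2),
corticothalamic ones facilitating (E1); pathway U/D/F and conductances
not printed in the source (they live in unpublished supplementary
tables) are surrogates following the stated generalization rules and are
flagged `surrogate` in `pathway_physiology()`. The Rt->Rt and ML->IN
conductances were calibrated at network level (the role PSP calibration
plays in the reference pipeline). Release probabilities scale with
extracellular calcium through a Hill curve anchored at 2 mM
(`calcium_scale()`, n = 2.5, K = 1.6 mM — imported "intermediate"
dependence, configuration not measurement). Spontaneous minis are
independent 0.01 Hz Poisson processes per synapse and engage the same
release machinery.

# Neuron models

Each cell is a two-compartment (soma + lumped dendrite) conductance
model with NaT/Kd spike currents, low-threshold calcium (distinct
thalamocortical and reticular kinetic variants, concentrated in the
dendrite), Ih, A-type K, high-threshold Ca, SK coupled to an
exponential-decay calcium pool, Kv3.1 (interneurons), and leak;
reversals E_Na = 50, E_K = -90, E_h = -43 mV, C_m = 1 uF/cm^2, 34 C
kinetics. Integration is exponential Euler at dt = 0.025 ms with
voltage-indexed lookup tables for the gating variables; halving dt does
not change spike patterns. The five reference e-models are hand-tuned
surrogates (experimental feature tables are not printed): silent at
rest (-69 to -77 mV), tonic firing from a -64 mV holding, stereotyped
low-threshold bursts from -84 mV, adapting (cAD, via spike-driven
CaH->SK) versus non-adapting (cNAD) tonic trains, and a deeper
post-burst afterhyperpolarization in Rt_RC. Two tuning tensions are
worth recording: (i) SK strength trades wakefulness Rt rates against
rebound-burst size — the defaults sit where single kicks evoke single
bursts (no intrinsic oscillation) yet post-inhibitory rebound survives;
(ii) the fixed-reversal (non-GHK) CaT formulation needs conductances
~10x smaller than permeability-based models, and an over-strong window
current silently bistabilizes the resting state. The f-I curves of the
reduced models are steeper than real neurons' (no slow adaptation
currents); network rates are set by synaptic calibration rather than by
rheobase multiples. Fitting machinery (`fit_emodel()`, a compact
(mu+lambda) evolutionary strategy minimizing the maximum feature
z-score; acceptance at z < 3 for fits and z < 5 with no spontaneous
firing for morphology variants) is exercised against surrogate targets
generated from the reference models themselves.

# Network experiments

Protocols follow the stated conditions: wakefulness (ML 25 Hz, CT 4 Hz
Poisson, Ca 1.2 mM), light anesthesia (ML 10 Hz), in vitro (no afferent
drive, minis only, Ca 2 mM), cortical up/down states (CT gated 500/500
ms), sensory pulse trains on the central ML fibers, 20-ms current pulses
into the central Rt subset (amplitude is not printed; the 0.4–0.6 nA
defaults evoke bursts in the stimulated cells), and population
polarization by per-e-model holding currents solved by binary search.
At the desk-scale operating point the wakefulness state fires
asynchronously at ~2 Hz (TC) and ~8 Hz (Rt); an Rt pulse evokes a
damped ~10–11 Hz oscillation in the VPL population; the in-vitro pulse
ignites a waxing-waning spindle-like oscillation at ~8 Hz that
terminates after ~2–3 s, does not terminate when the Rt->TC depression
recovery time constant is reduced to 85%, and collapses when gap
junctions are removed. Two honest shortfalls, analyzed in the decisions
ledger: the in-vitro frequency runs ~2 Hz faster than the measured 5–6
Hz (GABA_A-only inhibition bounds the ping-pong period from below), and
termination is metastable across stochastic seeds (the small dense
network has a narrow margin between ignition failure and a
self-sustained loop).

# Analysis statistics

Bursts are maximal runs with interspike intervals <= 15 ms whose first
spike is preceded by >= 50 ms of silence (the first spike of a recording
counts as preceded by silence); burst probability is computed only for
cells with 1–20 Hz baseline rates. Oscillation frequency is the inverse
lag of the first non-zero peak of the (lightly smoothed) rate-histogram
autocorrelation; duration is the span between the first and last peak
exceeding twice the baseline rate (5-ms bins; the prominence rule is our
operationalization of "significantly higher than baseline"); strength is
the maximal periodogram value; spectrograms use 10 kHz sampling,
5000-sample Hann windows, 99% overlap. Per-cycle recruitment assigns
spikes within 30 ms of each oscillation peak, with the stimulus time as
cycle 0.

# What a green test does and does not establish

The synthetic generator reproduces the *statistical couplings* the
reconstruction pipeline relies on — overlap-driven appositions,
bouton-density-limited synapse counts, geometric N_func, divergent
gap-junction coupling — but not the morphological detail of real
reconstructions: absolute synapse counts, the exact spatial profile of
coupling distances, and per-morphology electrical diversity are out of
reach by construction, and the corresponding published totals are
explicitly not targets. Network-level results at density_scale 0.1 are
qualitative reproductions (directions and orders of magnitude), with
quantitative agreement only where the acceptance targets state it.
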
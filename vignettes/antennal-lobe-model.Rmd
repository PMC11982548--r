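---
title: "An inhibitory-plasticity model of olfactory learning in the honeybee antennal lobe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An inhibitory-plasticity model of olfactory learning in the honeybee antennal lobe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`beeAL` simulates the honeybee antennal lobe (AL) as a conductance-based
network of 100 excitatory projection neurons (PNs) and 280 inhibitory local
interneurons (LNs), and asks how spike-triggered facilitation of the
*inhibitory* synapses reshapes odor representations during appetitive
conditioning. The package covers the full loop: network construction, odor
stimuli built from "percepts" (the AL footprint of one pure volatile
chemical), training protocols, representation analyses (binned-count
correlations, PCA trajectories, uniqueness-index regressions), and a small
graph-convolutional network (GCN) trained on sensor-array features as an
artificial analog of the same computation.

### Membrane dynamics

Each neuron is a single compartment with Hodgkin-Huxley kinetics. PNs carry
fast sodium (`I_Na`, m^3 h), delayed-rectifier potassium (`I_K`, n^4), a
transient A-type potassium current (`I_A`, m^4 h), a low-threshold calcium
current (`I_T`, m^2 h), a hyperpolarization-activated cation current (`I_h`),
and two leaks (`g_L`, `g_KL`); LNs omit `I_A` and `I_h`. Intracellular
calcium follows a first-order model driven by `I_T`. The published parameter
set is the default (`neuron_params()`); capacitances are printed as totals
(uF) while conductances are densities (mS/cm^2), so we adopt the implicit
membrane areas 2.9e-4 cm^2 (PN) and 1.43e-4 cm^2 (LN) that make both
consistent at 1 uF/cm^2.

The voltage-dependent steady states and relaxation times of the gates are
not part of the published parameter table; we use the forms standard in this
model family — Traub-type Na/K kinetics with the voltage origin shifted to
-50 mV, the Huguenard/McCormick A-current, the Destexhe low-threshold
calcium current, and a McCormick-style anomalous rectifier with
`E_h = -40 mV`. They are exposed as a swappable table (`al_kinetics()`), so
an alternative parameterization can be dropped in and compared.

### Synapses

Three synapse classes connect the network: nicotinic cholinergic PN->LN
(first-order activation driven by a 0.3 ms transmitter pulse per spike),
fast GABA-A LN->LN and LN->PN (activation driven by a sigmoid of the
presynaptic voltage), and a slow G-protein-coupled LN->PN inhibition whose
potassium conductance is a Hill-4 function of the G-protein concentration.
The slow receptor shares the fast-GABA transmitter drive and the fast
LN->PN adjacency (one anatomical pathway, two receptor types).

Two implementation choices matter here:

* **Per-target normalization.** The published maximal conductances (0.3 uS
  ACh, 0.015/0.02 uS GABA-A, 0.02 uS slow) are interpreted as class totals
  per postsynaptic neuron, divided by the afferent count — the normalization
  convention of this model family. Read per-edge, those numbers would exceed
  the cells' total leak conductance by two orders of magnitude and the
  network would be permanently shunted.
* **Shared kinetic state per presynaptic neuron.** All edges of one class
  share rate constants and the same presynaptic drive, so their kinetic
  states are identical trajectories; the engine therefore stores one state
  per presynaptic neuron and applies the per-edge facilitation multiplier at
  the conductance level. This is numerically identical to per-edge state and
  ~200x smaller.

### Plasticity

Every plastic synapse (LN->PN and LN->LN; the cholinergic inputs are fixed)
carries a multiplier `F >= 1` on its maximal conductance. During a rewarded
presentation, each presynaptic LN spike adds `dF_pre = 0.15` to the
multiplier of the LN's outgoing plastic synapses (the associative,
octopamine-gated pathway); during a habituated presentation each
postsynaptic spike adds `dF_post = 0.15` to the afferent plastic synapses
(nonassociative habituation). Between events `F` decays exponentially back
to 1 with `tau_F = 30 s` — the same decay acts as slow "forgetting" in the
two-environment experiments. The rule is uncapped, as printed; facilitation
reaches roughly 5-15x after a full training session and is self-limiting
through the inhibition it creates. `F` is stored with a last-event timestamp
and decayed lazily (at spike events and at 50 ms refresh points — a
worst-case staleness of 0.17 % of `F - 1`).

Any spike within the 2 s presentation of a rewarded odor counts as an
associative event (the rule is gated by the odor's reward class, not by the
500 ms stimulus window). After training, `freeze_weights()` collapses each
`(F, t)` pair to its effective multiplier; test-phase trials never modify
weights. `shuffle_weights()` permutes the effective conductances within each
synapse class — the control that separates learned *structure* from the
global increase in inhibition.

### Stimuli

Percepts tile the PN population in contiguous blocks (7 blocks of ~14 PNs
by default). An odor assigns each active percept a Gaussian activation
profile over its block; the Gaussian standard deviation ("width", as a
fraction of the half-block) is the odor's concentration-like handle.
Unipolar LNs receive the activation at their glomerulus position; multipolar
LNs optionally receive the mean activation at half amplitude (a
configuration switch — the published description does not resolve whether
glomerulus-free LNs receive direct odor drive). The input waveform is
the published 500 ms pulse (rise 66.7 ms, decay 200 ms) plus white Gaussian
current noise per neuron and step.

Three odor families are built in:

* **Simple classes** (`simple_environment()`): rewarded odors on percepts
  1-3, habituated on 2-4 (two of three percepts shared); within-class
  variants cycle the widths over {1.0, 0.7, 0.45} with seeded jitter for
  larger classes. The width values are a package choice (not printed),
  selected so a percept's profile covers most of its block at the widest
  setting.
* **Natural blends** (`ph_pp_environment()`): two floral blend classes of 6
  chemical components each; the width of percept *k* equals the component's
  proportion in the blend and the 7th percept stays inactive. Only the
  dominant component of the first rewarded blend (0.372) is anchored to the
  published value; the remaining proportion tables are synthetic stand-ins
  with the same structure (rewarded blends dominated by components 1-2,
  habituated by 3-4, each summing to 1).
* **Sensor-feature odors** (`sensor_odor()`): 16 percepts whose pulse peak,
  rise and decay constants are proportional to a gas sensor's `dR`,
  `1/ema_max` and `1/ema_min` features, for the scaled-up 400-PN/1120-LN
  network. `synthetic_sensor_dataset()` emulates the 16-sensor x 8-feature,
  6-odor schema (three odors rewarded, three habituated) with
  group-selective sensor blocks plus a common block, so no external download
  is needed.

### Input calibration

The stimulus amplitudes are not published. They were calibrated once,
before any learning experiment, so that the untrained network reproduces the
qualitative single-trial phenotype: most PNs inside activated percepts fire
during the 500 ms pulse (~10-30 Hz), LNs respond at comparable rates, and
the PN-population LFP shows strong stimulus-evoked oscillatory power in the
15-40 Hz band. The resulting defaults (`sim_config()`) are `peak_pn = 1e-3`
uA, `peak_ln = 5e-5` uA, a PN DC bias of `5.5e-4` uA and per-step current
noise of `5e-4` uA. They were not revisited afterwards; the training and
analysis results are downstream consequences.

## Numerical scheme

The engine (C++, classical fourth-order Runge-Kutta at `dt = 0.04 ms`)
advances all membrane, gating, calcium and synaptic kinetic equations
jointly. Three engineering details:

* Voltage-dependent rates are tabulated on a 0.025 mV grid and linearly
  interpolated; `sim_config(exact_kinetics = TRUE)` switches to direct
  evaluation (used by the convergence tests, which verify fourth-order
  behavior of subthreshold voltage traces and 1e-8 agreement of the gate
  relaxation with its closed form).
* The per-neuron synaptic conductance sums are computed once per step from
  the start-of-step kinetic state and held across the four RK4 stages, while
  the postsynaptic driving force `(V - E)` is evaluated at every stage. The
  kinetic variables move by well under 1 % of their range within one step
  (the fastest, the GABA open fraction during a presynaptic spike, has a
  ~0.1 ms time constant against ms-scale conductance decay), and the scheme
  is 4x cheaper.
* Spikes are detected as upward 0 mV crossings with a 2 ms refractory
  period (the published model does not state a criterion); facilitation
  events are applied at the detection instant. Noise is drawn per step from
  a seeded 64-bit generator inside the engine, so every trial is
  reproducible from its seed across platforms.

Trial state (membrane, gates, synaptic kinetics) resets between
presentations; facilitation and its timestamps persist across the session.

## Protocols and analyses

`run_training()` presents a randomized, class-balanced sequence (30
presentations of 2 s by default — 60 s of training) and applies the rule
matched to each odor's reward class; `plasticity_rule()` modes `both` /
`pre_only` / `post_only` / `off` correspond to differential conditioning,
absolute (associative-only) conditioning, nonassociative-only conditioning,
and a no-plasticity control.

Representation analyses follow the published recipes: Pearson correlation
between PN population vectors in 100 ms bins over the stimulation window,
averaged over bins and trial pairs (zero-variance bins are skipped and
counted, not imputed); PCA trajectories from 40 ms bins; the per-percept
uniqueness index `UI = (act_rew - act_hab) / act_hab` from the naive
network and the change in activity
`(act_trained - act_naive) / act_naive` for rewarded odors after
differential conditioning, with an OLS regression of change on UI
(`contrast_experiment()`). "Activation" is the mean PN firing rate over the
stimulation window within a percept's block; any per-unit activation table
(e.g. glomerular imaging vectors) can be passed to `uniqueness_index()`
directly, and the baseline (naive vs absolute-conditioned) is the caller's
choice of inputs.

The two-environment experiments (`run_environment_experiment()`) use a
10-percept tiling so that Environment 2 classes can be disjoint from, or
coincide with, Environment 1's P (percepts 1-3, rewarded) and Q (2-4,
habituated): Case 1 S(5-7)/T(6-8), Case 2 M(1-3)/N(2-4), Case 3 M(1-3) with
disjoint S(5-7), Case 4 N(2-4) with disjoint S(5-7). The percept
assignments are a package design (the published figure shows only the
overlap pattern); correlations are evaluated with frozen weights at three
stages (naive, after Env1, after Env2) while the facilitation decay runs
through both sessions.

## The GCN analog

`train_gcn()` implements the artificial counterpart: 16 sensor nodes plus
one reward node, two graph convolutions `H <- relu(A H W)` (8 features to 8,
then to 4), and a two-layer classifier head reading the sensor-node rows.
During training the reward node's edges are set to +1 (rewarded sample) or
-1 (habituated); at test time they are 0. Forward pass, backpropagation and
the Adam optimizer (learning rate 0.01, 20 epochs, cross-entropy) are
written in base R and verified against finite-difference gradients.

Two design choices depart from a literal all-ones adjacency, both forced by
the mathematics of a complete graph: sensor self-loops carry weight
`n_sensors / 2` (with uniform self-loops the convolved output is identical
for every node and the node-level analysis degenerates; with none, the
"sum minus self" aggregation inverts the sign of every node-level
contrast), and the classifier head reads only the sensor rows (the reward
node is a conditioning input — including its label-dependent row lets
training converge through the supervision edge alone and collapse at test
time). Degree normalization of `A` is available by passing a normalized
matrix to `gcn_layer()`. The layer-wise contrast analysis
(`gcn_contrast_analysis()`) computes per-node UI from layer-1 mean
activations and the change as layer-2 minus layer-1 mean activation for
rewarded samples, reusing `contrast_regression()`.

## Problem sizes, tests, and what they show

The default study conditions are the published ones: 100 PNs + 280 LNs,
30 x 2 s training, `dt = 0.04 ms`, dF = 0.15, `tau_F = 30 s`. A full
training session integrates 60 s of network time and takes a few minutes of
CPU; the test-suite therefore runs the directional protocol checks
(decorrelation, plasticity-mode dissociation, weight shuffling, environment
relearning) on a half-scale network (10 glomeruli: 50 PNs + 140 LNs) with
10-presentation training and small seed counts, sizes at which every
qualitative effect is already stable. The contrast-enhancement regression is
exercised at full scale in the acceptance tests and recomputed over 5 seeds
by `scripts/acceptance.R`.

The synthetic generators define what the tests can and cannot show. The
odor environments emulate percept overlap and concentration-like width
variation, but not receptor-level transduction, temporal odor plume
structure, or the heavy-tailed glomerular tuning of real antennal lobes;
passing tests demonstrate the circuit-plasticity mechanism under the
model's own stimulus statistics, not a fit to physiological recordings. The
sensor dataset emulates the schema and group structure of gas-sensor-array
features, not sensor drift or real chemical tuning — the published accuracy
on the real drift dataset is out of scope here.

## Known limitations

* Single-compartment neurons; no channel noise or temperature dependence.
* The gate kinetics follow one published lineage; other parameterizations
  of the same currents would shift rheobase and oscillation frequency
  (the kinetics table is swappable for exactly this reason).
* Facilitation is uncapped, as printed; extreme training schedules (many
  rewarded presentations of one odor) grow `F` without bound.
* LN spikes are treated as full sodium spikes (the LN parameter set
  includes `g_Na = 100 mS/cm^2`), not calcium spikelets.
* Slow inhibition is implemented LN->PN only, matching the LN membrane
  equation, which omits the slow term.
* Record output is CSV (spike long tables, weight edge lists); no HDF5.
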
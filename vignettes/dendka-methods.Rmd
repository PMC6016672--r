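---
title: "dendka: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dendka: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

dendka simulates how a dendritic A-type potassium conductance
(gK~A~) controls GABAergic inhibition of calcium signals evoked by
back-propagating action potentials (bAPs) in the apical dendrite of a
layer-5 pyramidal neuron, and reimplements the accompanying
line-scan-imaging analysis on synthetic data. This vignette documents
the model, its numerical treatment, the tunable parameters, and the
design decisions that were genuinely open.

## The biophysical model

The cell is a branched tree of cylindrical compartments: a 20 × 20 µm
somatic cylinder, a 500-µm apical trunk divided into 100 segments of
5 µm, two accessory apical branches (150 × 1 µm) at the distal end of
the trunk, and one spine (head 1 × 1 µm) connected by a thin neck
(1 µm long, 0.07 µm diameter) to the trunk compartment whose centre
lies 122.5 µm from the soma. Units are fixed package-wide: mV, ms, nA,
nS, µA/cm², mS/cm², µF/cm², µm, Ω·cm.

Each compartment obeys the discretised cable equation

$$C_m \frac{dV_i}{dt} = -\sum_k \bar g_k \, p_k(V_i,t)\,(V_i - E_k)
  + \sum_{j \sim i} g_{ij}(V_j - V_i) + I_i(t),$$

where $p_k$ is the product of Hodgkin–Huxley gating variables of
mechanism $k$, $g_{ij}$ the axial coupling conductance between
neighbouring compartments, and $I_i$ injected current. The mechanism
set is:

* **Na** (4 mS/cm², E = +50 mV) and **delayed-rectifier K**
  (0.1 mS/cm², E = −77 mV), classic Hodgkin–Huxley rate kinetics
  (m³h and n⁴), uniform over soma and dendrites; spike threshold sits
  near −50 mV from the −64 mV holding level.
* **A-type K** (E = −77 mV): conductance $\bar g_{KA}\, a\, b$. The
  density is 0 at the soma and over the most proximal trunk segment
  and rises linearly segment-by-segment, reaching the distal maximum
  in the last segment; with 100 segments the segment at 122.5 µm
  carries $\bar g \cdot 24/99$, i.e. 17.0 mS/cm² for the control
  maximum of 70 and 2.4 mS/cm² for the low (4-AP-like) maximum of 10.
  The accessory branches carry the distal density. 4-AP block is
  modelled exclusively as a reduction of this density; no other
  mechanism is touched.
* **Reporter Ca** (10⁻⁷ mS/cm², E = +120 mV) in the spine head and the
  synapse-bearing trunk compartment only: a two-gate ($c^2$)
  medium-threshold activation channel with no inactivation. The
  density is so low that the channel reads out voltage without
  perturbing it; its current is the model's calcium signal.
* **GABA~A~ synapse** on the trunk compartment at 122.5 µm: a
  peak-normalised biexponential conductance (rise 5 ms, decay 74 ms,
  peak 2 nS, E~Cl~ = −70 mV).

### Gate kinetics that are parameters, not constants

The A-type and reporter-calcium gate constants are exposed through
`default_kinetics()` and threaded through every simulation:

| gate | steady state | time constant | default |
|------|--------------|---------------|---------|
| KA activation *a* | Boltzmann, V½ = −25 mV, k = 6 mV | 1 ms | silent at rest, strongly recruited at bAP voltages |
| KA inactivation *b* | Boltzmann, V½ = −56 mV, k = −8 mV | 8 + 50/(1+exp((V+50)/10)) ms | ≈48 ms recovery at rest, ≈8 ms entry when depolarised |
| Ca activation *c* (squared) | Boltzmann, V½ = −12 mV, k = 3.5 mV | 1.5 ms | steep, high-threshold reporter |

These values are deliberate design choices:

* The A-type **activation midpoint (−25 mV, k = 6)** keeps the
  resting A-conductance negligible. With a shallower or more
  hyperpolarised activation curve, the large distal densities
  (70 mS/cm²) pass enough standing K⁺ current at rest to drag the
  distal dendrite below the chloride reversal (−70 mV), which both
  contradicts the bound that an IPSP can never hyperpolarise the
  membrane past E~Cl~ and distorts the holding-current search.
* The **calcium activation midpoint (−12 mV per gate) and slope
  (3.5 mV)** place the entire range of dendritic bAP peaks
  (≈ −37 … −25 mV across the gK~A~ sweep) on the steep, convex,
  far-below-midpoint limb of $c^2(V)$. This is what makes the
  peak-I~Ca~ vs. peak-V relation supralinear and lets a roughly
  constant GABAergic peak shift remove a progressively larger
  *fraction* of the calcium flux as gK~A~ falls — the central
  mechanism the model exists to demonstrate. A lower midpoint (e.g.
  −30 mV) lets the bAP cross into the saturating limb, where the
  fractional sensitivity *falls* as spikes grow, inverting the
  effect, and also passes a resting calcium current large enough to
  contaminate the 100-ms flux window.
* The **inactivation time constant** (fast entry when depolarised,
  ≈48 ms recovery at rest) lets inactivation accumulate across a
  5-spike train and persist over the 20-ms gap before the test
  pulse, with more accumulation at 100 Hz (10-ms inter-spike
  interval) than at 50 Hz.

### Passive properties

C~m~ = 1 µF/cm², R~a~ = 150 Ω·cm, leak reversal −70 mV, leak density
0.25 mS/cm² (effective membrane time constant 4 ms). The leak is at
the high-conductance end of the plausible range on purpose: with a
slow membrane (τ~m~ ≳ 30 ms) the dendrite is still ≈10 mV depolarised
20 ms after a 100-Hz train, and that residual depolarisation — via the
increased chloride driving force — rather than A-type inactivation
dominates the train effect on inhibition, and does so most strongly
when gK~A~ is already low. A fast effective membrane (common in
high-conductance cortical states) keeps the held potential restored
within the 20-ms gap so that the train acts through channel state, as
in the recordings. The resting level itself is not set by the leak: a
somatic holding current maintains −64.00 mV, re-found for every
condition.

## Protocols

* **Holding current**: a secant iteration on the steady-state somatic
  voltage, warm-started between evaluations, to |V − (−64)| ≤
  0.001 mV; verification requires the settled state to stay within
  that tolerance over a further 500-ms unstimulated run. The
  verification is stationarity of the held state rather than a
  cold-start run because an initialisation transient of the slow
  A-type inactivation gate would otherwise exceed the 0.001-mV
  criterion at *any* current.
* **Test pulse**: bisection (to 0.01 nA, bracket initialised to
  1.5–2.5 nA) for the smallest 0.5-ms somatic pulse that elicits
  exactly one somatic spike (upward crossing of 0 mV). A condition
  whose threshold pulse bursts is rejected. Trials then deliver
  pulses at 1.1 × the threshold amplitude: the recordings use clearly
  suprathreshold pulses, and the margin keeps every pulse of a train
  reliably single-spike despite sodium-channel inactivation.
* **Trial types**: bAP, IPSP–bAP, IPSP, and the train variants
  (train–bAP, train–IPSP–bAP, train–IPSP, train): 5 pulses at 50 or
  100 Hz ending 20 ms before the test pulse; any IPSP leads the test
  pulse by 15 ms.
* **Quantification**: calcium responses are trapezoidal integrals of
  the calcium-current magnitude over the 100-ms window starting at
  test-pulse onset; inhibition is
  $(\Delta Ca_{Ctl} - \Delta Ca_{Inh})/\Delta Ca_{Ctl}$. For train
  trials the train-alone (and train–IPSP) fluxes are subtracted as
  baselines, isolating the test-pulse response; the same subtraction
  (IPSP-alone) is applied to single inhibited trials, mirroring the
  photoartifact correction of the experimental analysis. AP half-width
  is measured at half amplitude above the fixed −64 mV holding level
  (not the pre-spike voltage) so widths are comparable across train
  conditions.

## Numerics

Fixed-step implicit (backward) Euler at dt = 0.005 ms. Each step
advances every gate by the exact exponential update at the step's
starting voltage, then solves the linear voltage system by
tree-structured (Hines) elimination — one upward and one downward
sweep, exact for the tree topology. The compiled path tabulates gate
steady states and per-step decay factors on a 0.005-mV voltage grid
with linear interpolation (the standard simulator optimisation);
`rate_tables = FALSE` evaluates the rates exactly and is bit-identical
to the R reference stepper `solver_step()`. The test suite pins the
tree solve against a dense LU oracle (≤ 10⁻¹⁰ mV per step on ≤ 12
compartments), the passive steady state against the analytic
sealed-end finite-cable profile (< 1%), tabulated against exact rates
(< 10⁻⁴ mV), and dt-halving (AP peak shift < 0.1 mV). Stimulus and
synapse event times are snapped to the nearest solver step (≤ 2.5 µs
timing error). Degenerate geometry (non-positive sizes) is rejected at
construction; a singular or non-finite solve aborts with an error.

## The synthetic line-scan generator

The generator emulates the structure of the study's raw data so the
experimental analysis chain can be exercised end-to-end:

* model calcium current → concentration: the current magnitude is
  low-pass filtered with a 50-ms single-exponential decay (the
  integral-based fraction is insensitive to the exact decay within
  the 100-ms window — tested), divided by the compartment volume, and
  scaled so a control single-bAP spine transient sits near 20% of
  indicator saturation (a low-affinity indicator regime; Kd default
  2.3 µM);
* concentration → green fluorescence by single-site Hill binding
  between a zero-calcium level G₀ and a saturating level G~sat~, plus
  a calcium-insensitive red channel;
* acquisition: resampling to a 500-Hz line scan, i.i.d. Gaussian
  noise on both channels per trial (10 interleaved trials per
  condition per cell; one spine/shaft pair per cell), and a
  rectangular blue-light photoartifact on uncaging (light) trials;
* analysis: per-trial baseline-subtracted ΔG/R, re-expressed as
  ΔG/G~sat~, artifact correction by subtracting the matching
  uncaging-alone average, trial averaging, 100-ms integrals, and the
  inhibition fraction; paired conditions are compared with an exact
  Wilcoxon matched-pairs signed-rank test (full 2ⁿ enumeration,
  zeros dropped, average ranks on ties).

Deliberate omissions: no scanning-optics point-spread function, no
motion or drift, no bleaching, no shot-noise scaling with intensity
(Gaussian noise of fixed SD is the default; the SD is a config knob).
Passing tests therefore show that the *analysis chain* is correct and
that saturation bias is small and one-signed in the default regime —
not that the generator reproduces every property of real recordings.

At zero noise with a linearised indicator the chain recovers the
model-side inhibition fraction to < 10⁻⁶ (tested); with the default
saturating indicator the recovered fraction is biased downward by a
few percent, because saturation compresses the larger control
response more than the inhibited one.

## Problem sizes and determinism

The default model has 133 compartments; trials simulate 145–200 ms at
dt = 0.005 ms and the gK~A~ sweep covers 7 conditions with a full
holding-current search and pulse recalibration per condition. The
population study defaults to 10 cells × 10 trials per condition, and
the type-I-error check in the test suite runs 1000 replicate
populations at zero effect. All stochastic stages derive from a
single master seed; simulations themselves are deterministic and
bit-reproducible.

## Known limitations

* The geometry of the soma and accessory apical branches, and the
  spine's active-channel complement, are choices (the spine head and
  neck carry their parent compartment's densities); the qualitative
  results are robust to them, but absolute values (input resistance,
  holding current, calibrated pulse amplitude) are not unique.
* Fractional calcium inhibition in the model is larger than typical
  experimental values; the model's fraction depends steeply on the
  reporter's activation slope, which trades off against the
  supralinearity range. Directions and orderings, not magnitudes, are
  the reproduction targets.
* The 50-vs-100-Hz ordering and the low-gK~A~ occlusion of the train
  effect are reproduced with deterministic but modest margins
  (≈ 0.004 and ≈ 0.01 of inhibition fraction); they are model
  predictions, since the original modelling work reported only
  single-bAP ± IPSP simulations.
* GABA~B~, NMDA and AMPA receptors (pharmacologically blocked in the
  experiments), temperature scaling, stochastic gating and
  reconstructed morphologies are out of scope.
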
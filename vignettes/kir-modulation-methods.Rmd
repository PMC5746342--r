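---
title: "Modelling serotonergic Kir suppression in fast-spiking interneurons: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling serotonergic Kir suppression in fast-spiking interneurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
what is modelled, which parameters matter, which decisions were genuinely
open and how they were resolved, and what the tests do and do not
establish. Code chunks are illustrative and not evaluated at build time;
every number quoted here is computed by the test suite or by
`scripts/acceptance.R`.

## The phenomenon

Fast-spiking, parvalbumin-expressing interneurons (FSIs) are the clock of
cortical gamma rhythms. Serotonin, through 5-HT2A receptors, suppresses
an inward-rectifier potassium (Kir) conductance in these cells. Three
observations follow from that one change: the resting potential
depolarizes (about +6 mV), the input resistance rises (about +31 %), and
single EPSPs decay more slowly (roughly 15 ms to 19–23 ms depending on
stimulation method) with essentially unchanged amplitude. The functional
claim the package exists to probe is that a slower EPSP decay selectively
enhances summation of inputs arriving 10–20 ms apart — gamma band — and
not of faster (0–5 ms) or slower (50 ms) trains.

## The two models

**Algebraic convolution model.** A unit-peak double-exponential EPSP
template with rise `tau_fast` and decay `tau_slow`, convolved with a
five-impulse train at a given inter-stimulus interval (ISI); the per-ISI
ratio of compound maxima (slow-decay template over fast-decay template)
is the tuning curve. It isolates the pure waveform effect: no driving
force, no cable, no conductance. With decays of 15 vs 23 ms the ratio
peaks at 15 ms ISI, and the peak stays inside 10–20 ms for any rise tau
between 1 and 3 ms. The printed normalisation constant
`(tau_slow/tau_fast)^(tau_fast/(tau_fast - tau_slow))` is applied and the
sampled waveform renormalised numerically, so a unit peak holds exactly
on the grid regardless of rounding; the template's published formula has
garbled parenthesisation and the standard positive EPSP sign convention
(decay term minus rise term) is used.

**Compartmental model.** A cylinder soma with unbranched dendrites,
K⁺/Na⁺ leaks split so potassium-selective modulation is expressible
(E_K = −107 mV, E_Na = +53 mV), an instantaneous Boltzmann Kir
conductance, double-exponential synapses, and optional Ornstein–Uhlenbeck
point-conductance background noise. Integration is backward Euler with a
Hines-ordered tree factorisation at `dt = 0.025` ms — unconditionally
stable on stiff passive trees; conductances are frozen over each step
(semi-implicit). The Kir gate is evaluated through a dense lookup table
(0.01 mV resolution, linear interpolation), the standard simulator
technique for gating functions.

## Morphology: a documented stand-in

The published model was adapted from a full reconstructed FSI morphology
that this package does not redistribute. The default stand-in is a
20 × 20 µm soma with 8 dendrites of 375 µm × 1.5 µm (diameter as
printed; total dendritic length ~3000 µm, typical of a cortical basket
cell), giving ~15,400 µm² of membrane. That size is not arbitrary: with
input resistance pinned at 92.9 MΩ, the membrane time constant is the
total capacitance times R_in, and ~15,000 µm² puts it near 14 ms — the
regime in which the measured EPSP decay (~15 ms) and its gamma-band
consequences exist at all. A smaller stand-in (e.g. 5 × 200 µm dendrites)
calibrates to the same V_m and R_in but with a ~5 ms membrane tau, which
would shift the summation peak below 10 ms and misrepresent the cell
class. SWC morphologies can be supplied instead (`load_swc()`; types 1
and 3 only; unbranched section chains merge on SWC round-trip, which is
inherent to the format).

## Rectification: the one free functional form

No functional form for the Kir conductance is printed, only its
signature: the current removed by the neuromodulator rectifies inward and
reverses at E_K. The package uses an instantaneous Boltzmann open
fraction (defaults `v_half = −85` mV, `k = 12` mV), validated
qualitatively: the subtracted ramp current of a reduced-Kir model shows a
large inward limb below E_K, a smaller outward limb above it, and
reverses at E_K exactly under somatic space clamp.

The calibration, however, exposed a genuine constraint worth recording.
A two-leak membrane cannot reproduce the measured effect: matching the
+31.1 % R_in increase fixes the K⁺ reduction, which then over-predicts
the depolarization (+11.2 mV instead of +6.1; the closed form is in the
test suite). A rectifier *can* reconcile the two, but only if its steep
region sits near rest: the conductance must be substantial during the
hyperpolarizing R_in test step yet contribute modest chord current at
rest. The fitted configuration (slope 12 mV, `v_half = −75` mV, Kir
carrying ~42 % of the resting K⁺ chord) achieves both targets with a
7.9 % pool reduction. The fitted fraction is far below the published ~70 %
because the real cell's serotonin-sensitive pool includes voltage-gated
channels (Kv3.1, SK and relatives) that this subthreshold model
deliberately omits; the reduction fraction is therefore reported, not
treated as a reproduction target.

## Calibration procedure

`calibrate_baseline()` root-finds the Na⁺ fraction against V_rest and the
overall density scale against R_in, alternating to convergence
(tolerances 0.01 mV, 0.02 MΩ — far inside the measurement SEMs of 1.3 mV
and 11.5 MΩ). `calibrate_modulated_state()` nests three deterministic
root-finds: for each candidate Kir share the baseline is recalibrated,
the reduction fraction `f` is matched to the R_in target, and the
remaining depolarization residual drives the outer root over the share.
This equals the SEM-normalised least squares whenever an exact solution
exists in the bracket, and it is reproducible bit-for-bit. One numerical
subtlety: measured R_in is *non-monotone* in `f` with a steep rectifier —
beyond a peak, the depolarized rest escapes the Kir-steep region and
R_in falls again. The fit therefore always walks the ascending branch,
where `f` is unique; monotonicity tests are likewise restricted to that
branch. All measurements use the printed conventions: 500 ms settle, V_m
as the mean of the final 100 ms, R_in by Ohm's law from a −50 pA, 500 ms
step.

## Summation protocols and their measurement conventions

Five synapses, 1 µm apart starting 96 µm from the soma, activated most
distal first (mirroring the uncaging order) at ISIs of 0.12, 5, 10, 20
and 50 ms. The last-EPSP amplitude is the compound-trace maximum within
30 ms of the last onset minus the pre-train baseline — the
baseline-referenced definition; whether the original measurement was
baseline- or trough-referenced is not stated, and the baseline-referenced
form is well defined at every ISI including fully fused (0.12 ms) trains.
The integral runs from the first onset to 200 ms after the last. In the
calibrated model the reduced/baseline amplitude ratio peaks at 10 ms
(with 20 ms within a fraction of a percent) and falls at 50 ms.

Distance dependence deserves honesty: dendritic K⁺ reduction suppresses
the *local* dendritic EPSP (driving-force loss; ~0.92 of baseline at
96 µm) while the somatic EPSP is nearly unchanged, and the somatic
amplitude ratio rises with synapse distance (0.94 proximal → 0.98 at
300 µm). The published crossover — distal amplitudes *increasing* — does
not occur here: it requires an electrotonically extended arbor
(dendrites comparable to the space constant, ~0.5 λ in this stand-in),
so the package's tests assert the gradient, not the sign change.

## Background noise

The point-conductance processes use the literature's correlation times
(2.7 ms excitatory, 10.5 ms inhibitory) and reversal potentials (0,
−75 mV), SD-to-mean ratios from the same source, and a single scale
factor fitted so the noise-condition R_in falls by a target fraction
(33 % for the headline check, matching in-vivo values). Two design
choices matter:

- **Balanced means.** The default `g_i0/g_e0` ratio makes the mean
  background current vanish at −71 mV. Unbalanced (excitation-dominant)
  means depolarize this model ~7 mV, pushing the rectifier out of its
  operating range — a distortion the original model, with its fuller
  channel complement, did not suffer. Background activity is reported in
  the source as an R_in reduction, and that is exactly what the balanced
  configuration delivers.
- **Trial averaging.** Compound amplitudes are measured on traces
  averaged across the 10 noise replicates (seeds paired between baseline
  and reduced conditions, plus a light 3 ms median filter). Taking a
  window maximum on single noisy traces is biased upward by an amount
  that grows with the fluctuation amplitude — and the reduced state
  fluctuates more, so per-trace maxima systematically inflate the ratio
  at long ISIs. Averaging before measuring is the standard experimental
  remedy and is what the replicate design is for.

Under that protocol the enhancement survives the 33 % R_in reduction with
its peak in the 10–20 ms band, though the margin over 5 ms is small
(ratio differences of ~0.01 against residual measurement noise of
similar size at unfavourable seeds); the tuning, not the exact argmax
under every seed, is the robust claim.

## Analysis toolkit conventions

- `fit_decay_tau()` fits a single exponential from the sample after the
  peak to 95 % decay, on the linear scale with a log-linear start, and
  reports R²; it is invariant to amplitude scaling and baseline offset.
- `estimate_reversal()` interpolates linearly between the two samples
  bracketing a single interior zero crossing and refuses anything else —
  robust to Kir curvature, no polynomial fitting.
- Ramp I-V curves include the capacitive command current; for a 3 s,
  100 mV ramp this biases a linear cell's zero crossing by
  C·(dV/dt)/g ≈ 0.2 mV, visible in the solver tests.
- The frequency bands are theta 4–8, alpha 8–12, beta 13–29, low gamma
  39–59, high gamma 61–100 Hz; gaps between bands are honoured literally
  (intervals there count as unassigned) and a shared edge goes to the
  lower band. The published theta label "48 Hz" is read as the obvious
  typographical loss of an en-dash (4–8 Hz).
- Spike removal excises ±2 ms around detected peaks (threshold −10 mV
  default), interpolates linearly and median-filters over 5 ms; recovery
  of a ~1.2 mV DC shift is verified at spike rates from 5 to 50 Hz.
- `nernst_potential()` defaults to 306.15 K, the midpoint of the
  32–34 °C recording range; with 3 mM external and 140 mM internal K⁺ it
  gives −101 mV.

## What the synthetic data do and do not show

The generators produce voltage traces with known EPSP parameters and
additive Gaussian noise, ramp currents from the same leak-plus-Kir
algebra the analysis assumes, inter-event-interval trains drawn
uniform-in-frequency within bands, and exponentially decaying
distance-response data with log-normal noise. Round-trip tests prove the
estimators recover these truths at the stated tolerances — parameter
recovery under the generator's assumptions. They do not establish
robustness to real-recording pathologies (drift, seal instability,
correlated noise, detection ambiguity), which are outside the package's
scope.

## Problem sizes and numerical settings

Defaults: 10 µm compartments (306 for the default morphology; halving
the compartment length moves steady-state somatic voltage by far less
than 0.05 mV), dt 0.025 ms (halving from 0.05 ms moves reported voltages
by < 0.001 mV), specific capacitance 1 µF/cm² (unstated in the source),
ramp −150 to −50 mV over 3 s with the −130 mV start available by
argument (the source's text and figure legend disagree). Ten noise
replicates per condition, the published replicate count. The acceptance
script runs the full calibration and template curve in well under a
minute on one core.

## Known limitations

- Subthreshold only: no spike-generating conductances, so spike-output
  questions are analysis-side (applied to synthetic or recorded spike
  trains), not simulated.
- The reduction fraction `f*` is not comparable to the published ~70 %
  (missing active K⁺ channels absorb most of that figure).
- The distal-amplitude crossover requires a more extended arbor than the
  reduced stand-in provides (documented above).
- Ideal voltage clamp (no series resistance) and no temperature scaling
  of rates (the model is passive).
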
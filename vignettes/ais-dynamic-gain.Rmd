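---
title: "AIS location and the dynamic-gain bandwidth: models and methods"
author: "aisgain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AIS location and the dynamic-gain bandwidth: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(aisgain)
```

## The scientific question

Cortical neurons encode fast-varying inputs in the timing of their action
potentials (APs).  How faithfully the *instantaneous firing rate* of a
neuron tracks a weak oscillatory component of its input — the *dynamic
transfer gain* as a function of the input's harmonic frequency — is limited
by the AP initiation mechanism: the sharper the somatic AP onset, the
broader the transfer bandwidth.  AP sharpness, in turn, depends on the
electrotonic separation between the soma and the axon initial segment
(AIS), the short stretch of proximal axon with dramatically elevated Na and
K channel densities where the AP actually starts.  Moving the AIS away from
the soma strengthens the axo-somatic dipole at initiation and sharpens the
somatic AP.

`aisgain` implements the full chain of this argument as a reproducible
pipeline:

1. a **ball-and-stick (BAS) conductance-based neuron** with a relocatable
   AIS (`bas_model()`, `simulate_bas()`);
2. the **sinusoid-in-noise stimulation protocol** with operating-point
   calibration (`compose_stimulus()`, `calibrate_operating_point()`);
3. **circular-statistics gain estimation**: cutoff frequency (COF),
   high-frequency power-law exponent, propagation delay (`gain_curve()`,
   `cutoff_frequency()`, `powerlaw_exponent()`, `phase_delay()`);
4. **phase-plane AP metrics**: onset threshold and rapidity
   (`extract_waveforms()`, `onset_metrics()`);
5. the **reduction to an exponential integrate-and-fire (eIF) point
   neuron** by the dynamic I–V method (`empirical_iv()`, `fit_eif()`);
6. a **liquid state machine (LSM)** of eIF neurons with short-term
   synaptic plasticity, evaluated on a delayed-XOR task
   (`run_xor_experiment()`).

## The ball-and-stick model

The neuron is a spherical soma (default diameter 20 µm, leak conductance
only) attached to a cylindrical axon of 1 µm diameter and 50 µm length,
discretized into 11 compartments of equal length.  Axial resistivity is
150 Ω·cm and specific capacitance 0.5625 µF/cm².  Every axonal compartment
carries fast-inactivating Na (m³h), delayed-rectifier K (n) and leak
currents with reversal potentials +60, −80 and −60 mV.  One compartment —
the one whose center is nearest the requested AIS distance `d` — carries
AIS-level densities (88 nS/µm² Na, 17.6 nS/µm² K); the rest carry the
~100-fold lower axonal densities (0.8 and 0.16 nS/µm²).  Relocating the
AIS therefore changes *where* the excitable hotspot sits without changing
the total membrane area or the passive circuit, which is why the somatic
input resistance is invariant to `d` to within ~0.01%.

Two deliberate modelling choices deserve comment:

* **Leak density.** The nominal leak density of 3.3·10⁻⁵ pS/µm² implies a
  membrane time constant of order 10⁵ ms, which we consider a units typo.
  The constructor keeps that number as its default for fidelity, but all
  calibrated experiments in this package use the documented alternative
  0.33 pS/µm², giving a passive time constant of ~17 ms — in the normal
  range for cortical membrane.  `run_gain_sweep()` logs which value is
  active.

* **Channel kinetics.** The Na/K rate functions are not uniquely
  determined by the model description; we implement the classic
  axo-somatic kinetics used in the cortical spike-initiation and
  backpropagation literature (Na activation/inactivation with trap-form
  rate functions, a high-threshold delayed-rectifier K), with every rate
  parameter exposed in `channel_kinetics()` and a Q10 temperature scaling
  (default 37 °C against a 23 °C reference).  All *qualitative* results —
  threshold hyperpolarization, onset sharpening, bandwidth increase, LSM
  improvement — are robust to this choice, but *quantitative* values of
  the COF, the power-law exponent and the fitted Δ_T scale with the
  kinetics, so those figures should be read as properties of this
  particular channel model.

### Numerics

The cable equation is integrated by a linearly implicit theta method on
the compartment graph: conductances are evaluated at the current gate
state, the voltage solve is tridiagonal (Thomas algorithm), and the
injected current enters with theta weighting.  The default
`theta = 0.5` (Crank–Nicolson with staggered exponential-Euler gate
updates from tabulated, linearly interpolated rate functions) gives
second-order spike timing: at the 5 spikes/s operating regime, halving the
production step `dt = 0.005 ms` moves individual spike times by less than
0.01 ms over sub-second windows.  (Over much longer deterministic windows
trajectory divergence accumulates, as it must for any fixed-order scheme.)
`theta = 1` (backward Euler) is available for extra robustness.  Somatic
spike times are detected as upward crossings of 0 mV with a 2 ms lockout
and linear interpolation of the crossing; the 10 mV/ms criterion is
reserved for waveform onset analysis, matching electrophysiological
convention.

Spatial refinement: because the AIS is *defined* as a single compartment,
doubling `n_axon_compartments` halves the AIS extent (and hence its total
conductance), so active properties are only comparable across
discretizations after recalibration; the passive circuit converges to
<0.1% under refinement, which the test suite checks.

## Stimulation and calibration

The injected somatic current is
$$I(t) = I_0 + I_1 \sin(2\pi f t) + s\, I_n(t),$$
where $I_n$ is an Ornstein–Uhlenbeck process with zero mean, unit
variance and autocorrelation time τ, generated by the exact update
$x_{k+1} = x_k e^{-dt/\tau} + \sqrt{1-e^{-2dt/\tau}}\,\xi_k$.  τ is not
constrained by the protocol description; we default to τ = 5 ms, typical
of the in-vitro experiments this protocol mimics, and expose it in
`stimulus_config()`.

`calibrate_operating_point()` fixes the working regime: with $I_1 = 0$ it
adjusts $s$ so that the subthreshold voltage SD sits inside 5–10 mV, then
bisects on $I_0$ (against a frozen noise realization, so the search is
deterministic) until the mean rate is 5 ± 0.25 spikes/s.  With the
calibrated leak this BAS model is weakly spontaneously active at zero
input, so the calibrated $I_0$ is a small hyperpolarizing current; for
that reason the sine amplitude for gain runs is $I_1 = 0.1\,\max(|I_0|,
s)$ — the spirit of "$I_1 \ll I_0$" (a weak probe relative to the
operating drive) carried over to a regime where $|I_0|$ itself can be
near zero.  A linearity check (halving $I_1$) leaves the normalized gain
unchanged within error bars.

## Gain estimation by circular statistics

For each frequency $f$ the response modulation is estimated from the
pooled spike times as twice the magnitude of the circular resultant
$$r = \frac{1}{N}\sum_{k=1}^{N} e^{j 2\pi f t_k},$$
normalized by its value at $f = 1$ cycle/s.  The response phase is
$\Phi = \pi/2 - \arg r$ (so that a pure response lag δt gives
$\Phi = -2\pi f\,\delta t$, and the delay is recovered from the slope of
the unwrapped high-frequency phase profile).

Two estimator details matter at desk scale.  First, $|\hat r|$ has a
Rayleigh noise floor: $E|\hat r|^2 \approx |r|^2 + 1/N$, so
`gain_curve()` debiases the raw magnitude as
$2\sqrt{\max(0, |\hat r|^2 - 1/N)}$ before normalizing (negligible when
$N |r|^2 \gg 1$, exact in the closed-form tests).  Second, the 0.70
crossing that defines the COF is located after a *decreasing isotonic
projection* of the normalized curve in log-frequency — a no-op for
monotone curves — followed by linear interpolation of the first downward
crossing.  The power-law exponent α is the negated slope of
log-gain vs log-f over the top measured decade (debiased points at zero
are excluded), and the delay fit uses the same window.

Sampling: the production scale matches the full protocol (100 s
repetitions, up to 100 repetitions per frequency, frequencies 1–1000
cycle/s, ~15 per decade), where tens of thousands of APs per frequency
make the noise floor negligible.  The desk preset uses 15 log-spaced
frequencies with 6 repetitions × 40 s below ~50 cycle/s (the reference
and cutoff region, ≈1200 APs per frequency at 5 spikes/s) and 3
repetitions above, which is sufficient for the COF and the ordinal
trends but leaves visibly larger error bars on α and δt.

## AP waveform metrics

AP waveforms are averaged from noisy-only runs (I₁ = 0) at the calibrated
operating point.  Averaging is aligned on the time of the first upward
crossing of dV/dt = 10 mV/ms before each spike (not on the peak), so
onset features are not blurred; APs whose window would overlap a
neighbouring spike are skipped and counted.  In the phase plane
(dV/dt vs V, restricted to −70…50 mV), the *threshold* is the voltage at
the 10 mV/ms crossing and the *rapidity* is the slope of the local
tangent there, fitted over a ±2 mV/ms band (widened automatically if it
contains fewer than 3 samples; halving the band changes the estimate by
<10% on smooth waveforms).

## Reduction to the eIF point neuron

The dynamic I–V method estimates the effective current–voltage relation
as the voltage-binned average
$$f(V) = \left\langle \frac{dV}{dt} - I/C_m \right\rangle_V ,$$
using a forward difference aligned with the current sample driving the
same step, 0.5 mV bins, and a blanking window from 0.1 ms before to 5 ms
after each spike (3 ms plus the 2 ms refractory period).  The
capacitance $C_m$ is itself estimated by minimizing the pooled
within-bin variance of $dV/dt - I/C_m$ over well-populated subthreshold
bins — a 1-D problem with a closed-form solution.  `fit_eif()` then fits
$$f(V) = \frac{1}{\tau_m}\left(E_L - V + \Delta_T\,
  e^{(V - V_T)/\Delta_T}\right)$$
to the usable bins (weighted by √count, up to the point where f exceeds
30 mV/ms) with multi-start Δ_T initialization.  On synthetic eIF data the
round trip (simulate → I–V → refit) recovers τ_m, E_L, V_T and Δ_T within
5% from 100 s of calibrated input.

For network simulations the remaining eIF parameters follow standard eIF
practice: $g_L = 14$ nS fixed with $C_m = \tau_m g_L$ (the printed
description "C_m = τ_m, g_L = 14 pF" is dimensionally inconsistent and is
interpreted this way), reset −80 mV, refractory 2 ms, and a 0 mV
numerical cutoff at which the spike time is recorded.  The packaged
reference table `eif_reference_params()` (one row per AIS distance,
Δ_T falling from 4.57 mV at d = 0 to 0.87 mV at d = 50 µm, τ_m rising
from 3.4 to ~7.8 ms) is the input of the network experiment.

## The liquid state machine

The liquid is 1000 excitatory + 250 inhibitory eIF neurons sharing one
parameter row.  Every neuron receives a fixed in-degree of 28 excitatory
and 48 inhibitory synapses; 10 input channels each project to a fixed
out-degree of 70 excitatory targets.  Synapses are current-based
exponential pulses (decay 3 ms excitatory / 2 ms inhibitory) with
delays ~U(1,10) ms for excitatory-source and input synapses, U(0.1,2) ms
for inhibitory-source synapses, and per-neuron independent 20 event/s,
2 nA excitatory Poisson background.  Recurrent weights are
Normal(J, 0.7 J) by class (J = 1.9, 6.7, 6.1, 4.9 nA for E→E, E→I, I→E,
I→I; negative draws are truncated to zero), input weights
U(0.5 J, 1.5 J) with J = 8.9 nA.

All recurrent synapses show Tsodyks–Markram short-term dynamics: the
efficacy at the n-th presynaptic spike is $w_n = w_0 R_n u_n$ with
$$u_n = U + u_{n-1}(1-U)e^{-\Delta t/F}, \qquad
  R_n = 1 + (R_{n-1} - R_{n-1}u_{n-1} - 1)e^{-\Delta t/D},$$
$R_1 = 1$, $u_1 = U$ — the canonical facilitation-u / depression-R form
(with per-class U, D, F; e.g. strongly depressing E→E with U = 0.59,
D = 813 ms, and facilitating E→I with F = 1790 ms).  Input synapses carry
no short-term dynamics.  The network integrates on a fixed 0.1 ms grid
with exact exponential decay factors and delays rounded to the grid;
background noise uses R's RNG, so runs are reproducible under a seed.
Runaway activity (population mean rate above 400 spikes/s) aborts a run
with a warning instead of silently returning.

**Task.** Two fixed 10-channel, 50 ms spike templates (Poisson at
20 events/s per channel) are presented back-to-back in random order, each
presentation freshly jittered with 5 ms Gaussian SD (times clipped to the
template window; a "drop" mode exists).  Liquid states are the
exponentially filtered spike counts (τ = 20 ms) of 200 fixed random
excitatory neurons, sampled at each 50 ms epoch end.  The target at each
epoch is the XOR of the identities of the last two templates.  The
readout is regularized linear least squares (ridge, penalty 10⁻² of the
mean feature second moment) with a 0.5 decision threshold; a run's
performance is the mean test accuracy over random 80/20 splits.
Identical wirings are reused across AIS-distance conditions, and
significance between conditions is assessed with Wilcoxon rank-sum
tests.

## Scale presets

* **production** — the full protocol: 11 distances (0–50 µm step 5),
  frequencies 1–1000 cycle/s at ~15/decade, 100 × 100 s repetitions,
  50 networks × 500 s training.  This is cluster-scale.
* **desk** — the documented reduced scale used by the test-suite and the
  acceptance script: distances {0, 25, 50} µm, 15 frequencies with
  6 × 40 s repetitions in the cutoff region and 3 above, 40–60 s
  AP/I–V runs, 10 networks × 100 s training (the acceptance script
  uses 5 networks with 200 s of training each).  At this scale the
  COF carries a few-percent
  interpolation/noise error, α and δt are noticeably noisier, and XOR
  accuracies carry ~1–2% per-network SD for a fixed template pair.

One further protocol option concerns the network task's input templates:
the reference protocol fixes one random template pair for the whole
experiment, but the task difficulty varies considerably between pairs
(accuracy on the same network can range over ~±10 percentage points
across pairs).  `run_xor_experiment(templates_per_network = TRUE)` draws
one pair per network (shared across all conditions of that network), so
that mean accuracies are marginalized over pair difficulty; the
acceptance script uses this mode, while significance comparisons between
AIS distances use the fixed-pair protocol, where the shared pairing
makes the rank-sum comparison most sensitive.

## What the synthetic inputs do and do not emulate

All inputs are generated internally: OU current noise with a weak sine,
and jittered Poisson templates.  They emulate the *statistics* of
in-vitro-like stimulation (stationary colored noise, controlled operating
point) and a minimal structured classification task.  They do not emulate
dendritic filtering (the BAS model has no dendrites — unlike detailed
reconstructed models, its AP onset is monophasic), conductance-based
synaptic input, channel noise, or any morphological diversity.  Passing
tests therefore demonstrate the internal consistency of the mechanism —
AIS distance → onset sharpness → bandwidth → network performance — for
this model family, not quantitative agreement with any particular real
neuron.

## Known limitations

* Quantitative COF, α, rapidity and fitted Δ_T values depend on the
  choice of Na/K rate functions, which the model description leaves open;
  with the kinetics implemented here the BAS bandwidth is lower (COF
  ≈ 10–15 cycle/s with the AIS at the soma, saturating near ≈ 16
  cycle/s once the AIS is 25 µm or more away) than with the original
  (unpublished) channel set, and the bandwidth gain saturates by
  ~25 µm instead of rising through 50 µm.  The proximal-vs-distal
  contrast and every other directional effect — rapidity increasing
  with AIS distance, ~4 mV threshold hyperpolarization, fitted
  Δ_T ≈ 4 mV at d = 0 falling with distance, better network
  classification with a distal AIS — are reproduced.
* The logistic COF(d) summary needs ≥4 distinct distances and is skipped
  in the 3-distance desk sweep.
* The LSM connectivity/weight means are taken as given; the optimization
  procedure that produced them is out of scope.
* Serialization uses plain text (CSV/JSON/one-column spike times)
  throughout.
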
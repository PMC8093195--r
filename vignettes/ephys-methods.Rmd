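---
title: "Methods: intrinsic electrophysiology features, Ih, resonance and gain"
author: "ephys package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intrinsic electrophysiology features, Ih, resonance and gain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ephys)
```

## The problem this package addresses

Deep-layer pyramidal neurons of the cortex express a prominent
hyperpolarization-activated cation current (Ih, carried by HCN channels).
Ih activates below rest and reverses around -30 mV, so it produces a
depolarizing "sag" during hyperpolarizing current steps, a rebound
depolarization (sometimes with rebound spikes) on release, subthreshold
resonance in the few-Hz range, and characteristic changes in how reliably a
neuron's spiking tracks oscillatory input components. Quantifying this
phenotype from whole-cell patch-clamp recordings requires a chain of
analyses — passive membrane properties, sag and rebound, single-spike and
spike-train features, ZAP impedance profiles, noise-driven transfer
functions, voltage-clamp activation curves — each with small methodological
choices that matter.

`ephys` implements that chain as a tested pipeline, and pairs it with a
single-compartment conductance-based simulator so that every stage can be
validated against analytic ground truth: the simulator's quasi-active
linearization provides closed-form impedance curves, pasted spike waveforms
provide exact spike times, and the gating ordinary differential equation
provides closed-form voltage-clamp currents.

## The membrane model

The simulator integrates

$$C \frac{dV}{dt} = -g_L (V - E_L) - g_h\, m\, (V - E_h) - w + I(t),$$

with first-order HCN gating

$$\frac{dm}{dt} = \frac{m_\infty(V) - m}{\tau_h}, \qquad
  m_\infty(V) = \frac{1}{1 + e^{(V - V_{50})/k}},$$

so the gate opens with hyperpolarization. With the spike mechanism enabled,
the adaptive-exponential terms $g_L \Delta_T e^{(V-V_T)/\Delta_T}$ and the
adaptation current $w$ (with $dw/dt = (a(V-E_L) - w)/\tau_w$ and $w \to w +
b$ at each spike) generate spiking; at each threshold crossing a stereotyped
action-potential waveform (linear rise to a peak above 0 mV, linear fall to
the reset) is pasted into the trace. Pasting rather than simulating fast
sodium/potassium currents keeps ground-truth spike times exact, which is
what the spike-detector tests need; the cost is that the fine shape of the
upstroke is piecewise linear, so waveform features on simulated cells test
the measurement geometry, not biophysical realism of the spike shape.

Integration is fixed-step explicit Euler at the stimulus sampling rate
(default 10 kHz) with optional substepping, implemented in C++. A fixed
step was chosen over adaptive integration for bit-level reproducibility
under a seed; the convergence test asserts that halving the step changes
subthreshold voltage by less than 0.1%. Where impedance is measured against
closed forms the analyses use two substeps per sample, which keeps the
integrator error comfortably below the 2% tolerance of those checks.

### Quasi-active linearization

For the subthreshold model, small-signal expansion around a holding
potential $V^*$ gives the admittance

$$Y(f) = g_L + g_h m_\infty(V^*) + i 2\pi f C +
  \frac{g_h (V^* - E_h)\, m_\infty'(V^*)}{1 + i 2\pi f \tau_h},$$

whose inverse magnitude is the impedance. The slow gate term acts as a
phenomenological inductance and generates a resonance peak when Ih is
strong and its activation curve is steep near rest. `linearized_impedance()`
evaluates this exactly and serves as the oracle for the empirical ZAP
pipeline; with $g_h = 0$ it reduces to the RC closed form.

## Stimulus protocols

* **Current steps**: 600-ms rectangular steps, -400 to +400 pA in 50-pA
  increments, 100 ms of pre-stimulus baseline and 300 ms post.
* **ZAP (chirp)**: constant-amplitude sinusoid with linearly swept
  frequency, 1 to 20 Hz over 20 s at 10 kHz. A linear sweep is the
  convention of the impedance literature; an exponential sweep is available
  by argument. Simulated ZAP sweeps carry 0.2 s of leading and 0.3 s of
  trailing baseline: analyzing a record that has settled at both ends
  removes the spectral-leakage ripple (up to ~2% in the band) that a record
  truncated exactly at the chirp edges exhibits.
* **Frozen filtered noise**: Gaussian white noise convolved with a 3-ms
  unit-sum boxcar, 2.5 s duration, identical for identical seed. The
  unit-sum kernel passes the DC offset unchanged and makes the post-filter
  standard deviation `noise_sd / sqrt(width * fs)`; the autocovariance is
  the triangle of width twice the kernel.
* **Voltage-clamp steps**: 600 ms from -60 mV holding down to -140 mV in
  -10 mV increments. Because the clamp fixes the voltage, the synthetic
  responses are generated from the gating ODE in closed form, with decaying
  capacitive transients and measurement noise added.

## Feature extraction choices

**Passive features.** The resting potential is the mean pre-stimulus
voltage of zero-holding sweeps. Input resistance is the slope of the
steady-state deflection against current over hyperpolarizing sweeps between
-200 and -50 pA; the membrane time constant is a single-exponential fit of
each sweep's onset, averaged. Two analysis windows are fixed at 100 ms: the baseline window before stimulus
onset and the steady-state window at the end of the step. The exponential
fit runs from onset to the first voltage extremum so the sag rebound does
not contaminate it.

**Sag and rebound.** Sag amplitude is steady-state minus minimum in-step
voltage; sag ratio divides by the peak deflection from baseline, making it
offset-invariant and confined to [0, 1] for monotone responses. Both are
measured on the -400 pA sweep by default. Rebound amplitude is referenced
to the pre-stimulus baseline (not the in-step steady state, which would
conflate rebound with deflection size); spike samples are masked by the
overshoot detector before taking the post-stimulus maximum, and rebound
spikes are counted in the post-stimulus window.

**Spikes and trains.** Spike detection is peak-based: local maxima above
0 mV separated by at least 2 ms (overshoot mode), or upward crossings of a
20 mV/ms slope criterion followed to the next peak (dV/dt mode). Waveform
features come from the first spike of the rheobase sweep; the threshold is
the voltage where dV/dt first stays above 20 mV/ms before the peak, and the
half-width is measured at threshold plus half the amplitude with linear
interpolation of the crossings. The hero sweep is the qualifying sweep
closest to rheobase + 50 pA within [+39, +61] pA, ties toward the smaller
amplitude; if the window is empty the nearest suprathreshold sweep is used
and flagged. Firing rate per sweep is spike count over the 0.6-s step.
Bursting is instantaneous frequency above 75 Hz for the first inter-spike
interval, evaluated at rheobase and at rheobase + 50 pA; a putative
interneuron must jointly satisfy half-width under 1 ms,
after-hyperpolarization over 10 mV and maximum rate over 75 Hz.

**Impedance resonance.** The impedance profile is the magnitude of the
ratio of Fourier transforms of mean voltage over command current across the
1-20 Hz band, smoothed with a centered moving average of 0.5 Hz (eleven
native bins of the 20-s record; shrinking windows at the edges). The
resonance frequency is the argmax of the smoothed profile; a maximum at the
lowest evaluated frequency is reported but classified non-resonant. The
cutoff frequency uses the conventional 3-dB amplitude fraction 0.707 by
default; a half-amplitude reading (0.5) is available via
`cutoff_fraction` — half of the center impedance is -6 dB, not -3 dB, so
the two conventions are kept distinct rather than conflated.

**Spike-probability densities.** Each spike in a suprathreshold ZAP trial
is assigned the instantaneous chirp frequency at its time (relative to the
chirp epoch of that sweep); frequencies pool over trials into a histogram
divided by the total spike count, and comparisons run a two-sample
Kolmogorov-Smirnov test on the retained per-spike samples, never on the
binned densities, with optional band restriction.

**Frequency-dependent gain.** The time-varying rate is `1/dt` at spike
samples and zero elsewhere. Stimulus-rate cross-correlation and stimulus
autocorrelation are biased estimates computed per trial and averaged, which
excludes inter-trial boundaries by construction; both signals are
mean-subtracted first so the DC injection does not dominate the lag
functions (the identity contract G = 1 for r = s is unaffected). For each
frequency on the 2-100 Hz grid (0.2-Hz steps, 491 points), the lag
functions are windowed with a Gaussian of width sigma = 1/f and the Fourier
components taken; gain is the magnitude ratio, phase the four-quadrant
argument of the cross component. The window on the cross-correlation is
centered at its peak lag (tau_delay) rather than zero: with a zero-centered
window a pure transmission delay leaves a residual phase bias at high
frequencies (~0.06 rad at 90-100 Hz for a 5-ms delay) because sigma shrinks
toward the delay itself; centering at tau_delay makes the corrected phase
(phi + 2 pi f tau_delay, wrapped) exactly zero for a pure delay. The
estimator was checked against a constructed linear kernel with known
transfer (unbiased within 1.5%) and against a direct sinusoidal
perturbation oracle on the spiking model.

The sinusoidal oracle is paired: each noise realization is simulated with
and without a small added sinusoid and the Fourier component of the rate
difference is averaged over trials, so the response to the noise itself
cancels exactly. The perturbation amplitude (2.5 pA against a 27-pA
post-filter noise SD) sits in the linear regime; at larger amplitudes the
modulation depth is visibly compressive because spikes phase-lock to the
sinusoid, and the measured "gain" then depends on amplitude.

The per-frequency group comparison takes one pooled gain profile per cell
(trial-level pooling is available), excludes cells at or below 5 Hz mean
rate, runs a two-sided rank-sum test at each of the 491 frequencies and
controls the false-discovery rate with the Benjamini-Hochberg step-up
procedure at alpha = 0.01.

**Voltage-clamp Ih.** The measurement windows are fixed as:
10 ms capacitive blanking after each transition, instantaneous current
averaged over 10-30 ms post-transition, steady state over the final 50 ms
of the step. The Ih amplitude is |steady - instantaneous|; the tail is the
peak residual current after return to holding minus the final holding
steady state. With slow gating a fifth or so of the relaxation is already
over by the instantaneous window; the validation oracle therefore evaluates
the gating ODE averaged over the same windows rather than the naive full
amplitude. The activation curve normalizes tails to [0, 1] over the step
range and fits a Boltzmann sigmoid with free scale and offset — the step
range does not saturate activation at both ends, and fitting a
fixed-amplitude sigmoid to range-normalized data would bias V50 by about a
millivolt even on noiseless data. Relaxation kinetics fit single and double
exponentials and prefer the double only when it improves the small-sample
corrected information criterion by more than 2.

**Junction potential.** The Henderson equation is evaluated from ionic
concentrations, valences and relative mobilities at the bath temperature
(default 33 C, the midpoint of a 32-34 C bath). The built-in mobility
table follows the classical patch-clamp junction-potential tables,
including their acetate-analogue entry for gluconate (0.556 relative to
K+); with the more recent directly measured gluconate mobility (0.33) the
same K-gluconate/aCSF pair computes several millivolts more negative.
Both the table and the speciation are overridable; HEPES is treated as
fully anionic at pH 7.4 and the nucleotides as divalent anions. Voltages
are not junction-corrected anywhere in the pipeline.

**Multivariate embedding.** The 14-feature vector (RMP, input resistance,
time constant, sag ratio, sag amplitude; threshold, amplitude, half-width,
upstroke-downstroke ratio, AHP amplitude, rheobase, latency of the first
rheobase spike; f-I slope and hero-sweep rate) is standardized to zero mean
and unit variance; cells missing more than two features are dropped with a
report and remaining gaps are imputed by feature medians. The embedding is
UMAP with default parameters, seeded, single-threaded, and therefore
reproducible. Adaptation and ISI statistics are computed and carried in the
cohort table but stay outside the embedding vector.

## What the synthetic cohort does and does not emulate

The cohort generator samples per-archetype parameters (log-normal jitter on
capacitance, leak and HCN conductance) for four archetypes: superficial and
deep-L3 pyramidal cells with modest Ih, a layer-5 archetype with high Ih,
burst-onset firing and a depolarized reset, and a fast-spiking interneuron
with a narrow pasted spike, deep after-hyperpolarization and high maximal
rate. Conductance ordering (L5 > L3c > L2&3) encodes the direction of the
depth gradient, not any measured means. The archetypes were designed so
their intended class labels sit far from the rule boundaries across the
jitter distribution — e.g. the interneuron's first inter-spike interval
50 pA above rheobase stays well above the 75-Hz bursting criterion while
its maximal rate stays well above it.

Separate from the step-protocol archetypes, the noise-gain reference cell
(`gain_reference_params()`) uses a hyperpolarized reset (-62 mV) and a
shallower, more depolarized HCN activation curve so that the inter-spike
voltage range actually engages the gate: with the step-archetype reset of
-53 mV the gate is essentially shut between spikes and blocking Ih cannot
change the transfer function — a genuine property of this model class, not
an analysis artifact. The in-silico analogue of the Ih blocker ZD7288 is
simply gh = 0 with everything else, including the frozen stimuli and
intrinsic-noise seeds, held fixed (a paired design); the DC offset is
recalibrated per condition by the same raise-until-firing rule used in
acquisition.

Passing tests on this cohort show that the measurement chain recovers what
the generator put in. They do not show robustness to the things real
recordings add: electrode drift and access-resistance changes, dendritic
filtering and space-clamp error, channel diversity beyond one HCN gate,
seizure-margin tissue heterogeneity, or true spike waveform diversity.

## Problem sizes and reproducibility

The shipped checks run at desk scale: up to five averaged subthreshold ZAP
trials per cell, 25-100 noise trials per gain estimate with 300 trial pairs
for the sinusoidal oracle, cohorts of 60 cells for classification and 12
for the end-to-end determinism check, 400 replicates for the type-I
calibrations and 25 for the FDR null. Every stochastic step takes an
explicit integer seed; derived seeds stay within the 32-bit range. Running
the pipeline twice with the same configuration and seed reproduces the
report tables bit for bit.

## Known limitations

* The sweep format is the package's own plain-text manifest layout; vendor
  binaries and NWB files are not read.
* Sag and rebound are measured on a single step amplitude (default
  -400 pA), not averaged over the family.
* The single-compartment model cannot express dendritic Ih gradients; the
  quasi-active oracle is exact only for the model itself.
* The gain estimator's sigma = 1/f smoothing trades variance for a small
  bias where the transfer function is strongly curved; the oracle
  comparison quantifies this on the reference cell.
* Group statistics cover rank-based two-group designs and the
  per-frequency FDR screen; omnibus ANOVA-style reporting is out of scope.
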
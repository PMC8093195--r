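# ephys

Intrinsic electrophysiology feature extraction for whole-cell patch-clamp
recordings of cortical neurons, with conductance-based synthetic benchmarks.

Deep-layer cortical pyramidal neurons carry a prominent
hyperpolarization-activated cation current (Ih). It shapes nearly every
intrinsic measurement made at the rig: the depolarizing *sag* during
hyperpolarizing current steps, the rebound depolarization on release,
subthreshold *resonance* in the theta range, and how reliably spiking tracks
oscillatory components of an input. `ephys` is for physiologists and
computational neuroscientists who need that measurement chain as code:
reproducible, tested against analytic ground truth, and runnable end to end
on a cohort.

## What it computes

* **Passive / sag / rebound** — resting potential; input resistance as the
  slope of steady-state deflection vs current over −200…−50 pA sweeps;
  membrane time constant; sag amplitude `V_ss − V_min` and sag ratio
  `(V_ss − V_min)/(V_base − V_min)`; rebound amplitude and rebound spikes.
* **Spikes** — overshoot (>0 mV peaks) and dV/dt detection; threshold,
  amplitude, half-width, upstroke/downstroke ratio, AHP, latency from the
  first rheobase spike; rheobase, f–I slope, adaptation index and ISI
  statistics on the "hero" sweep (rheobase + 39…61 pA); rule-based bursting
  (first-ISI instantaneous frequency > 75 Hz) and putative-interneuron
  classification.
* **ZAP resonance** — impedance magnitude `|Z(f)| = |FFT(V)/FFT(I)|` over
  the 1–20 Hz chirp band, smoothed; resonance frequency fR, cutoff
  frequency, resonant flag; suprathreshold spike-probability densities over
  instantaneous stimulus frequency with two-sample KS comparison.
* **Frequency-dependent gain** — from frozen filtered-noise trials: rate
  signal `r(t) = 1/Δt` at spikes; correlations `c_sr(τ) = ⟨s(t) r(t+τ)⟩`,
  `c_ss(τ) = ⟨s(t) s(t+τ)⟩`; Gaussian windowing with `σ = 1/f`;
  `G(f) = |C_sr(f)|/|C_ss(f)|` and phase `φ(f) = Arg C_sr(f)` on a 2–100 Hz
  grid (491 points), delay-corrected by `2πf·τ_delay`; spike-triggered
  averages; per-frequency rank-sum group comparison with
  Benjamini–Hochberg FDR at α = 0.01.
* **Voltage-clamp Ih** — step and tail-current amplitudes from −60…−140 mV
  families; Boltzmann activation fit `A(V) = 1/(1 + exp((V − V50)/k))`;
  single/double-exponential kinetics with information-criterion selection.
* **Cohort** — the standard 14-feature vector per cell, seeded UMAP
  embedding, rank-based paired/independent group statistics, and a
  one-call pipeline (`run_cohort_analysis()`) producing CSV report tables
  plus a provenance record.
* **Synthetic neuron** — single-compartment leak + HCN + adaptive
  exponential model with pasted spike waveforms (exact ground-truth spike
  times), a quasi-active impedance linearization used as an analytic
  oracle, all stimulus protocols (steps, ZAP, frozen noise, voltage clamp),
  and a layer-archetype cohort generator with ground-truth labels.
* **Junction potential** — Henderson-equation calculator with a built-in
  relative-mobility table and ready-made K-gluconate internal / aCSF
  solution specs.

## A worked example

Simulate a deep-layer (L5-type) cell with strong Ih and run the main
analyses:

```r
library(ephys)

p <- default_archetypes()[["L5"]]$params
p$noise_sd_pA <- 10
cell <- simulate_cell(p, protocols = c("steps", "zap_sub", "vclamp"),
                      cell_id = "demo", layer_label = "L5", seed = 1L)

pf <- passive_features(cell$steps)
tf <- train_features(cell$steps)
ap <- ap_waveform_features(cell$steps)
cls <- classify_cell(ap, tf)
prof <- impedance_profile(cell$zap_sub, attr(cell$zap_sub, "zap"))
vc <- activation_curve(ih_step_amplitudes(cell$vclamp))
ljp <- henderson_junction_potential(solution_kgluconate_internal(),
                                    solution_acsf())
```

Output (formatted with `sprintf`):

```
RMP -67.1 mV | Rin 42 MOhm | tau_m 11.9 ms
sag 6.88 mV (ratio 0.30) | rebound 5.36 mV at -400 pA
rheobase 300 pA | f-I slope 0.117 Hz/pA | hero rate 8.3 Hz
class pyramidal | bursting at_rheobase
fR 4.93 Hz | cutoff 13.66 Hz | resonant TRUE
Ih V50 -82.3 mV | slope k 8.0 mV
junction potential -10.2 mV
```

Reading it: the cell rests at −67 mV, depolarized relative to its leak
reversal (−70 mV) because Ih is partially open at rest; the same open
fraction shunts the input resistance down to 42 MΩ. The −400 pA step
produces a 6.9 mV sag (ratio 0.30) and a 5.4 mV rebound — hallmarks of
strong Ih. The cell fires from 300 pA with burst onset (first ISI above
75 Hz instantaneous), and its subthreshold impedance peaks at ~5 Hz, so it
is classified resonant. The voltage-clamp protocol recovers the HCN
half-activation near −82 mV. The junction potential of the K-gluconate
internal against aCSF computes to −10.2 mV with the built-in mobility
table (not applied to any voltage — recordings are left uncorrected).

For the full cohort path, `make_cohort()` writes simulated sweep manifests
and ground-truth labels to a directory and `run_cohort_analysis()` turns
them into feature, resonance, gain, voltage-clamp and embedding tables.

## The methods vignette

`vignettes/ephys-methods.Rmd` documents the model, every fixed analysis
window and threshold with its rationale, the design decisions taken where
the methodology was ambiguous, what the synthetic cohort does and does not
emulate, and known limitations.
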
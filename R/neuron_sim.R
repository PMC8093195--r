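#' Parameters of the single-compartment conductance model
#'
#' The model integrates
#' `C dV/dt = -gL (V - EL) - gh m (V - Eh) - w + I(t) + noise`,
#' with HCN gating `dm/dt = (m_inf(V) - m)/tau_h`,
#' `m_inf(V) = 1 / (1 + exp((V - V50h)/kh))` (activating with
#' hyperpolarization), and, when `spike = "adex"`, the adaptive-exponential
#' spike current `gL DeltaT exp((V - VT)/DeltaT)` with adaptation
#' `dw/dt = (a (V - EL) - w)/tau_w`, reset at divergence, and a stereotyped
#' action-potential waveform pasted at each spike (peak above 0 mV) so that
#' overshoot-based detection applies and ground-truth spike times are exact.
#'
#' @param C_pF membrane capacitance (pF).
#' @param gL_nS leak conductance (nS).
#' @param EL_mV leak reversal (mV).
#' @param gh_nS maximal HCN conductance (nS); 0 removes Ih (the in-silico
#'   analogue of the Ih blocker ZD7288).
#' @param Eh_mV HCN reversal (mV), depolarized (~-30 mV).
#' @param V50h_mV half-activation voltage of the HCN gate (mV).
#' @param kh_mV activation steepness (mV, > 0).
#' @param tau_h_ms HCN gating time constant (ms).
#' @param spike `"none"` (subthreshold model) or `"adex"`.
#' @param VT_mV,DeltaT_mV,Vreset_mV adaptive-exponential threshold, slope
#'   factor and reset (mV).
#' @param a_nS,b_pA,tau_w_ms subthreshold adaptation coupling, spike-triggered
#'   adaptation increment, and adaptation time constant.
#' @param ap_peak_mV,ap_rise_ms,ap_fall_ms pasted AP waveform: peak voltage
#'   and linear rise/fall durations.
#' @param noise_sd_pA SD of intrinsic current noise added per sample (pA).
#' @param seed integer seed for the intrinsic noise.
#' @return object of class `model_params`.
#' @export
model_params <- function(C_pF = 150, gL_nS = 10, EL_mV = -70,
                         gh_nS = 4, Eh_mV = -30, V50h_mV = -82, kh_mV = 8,
                         tau_h_ms = 50,
                         spike = c("none", "adex"),
                         VT_mV = -45, DeltaT_mV = 2, Vreset_mV = -53,
                         a_nS = 2, b_pA = 40, tau_w_ms = 150,
                         ap_peak_mV = 35, ap_rise_ms = 0.8, ap_fall_ms = 2.5,
                         noise_sd_pA = 0, seed = 1L) {
  spike <- match.arg(spike)
  stopifnot(C_pF > 0, gL_nS > 0, tau_h_ms > 0, tau_w_ms > 0,
            gh_nS >= 0, kh_mV > 0)
  structure(list(C_pF = C_pF, gL_nS = gL_nS, EL_mV = EL_mV,
                 gh_nS = gh_nS, Eh_mV = Eh_mV, V50h_mV = V50h_mV,
                 kh_mV = kh_mV, tau_h_ms = tau_h_ms, spike = spike,
                 VT_mV = VT_mV, DeltaT_mV = DeltaT_mV, Vreset_mV = Vreset_mV,
                 a_nS = a_nS, b_pA = b_pA, tau_w_ms = tau_w_ms,
                 ap_peak_mV = ap_peak_mV, ap_rise_ms = ap_rise_ms,
                 ap_fall_ms = ap_fall_ms,
                 noise_sd_pA = noise_sd_pA, seed = as.integer(seed)),
            class = "model_params")
}

.m_inf <- function(V, p) 1 / (1 + exp((V - p$V50h_mV) / p$kh_mV))

#' Resting state of the model at zero input
#'
#' Solves the zero-current fixed point of the subthreshold system (leak, Ih
#' and subthreshold adaptation), ignoring the exponential spike current.
#'
#' @param p a [model_params()].
#' @return list with `V` (mV), `m` and `w` at rest.
#' @export
resting_state <- function(p) {
  f <- function(V) -p$gL_nS * (V - p$EL_mV) -
    p$gh_nS * .m_inf(V, p) * (V - p$Eh_mV) -
    (if (p$spike == "adex") p$a_nS * (V - p$EL_mV) else 0)
  lo <- min(p$EL_mV, p$Eh_mV) - 1
  hi <- max(p$EL_mV, -40)
  V <- uniroot(f, c(lo, hi), tol = 1e-10)$root
  list(V = V,
       m = .m_inf(V, p),
       w = if (p$spike == "adex") p$a_nS * (V - p$EL_mV) else 0)
}

#' Simulate the model neuron under a current stimulus
#'
#' Fixed-step explicit Euler integration at the stimulus sampling rate (with
#' optional substepping), deterministic given the parameter seed.
#'
#' @param p a [model_params()].
#' @param stimulus injected-current series in pA.
#' @param fs sampling rate in Hz.
#' @param oversample integer >= 1; number of integrator substeps per sample.
#' @param init optional list(V, m, w) initial state; defaults to
#'   [resting_state()].
#' @param stim_onset,stim_offset epoch annotation passed to the sweep record.
#' @param cell_id,protocol_id,layer_label,amplitude sweep metadata.
#' @return object of class `sim_result`: `sweep` (a `sweep_record` of the
#'   voltage trace with the clean command as its current channel),
#'   `spike_times` / `peak_times` (s, ground truth), and the gating (`m`) and
#'   adaptation (`w`) trajectories.
#' @export
simulate_neuron <- function(p, stimulus, fs, oversample = 1L, init = NULL,
                            stim_onset = 0, stim_offset = NULL,
                            cell_id = "sim", protocol_id = "sim",
                            layer_label = "unknown", amplitude = NA_real_) {
  stopifnot(inherits(p, "model_params"), all(is.finite(stimulus)))
  if (is.null(init)) init <- resting_state(p)
  stim <- stimulus
  if (p$noise_sd_pA > 0)
    stim <- stim + with_seed(p$seed, rnorm(length(stim), 0, p$noise_sd_pA))
  prm <- p
  prm$V0 <- init$V; prm$m0 <- init$m; prm$w0 <- init$w
  res <- sim_neuron_cpp(stim, fs, prm, as.integer(oversample))
  sweep <- sweep_record(res$V, stimulus, fs,
                        cell_id = cell_id, protocol_id = protocol_id,
                        layer_label = layer_label,
                        stim_onset = stim_onset, stim_offset = stim_offset,
                        amplitude = amplitude)
  ok <- res$peak_idx <= length(res$V)   # drop spikes truncated by record end
  structure(list(sweep = sweep,
                 spike_times = (res$spike_idx[ok] - 1) / fs,
                 peak_times = (res$peak_idx[ok] - 1) / fs,
                 m = res$m, w = res$w, params = p),
            class = "sim_result")
}

#' Quasi-active (linearized) impedance of the subthreshold model
#'
#' Small-signal expansion around a holding potential `V_star`: the admittance
#' is `gL + gh m_inf(V*) + i 2 pi f C + gh (V* - Eh) m_inf'(V*) /
#' (1 + i 2 pi f tau_h)`; the slow Ih gate acts as a phenomenological
#' inductance and can produce a subthreshold resonance. With `gh = 0` this
#' reduces exactly to the RC magnitude `1/sqrt(gL^2 + (2 pi f C)^2)`.
#'
#' @param p a [model_params()] (spike mechanism ignored).
#' @param freqs frequency grid in Hz.
#' @param V_star holding potential in mV; defaults to the resting potential.
#' @return list with `freqs` (Hz), `z_mag` (MOhm), and `fR` (Hz, argmax of
#'   the analytic magnitude on the grid).
#' @export
linearized_impedance <- function(p, freqs = seq(0.5, 20, by = 0.01),
                                 V_star = NULL) {
  stopifnot(inherits(p, "model_params"))
  if (is.null(V_star)) V_star <- resting_state(p)$V
  m <- .m_inf(V_star, p)
  dm_dV <- -m * (1 - m) / p$kh_mV                     # 1/mV
  w <- 2 * pi * freqs                                  # rad/s
  Y <- (p$gL_nS + p$gh_nS * m) * 1e-9 +                # S
    1i * w * p$C_pF * 1e-12 +
    p$gh_nS * 1e-9 * (V_star - p$Eh_mV) * dm_dV / (1 + 1i * w * p$tau_h_ms / 1000)
  z <- 1 / Y / 1e6                                     # MOhm
  zm <- Mod(z)
  list(freqs = freqs, z_mag = zm, fR = freqs[which.max(zm)], V_star = V_star)
}

# ---------------------------------------------------------------------------
# Cohort generation

#' Default layer archetypes of the synthetic cohort
#'
#' Four archetypes: superficial (`L2&3`) and deep-L3 (`L3c`) pyramidal cells
#' with modest Ih, a layer-5 (`L5`) pyramidal archetype with high Ih and
#' burst-onset firing (high reset), and a fast-spiking interneuron archetype
#' (`INT`, narrow pasted AP, deep after-hyperpolarization, high maximal rate).
#' Conductances are chosen to reproduce directions and orders of magnitude of
#' cross-layer contrasts (deep cells: larger sag, more depolarized rest,
#' larger Ih), not any particular cell's values.
#'
#' @return named list of lists, each with `params` (a [model_params()]),
#'   `layer_label`, intended `cell_class` and `bursting` labels, and `jitter`
#'   (relative SD applied to C, gL and gh when sampling a cohort).
#' @export
default_archetypes <- function() {
  list(
    `L2&3` = list(
      params = model_params(C_pF = 150, gL_nS = 10, EL_mV = -72, gh_nS = 2,
                            spike = "adex", VT_mV = -45, Vreset_mV = -53,
                            a_nS = 2, b_pA = 40, tau_w_ms = 150,
                            ap_peak_mV = 35, ap_rise_ms = 0.8, ap_fall_ms = 2.5),
      layer_label = "L2&3", cell_class = "pyramidal", bursting = "none",
      jitter = 0.05),
    L3c = list(
      params = model_params(C_pF = 170, gL_nS = 11, EL_mV = -71, gh_nS = 4,
                            spike = "adex", VT_mV = -45, Vreset_mV = -53,
                            a_nS = 2, b_pA = 40, tau_w_ms = 150,
                            ap_peak_mV = 35, ap_rise_ms = 0.8, ap_fall_ms = 2.5),
      layer_label = "L3c", cell_class = "pyramidal", bursting = "none",
      jitter = 0.05),
    L5 = list(
      params = model_params(C_pF = 200, gL_nS = 12, EL_mV = -70, gh_nS = 8,
                            spike = "adex", VT_mV = -45, Vreset_mV = -40,
                            a_nS = 2, b_pA = 120, tau_w_ms = 120,
                            ap_peak_mV = 35, ap_rise_ms = 0.8, ap_fall_ms = 2.5),
      layer_label = "L5", cell_class = "pyramidal", bursting = "at_rheobase",
      jitter = 0.05),
    INT = list(
      params = model_params(C_pF = 100, gL_nS = 8, EL_mV = -70, gh_nS = 1,
                            spike = "adex", VT_mV = -45, Vreset_mV = -58,
                            a_nS = 0, b_pA = 5, tau_w_ms = 30,
                            ap_peak_mV = 30, ap_rise_ms = 0.25, ap_fall_ms = 0.55),
      layer_label = "unknown", cell_class = "putative_interneuron",
      bursting = "none", jitter = 0.05)
  )
}

.jitter_params <- function(p, rel_sd) {
  for (f in c("C_pF", "gL_nS", "gh_nS")) {
    if (p[[f]] > 0) p[[f]] <- p[[f]] * exp(rnorm(1, 0, rel_sd))
  }
  p
}

#' Simulate all stimulus protocols for one cell
#'
#' Runs the current-step family, subthreshold and suprathreshold ZAP trials,
#' frozen filtered-noise trials, and a closed-form voltage-clamp Ih protocol
#' for a single parameter set.
#'
#' @param p a [model_params()] (spike mechanism `"adex"` for suprathreshold
#'   protocols).
#' @param protocols character subset of
#'   `c("steps", "zap_sub", "zap_supra", "noise", "vclamp")`.
#' @param cell_id,layer_label metadata for the generated sweeps.
#' @param n_zap_sub,n_zap_supra,n_noise trial counts.
#' @param zap_sub_amp,zap_supra_amp ZAP amplitudes (pA); the subthreshold
#'   amplitude should not elicit spikes.
#' @param noise_sd,noise_dc frozen-noise SD and DC offset (pA).
#' @param seed integer seed controlling trial-to-trial intrinsic noise.
#' @return named list of `sweep_set` objects (one per requested protocol).
#' @export
simulate_cell <- function(p, protocols = c("steps", "zap_sub", "zap_supra",
                                           "noise", "vclamp"),
                          cell_id = "sim", layer_label = "unknown",
                          n_zap_sub = 3, n_zap_supra = 5, n_noise = 30,
                          zap_sub_amp = 20, zap_supra_amp = NULL,
                          noise_sd = 120, noise_dc = NULL, seed = 1L) {
  out <- list()
  fs <- 1e4
  if ("steps" %in% protocols) {
    cmds <- make_current_steps(-400, 400, 50, fs = fs, cell_id = cell_id)
    sweeps <- lapply(seq_len(length(cmds)), function(k) {
      cmd <- cmds[[k]]
      pp <- p; pp$seed <- sub_seed(seed, 1000 + k)
      sim <- simulate_neuron(pp, cmd$current, fs,
                             stim_onset = cmd$stim_onset,
                             stim_offset = cmd$stim_offset,
                             cell_id = cell_id, protocol_id = "steps",
                             layer_label = layer_label,
                             amplitude = cmd$amplitude)
      sim$sweep
    })
    out$steps <- sweep_set(sweeps)
  }
  if (any(c("zap_sub", "zap_supra") %in% protocols)) {
    if (is.null(zap_supra_amp)) {
      # emulate the acquisition rule: raise the ZAP gain until spikes appear
      rh <- tryCatch(.approx_rheobase(p), error = function(e) 200)
      zap_supra_amp <- max(1.3 * rh, 100)
    }
    for (kind in intersect(protocols, c("zap_sub", "zap_supra"))) {
      amp <- if (kind == "zap_sub") zap_sub_amp else zap_supra_amp
      ntr <- if (kind == "zap_sub") n_zap_sub else n_zap_supra
      zp <- zap_protocol(amplitude = amp, sampling_rate = fs)
      zap <- make_zap(zp)
      # flank the chirp with baseline so the record settles (leakage control)
      stim <- c(rep(0, round(0.2 * fs)), zap$current, rep(0, round(0.3 * fs)))
      sweeps <- lapply(seq_len(ntr), function(k) {
        pp <- p
        if (kind == "zap_sub") pp$spike <- "none"
        pp$seed <- sub_seed(seed, 2000 + k + (kind == "zap_supra") * 500)
        sim <- simulate_neuron(pp, stim, fs,
                               stim_onset = 0.2, stim_offset = 0.2 + zp$T_s,
                               cell_id = cell_id, protocol_id = kind,
                               layer_label = layer_label, amplitude = amp)
        sim$sweep
      })
      out[[kind]] <- sweep_set(sweeps)
      attr(out[[kind]], "zap") <- zp
    }
  }
  if ("noise" %in% protocols) {
    if (is.null(noise_dc)) noise_dc <- calibrate_dc(p, noise_sd, target_rate = 8,
                                                    seed = seed)
    sweeps <- lapply(seq_len(n_noise), function(k) {
      np <- noise_protocol(noise_sd = noise_sd, dc_offset = noise_dc,
                           seed = 777L)  # frozen across trials
      stim <- make_frozen_filtered_noise(np)
      pp <- p; pp$noise_sd_pA <- max(p$noise_sd_pA, 30)
      pp$seed <- sub_seed(seed, 3000 + k)
      sim <- simulate_neuron(pp, stim, fs, stim_onset = 0,
                             stim_offset = np$duration,
                             cell_id = cell_id, protocol_id = "noise",
                             layer_label = layer_label, amplitude = noise_dc)
      sim$sweep
    })
    out$noise <- sweep_set(sweeps)
  }
  if ("vclamp" %in% protocols) {
    out$vclamp <- simulate_vclamp_ih(p, cell_id = cell_id,
                                     layer_label = layer_label,
                                     seed = sub_seed(seed, 4000))
  }
  out
}

# smallest 50-pA step (<= 400 pA) that elicits a spike, by direct simulation
.approx_rheobase <- function(p) {
  fs <- 1e4
  for (a in seq(50, 400, by = 50)) {
    stim <- c(rep(0, 1000), rep(a, 6000), rep(0, 1000))
    sim <- simulate_neuron(p, stim, fs, stim_onset = 0.1, stim_offset = 0.7)
    if (length(sim$spike_times) > 0) return(a)
  }
  stop("no spikes up to 400 pA")
}

#' Calibrate the DC offset of the noise stimulus to a target firing rate
#'
#' Emulates the acquisition procedure of adding steady current to the frozen
#' noise until the cell fires above a target rate (> 5 Hz).
#'
#' @param p a [model_params()] with `spike = "adex"`.
#' @param noise_sd noise SD in pA.
#' @param target_rate desired firing rate in Hz.
#' @param seed integer seed.
#' @return DC offset in pA.
#' @export
calibrate_dc <- function(p, noise_sd = 120, target_rate = 8, seed = 1L) {
  fs <- 1e4
  np0 <- noise_protocol(noise_sd = noise_sd, dc_offset = 0, seed = 777L)
  base <- make_frozen_filtered_noise(np0)
  rate_at <- function(dc) {
    pp <- p; pp$noise_sd_pA <- max(p$noise_sd_pA, 30); pp$seed <- seed
    sim <- simulate_neuron(pp, base + dc, fs, stim_offset = np0$duration)
    length(sim$spike_times) / np0$duration
  }
  lo <- 0; hi <- 800
  for (iter in 1:12) {
    mid <- (lo + hi) / 2
    if (rate_at(mid) < target_rate) lo <- mid else hi <- mid
  }
  hi
}

#' Reference parameter set for noise-driven gain experiments
#'
#' A spiking cell whose inter-spike voltage range (reset -62 mV to threshold)
#' overlaps the HCN activation curve (V50h = -78 mV, kh = 12 mV), so that Ih
#' actually shapes the noise-driven transfer function; with a more
#' depolarized reset the gate deactivates between spikes and blocking Ih has
#' no effect to measure.
#'
#' @param gh_nS HCN conductance (nS); set 0 for the in-silico analogue of
#'   the Ih blocker ZD7288.
#' @return a [model_params()].
#' @export
gain_reference_params <- function(gh_nS = 8) {
  model_params(C_pF = 150, gL_nS = 10, EL_mV = -72, gh_nS = gh_nS,
               V50h_mV = -78, kh_mV = 12, tau_h_ms = 50, spike = "adex",
               VT_mV = -45, Vreset_mV = -62, a_nS = 2, b_pA = 60,
               tau_w_ms = 120, noise_sd_pA = 30)
}

#' Correlation-based gain of a simulated neuron under noise stimulation
#'
#' Runs `n_trials` filtered-noise trials (independent noise realizations and
#' intrinsic-noise seeds per trial), detects the pasted AP peaks as ground
#' truth, and returns the correlation-based gain profile.
#'
#' @param p a [model_params()] with `spike = "adex"`.
#' @param n_trials number of trials.
#' @param noise_sd,dc_offset stimulus parameters (pA); `dc_offset = NULL`
#'   calibrates to `target_rate`.
#' @param target_rate rate target for the DC calibration (Hz).
#' @param freqs frequency grid of the gain profile.
#' @param duration trial duration (s).
#' @param seed integer seed.
#' @return a `gain_profile` (with `mean_rate` filled in).
#' @export
simulate_noise_gain <- function(p, n_trials = 30, noise_sd = 150,
                                dc_offset = NULL, target_rate = 8,
                                freqs = seq(2, 100, by = 0.2),
                                duration = 2.5, seed = 1L) {
  fs <- 1e4
  if (is.null(dc_offset))
    dc_offset <- calibrate_dc(p, noise_sd = noise_sd,
                              target_rate = target_rate, seed = seed)
  n <- round(duration * fs)
  smat <- matrix(0, n, n_trials); rmat <- matrix(0, n, n_trials); nsp <- 0
  for (k in seq_len(n_trials)) {
    stim <- make_frozen_filtered_noise(
      noise_protocol(duration = duration, noise_sd = noise_sd,
                     dc_offset = dc_offset, seed = sub_seed(seed, 1000 + k)))
    pp <- p; pp$noise_sd_pA <- max(p$noise_sd_pA, 30)
    pp$seed <- sub_seed(seed, 7000 + k)
    sim <- simulate_neuron(pp, stim, fs, stim_offset = duration)
    smat[, k] <- stim
    rmat[, k] <- firing_rate_signal(sim$peak_times, n, fs)$values
    nsp <- nsp + length(sim$peak_times)
  }
  cp <- correlations(smat, rmat, fs, max_lag = 1)
  frequency_dependent_gain(cp, freqs,
                           mean_rate = nsp / (n_trials * duration))
}

#' Direct sinusoidal-perturbation measurement of the gain at one frequency
#'
#' Superimposes a small sinusoid at frequency `f` on noise trials and
#' measures the trial-averaged spike-rate modulation depth divided by the
#' sinusoid amplitude — an estimate of G(f) that shares no code with the
#' correlation-based estimator. Trials are paired: each noise realization
#' (and intrinsic-noise seed) is simulated with and without the sinusoid and
#' the Fourier component of the rate difference is averaged, so the response
#' to the noise itself cancels exactly and the estimate converges as
#' `eps` shrinks.
#'
#' @param p a [model_params()] with `spike = "adex"`.
#' @param f perturbation frequency (Hz).
#' @param eps sinusoid amplitude (pA), small relative to the noise SD.
#' @param n_trials number of trial pairs (hundreds for a tight standard
#'   error).
#' @param noise_sd,dc_offset stimulus parameters (pA).
#' @param duration trial duration (s).
#' @param seed integer seed.
#' @return list with `gain` (Hz/pA), `se` (standard error across trial
#'   pairs), `n_trials`, `f`.
#' @export
measure_gain_sinusoidal <- function(p, f, eps = 10, n_trials = 200,
                                    noise_sd = 150, dc_offset = 300,
                                    duration = 2.5, seed = 1L) {
  fs <- 1e4
  n <- round(duration * fs)
  tt <- (seq_len(n) - 1) / fs
  sinv <- sin(2 * pi * f * tt)
  ew <- exp(-2i * pi * f * tt)
  z <- complex(n_trials)
  for (k in seq_len(n_trials)) {
    noise <- make_frozen_filtered_noise(
      noise_protocol(duration = duration, noise_sd = noise_sd,
                     dc_offset = dc_offset, seed = sub_seed(seed, 1000 + k)))
    pp <- p; pp$noise_sd_pA <- max(p$noise_sd_pA, 30)
    pp$seed <- sub_seed(seed, 7000 + k)
    rate_of <- function(stim) {
      sim <- simulate_neuron(pp, stim, fs, stim_offset = duration)
      firing_rate_signal(sim$peak_times, n, fs)$values
    }
    dr <- rate_of(noise + eps * sinv) - rate_of(noise)
    z[k] <- sum(dr * ew) / fs * 2 / duration
  }
  mz <- mean(z)
  dirm <- mz / Mod(mz)
  proj <- Re(z * Conj(dirm))
  list(gain = Mod(mz) / eps, se = sd(proj) / sqrt(n_trials) / eps,
       n_trials = n_trials, f = f)
}

#' Closed-form voltage-clamp Ih protocol for the model
#'
#' Generates the clamp-current responses to 600-ms voltage steps from a
#' -60 mV holding potential down to -140 mV in -10 mV increments. Because the
#' membrane potential is clamped, the ionic current has the closed form
#' `I(t) = gL (V - EL) + gh m(t) (V - Eh)` with exponentially relaxing
#' gating `m(t)`; brief decaying capacitive transients and Gaussian noise are
#' added at the step transitions.
#'
#' @param p a [model_params()].
#' @param steps_mV step potentials (default -60 to -140 by -10).
#' @param holding_mV holding potential (default -60).
#' @param step_s,pre_s,post_s durations in s.
#' @param fs sampling rate (Hz).
#' @param noise_sd_pA measurement noise SD.
#' @param cap_tau_ms,cap_amp_pA capacitive-transient decay and size.
#' @param cell_id,layer_label metadata.
#' @param seed integer seed for the noise.
#' @return a voltage-clamp `sweep_set` (voltage slot = recorded current in
#'   pA, current slot = command potential in mV).
#' @export
simulate_vclamp_ih <- function(p, steps_mV = seq(-60, -140, by = -10),
                               holding_mV = -60, step_s = 0.6, pre_s = 0.1,
                               post_s = 0.4, fs = 1e4, noise_sd_pA = 2,
                               cap_tau_ms = 1, cap_amp_pA = 500,
                               cell_id = "sim", layer_label = "unknown",
                               seed = 1L) {
  n_pre <- round(pre_s * fs); n_step <- round(step_s * fs)
  n_post <- round(post_s * fs)
  t_step <- (seq_len(n_step) - 1) / fs * 1000   # ms
  t_post <- (seq_len(n_post) - 1) / fs * 1000
  m_h <- .m_inf(holding_mV, p)
  ionic <- function(V, m) p$gL_nS * (V - p$EL_mV) + p$gh_nS * m * (V - p$Eh_mV)
  sweeps <- with_seed(seed, lapply(seq_along(steps_mV), function(k) {
    Vs <- steps_mV[k]
    m_inf_s <- .m_inf(Vs, p)
    m_t <- m_inf_s + (m_h - m_inf_s) * exp(-t_step / p$tau_h_ms)
    I_pre <- rep(ionic(holding_mV, m_h), n_pre)
    I_step <- ionic(Vs, m_t)
    m_end <- m_t[n_step]
    m_post <- m_h + (m_end - m_h) * exp(-t_post / p$tau_h_ms)
    I_post <- ionic(holding_mV, m_post)
    cap1 <- -cap_amp_pA * sign(holding_mV - Vs) * exp(-t_step / cap_tau_ms)
    cap2 <- cap_amp_pA * sign(holding_mV - Vs) * exp(-t_post / cap_tau_ms)
    i_rec <- c(I_pre, I_step + cap1, I_post + cap2) +
      rnorm(n_pre + n_step + n_post, 0, noise_sd_pA)
    v_cmd <- c(rep(holding_mV, n_pre), rep(Vs, n_step), rep(holding_mV, n_post))
    sweep_record(i_rec, v_cmd, fs, cell_id = cell_id,
                 protocol_id = "vclamp", layer_label = layer_label,
                 clamp_mode = "voltage", stim_onset = pre_s,
                 stim_offset = pre_s + step_s, amplitude = Vs)
  }))
  sweep_set(sweeps)
}

#' Generate a synthetic cohort and write it in the canonical sweep format
#'
#' Samples jittered parameters per archetype, simulates the requested
#' protocols for each cell, writes one manifest per cell and protocol plus an
#' index file `cells.csv` with the generating (ground-truth) labels.
#'
#' @param dir output directory.
#' @param n_per_archetype cells per archetype.
#' @param archetypes archetype list as in [default_archetypes()].
#' @param protocols protocol subset, see [simulate_cell()].
#' @param seed integer seed.
#' @return data frame (the index): `cell_id`, `layer_label`, `archetype`,
#'   `cell_class`, `bursting`, one manifest-path column per protocol, and the
#'   sampled `gh_nS`. Written to `<dir>/cells.csv`.
#' @export
make_cohort <- function(dir, n_per_archetype = 5,
                        archetypes = default_archetypes(),
                        protocols = c("steps", "vclamp"),
                        seed = 1L) {
  stopifnot(n_per_archetype >= 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  idx <- 0L
  with_seed(seed, {
    for (an in names(archetypes)) {
      at <- archetypes[[an]]
      for (j in seq_len(n_per_archetype)) {
        idx <- idx + 1L
        cid <- sprintf("cell%03d", idx)
        pj <- .jitter_params(at$params, at$jitter)
        pj$noise_sd_pA <- max(pj$noise_sd_pA, 10)
        sets <- simulate_cell(pj, protocols = protocols, cell_id = cid,
                              layer_label = at$layer_label,
                              seed = sub_seed(seed, idx))
        row <- list(cell_id = cid, layer_label = at$layer_label,
                    archetype = an, cell_class = at$cell_class,
                    bursting = at$bursting, gh_nS = pj$gh_nS)
        for (pn in names(sets)) {
          mpath <- file.path(dir, sprintf("%s_%s.csv", cid, pn))
          write_sweep_table(sets[[pn]], mpath)
          row[[paste0("manifest_", pn)]] <- basename(mpath)
        }
        rows[[idx]] <- as.data.frame(row, stringsAsFactors = FALSE)
      }
    }
  })
  index <- do.call(rbind, rows)
  write.csv(index, file.path(dir, "cells.csv"), row.names = FALSE)
  index
}
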
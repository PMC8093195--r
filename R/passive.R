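#' Resting membrane potential
#'
#' Mean pre-stimulus voltage across sweeps held at zero current with at least
#' `min_window_s` of pre-stimulus baseline.
#'
#' @param sweeps a `sweep_set` of current-clamp sweeps.
#' @param min_window_s minimum usable pre-stimulus window (default 0.1 s).
#' @param zero_tol_pa tolerance on the holding current (pA).
#' @return resting membrane potential in mV.
#' @export
resting_potential <- function(sweeps, min_window_s = 0.1, zero_tol_pa = 1) {
  stopifnot(inherits(sweeps, "sweep_set"))
  vals <- c()
  for (k in seq_len(length(sweeps))) {
    sw <- sweeps[[k]]
    n_on <- floor(sw$stim_onset * sw$sampling_rate)
    if (n_on < round(min_window_s * sw$sampling_rate)) next
    idx <- seq_len(n_on)
    if (mean(abs(sw$current[idx])) > zero_tol_pa) next
    vals <- c(vals, mean(sw$voltage[idx]))
  }
  if (length(vals) == 0)
    stop("no sweep with a zero-current pre-stimulus window >= ",
         min_window_s, " s")
  mean(vals)
}

.baseline_window <- function(sw, window_s = 0.1) {
  fs <- sw$sampling_rate
  i1 <- max(1L, floor(sw$stim_onset * fs) - round(window_s * fs) + 1L)
  i2 <- max(i1, floor(sw$stim_onset * fs))
  i1:i2
}

.steady_window <- function(sw, window_s = 0.1) {
  fs <- sw$sampling_rate
  i2 <- floor(sw$stim_offset * fs)
  i1 <- max(1L, i2 - round(window_s * fs) + 1L)
  i1:i2
}

.step_window <- function(sw) {
  fs <- sw$sampling_rate
  (floor(sw$stim_onset * fs) + 1L):floor(sw$stim_offset * fs)
}

#' Input resistance and membrane time constant
#'
#' Input resistance is the slope of the steady-state voltage deflection
#' against injected current over hyperpolarizing sweeps between -200 and
#' -50 pA; the membrane time constant is a single-exponential fit to the
#' voltage onset of each qualifying sweep (from step onset to the first
#' voltage extremum, so the sag rebound does not contaminate the fit),
#' averaged across sweeps.
#'
#' @param sweeps a `sweep_set` of current-step sweeps.
#' @param amp_range amplitude window in pA (default c(-200, -50)).
#' @return list with `input_resistance` (MOhm, `NA` + `rin_defined = FALSE`
#'   with fewer than 2 qualifying sweeps), `tau_m` (ms, `NA` + flag if no fit
#'   converged), and `n_sweeps`.
#' @export
input_resistance_and_tau <- function(sweeps, amp_range = c(-200, -50)) {
  stopifnot(inherits(sweeps, "sweep_set"))
  amps <- sweep_amplitudes(sweeps)
  sel <- which(amps >= amp_range[1] & amps <= amp_range[2])
  dv <- ii <- c(); taus <- c()
  for (k in sel) {
    sw <- sweeps[[k]]
    vb <- mean(sw$voltage[.baseline_window(sw)])
    vs <- mean(sw$voltage[.steady_window(sw)])
    dv <- c(dv, vs - vb); ii <- c(ii, amps[k])
    tau <- .fit_onset_tau(sw)
    if (!is.na(tau)) taus <- c(taus, tau)
  }
  rin <- NA_real_; rin_def <- FALSE
  if (length(sel) >= 2) {
    rin <- unname(coef(lm(dv ~ ii))[2]) * 1000   # mV/pA -> MOhm
    rin_def <- is.finite(rin) && rin > 0
  }
  tau_m <- if (length(taus) > 0) mean(taus) else NA_real_
  list(input_resistance = rin, rin_defined = rin_def,
       tau_m = tau_m, tau_defined = length(taus) > 0, n_sweeps = length(sel))
}

# single-exponential fit of the onset; returns tau in ms or NA
.fit_onset_tau <- function(sw) {
  fs <- sw$sampling_rate
  step <- .step_window(sw)
  v <- sw$voltage[step]
  # smooth lightly, then cut the fit at the first extremum (the sag trough)
  ks <- max(1L, round(0.002 * fs))
  vs <- as.numeric(stats::filter(v, rep(1 / ks, ks), sides = 2))
  vs[is.na(vs)] <- v[is.na(vs)]
  ext <- which.min(vs)
  n_fit <- max(ext, round(0.02 * fs))
  n_fit <- min(n_fit, length(v))
  t_ms <- (seq_len(n_fit) - 1) / fs * 1000
  vv <- v[seq_len(n_fit)]
  v0 <- vv[1]; vinf <- mean(vv[max(1, n_fit - round(0.002 * fs)):n_fit])
  if (abs(vinf - v0) < 0.5) return(NA_real_)
  fit <- tryCatch(
    minpack.lm::nlsLM(vv ~ vf + (v0f - vf) * exp(-t_ms / tau),
                      start = list(vf = vinf, v0f = v0, tau = 15),
                      lower = c(-150, -150, 0.1), upper = c(50, 50, 500)),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  unname(coef(fit)["tau"])
}

#' Sag amplitude and sag ratio of a hyperpolarizing step sweep
#'
#' Sag amplitude is the steady-state voltage minus the in-step minimum; sag
#' ratio divides by the peak deflection from baseline:
#' `(V_ss - V_min) / (V_base - V_min)`.
#'
#' @param sweep a hyperpolarizing current-clamp `sweep_record` (the default
#'   measurement sweep of the protocol is the -400 pA step).
#' @param baseline_s,steady_s window lengths in s (defaults 0.1).
#' @return list with `sag_amplitude` (mV), `sag_ratio`, component voltages,
#'   and `ratio_defined` (FALSE when the step produced no hyperpolarizing
#'   deflection).
#' @export
sag_features <- function(sweep, baseline_s = 0.1, steady_s = 0.1) {
  stopifnot(inherits(sweep, "sweep_record"))
  amp <- sweep$amplitude
  if (is.na(amp)) amp <- detect_stimulus_epoch(sweep)$amplitude
  if (amp >= 0) stop("sag analysis requires a hyperpolarizing step")
  v_base <- mean(sweep$voltage[.baseline_window(sweep, baseline_s)])
  step <- .step_window(sweep)
  v_min <- min(sweep$voltage[step])
  v_ss <- mean(sweep$voltage[.steady_window(sweep, steady_s)])
  sag_amp <- v_ss - v_min
  ratio_def <- (v_base - v_min) > 1e-6
  list(sag_amplitude = sag_amp,
       sag_ratio = if (ratio_def) sag_amp / (v_base - v_min) else NA_real_,
       ratio_defined = ratio_def,
       v_base = v_base, v_min = v_min, v_ss = v_ss)
}

#' Rebound depolarization and rebound spikes after a hyperpolarizing step
#'
#' Rebound amplitude is the maximum post-offset voltage (spike samples
#' masked) minus the pre-stimulus baseline; rebound spikes are counted in the
#' post-offset window with the overshoot detector.
#'
#' @param sweep a hyperpolarizing current-clamp `sweep_record` with at least
#'   `min_post_s` of post-stimulus recording.
#' @param baseline_s baseline window length (s).
#' @param min_post_s required post-stimulus window (default 0.3 s).
#' @return list with `rebound_amplitude` (mV) and `rebound_spike_count`.
#' @export
rebound_features <- function(sweep, baseline_s = 0.1, min_post_s = 0.3) {
  stopifnot(inherits(sweep, "sweep_record"))
  fs <- sweep$sampling_rate
  n <- length(sweep$voltage)
  post_start <- floor(sweep$stim_offset * fs) + 1L
  if ((n - post_start + 1) / fs < min_post_s - 1e-9)
    stop("post-stimulus window shorter than ", min_post_s, " s")
  v_base <- mean(sweep$voltage[.baseline_window(sweep, baseline_s)])
  post <- post_start:n
  v_post <- sweep$voltage[post]
  st <- detect_spikes(sweep, mode = "overshoot")
  post_spikes <- st$spike_times[st$spike_times >= (post_start - 1) / fs]
  mask <- rep(TRUE, length(post))
  if (length(post_spikes) > 0) {
    half <- round(0.005 * fs)   # blank 5 ms around each spike peak
    for (tsp in post_spikes) {
      i0 <- round(tsp * fs) + 1L - post_start + 1L
      mask[max(1, i0 - half):min(length(post), i0 + half)] <- FALSE
    }
  }
  vmax <- if (any(mask)) max(v_post[mask]) else v_base
  list(rebound_amplitude = max(vmax - v_base, 0),
       rebound_spike_count = length(post_spikes))
}

#' All passive and sag features for one cell's step family
#'
#' @param sweeps a `sweep_set` from the current-step protocol.
#' @param sag_at_pa amplitude of the sag measurement sweep (default -400 pA).
#' @return list of class `passive_features`: `rmp`, `input_resistance`,
#'   `tau_m`, `sag_amplitude`, `sag_ratio`, `rebound_amplitude`,
#'   `rebound_spike_count`, `sag_measured_at`.
#' @export
passive_features <- function(sweeps, sag_at_pa = -400) {
  stopifnot(inherits(sweeps, "sweep_set"))
  amps <- sweep_amplitudes(sweeps)
  rmp <- tryCatch(resting_potential(sweeps), error = function(e) NA_real_)
  rt <- input_resistance_and_tau(sweeps)
  k <- which.min(abs(amps - sag_at_pa))
  sag <- rb <- NULL
  if (amps[k] < 0) {
    sag <- tryCatch(sag_features(sweeps[[k]]), error = function(e) NULL)
    rb <- tryCatch(rebound_features(sweeps[[k]]), error = function(e) NULL)
  }
  structure(list(
    rmp = rmp,
    input_resistance = rt$input_resistance,
    tau_m = rt$tau_m,
    sag_amplitude = sag$sag_amplitude %||% NA_real_,
    sag_ratio = sag$sag_ratio %||% NA_real_,
    rebound_amplitude = rb$rebound_amplitude %||% NA_real_,
    rebound_spike_count = rb$rebound_spike_count %||% NA_integer_,
    sag_measured_at = amps[k]
  ), class = "passive_features")
}
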
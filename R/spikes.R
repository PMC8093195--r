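#' Detect action potentials in a current-clamp sweep
#'
#' Overshoot mode takes local voltage maxima above 0 mV separated by a
#' refractory margin; dV/dt mode takes upward crossings of a slope threshold
#' and reports the following voltage peak.
#'
#' @param sweep a current-clamp `sweep_record`.
#' @param mode `"overshoot"` (default) or `"dvdt"`.
#' @param refractory_s minimum peak separation (default 2 ms).
#' @param dvdt_threshold slope criterion in mV/ms for `"dvdt"` mode
#'   (default 20).
#' @return object of class `spike_train`: `spike_times` (s, strictly
#'   increasing), `detection_mode`, `sweep` (the input).
#' @export
detect_spikes <- function(sweep, mode = c("overshoot", "dvdt"),
                          refractory_s = 2e-3, dvdt_threshold = 20) {
  stopifnot(inherits(sweep, "sweep_record"))
  if (sweep$clamp_mode != "current")
    stop("spike detection requires a current-clamp sweep")
  mode <- match.arg(mode)
  v <- sweep$voltage
  fs <- sweep$sampling_rate
  peaks <- integer(0)
  if (mode == "overshoot") {
    cand <- which(v > 0)
    cand <- cand[cand > 1 & cand < length(v)]
    cand <- cand[v[cand] >= v[cand - 1] & v[cand] >= v[cand + 1]]
    peaks <- .enforce_refractory(cand, v, round(refractory_s * fs))
  } else {
    dvdt <- c(diff(v), 0) * fs / 1000   # mV/ms
    up <- which(dvdt[-1] >= dvdt_threshold & dvdt[-length(dvdt)] < dvdt_threshold) + 1L
    for (i0 in up) {
      j <- i0
      while (j < length(v) && v[j + 1] >= v[j]) j <- j + 1L
      peaks <- c(peaks, j)
    }
    peaks <- .enforce_refractory(unique(peaks), v, round(refractory_s * fs))
  }
  structure(list(spike_times = (peaks - 1) / fs,
                 spike_idx = peaks,
                 detection_mode = mode,
                 sweep = sweep),
            class = "spike_train")
}

.enforce_refractory <- function(cand, v, min_sep) {
  if (length(cand) < 2) return(cand)
  keep <- cand[1]
  for (k in cand[-1]) {
    last <- keep[length(keep)]
    if (k - last >= min_sep) keep <- c(keep, k)
    else if (v[k] > v[last]) keep[length(keep)] <- k
  }
  keep
}

#' Single action-potential waveform features
#'
#' Measured on the first spike of the rheobase sweep: threshold at the dV/dt
#' criterion crossing, amplitude = peak - threshold, width at half amplitude,
#' upstroke-downstroke ratio, after-hyperpolarization amplitude (threshold
#' minus the post-spike trough) and latency from stimulus onset.
#'
#' @param sweepset a `sweep_set` of depolarizing step sweeps.
#' @param dvdt_threshold threshold criterion in mV/ms (default 20).
#' @return object of class `ap_features` with fields `threshold`, `peak`,
#'   `amplitude`, `half_width` (ms), `upstroke_downstroke_ratio`,
#'   `ahp_amplitude`, `latency` (ms), `rheobase_amplitude`.
#' @export
ap_waveform_features <- function(sweepset, dvdt_threshold = 20) {
  stopifnot(inherits(sweepset, "sweep_set"))
  rh <- .rheobase_index(sweepset)
  if (is.na(rh$index)) stop("no suprathreshold sweep in the set")
  sw <- sweepset[[rh$index]]
  st <- detect_spikes(sw, "overshoot")
  fs <- sw$sampling_rate
  pk <- st$spike_idx[1]
  v <- sw$voltage
  dvdt <- c(diff(v), 0) * fs / 1000
  # search backwards from the peak for the threshold crossing
  lo <- max(1L, pk - round(0.01 * fs))
  seg <- lo:max(lo, pk - 1L)
  below <- seg[dvdt[seg] < dvdt_threshold]
  thr_idx <- if (length(below) > 0) below[length(below)] + 1L else lo
  thr_idx <- min(thr_idx, pk)
  threshold <- v[thr_idx]
  peak <- v[pk]
  amplitude <- peak - threshold
  half_level <- threshold + amplitude / 2
  # half-width by linear interpolation of the two half-level crossings
  i_up <- thr_idx
  while (i_up < pk && v[i_up + 1] < half_level) i_up <- i_up + 1L
  t_up <- i_up + (half_level - v[i_up]) / (v[i_up + 1] - v[i_up])
  end <- min(length(v), pk + round(0.02 * fs))
  i_dn <- pk
  while (i_dn < end && v[i_dn + 1] > half_level) i_dn <- i_dn + 1L
  t_dn <- if (i_dn < length(v) && v[i_dn + 1] <= half_level)
    i_dn + (v[i_dn] - half_level) / (v[i_dn] - v[i_dn + 1]) else NA_real_
  half_width <- (t_dn - t_up) / fs * 1000
  # upstroke / downstroke within +-10 ms of the peak
  win <- max(1L, pk - round(0.01 * fs)):min(length(v), pk + round(0.01 * fs))
  updown <- max(dvdt[win]) / abs(min(dvdt[win]))
  # AHP: trough between this spike and the next (or stimulus end)
  nxt <- if (length(st$spike_idx) > 1) st$spike_idx[2] else
    min(length(v), floor(sw$stim_offset * fs))
  trough <- min(v[pk:nxt])
  structure(list(threshold = threshold, peak = peak, amplitude = amplitude,
                 half_width = half_width,
                 upstroke_downstroke_ratio = updown,
                 ahp_amplitude = threshold - trough,
                 latency = (st$spike_times[1] - sw$stim_onset) * 1000,
                 rheobase_amplitude = rh$amplitude),
            class = "ap_features")
}

.rheobase_index <- function(sweepset, mode = "overshoot") {
  amps <- sweep_amplitudes(sweepset)
  counts <- vapply(seq_len(length(sweepset)), function(k) {
    sw <- sweepset[[k]]
    st <- detect_spikes(sw, mode)
    sum(st$spike_times >= sw$stim_onset & st$spike_times <= sw$stim_offset)
  }, numeric(1))
  supra <- which(counts > 0 & amps > 0)
  if (length(supra) == 0)
    return(list(index = NA_integer_, amplitude = NA_real_, counts = counts))
  k <- supra[which.min(amps[supra])]
  list(index = k, amplitude = amps[k], counts = counts)
}

#' Spike-train features from a depolarizing step family
#'
#' Rheobase, f-I slope, and hero-sweep statistics. The hero sweep is the
#' sweep closest to rheobase + 50 pA within the +39 to +61 pA window (ties
#' toward the smaller amplitude); when the window is empty the nearest
#' suprathreshold sweep is used and flagged. The adaptation index is the mean
#' over consecutive inter-spike-interval pairs of
#' `(ISI[i+1] - ISI[i]) / (ISI[i+1] + ISI[i])` on the hero sweep.
#'
#' @param sweepset a `sweep_set` of step sweeps (e.g. 0 to 400 pA by 50).
#' @return object of class `train_features`: `rheobase` (pA), `fi_slope`
#'   (Hz/pA), `adaptation_index`, `isi_first`, `isi_mean`, `isi_median`
#'   (ms), `isi_cv`, `avg_rate_hero` (Hz), `hero_amplitude` (pA),
#'   `max_rate` (Hz), `isi_first_rheobase`, `isi_first_rheo50` (ms),
#'   `hero_fallback` flag, and `defined` (FALSE when no sweep spiked).
#' @export
train_features <- function(sweepset) {
  stopifnot(inherits(sweepset, "sweep_set"))
  amps <- sweep_amplitudes(sweepset)
  rh <- .rheobase_index(sweepset)
  und <- structure(list(rheobase = NA_real_, fi_slope = NA_real_,
                        adaptation_index = NA_real_, isi_first = NA_real_,
                        isi_mean = NA_real_, isi_median = NA_real_,
                        isi_cv = NA_real_, avg_rate_hero = NA_real_,
                        hero_amplitude = NA_real_, max_rate = NA_real_,
                        isi_first_rheobase = NA_real_,
                        isi_first_rheo50 = NA_real_,
                        hero_fallback = FALSE, defined = FALSE),
                   class = "train_features")
  if (is.na(rh$index)) return(und)
  rheobase <- rh$amplitude
  dur <- vapply(seq_len(length(sweepset)), function(k)
    sweepset[[k]]$stim_offset - sweepset[[k]]$stim_onset, numeric(1))
  rates <- rh$counts / dur
  # f-I fit over sweeps at or above rheobase
  sel <- which(amps >= rheobase)
  fi_slope <- if (length(sel) >= 2)
    unname(coef(lm(rates[sel] ~ amps[sel]))[2]) else NA_real_
  # hero sweep
  in_win <- which(amps >= rheobase + 39 & amps <= rheobase + 61 & rh$counts > 0)
  fallback <- FALSE
  if (length(in_win) > 0) {
    d <- abs(amps[in_win] - (rheobase + 50))
    cand <- in_win[d == min(d)]
    hero <- cand[which.min(amps[cand])]
  } else {
    supra <- which(rh$counts > 0 & amps > 0 & seq_along(amps) != rh$index)
    if (length(supra) == 0) supra <- rh$index
    hero <- supra[which.min(abs(amps[supra] - (rheobase + 50)))]
    fallback <- TRUE
  }
  isis_of <- function(k) {
    sw <- sweepset[[k]]
    st <- detect_spikes(sw, "overshoot")
    tt <- st$spike_times[st$spike_times >= sw$stim_onset &
                           st$spike_times <= sw$stim_offset]
    if (length(tt) < 2) return(numeric(0))
    diff(tt) * 1000
  }
  isis <- isis_of(hero)
  adapt <- if (length(isis) >= 2)
    mean((isis[-1] - isis[-length(isis)]) / (isis[-1] + isis[-length(isis)]))
  else NA_real_
  isi_rheo <- isis_of(rh$index)
  k50 <- which(abs(amps - (rheobase + 50)) < 1)
  isi_50 <- if (length(k50) == 1) isis_of(k50) else numeric(0)
  structure(list(
    rheobase = rheobase, fi_slope = fi_slope,
    adaptation_index = adapt,
    isi_first = if (length(isis) > 0) isis[1] else NA_real_,
    isi_mean = if (length(isis) > 0) mean(isis) else NA_real_,
    isi_median = if (length(isis) > 0) median(isis) else NA_real_,
    isi_cv = if (length(isis) > 1) sd(isis) / mean(isis) else
      if (length(isis) == 1) 0 else NA_real_,
    avg_rate_hero = rates[hero],
    hero_amplitude = amps[hero],
    max_rate = max(rates),
    isi_first_rheobase = if (length(isi_rheo) > 0) isi_rheo[1] else NA_real_,
    isi_first_rheo50 = if (length(isi_50) > 0) isi_50[1] else NA_real_,
    hero_fallback = fallback, defined = TRUE
  ), class = "train_features")
}

#' Rule-based cell classification
#'
#' Bursting at rheobase iff the instantaneous frequency of the first
#' inter-spike interval at rheobase exceeds 75 Hz (equivalently first ISI
#' under 1000/75 ms); also evaluated at rheobase + 50 pA. Putative
#' interneuron iff spike half-width < 1 ms AND after-hyperpolarization
#' amplitude > 10 mV AND maximum firing rate > 75 Hz; otherwise pyramidal.
#'
#' @param ap an `ap_features` object.
#' @param train a `train_features` object.
#' @param max_rate maximum firing rate over the step family in Hz; defaults
#'   to `train$max_rate`.
#' @param inst_freq_hz bursting threshold (default 75 Hz).
#' @return list with `cell_class` (`"pyramidal"` or
#'   `"putative_interneuron"`), `bursting` (`"none"`, `"at_rheobase"`,
#'   `"at_rheobase_plus_50"`), and `classified` (FALSE with missing inputs).
#' @export
classify_cell <- function(ap, train, max_rate = NULL, inst_freq_hz = 75) {
  if (is.null(max_rate)) max_rate <- train$max_rate
  if (!isTRUE(train$defined) || is.na(ap$half_width) || is.na(max_rate))
    return(list(cell_class = NA_character_, bursting = NA_character_,
                classified = FALSE))
  burst_rheo <- !is.na(train$isi_first_rheobase) &&
    1000 / train$isi_first_rheobase > inst_freq_hz
  burst_50 <- !is.na(train$isi_first_rheo50) &&
    1000 / train$isi_first_rheo50 > inst_freq_hz
  bursting <- if (burst_rheo) "at_rheobase" else
    if (burst_50) "at_rheobase_plus_50" else "none"
  interneuron <- ap$half_width < 1 && ap$ahp_amplitude > 10 &&
    max_rate > inst_freq_hz
  list(cell_class = if (interneuron) "putative_interneuron" else "pyramidal",
       bursting = bursting, classified = TRUE)
}
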
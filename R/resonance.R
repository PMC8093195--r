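#' Subthreshold impedance profile from ZAP trials
#'
#' The voltage responses of non-spiking trials are averaged; the impedance is
#' the ratio of the Fourier transform of the mean voltage to the transform of
#' the common ZAP command, with magnitude taken over the stimulus band and
#' smoothed by a centered moving average. The resonance (center) frequency fR
#' is the argmax of the smoothed magnitude; the cutoff frequency is where the
#' smoothed magnitude first falls to `cutoff_fraction` of the center value
#' above fR.
#'
#' @param trials a `sweep_set` of ZAP trials (up to five are averaged).
#' @param zap the [zap_protocol()] describing the common command.
#' @param smooth_hz width of the moving-average smoother in Hz (default 0.5).
#' @param cutoff_fraction fraction of the center impedance defining the
#'   cutoff: 0.707 (default, the conventional 3 dB amplitude point) or 0.5
#'   (half the center impedance).
#' @param resonant_min_hz lower edge of the fR search and the resonance
#'   criterion: a maximum at the lowest evaluated band frequency is reported
#'   but classified non-resonant.
#' @return object of class `impedance_profile`: `freqs` (Hz), `z_mag`
#'   (MOhm, smoothed), `z_mag_norm` (max 1), `fR`, `f3db`, `resonant`,
#'   `n_trials_averaged`.
#' @export
impedance_profile <- function(trials, zap, smooth_hz = 0.5,
                              cutoff_fraction = 0.707,
                              resonant_min_hz = 0.5) {
  stopifnot(inherits(trials, "sweep_set"), inherits(zap, "zap_protocol"))
  keep <- list()
  for (k in seq_len(length(trials))) {
    sw <- trials[[k]]
    st <- detect_spikes(sw, "overshoot")
    if (length(st$spike_times) > 0) {
      warning("trial ", k, " contains spikes and was rejected")
      next
    }
    keep[[length(keep) + 1]] <- sw
  }
  if (length(keep) == 0) stop("all ZAP trials contained spikes")
  keep <- keep[seq_len(min(5, length(keep)))]
  fs <- keep[[1]]$sampling_rate
  vmat <- vapply(keep, `[[`, numeric(length(keep[[1]]$voltage)), "voltage")
  v <- rowMeans(vmat)
  i <- keep[[1]]$current
  n <- length(v)
  V <- fft(v - mean(v))
  I <- fft(i - mean(i))
  freqs_all <- (seq_len(n) - 1) * fs / n
  band <- which(freqs_all >= zap$f0 - 1e-9 & freqs_all <= zap$f1 + 1e-9)
  z <- Mod(V[band] / I[band]) * 1000      # mV/pA -> GOhm -> MOhm
  freqs <- freqs_all[band]
  df <- fs / n
  wbins <- max(1L, round(smooth_hz / df))
  if (wbins %% 2 == 0) wbins <- wbins + 1L
  zs <- .centered_ma(z, wbins)
  search <- which(freqs >= resonant_min_hz)
  fR_idx <- search[which.max(zs[search])]
  fR <- freqs[fR_idx]
  zc <- zs[fR_idx]
  above <- which(freqs > fR & zs <= cutoff_fraction * zc)
  f3db <- if (length(above) > 0) freqs[above[1]] else NA_real_
  lowest <- freqs[search[1]]
  resonant <- fR > resonant_min_hz && fR > lowest + 1e-9
  structure(list(freqs = freqs, z_mag = zs, z_mag_norm = zs / max(zs),
                 fR = fR, f3db = f3db, resonant = resonant,
                 n_trials_averaged = length(keep)),
            class = "impedance_profile")
}

# centered moving average with shrinking windows at the edges
.centered_ma <- function(x, w) {
  if (w <= 1) return(x)
  h <- (w - 1) %/% 2
  n <- length(x)
  out <- numeric(n)
  cs <- cumsum(c(0, x))
  for (k in seq_len(n)) {
    i1 <- max(1, k - h); i2 <- min(n, k + h)
    out[k] <- (cs[i2 + 1] - cs[i1]) / (i2 - i1 + 1)
  }
  out
}

#' Spike-probability density over stimulus frequency from suprathreshold ZAP
#'
#' Each spike is assigned the instantaneous frequency of the chirp at its
#' time; frequencies are pooled over trials, and the histogram over the bin
#' grid is divided by the total spike count.
#'
#' @param trials a `sweep_set` of suprathreshold ZAP trials.
#' @param zap the [zap_protocol()] of the command.
#' @param bin_hz histogram bin width in Hz (default 0.5).
#' @return object of class `spike_frequency_density`: `bin_edges`,
#'   `probability` (sums to 1 when spikes exist), `n_spikes_total`,
#'   `spike_freqs` (the per-spike frequency samples, retained).
#' @export
spike_probability_density <- function(trials, zap, bin_hz = 0.5) {
  stopifnot(inherits(trials, "sweep_set"), inherits(zap, "zap_protocol"))
  freqs <- c()
  for (k in seq_len(length(trials))) {
    sw <- trials[[k]]
    st <- detect_spikes(sw, "overshoot")
    tt <- st$spike_times[st$spike_times >= sw$stim_onset &
                           st$spike_times <= sw$stim_offset]
    if (length(tt) == 0) next
    f <- zap$f0 + (zap$f1 - zap$f0) * (tt - sw$stim_onset) / zap$T_s
    freqs <- c(freqs, pmin(pmax(f, zap$f0), zap$f1))
  }
  edges <- seq(zap$f0, zap$f1, by = bin_hz)
  if (edges[length(edges)] < zap$f1) edges <- c(edges, zap$f1)
  if (length(freqs) == 0) {
    return(structure(list(bin_edges = edges,
                          probability = rep(0, length(edges) - 1),
                          n_spikes_total = 0L, spike_freqs = numeric(0),
                          empty = TRUE),
                     class = "spike_frequency_density"))
  }
  h <- graphics::hist(freqs, breaks = edges, plot = FALSE)
  structure(list(bin_edges = edges, probability = h$counts / length(freqs),
                 n_spikes_total = length(freqs), spike_freqs = freqs,
                 empty = FALSE),
            class = "spike_frequency_density")
}

#' Compare two spike-frequency distributions
#'
#' Two-sample Kolmogorov-Smirnov test on the retained per-spike frequency
#' samples (not the binned densities), optionally restricted to a band.
#'
#' @param a,b `spike_frequency_density` objects.
#' @param band optional `c(lo, hi)` in Hz restricting the samples (e.g.
#'   `c(12, Inf)` for an above-12-Hz comparison).
#' @return list with `ks_statistic` and `p_value`.
#' @export
compare_densities <- function(a, b, band = NULL) {
  xa <- a$spike_freqs; xb <- b$spike_freqs
  if (!is.null(band)) {
    xa <- xa[xa >= band[1] & xa <= band[2]]
    xb <- xb[xb >= band[1] & xb <= band[2]]
  }
  if (length(xa) == 0 || length(xb) == 0)
    stop("no spikes left after band restriction")
  kt <- suppressWarnings(ks.test(xa, xb))
  list(ks_statistic = unname(kt$statistic), p_value = kt$p.value)
}
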
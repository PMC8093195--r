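#' Delta-function firing-rate signal
#'
#' The time-varying rate equals `1/dt` at spike samples and 0 elsewhere, so
#' its integral over time is the spike count.
#'
#' @param spikes a `spike_train`, or numeric spike times in s.
#' @param n_samples length of the signal.
#' @param fs sampling rate (Hz).
#' @return object of class `rate_signal`: `values` (Hz per sample), `fs`.
#' @export
firing_rate_signal <- function(spikes, n_samples, fs) {
  tt <- if (inherits(spikes, "spike_train")) spikes$spike_times else spikes
  idx <- round(tt * fs) + 1L
  if (any(idx < 1 | idx > n_samples))
    stop("spike outside the signal window")
  if (anyDuplicated(idx))
    stop("duplicate spike sample")
  r <- numeric(n_samples)
  r[idx] <- fs
  structure(list(values = r, fs = fs), class = "rate_signal")
}

#' Stimulus-response and stimulus-stimulus correlation functions
#'
#' Biased cross- and auto-correlation estimates on a symmetric lag grid,
#' averaged over trials when matrices are supplied (each column one trial, so
#' inter-trial boundaries never contribute). Both signals are mean-subtracted
#' first (the DC injection would otherwise dominate the lag functions).
#' `tau_delay` is the lag at the maximum of `c_sr`.
#'
#' @param s stimulus series in pA (vector, or matrix with one trial per
#'   column).
#' @param r a `rate_signal`, a numeric vector, or a matrix matching `s`.
#' @param fs sampling rate (Hz).
#' @param max_lag maximum lag in s (must be < duration/2; default 1).
#' @return object of class `correlation_pair`: `lags` (s), `c_sr` (pA Hz),
#'   `c_ss` (pA^2), `tau_delay` (s), `fs`.
#' @export
correlations <- function(s, r, fs, max_lag = 1) {
  if (inherits(r, "rate_signal")) r <- r$values
  s <- as.matrix(s); r <- as.matrix(r)
  stopifnot(nrow(s) == nrow(r), ncol(s) == ncol(r) || ncol(s) == 1)
  if (ncol(s) == 1 && ncol(r) > 1) s <- s[, rep(1, ncol(r)), drop = FALSE]
  n <- nrow(s)
  if (max_lag >= n / fs / 2) stop("max_lag must be < duration/2")
  if (all(apply(s, 2, sd) == 0)) stop("constant stimulus: c_ss degenerate")
  L <- round(max_lag * fs)
  nfft <- stats::nextn(n + L, 2)
  acc_sr <- acc_ss <- 0
  for (j in seq_len(ncol(s))) {
    sj <- s[, j] - mean(s[, j])
    rj <- r[, j] - mean(r[, j])
    S <- fft(c(sj, rep(0, nfft - n)))
    R <- fft(c(rj, rep(0, nfft - n)))
    # cross-correlation c_sr(tau) = (1/n) sum_t s(t) r(t+tau)
    cc <- Re(fft(Conj(S) * R, inverse = TRUE)) / nfft / n
    aa <- Re(fft(Conj(S) * S, inverse = TRUE)) / nfft / n
    # wrap to lags -L..L
    acc_sr <- acc_sr + c(cc[(nfft - L + 1):nfft], cc[1:(L + 1)])
    acc_ss <- acc_ss + c(aa[(nfft - L + 1):nfft], aa[1:(L + 1)])
  }
  c_sr <- acc_sr / ncol(s)
  c_ss <- acc_ss / ncol(s)
  lags <- (-L:L) / fs
  structure(list(lags = lags, c_sr = c_sr, c_ss = c_ss,
                 tau_delay = lags[which.max(c_sr)], fs = fs),
            class = "correlation_pair")
}

#' Frequency-dependent gain and phase
#'
#' For each grid frequency the lag functions are multiplied by a Gaussian
#' window `exp(-tau^2/(2 sigma^2))` with `sigma = 1/f` (so spectral
#' estimates are not dominated by noise), the Fourier components at `f` are
#' taken, and the gain is `G(f) = |C_sr(f)| / |C_ss(f)|`, with four-quadrant
#' phase `phi(f) = Arg(C_sr(f))`. The corrected phase removes the pure
#' transmission delay: `phi(f) + 2 pi f tau_delay`, wrapped to `(-pi, pi]`.
#'
#' The window on the cross-correlation is centered at `tau_delay` (where its
#' mass sits) and the window on the autocorrelation at zero; a zero-centered
#' window on a delayed cross-correlation would bias the phase at high
#' frequencies, where `sigma` shrinks toward the delay itself.
#'
#' @param cp a [correlations()] result.
#' @param freqs frequency grid in Hz (default 2 to 100 by 0.2: 491 points).
#' @param mean_rate optional mean firing rate (Hz) recorded in the profile.
#' @return object of class `gain_profile`: `freqs`, `gain` (Hz/pA),
#'   `phase_raw`, `phase_corrected` (rad), `tau_delay` (s), `mean_rate`.
#' @export
frequency_dependent_gain <- function(cp, freqs = seq(2, 100, by = 0.2),
                                     mean_rate = NA_real_) {
  stopifnot(inherits(cp, "correlation_pair"))
  if (any(freqs <= 0)) stop("frequencies must be > 0")
  tau <- cp$lags
  dt <- 1 / cp$fs
  gain <- phase <- numeric(length(freqs))
  for (k in seq_along(freqs)) {
    f <- freqs[k]
    wgt_sr <- exp(-(tau - cp$tau_delay)^2 / (2 * (1 / f)^2))
    wgt_ss <- exp(-tau^2 / (2 * (1 / f)^2))
    e <- exp(-2i * pi * f * tau)
    Csr <- sum(cp$c_sr * wgt_sr * e) * dt
    Css <- sum(cp$c_ss * wgt_ss * e) * dt
    gain[k] <- Mod(Csr) / Mod(Css)
    phase[k] <- Arg(Csr)
  }
  corrected <- .wrap_pi(phase + 2 * pi * freqs * cp$tau_delay)
  structure(list(freqs = freqs, gain = gain, phase_raw = phase,
                 phase_corrected = corrected, tau_delay = cp$tau_delay,
                 mean_rate = mean_rate),
            class = "gain_profile")
}

.wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi + 1e-12] <- y[y <= -pi + 1e-12] + 2 * pi
  y
}

#' Frequency-dependent gain of one cell from its noise trials
#'
#' Convenience wrapper: detects spikes (overshoot mode) on every trial of the
#' frozen-noise protocol, builds the rate signals, averages per-trial
#' correlations, and returns the gain profile with the cell's mean rate.
#'
#' @param trials a `sweep_set` from the frozen-noise protocol.
#' @param freqs frequency grid (Hz).
#' @param max_lag maximum correlation lag (s).
#' @return a `gain_profile`.
#' @export
cell_gain <- function(trials, freqs = seq(2, 100, by = 0.2), max_lag = 1) {
  stopifnot(inherits(trials, "sweep_set"))
  n <- length(trials[[1]]$voltage)
  fs <- trials[[1]]$sampling_rate
  smat <- matrix(0, n, length(trials))
  rmat <- matrix(0, n, length(trials))
  nsp <- 0
  for (k in seq_len(length(trials))) {
    sw <- trials[[k]]
    st <- detect_spikes(sw, "overshoot")
    smat[, k] <- sw$current
    rmat[, k] <- firing_rate_signal(st, n, fs)$values
    nsp <- nsp + length(st$spike_times)
  }
  cp <- correlations(smat, rmat, fs, max_lag = max_lag)
  frequency_dependent_gain(cp, freqs,
                           mean_rate = nsp / (length(trials) * n / fs))
}

#' Spike-triggered average stimulus
#'
#' Mean of the stimulus over the `window` seconds preceding each spike, with
#' the stimulus mean subtracted. Spikes earlier than `window` from the start
#' are skipped and counted.
#'
#' @param s stimulus series (pA).
#' @param spikes a `spike_train` or numeric spike times (s).
#' @param window pre-spike window length in s (default 0.2).
#' @param fs sampling rate (Hz).
#' @return object of class `sta_result`: `lags` (s, `-window` to 0,
#'   `round(window*fs)+1` points), `sta` (pA), `n_spikes`, `n_skipped`.
#' @export
spike_triggered_average <- function(s, spikes, window = 0.2, fs) {
  tt <- if (inherits(spikes, "spike_train")) spikes$spike_times else spikes
  L <- round(window * fs)
  idx <- round(tt * fs) + 1L
  usable <- idx[idx > L & idx <= length(s)]
  if (length(usable) == 0) stop("no usable spikes for the STA window")
  acc <- numeric(L + 1)
  for (i in usable) acc <- acc + s[(i - L):i]
  structure(list(lags = (-L:0) / fs,
                 sta = acc / length(usable) - mean(s),
                 n_spikes = length(usable),
                 n_skipped = length(idx) - length(usable)),
            class = "sta_result")
}

#' Per-frequency group comparison of gain profiles
#'
#' Two-sided rank-sum (Mann-Whitney) test of gain between two groups of
#' cells at each grid frequency, with step-up false-discovery-rate
#' (Benjamini-Hochberg) correction. Cells with mean firing rate at or below
#' `min_rate` are excluded.
#'
#' @param groupA,groupB lists of `gain_profile` objects (one per cell).
#' @param alpha FDR level (default 0.01).
#' @param min_rate firing-rate inclusion threshold in Hz (default 5).
#' @return data frame with `freq`, `p_value`, `p_adjusted`, `significant`.
#' @export
groupwise_gain_comparison <- function(groupA, groupB, alpha = 0.01,
                                      min_rate = 5) {
  keep <- function(g) Filter(function(p)
    is.na(p$mean_rate) || p$mean_rate > min_rate, g)
  groupA <- keep(groupA); groupB <- keep(groupB)
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("each group needs at least 2 cells above the rate threshold")
  fr <- groupA[[1]]$freqs
  for (p in c(groupA, groupB))
    if (!isTRUE(all.equal(p$freqs, fr)))
      stop("gain profiles must share one frequency grid")
  ga <- vapply(groupA, `[[`, numeric(length(fr)), "gain")
  gb <- vapply(groupB, `[[`, numeric(length(fr)), "gain")
  pv <- vapply(seq_along(fr), function(k)
    suppressWarnings(wilcox.test(ga[k, ], gb[k, ])$p.value),
    numeric(1))
  padj <- p.adjust(pv, method = "BH")
  data.frame(freq = fr, p_value = pv, p_adjusted = padj,
             significant = padj < alpha)
}
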
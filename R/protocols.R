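#' Rectangular current-step command family
#'
#' Builds one command trace per amplitude between `start` and `stop` in
#' `increment` steps, each a rectangular step of `duration` seconds flanked by
#' `pre` and `post` baseline.
#'
#' @param start,stop,increment step amplitudes in pA; `(stop - start)` must be
#'   an integer multiple of `increment`.
#' @param duration step duration in s (default 0.6).
#' @param pre,post baseline before and after the step in s.
#' @param fs sampling rate in Hz.
#' @param cell_id,protocol_id identifiers for the resulting set.
#' @return a `sweep_set` of current-clamp command sweeps (voltage channel zero).
#' @export
make_current_steps <- function(start, stop, increment,
                               duration = 0.6, pre = 0.1, post = 0.3,
                               fs = 1e4, cell_id = "command",
                               protocol_id = "steps") {
  if (increment == 0) stop("increment must be nonzero")
  k <- (stop - start) / increment
  if (abs(k - round(k)) > 1e-9) {
    achievable <- start + increment * seq(0, floor(k))
    stop("(stop - start) is not divisible by increment; achievable amplitudes: ",
         paste(achievable, collapse = ", "))
  }
  amps <- start + increment * seq(0, round(k))
  n_pre <- round(pre * fs); n_step <- round(duration * fs); n_post <- round(post * fs)
  n <- n_pre + n_step + n_post
  sweeps <- lapply(amps, function(a) {
    i <- c(rep(0, n_pre), rep(a, n_step), rep(0, n_post))
    sweep_record(rep(0, n), i, fs, cell_id = cell_id, protocol_id = protocol_id,
                 stim_onset = pre, stim_offset = pre + duration, amplitude = a)
  })
  sweep_set(sweeps)
}

#' ZAP (chirp) stimulus parameters
#'
#' @param f0,f1 start and end frequency in Hz (`0 < f0 < f1`).
#' @param T_s duration in s.
#' @param amplitude peak current in pA.
#' @param sampling_rate sampling rate in Hz.
#' @param sweep `"linear"` (default, the convention of the impedance-profile
#'   literature) or `"exponential"` frequency sweep.
#' @return object of class `zap_protocol`.
#' @export
zap_protocol <- function(f0 = 1, f1 = 20, T_s = 20, amplitude = 50,
                         sampling_rate = 1e4,
                         sweep = c("linear", "exponential")) {
  sweep <- match.arg(sweep)
  if (!(f0 > 0 && f1 > f0)) stop("need 0 < f0 < f1")
  if (T_s <= 0) stop("duration must be > 0")
  structure(list(f0 = f0, f1 = f1, T_s = T_s, amplitude = amplitude,
                 sampling_rate = sampling_rate, sweep = sweep),
            class = "zap_protocol")
}

#' Generate a ZAP (chirp) current command
#'
#' Linear chirp: I(t) = A sin(2 pi (f0 t + (f1 - f0) t^2 / (2 T))), with
#' instantaneous frequency f0 + (f1 - f0) t / T.
#'
#' @param p a [zap_protocol()].
#' @return list with `current` (pA), `inst_freq` (Hz) and `time` (s), each of
#'   length `round(T_s * sampling_rate)`.
#' @export
make_zap <- function(p) {
  stopifnot(inherits(p, "zap_protocol"))
  fs <- p$sampling_rate
  if (fs < 2 * p$f1)
    stop("sampling rate ", fs, " Hz aliases the ", p$f1, " Hz end frequency")
  n <- round(p$T_s * fs)
  t <- (seq_len(n) - 1) / fs
  if (p$sweep == "linear") {
    phase <- 2 * pi * (p$f0 * t + (p$f1 - p$f0) * t^2 / (2 * p$T_s))
    inst <- p$f0 + (p$f1 - p$f0) * t / p$T_s
  } else {
    k <- (p$f1 / p$f0)^(1 / p$T_s)
    phase <- 2 * pi * p$f0 * (k^t - 1) / log(k)
    inst <- p$f0 * k^t
  }
  list(current = p$amplitude * sin(phase), inst_freq = inst, time = t)
}

#' Frozen filtered-noise stimulus parameters
#'
#' @param duration duration in s (default 2.5).
#' @param sampling_rate Hz (default 10 kHz).
#' @param box_width square-kernel width in s (default 3 ms).
#' @param noise_sd pre-filter white-noise SD in pA.
#' @param dc_offset steady current added to the noise, pA.
#' @param seed integer seed making the stimulus frozen.
#' @return object of class `noise_protocol`.
#' @export
noise_protocol <- function(duration = 2.5, sampling_rate = 1e4,
                           box_width = 3e-3, noise_sd = 100,
                           dc_offset = 0, seed = 1L) {
  if (box_width <= 0) stop("box_width must be > 0")
  if (duration <= 0) stop("duration must be > 0")
  structure(list(duration = duration, sampling_rate = sampling_rate,
                 box_width = box_width, noise_sd = noise_sd,
                 dc_offset = dc_offset, seed = as.integer(seed)),
            class = "noise_protocol")
}

#' Generate a frozen filtered Gaussian-noise current
#'
#' Gaussian white noise of SD `noise_sd` convolved with a discrete unit-sum
#' boxcar of width `box_width` (so the mean passes unchanged and the
#' post-filter SD is `noise_sd / sqrt(width * fs)`), plus `dc_offset`.
#' Identical output for identical seed.
#'
#' @param p a [noise_protocol()].
#' @return numeric current series in pA.
#' @export
make_frozen_filtered_noise <- function(p) {
  stopifnot(inherits(p, "noise_protocol"))
  fs <- p$sampling_rate
  n <- round(p$duration * fs)
  w <- max(1L, round(p$box_width * fs))
  with_seed(p$seed, {
    white <- rnorm(n + w - 1, 0, p$noise_sd)
    kern <- rep(1 / w, w)
    filt <- as.numeric(stats::filter(white, kern, sides = 1))
    filt <- filt[w:(n + w - 1)]
    filt + p$dc_offset
  })
}
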
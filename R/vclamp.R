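#' Ih step and tail-current amplitudes from a voltage-clamp family
#'
#' For each 600-ms step from the holding potential, the Ih amplitude is the
#' absolute difference between the steady-state current at the end of the
#' step and the instantaneous current measured just after the capacitive
#' transient; the tail amplitude is the peak residual current after the
#' return to holding minus the final holding steady state.
#'
#' @param sweeps a voltage-clamp `sweep_set` (recorded current in the voltage
#'   slot, command potential in the current slot; amplitudes are the step
#'   potentials in mV).
#' @param blank_ms capacitive blanking window after each transition
#'   (default 10 ms).
#' @param inst_window_ms instantaneous-current window after blanking
#'   (default 10-30 ms post-transition, i.e. 20 ms long).
#' @param steady_ms steady-state window at the end of the step (default 50).
#' @return object of class `ih_step_result`: `step_potentials` (mV, sorted
#'   decreasing), `ih_amplitude`, `tail_amplitude` (pA), `holding` (mV),
#'   `complete` flag.
#' @export
ih_step_amplitudes <- function(sweeps, blank_ms = 10, inst_window_ms = 20,
                               steady_ms = 50) {
  stopifnot(inherits(sweeps, "sweep_set"))
  if (sweeps[[1]]$clamp_mode != "voltage")
    stop("ih_step_amplitudes requires voltage-clamp sweeps")
  ord <- order(sweep_amplitudes(sweeps), decreasing = TRUE)
  pots <- ih <- tail_amp <- numeric(length(ord))
  holding <- NA_real_
  for (j in seq_along(ord)) {
    sw <- sweeps[[ord[j]]]
    fs <- sw$sampling_rate
    i_rec <- sw$voltage       # recorded current, pA
    on <- floor(sw$stim_onset * fs); off <- floor(sw$stim_offset * fs)
    holding <- sw$current[1]
    pots[j] <- sw$amplitude
    b <- round(blank_ms / 1000 * fs)
    iw <- round(inst_window_ms / 1000 * fs)
    stw <- round(steady_ms / 1000 * fs)
    inst <- mean(i_rec[(on + b + 1):(on + b + iw)])
    steady <- mean(i_rec[(off - stw + 1):off])
    ih[j] <- abs(steady - inst)
    # tail on return to holding
    n <- length(i_rec)
    hold_ss <- mean(i_rec[(n - stw + 1):n])
    tail_seg <- i_rec[(off + b + 1):min(n, off + b + round(0.2 * fs))]
    pk <- tail_seg[which.max(abs(tail_seg - hold_ss))]
    tail_amp[j] <- abs(pk - hold_ss)
  }
  structure(list(step_potentials = pots, ih_amplitude = ih,
                 tail_amplitude = tail_amp, holding = holding,
                 complete = length(ord) >= 9),
            class = "ih_step_result")
}

#' Boltzmann activation curve of Ih from tail currents
#'
#' Tail amplitudes are normalized to the unit interval over the step range
#' and fitted with the Boltzmann sigmoid `A(V) = 1 / (1 + exp((V - V50)/k))`
#' by least squares, giving the half-maximal activation voltage `V50` and
#' slope `k` (activation grows with hyperpolarization for `k > 0`). Because
#' the step range need not saturate the channel at either end, the sigmoid is
#' fitted with a free scale and offset; `V50` and `k` are the parameters of
#' the underlying sigmoid, and the reported activation values are the
#' normalized tails.
#'
#' @param step_result an [ih_step_amplitudes()] result with >= 5 steps.
#' @return object of class `activation_curve`: `step_potentials`,
#'   `activation` (normalized), `V50` (mV), `k` (mV), `residual` (RMS),
#'   `converged`.
#' @export
activation_curve <- function(step_result) {
  stopifnot(inherits(step_result, "ih_step_result"))
  V <- step_result$step_potentials
  tails <- step_result$tail_amplitude
  ok <- is.finite(tails)
  if (sum(ok) < 5) stop("need at least 5 steps with defined tail amplitudes")
  V <- V[ok]; tails <- tails[ok]
  rng <- range(tails)
  if (diff(rng) < 1e-9)
    return(structure(list(step_potentials = V, activation = rep(NA_real_, length(V)),
                          V50 = NA_real_, k = NA_real_, residual = NA_real_,
                          converged = FALSE),
                     class = "activation_curve"))
  act <- (tails - rng[1]) / diff(rng)
  fit <- tryCatch(
    minpack.lm::nlsLM(act ~ c0 + c1 / (1 + exp((V - v50) / k)),
                      start = list(c0 = 0, c1 = 1, v50 = median(V), k = 8),
                      lower = c(-0.5, 0.1, min(V) - 60, 0.5),
                      upper = c(0.5, 2, max(V) + 60, 60)),
    error = function(e) NULL)
  if (is.null(fit))
    return(structure(list(step_potentials = V, activation = act,
                          V50 = NA_real_, k = NA_real_,
                          residual = sqrt(mean((act - mean(act))^2)),
                          converged = FALSE),
                     class = "activation_curve"))
  co <- coef(fit)
  structure(list(step_potentials = V, activation = act,
                 V50 = unname(co["v50"]), k = unname(co["k"]),
                 residual = sqrt(mean(stats::residuals(fit)^2)),
                 converged = TRUE),
            class = "activation_curve")
}

#' Exponential kinetics of an Ih relaxation
#'
#' Fits single- and double-exponential models to a current relaxation and
#' selects the double only when it improves the small-sample-corrected
#' information criterion by more than `aicc_margin`.
#'
#' @param trace current series (pA), the in-step relaxation segment after
#'   capacitive blanking.
#' @param fs sampling rate (Hz).
#' @param aicc_margin AICc improvement required to prefer the double
#'   exponential (default 2).
#' @return object of class `ih_kinetics`: `model` (`"single"`/`"double"`),
#'   `tau_fast`, `tau_slow` (ms; slow absent for single), `fractions`
#'   (amplitude fractions), `aicc` (both models).
#' @export
ih_kinetics <- function(trace, fs, aicc_margin = 2) {
  n <- length(trace)
  if (n < 10) stop("relaxation segment too short")
  if (sd(trace) < 1e-9) stop("flat trace: no relaxation to fit")
  t_ms <- (seq_len(n) - 1) / fs * 1000
  y <- trace
  a0 <- y[1] - y[n]
  c0 <- y[n]
  aicc <- function(fit, k) {
    rss <- sum(stats::residuals(fit)^2)
    ll_terms <- n * log(rss / n)
    ll_terms + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
  }
  f1 <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-t_ms / tau) + C0,
                      start = list(A = a0, tau = max(t_ms) / 3, C0 = c0),
                      lower = c(-Inf, 0.1, -Inf)),
    error = function(e) NULL)
  if (is.null(f1)) stop("single-exponential fit failed to converge")
  f2 <- tryCatch(
    minpack.lm::nlsLM(y ~ A1 * exp(-t_ms / tau1) + A2 * exp(-t_ms / tau2) + C0,
                      start = list(A1 = a0 / 2, tau1 = max(t_ms) / 10,
                                   A2 = a0 / 2, tau2 = max(t_ms) / 2, C0 = c0),
                      lower = c(-Inf, 0.1, -Inf, 0.1, -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  a1 <- aicc(f1, 4)
  a2 <- if (!is.null(f2)) aicc(f2, 6) else Inf
  if (a2 < a1 - aicc_margin) {
    co <- coef(f2)
    taus <- sort(c(unname(co["tau1"]), unname(co["tau2"])))
    amps <- abs(c(unname(co["A1"]), unname(co["A2"])))
    if (unname(co["tau1"]) > unname(co["tau2"])) amps <- rev(amps)
    structure(list(model = "double", tau_fast = taus[1], tau_slow = taus[2],
                   fractions = amps / sum(amps), aicc = c(single = a1, double = a2)),
              class = "ih_kinetics")
  } else {
    structure(list(model = "single", tau_fast = unname(coef(f1)["tau"]),
                   tau_slow = NA_real_, fractions = 1,
                   aicc = c(single = a1, double = a2)),
              class = "ih_kinetics")
  }
}
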
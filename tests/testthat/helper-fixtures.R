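# Shared fixtures, built lazily and cached for the whole run.
.fx <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (!exists(name, envir = .fx)) assign(name, build(), envir = .fx)
  get(name, envir = .fx)
}

# a passive RC cell (R = 100 MOhm, tau = 15 ms) probed with the step family
fx_rc_steps <- function() fx("rc_steps", function() {
  p <- model_params(C_pF = 150, gL_nS = 10, EL_mV = -65, gh_nS = 0,
                    spike = "none")
  cmds <- make_current_steps(-200, -50, 50)
  sweep_set(lapply(seq_len(length(cmds)), function(k) {
    cmd <- cmds[[k]]
    simulate_neuron(p, cmd$current, 1e4, stim_onset = cmd$stim_onset,
                    stim_offset = cmd$stim_offset, protocol_id = "steps",
                    amplitude = cmd$amplitude)$sweep
  }))
})

# subthreshold ZAP response of the same RC membrane (with settle flanks)
fx_rc_zap <- function() fx("rc_zap", function() {
  p <- model_params(C_pF = 200, gL_nS = 10, EL_mV = -65, gh_nS = 0,
                    spike = "none")
  zp <- zap_protocol(amplitude = 20)
  fs <- zp$sampling_rate
  stim <- c(rep(0, round(0.2 * fs)), make_zap(zp)$current,
            rep(0, round(0.3 * fs)))
  trials <- sweep_set(lapply(1:3, function(k)
    simulate_neuron(p, stim, fs, oversample = 2, stim_onset = 0.2,
                    stim_offset = 0.2 + zp$T_s, protocol_id = "zap")$sweep))
  list(trials = trials, zap = zp, R = 100, C_pF = 200)
})

# step-family simulations of the default archetypes (light noise, one cell
# each), reused by spike/classification tests
fx_archetype_steps <- function() fx("arch_steps", function() {
  lapply(default_archetypes(), function(at) {
    p <- at$params; p$noise_sd_pA <- 10; p$seed <- 42L
    simulate_cell(p, protocols = "steps", seed = 42L)$steps
  })
})

# a synthetic voltage sweep with stereotyped triangular APs at given times
make_spiky_sweep <- function(spike_times_s, amplitude, fs = 1e4,
                             pre = 0.1, dur = 0.6, post = 0.3,
                             v_rest = -70, peak = 30,
                             rise_ms = 0.5, fall_ms = 0.5) {
  n <- round((pre + dur + post) * fs)
  v <- rep(v_rest, n)
  nr <- round(rise_ms / 1000 * fs); nf <- round(fall_ms / 1000 * fs)
  for (ts in spike_times_s) {
    i0 <- round(ts * fs) + 1L
    up <- seq(v_rest, peak, length.out = nr + 1)
    dn <- seq(peak, v_rest, length.out = nf + 1)[-1]
    seg <- c(up, dn)
    idx <- (i0 - nr):(i0 - nr + length(seg) - 1)
    ok <- idx >= 1 & idx <= n
    v[idx[ok]] <- seg[ok]
  }
  i <- c(rep(0, round(pre * fs)), rep(amplitude, round(dur * fs)),
         rep(0, round(post * fs)))
  sweep_record(v, i, fs, stim_onset = pre, stim_offset = pre + dur,
               amplitude = amplitude)
}
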
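test_that("identical voltage and current give unit impedance across the band", {
  zp <- zap_protocol(amplitude = 20)
  sig <- make_zap(zp)$current - 50   # below 0 mV so no spikes are detected
  sw <- sweep_record(sig, sig, zp$sampling_rate, stim_onset = 0,
                     stim_offset = zp$T_s, amplitude = 20)
  prof <- impedance_profile(sweep_set(list(sw)), zp)
  # |Z| = 1 mV/pA = 1000 MOhm everywhere; normalization is exactly 1
  expect_lt(max(abs(prof$z_mag - 1000)) / 1000, 1e-9)
  expect_equal(max(prof$z_mag_norm), 1)
})

test_that("the passive RC membrane matches its closed form and is non-resonant", {
  fxd <- fx_rc_zap()
  prof <- impedance_profile(fxd$trials, fxd$zap)
  closed <- fxd$R / sqrt(1 + (2 * pi * prof$freqs * fxd$R * 1e6 *
                                fxd$C_pF * 1e-12)^2)
  expect_lt(max(abs(prof$z_mag - closed) / closed), 0.02)
  expect_false(prof$resonant)
  # monotone decreasing magnitude (smoothed)
  expect_true(all(diff(prof$z_mag) < 1e-6))
  # cutoff near the analytic RC corner sqrt(2 (2 pi R C)^-2 ...) ~ 8.1 Hz
  expect_equal(prof$f3db, 8.1, tolerance = 0.05)
})

test_that("normalized impedance is invariant to stimulus amplitude", {
  p <- model_params(C_pF = 200, gL_nS = 10, EL_mV = -65, gh_nS = 0,
                    spike = "none")
  prof_at <- function(amp) {
    zp <- zap_protocol(amplitude = amp)
    fs <- zp$sampling_rate
    stim <- c(rep(0, 2000), make_zap(zp)$current, rep(0, 3000))
    tr <- sweep_set(list(simulate_neuron(p, stim, fs, stim_onset = 0.2,
                                         stim_offset = 20.2)$sweep))
    impedance_profile(tr, zp)
  }
  a <- prof_at(10); b <- prof_at(20)
  expect_lt(max(abs(a$z_mag_norm - b$z_mag_norm)), 1e-6)
})

test_that("spiking trials are rejected and an all-spiking set errors", {
  zp <- zap_protocol(amplitude = 20)
  fs <- zp$sampling_rate
  good <- sweep_record(make_zap(zp)$current - 50, make_zap(zp)$current, fs,
                       stim_offset = zp$T_s)
  t <- (seq_len(200000) - 1) / fs
  spiky <- sweep_record(10 * sin(2 * pi * 2 * t), make_zap(zp)$current, fs,
                        stim_offset = zp$T_s)
  expect_warning(prof <- impedance_profile(sweep_set(list(good, spiky)), zp),
                 "rejected")
  expect_equal(prof$n_trials_averaged, 1L)
  expect_error(suppressWarnings(
    impedance_profile(sweep_set(list(spiky)), zp)), "spikes")
})

test_that("spike probability densities pool per-spike chirp frequencies", {
  zp <- zap_protocol(amplitude = 100)
  fs <- zp$sampling_rate
  # chirp from 1 to 20 Hz over 20 s: frequency f occurs at t = (f-1)*20/19
  t_of_f <- function(f) (f - 1) * zp$T_s / (zp$f1 - zp$f0)
  mk <- function(ff) {
    v <- rep(-70, 200000)
    for (f in ff) v[round(t_of_f(f) * fs) + 1] <- 10   # one-sample spikes
    sweep_record(v, make_zap(zp)$current, fs, stim_offset = zp$T_s)
  }
  d <- spike_probability_density(
    sweep_set(list(mk(c(4.2, 4.6)), mk(c(4.4, 4.9)))), zp, bin_hz = 1)
  expect_equal(sum(d$probability), 1)
  expect_equal(d$n_spikes_total, 4L)
  bin <- findInterval(4.5, d$bin_edges)
  expect_equal(d$probability[bin], 1)
  # a single spike concentrates all mass in one bin
  d1 <- spike_probability_density(sweep_set(list(mk(7.3))), zp, bin_hz = 1)
  expect_equal(max(d1$probability), 1)
  expect_equal(d1$n_spikes_total, 1L)
  # zero spikes: flagged empty
  d0 <- spike_probability_density(sweep_set(list(mk(numeric(0)))), zp)
  expect_true(d0$empty)
})

test_that("density comparison runs the KS test on retained samples", {
  mkd <- function(x) structure(list(spike_freqs = x),
                               class = "spike_frequency_density")
  same <- compare_densities(mkd(c(1, 2, 3, 4)), mkd(c(1, 2, 3, 4)))
  expect_equal(same$ks_statistic, 0)
  expect_equal(same$p_value, 1)
  far <- compare_densities(mkd(1:10), mkd(101:110))
  expect_equal(far$ks_statistic, 1)
  # band restriction filters the samples; emptied bands error
  bandres <- compare_densities(mkd(c(5, 13, 14)), mkd(c(6, 13.5, 15)),
                               band = c(12, Inf))
  expect_equal(bandres$ks_statistic,
               suppressWarnings(stats::ks.test(c(13, 14),
                                               c(13.5, 15))$statistic[[1]]))
  expect_error(compare_densities(mkd(c(1, 2)), mkd(c(3, 4)), band = c(50, 60)),
               "band")
})
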
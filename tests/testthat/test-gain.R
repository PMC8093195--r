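test_that("the rate signal satisfies the delta-function contract", {
  r <- firing_rate_signal(c(99 / 1e4), 1000, 1e4)
  expect_equal(r$values[100], 1e4)
  expect_equal(sum(r$values != 0), 1L)
  # integral equals the spike count for any spike set
  set.seed(4)
  tt <- sort(sample(0:9999, 25)) / 1e4
  rk <- firing_rate_signal(tt, 10000, 1e4)
  expect_equal(sum(rk$values) / 1e4, 25)
  expect_equal(sum(firing_rate_signal(numeric(0), 100, 1e4)$values), 0)
  expect_error(firing_rate_signal(c(0.01, 0.01), 1000, 1e4), "duplicate")
  expect_error(firing_rate_signal(c(0.5), 1000, 1e4), "outside")
})

test_that("correlation estimates obey identity, variance and delay checks", {
  fs <- 1e4
  s <- make_frozen_filtered_noise(noise_protocol(duration = 10, noise_sd = 1,
                                                 seed = 5))
  cp <- correlations(s, s, fs, max_lag = 0.5)
  expect_equal(cp$c_sr, cp$c_ss, tolerance = 1e-12)
  expect_equal(cp$tau_delay, 0)
  # white unit-variance noise: c_ss(0) ~ 1 within 3 SE over 100 s
  set.seed(6)
  w <- rnorm(100 * fs)
  cpw <- correlations(w, w, fs, max_lag = 0.01)
  se <- sqrt(2 / (100 * fs))
  expect_lt(abs(cpw$c_ss[cpw$lags == 0] - 1), 3 * se)
  # a response delayed by d shifts the cross-correlation peak to d
  d <- round(0.005 * fs)
  r <- c(rep(0, d), s[1:(length(s) - d)])
  cpd <- correlations(s, r, fs, max_lag = 0.5)
  expect_lt(abs(cpd$tau_delay - 0.005), 1e-3)
  expect_error(correlations(rep(1, 1000), rnorm(1000), fs, 0.01), "constant")
  expect_error(correlations(s, s, fs, max_lag = 6), "max_lag")
})

test_that("gain is exactly one with zero phase for identical signals", {
  fs <- 1e4
  s <- make_frozen_filtered_noise(noise_protocol(duration = 10, noise_sd = 1,
                                                 seed = 7))
  gp <- frequency_dependent_gain(correlations(s, s, fs, max_lag = 1))
  expect_equal(length(gp$freqs), 491L)
  expect_lt(max(abs(gp$gain - 1)), 1e-6)
  expect_lt(max(abs(gp$phase_raw)), 1e-6)
  expect_error(frequency_dependent_gain(correlations(s, s, fs, 1),
                                        freqs = c(-1, 5)), "> 0")
})

test_that("a pure transmission delay is removed by the phase correction", {
  fs <- 1e4
  s <- make_frozen_filtered_noise(noise_protocol(duration = 10, noise_sd = 1,
                                                 seed = 8))
  d <- round(0.005 * fs)
  r <- c(rep(0, d), s[1:(length(s) - d)])
  gp <- frequency_dependent_gain(correlations(s, r, fs, max_lag = 1))
  expect_equal(gp$tau_delay, 0.005)
  # raw phase tracks -2 pi f d; corrected phase collapses to zero
  mid <- which(abs(gp$freqs - 10) < 0.01)
  expect_equal(gp$phase_raw[mid], -2 * pi * 10 * 0.005, tolerance = 0.05)
  expect_lt(max(abs(gp$phase_corrected)), 0.05)
})

test_that("gain scales inversely with the stimulus amplitude", {
  fs <- 1e4
  s <- make_frozen_filtered_noise(noise_protocol(duration = 5, noise_sd = 1,
                                                 seed = 9))
  r <- c(0, s[-length(s)])
  g1 <- frequency_dependent_gain(correlations(s, r, fs, 1),
                                 freqs = c(5, 20, 60))
  g2 <- frequency_dependent_gain(correlations(3 * s, r, fs, 1),
                                 freqs = c(5, 20, 60))
  expect_equal(g2$gain, g1$gain / 3, tolerance = 1e-9)
  # common rescaling of both leaves the gain unchanged
  g3 <- frequency_dependent_gain(correlations(3 * s, 3 * r, fs, 1),
                                 freqs = c(5, 20, 60))
  expect_equal(g3$gain, g1$gain, tolerance = 1e-9)
})

test_that("spike-triggered averages recover constructed structure", {
  fs <- 1e4
  set.seed(10)
  s <- rnorm(20 * fs)
  # independent spikes: STA flat within noise
  tt <- sort(sample(seq(3000, length(s) - 1), 300)) / fs
  sta <- spike_triggered_average(s, tt, window = 0.2, fs = fs)
  expect_equal(length(sta$lags), 2001L)
  expect_lt(max(abs(sta$sta)), 4 / sqrt(300))
  # spikes placed at the largest stimulus values: peak at lag zero
  top <- order(s, decreasing = TRUE)
  top <- top[top > 2000][1:100]
  sta2 <- spike_triggered_average(s, (top - 1) / fs, window = 0.2, fs = fs)
  expect_equal(which.max(sta2$sta), 2001L)
  expect_equal(max(sta2$sta), mean(s[top]) - mean(s), tolerance = 0.01)
  # early spikes are skipped and reported
  sta3 <- spike_triggered_average(s, c(0.05, 0.5), window = 0.2, fs = fs)
  expect_equal(sta3$n_skipped, 1L)
  expect_error(spike_triggered_average(s, c(0.05), window = 0.2, fs = fs),
               "usable")
})

test_that("groupwise comparison flags only real differences at 491 points", {
  f <- seq(2, 100, by = 0.2)
  mkprof <- function(g) structure(list(freqs = f, gain = g, mean_rate = 10),
                                  class = "gain_profile")
  set.seed(11)
  base <- lapply(1:8, function(i) mkprof(1 + runif(length(f))))
  # identical groups: nothing significant
  same <- groupwise_gain_comparison(base, base)
  expect_equal(nrow(same), 491L)
  expect_equal(sum(same$significant), 0L)
  # doubled gains, distinct values: the exact two-sided rank-sum p for
  # complete separation of 8 vs 8 is 2 * 8! * 8! / 16!
  doubled <- lapply(base, function(p) mkprof(2 * p$gain))
  cmp <- groupwise_gain_comparison(base, doubled)
  p_exact <- 2 * prod(factorial(c(8, 8))) / factorial(16)
  expect_equal(max(abs(cmp$p_value - p_exact)), 0, tolerance = 1e-12)
  expect_equal(sum(cmp$significant), 491L)
  # cells at or below the 5 Hz rate floor are excluded
  slow <- lapply(base, function(p) { p$mean_rate <- 3; p })
  expect_error(groupwise_gain_comparison(slow, doubled), "rate threshold")
  # mismatched grids are rejected
  off <- base
  off[[1]]$freqs <- off[[1]]$freqs + 0.1
  expect_error(groupwise_gain_comparison(off, doubled), "grid")
})
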
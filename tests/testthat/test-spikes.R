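test_that("overshoot detection counts suprathreshold peaks only", {
  fs <- 1e4
  t <- (0:9999) / fs
  sine <- sweep_record(10 * sin(2 * pi * 5 * t), rep(0, 1e4), fs)
  expect_equal(length(detect_spikes(sine, "overshoot")$spike_times), 5L)
  sub <- sweep_record(-20 + 10 * sin(2 * pi * 5 * t), rep(0, 1e4), fs)
  expect_equal(length(detect_spikes(sub, "overshoot")$spike_times), 0L)
  vc <- sweep_record(rep(0, 100), rep(-60, 100), fs, clamp_mode = "voltage")
  expect_error(detect_spikes(vc), "current-clamp")
})

test_that("both detection modes recover ground-truth pasted spike times", {
  p <- default_archetypes()[["L5"]]$params
  p$noise_sd_pA <- 10; p$seed <- 99L
  cmd <- make_current_steps(400, 400, 50)[[1]]
  truth <- simulate_neuron(p, cmd$current, 1e4, stim_onset = 0.1,
                           stim_offset = 0.7, amplitude = 400)
  expect_gt(length(truth$peak_times), 3)
  for (mode in c("overshoot", "dvdt")) {
    det <- detect_spikes(truth$sweep, mode)$spike_times
    expect_equal(length(det), length(truth$peak_times))
    expect_lt(max(abs(det - truth$peak_times)), 1.5 / 1e4)
  }
})

test_that("AP waveform geometry is measured exactly on triangular spikes", {
  # symmetric triangle: -40 to +40 mV in 1 ms up, 1 ms down
  sym <- make_spiky_sweep(0.3, amplitude = 200, v_rest = -40, peak = 40,
                          rise_ms = 1, fall_ms = 1)
  ap <- ap_waveform_features(sweep_set(list(sym)))
  expect_equal(ap$amplitude, 80, tolerance = 0.02)
  expect_equal(ap$half_width, 1.0, tolerance = 0.03)
  expect_equal(ap$upstroke_downstroke_ratio, 1.0, tolerance = 0.01)
  expect_equal(ap$latency, 200, tolerance = 2)  # spike at 0.3 s, onset 0.1 s
  # asymmetric triangle: rise 0.5 ms, fall 1 ms
  asym <- make_spiky_sweep(0.3, amplitude = 200, v_rest = -40, peak = 40,
                           rise_ms = 0.5, fall_ms = 1)
  ap2 <- ap_waveform_features(sweep_set(list(asym)))
  expect_equal(ap2$upstroke_downstroke_ratio, 2.0, tolerance = 0.02)
  expect_error(ap_waveform_features(
    sweep_set(list(make_spiky_sweep(numeric(0), 200)))), "suprathreshold")
})

test_that("threshold from the simulator is near the spike take-off voltage", {
  arch <- fx_archetype_steps()
  ap <- ap_waveform_features(arch[["L2&3"]])
  p <- default_archetypes()[["L2&3"]]$params
  v_takeoff <- p$VT_mV + 5 * p$DeltaT_mV   # paste onset of the model
  expect_lt(abs(ap$threshold - v_takeoff), 1)
})

test_that("train features reproduce constructed rates and intervals", {
  mk <- function(amp, n_spikes) {
    tt <- if (n_spikes > 0) seq(0.15, 0.65, length.out = n_spikes) else numeric(0)
    make_spiky_sweep(tt, amplitude = amp)
  }
  # rates 0, 5, 10 Hz at 100, 150, 200 pA over the 0.6 s step
  set <- sweep_set(list(mk(100, 0), mk(150, 3), mk(200, 6)))
  tf <- train_features(set)
  expect_equal(tf$rheobase, 150)
  expect_equal(tf$fi_slope, 0.1, tolerance = 1e-6)
  # hero window empty (only +50 pA available beyond rheobase): fallback flag
  expect_equal(tf$hero_amplitude, 200)
  # equal hero ISIs: adaptation 0, CV 0
  iso <- sweep_set(list(mk(100, 0), mk(150, 2),
                        make_spiky_sweep(seq(0.2, 0.5, by = 0.05), 200)))
  tfi <- train_features(iso)
  expect_equal(tfi$adaptation_index, 0, tolerance = 1e-9)
  expect_equal(tfi$isi_cv, 0, tolerance = 1e-9)
  expect_equal(tfi$isi_mean, 50, tolerance = 0.2)
  # ISIs of 10 then 20 ms give the textbook adaptation index 1/3
  ad <- sweep_set(list(mk(100, 0), mk(150, 2),
                       make_spiky_sweep(c(0.2, 0.21, 0.23), 200)))
  expect_equal(train_features(ad)$adaptation_index, 1 / 3, tolerance = 1e-6)
  # no spiking sweep: everything undefined but flagged, not an error
  none <- train_features(sweep_set(list(mk(100, 0), mk(150, 0))))
  expect_false(none$defined)
  expect_true(is.na(none$rheobase))
})

test_that("classification rules match their stated thresholds", {
  ap_int <- structure(list(half_width = 0.8, ahp_amplitude = 12,
                           threshold = -40), class = "ap_features")
  ap_pyr <- structure(list(half_width = 1.8, ahp_amplitude = 8,
                           threshold = -40), class = "ap_features")
  tr <- function(isi_rheo, isi_50 = NA, max_rate = 20)
    structure(list(defined = TRUE, isi_first_rheobase = isi_rheo,
                   isi_first_rheo50 = isi_50, max_rate = max_rate),
              class = "train_features")
  # first rheobase ISI of 12 ms is 83 Hz: bursting at rheobase
  expect_equal(classify_cell(ap_pyr, tr(12))$bursting, "at_rheobase")
  expect_equal(classify_cell(ap_pyr, tr(20, 10))$bursting,
               "at_rheobase_plus_50")
  expect_equal(classify_cell(ap_pyr, tr(20, 20))$bursting, "none")
  expect_equal(classify_cell(ap_int, tr(20, max_rate = 90))$cell_class,
               "putative_interneuron")
  expect_equal(classify_cell(ap_pyr, tr(20, max_rate = 90))$cell_class,
               "pyramidal")
  # narrow AP but weak AHP is not an interneuron
  ap_mid <- structure(list(half_width = 0.8, ahp_amplitude = 8),
                      class = "ap_features")
  expect_equal(classify_cell(ap_mid, tr(20, max_rate = 90))$cell_class,
               "pyramidal")
  # missing inputs: unclassified flag
  expect_false(classify_cell(ap_pyr, structure(list(defined = FALSE),
                                               class = "train_features"))$classified)
})
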
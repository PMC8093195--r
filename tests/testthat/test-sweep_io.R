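test_that("write/read round-trips a sweep set with metadata intact", {
  fs <- 1e4
  s1 <- sweep_record(rnorm(500, -65), c(rep(0, 100), rep(-50, 300), rep(0, 100)),
                     fs, cell_id = "c1", protocol_id = "steps",
                     layer_label = "L5", stim_onset = 0.01, stim_offset = 0.04,
                     amplitude = -50)
  s2 <- sweep_record(rnorm(500, -70), rep(0, 500), fs, cell_id = "c1",
                     protocol_id = "steps", layer_label = "L5", amplitude = 0)
  set <- sweep_set(list(s1, s2))
  path <- file.path(withr::local_tempdir(), "c1_steps.csv")
  write_sweep_table(set, path)
  back <- read_sweep_table(path)
  expect_equal(length(back), 2L)
  for (k in 1:2) {
    expect_equal(back[[k]]$voltage, set[[k]]$voltage, tolerance = 1e-8)
    expect_equal(back[[k]]$current, set[[k]]$current, tolerance = 1e-8)
    expect_identical(back[[k]]$cell_id, "c1")
    expect_identical(back[[k]]$layer_label, "L5")
    expect_equal(back[[k]]$sampling_rate, fs)
    expect_equal(back[[k]]$stim_onset, set[[k]]$stim_onset)
    expect_equal(back[[k]]$amplitude, set[[k]]$amplitude)
  }
  # empty set: a valid header-only manifest
  p2 <- file.path(withr::local_tempdir(), "empty.csv")
  write_sweep_table(sweep_set(list()), p2)
  expect_equal(length(read_sweep_table(p2)), 0L)
})

test_that("invariant violations are rejected with informative errors", {
  expect_error(sweep_record(1:10, 1:9, 1e4), "equal length")
  expect_error(sweep_record(1, 1, 1e4), "at least 2")
  expect_error(sweep_record(1:10, 1:10, -5), "sampling_rate")
  expect_error(sweep_record(1:10, 1:10, 1e4, stim_onset = 0.5,
                            stim_offset = 0.2), "epoch")
  a <- sweep_record(1:10, 1:10, 1e4, cell_id = "a")
  b <- sweep_record(1:10, 1:10, 1e4, cell_id = "b")
  expect_error(sweep_set(list(a, b)), "one cell_id")
})

test_that("malformed sweep files produce format errors naming the problem", {
  dir <- withr::local_tempdir()
  set <- sweep_set(list(sweep_record(c(-65, -65, -65), c(0, 0, 0), 1e4)))
  man <- file.path(dir, "m.csv")
  write_sweep_table(set, man)
  swfile <- file.path(dir, "m_001.sweep")
  lines <- readLines(swfile)
  # voltage column shorter than current column on one line
  lines[length(lines)] <- "0.5"
  writeLines(lines, swfile)
  expect_error(read_sweep_table(man), "column")
  # missing voltage value on one line
  lines[length(lines)] <- "\t0.5"
  writeLines(lines, swfile)
  expect_error(read_sweep_table(man), "voltage_mV")
  # missing sampling rate header
  writeLines(lines[!grepl("sampling_rate_hz", lines)][1:(length(lines) - 1)],
             swfile)
  expect_error(read_sweep_table(man), "sampling_rate_hz")
})

test_that("stimulus epochs are detected with accurate amplitude", {
  fs <- 1e4
  i <- c(rep(0, 1000), rep(-400, 6000), rep(0, 3000))
  sw <- sweep_record(rep(-65, length(i)), i, fs)
  ep <- detect_stimulus_epoch(sw)
  expect_true(ep$detected)
  expect_equal(ep$stim_onset, 0.1)
  expect_equal(ep$stim_offset, 0.7)
  expect_equal(ep$amplitude, -400)
  # flat zero current: flagged empty epoch
  flat <- detect_stimulus_epoch(sweep_record(rep(-65, 100), rep(0, 100), fs))
  expect_false(flat$detected)
  expect_equal(flat$amplitude, 0)
  # amplitude accuracy under additive noise, sigma = 5 pA, 100 seeds
  errs <- vapply(1:100, function(seed) {
    set.seed(seed)
    swn <- sweep_record(rep(-65, length(i)), i + rnorm(length(i), 0, 5), fs)
    detect_stimulus_epoch(swn, threshold_pa = 50)$amplitude - (-400)
  }, numeric(1))
  expect_lt(max(abs(errs)), 2)
})

test_that("Henderson junction potential obeys symmetry and scale invariance", {
  pip <- solution_kgluconate_internal()
  bath <- solution_acsf()
  # identical solutions: zero
  expect_equal(henderson_junction_potential(bath, bath), 0)
  # antisymmetry
  expect_equal(henderson_junction_potential(pip, bath),
               -henderson_junction_potential(bath, pip), tolerance = 1e-10)
  # common concentration scaling leaves the potential unchanged
  scale_sol <- function(sol, f) {
    sol$conc_mM <- sol$conc_mM * f
    sol
  }
  expect_equal(henderson_junction_potential(scale_sol(pip, 2.5),
                                            scale_sol(bath, 2.5)),
               henderson_junction_potential(pip, bath), tolerance = 1e-10)
})

test_that("Henderson matches an independent scripted evaluation on KCl|NaCl", {
  # frozen from a standalone one-off evaluation of the Henderson formula
  # with the same mobility table (relative u: K 1.0, Na 0.682, Cl 1.0388)
  # at 25 C: 150 mM KCl pipette against 150 mM NaCl bath
  kcl <- solution_spec(c("K", "Cl"), c(150, 150), temperature_c = 25)
  nacl <- solution_spec(c("Na", "Cl"), c(150, 150), temperature_c = 25)
  expect_equal(henderson_junction_potential(kcl, nacl), -4.35674333,
               tolerance = 1e-6)
})

test_that("degenerate solutions error and neutral species warn", {
  neutral <- solution_spec("glucose", 10, valence = 0L, mobility = 0)
  expect_error(henderson_junction_potential(neutral, neutral), "neutral")
  expect_warning(solution_spec("glucose", 10, valence = 0L, mobility = 0.5),
                 "neutral")
})
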
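test_that("feature vectors map inputs one-to-one with a completeness mask", {
  pf <- structure(list(rmp = -65, input_resistance = 100, tau_m = 15,
                       sag_ratio = 0.2, sag_amplitude = 2,
                       rebound_amplitude = 1, rebound_spike_count = 0L,
                       sag_measured_at = -400), class = "passive_features")
  ap <- structure(list(threshold = -42, amplitude = 75, half_width = 1.4,
                       upstroke_downstroke_ratio = 3, ahp_amplitude = 9,
                       latency = 120, peak = 33), class = "ap_features")
  tr <- structure(list(rheobase = 150, fi_slope = 0.1, avg_rate_hero = 12,
                       defined = TRUE), class = "train_features")
  fv <- assemble_feature_vector(pf, ap, tr)
  expect_length(fv$values, 14L)
  expect_true(all(fv$mask))
  expect_equal(fv$values[["ap_threshold"]], -42)
  expect_equal(fv$values[["latency"]], 120)
  # no suprathreshold data: the nine suprathreshold fields are masked
  sub_only <- assemble_feature_vector(pf, NULL, NULL)
  expect_equal(sum(!sub_only$mask), 9L)
  expect_true(all(sub_only$mask[c("rmp", "input_resistance", "tau_m",
                                  "sag_ratio", "sag_amplitude")]))
  # table round-trip preserves the values
  tab <- feature_table(list(c1 = fv, c2 = sub_only))
  expect_equal(unlist(tab[1, names(fv$values)]), fv$values)
  expect_equal(tab$n_missing, c(0L, 9L))
})

test_that("cohort embedding is deterministic and separates archetypes", {
  set.seed(30)
  n <- 20
  mkcell <- function(rin, rheo) {
    v <- c(rmp = rnorm(1, -65), input_resistance = rin, tau_m = rnorm(1, 15),
           sag_ratio = runif(1, 0.1, 0.3), sag_amplitude = rnorm(1, 2, 0.2),
           ap_threshold = rnorm(1, -42), ap_amplitude = rnorm(1, 75),
           ap_half_width = rnorm(1, 1.4, 0.1),
           upstroke_downstroke_ratio = rnorm(1, 3, 0.2),
           ahp_amplitude = rnorm(1, 9), rheobase = rheo,
           latency = rnorm(1, 100, 10), fi_slope = rnorm(1, 0.1, 0.01),
           avg_rate_hero = rnorm(1, 12, 1))
    structure(list(values = v, mask = !is.na(v)), class = "feature_vector")
  }
  fvs <- c(lapply(1:n, function(i) mkcell(rnorm(1, 60, 5), rnorm(1, 300, 20))),
           lapply(1:n, function(i) mkcell(rnorm(1, 160, 5), rnorm(1, 100, 20))))
  names(fvs) <- sprintf("c%02d", seq_along(fvs))
  tab <- feature_table(fvs)
  tab$group <- rep(c("A", "B"), each = n)
  e1 <- embed_cohort(tab, seed = 3L)
  e2 <- embed_cohort(tab, seed = 3L)
  expect_identical(e1$coords, e2$coords)
  expect_equal(nrow(e1$coords), 2 * n)
  # archetypes differing in input resistance and rheobase separate:
  # positive mean silhouette of the generating labels in embedded space
  xy <- as.matrix(e1$coords[, c("umap1", "umap2")])
  d <- as.matrix(dist(xy))
  sil <- vapply(seq_len(nrow(xy)), function(i) {
    own <- tab$group == tab$group[i]
    a <- mean(d[i, own & seq_len(nrow(xy)) != i])
    b <- mean(d[i, !own])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0)
  # incomplete cells beyond the threshold are dropped with a report
  tab2 <- tab
  tab2[1, c("rmp", "tau_m", "sag_ratio")] <- NA
  e3 <- embed_cohort(tab2, seed = 3L)
  expect_equal(e3$dropped, tab2$cell_id[1])
  expect_error(embed_cohort(tab[1:5, ], seed = 1L), "at least 10")
})

test_that("rank-based group statistics handle paired and independent designs", {
  x <- c(3.2, 4.1, 5.0, 2.8, 3.9)
  # paired with identical samples: no nonzero differences, p = 1
  same <- group_stats(x, x, design = "paired")
  expect_equal(same$p_value, 1)
  # independent, completely separated n = 8 vs 8: exact combinatorial p
  a <- 1:8; b <- 101:108
  sep <- group_stats(a, b, design = "independent")
  expect_equal(sep$p_value, 2 * prod(factorial(c(8, 8))) / factorial(16),
               tolerance = 1e-12)
  expect_error(group_stats(1:4, 1:5, design = "paired"), "equal-length")
})

test_that("rank-sum and KS type-I error rates are calibrated at the 5% level", {
  set.seed(31)
  n_rep <- 400
  rej_rs <- rej_ks <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    x <- rnorm(30); y <- rnorm(30)
    rej_rs[i] <- group_stats(x, y)$p_value < 0.05
    a <- structure(list(spike_freqs = runif(200, 1, 20)),
                   class = "spike_frequency_density")
    b <- structure(list(spike_freqs = runif(200, 1, 20)),
                   class = "spike_frequency_density")
    rej_ks[i] <- compare_densities(a, b)$p_value < 0.05
  }
  expect_lt(abs(mean(rej_rs) - 0.05), 0.03)
  expect_lt(abs(mean(rej_ks) - 0.05), 0.03)
})
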
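# mEPSC detection/kinetics and rectification analysis.

test_that("detection finds nothing on flat traces and one clear event", {
  flat <- ephys_trace(rep(0, 40000), 20000)
  expect_identical(nrow(detect_minis(flat)), 0L)
  sim <- gen_mepsc_trace(2, 0, amp_median_pA = 20, amp_sigma = 0,
                         noise_sd_pA = 2, onset_times = 1, seed = 5)
  det <- detect_minis(sim$trace)
  expect_identical(nrow(det), 1L)
  expect_lt(abs(det$onset_s - 1), 0.002)
  expect_error(detect_minis(ephys_trace(rep(0, 1000), 20000)), "1 s")
  expect_error(detect_minis(flat, lp_cutoff_hz = 15000), "twice")
})

test_that("detection and kinetics are invariant to a DC offset", {
  sim <- gen_mepsc_trace(5, 2, noise_sd_pA = 2, seed = 31)
  shifted <- sim$trace
  shifted$samples <- shifted$samples - 150
  d1 <- detect_minis(sim$trace)
  d2 <- detect_minis(shifted)
  expect_equal(d1$onset_s, d2$onset_s)
  k1 <- event_kinetics(sim$trace, d1$onset_s[1])
  k2 <- event_kinetics(shifted, d2$onset_s[1])
  expect_equal(k1$peak_amplitude_pA, k2$peak_amplitude_pA, tolerance = 1e-9)
  expect_equal(k1$charge_pA_ms, k2$charge_pA_ms, tolerance = 1e-9)
})

test_that("noiseless kinetics round-trip the generator parameters", {
  sim <- gen_mepsc_trace(2, 0, amp_median_pA = 20, amp_sigma = 0,
                         noise_sd_pA = 0, rise_tau_ms = 0.5,
                         decay_tau_ms = 5, onset_times = 0.5)
  k <- event_kinetics(sim$trace, 0.5)
  expect_equal(k$peak_amplitude_pA, 20, tolerance = 0.5)
  expect_equal(k$decay_tau_ms, 5, tolerance = 5 * 0.02)
  expect_gt(k$rise_time_10_90_ms, 0)
  # amplitude and charge scale linearly; time constants do not change
  x2 <- sim$trace; x2$samples <- 2 * x2$samples
  k2 <- event_kinetics(x2, 0.5)
  expect_equal(k2$peak_amplitude_pA, 2 * k$peak_amplitude_pA)
  expect_equal(k2$charge_pA_ms, 2 * k$charge_pA_ms)
  expect_equal(k2$decay_tau_ms, k$decay_tau_ms, tolerance = 1e-6)
  expect_equal(k2$rise_time_10_90_ms, k$rise_time_10_90_ms,
               tolerance = 1e-9)
})

test_that("a rectangular pulse carries its analytic charge", {
  fs <- 20000
  x <- rep(0, 2 * fs)
  on <- fs + 1
  x[on:(on + 0.010 * fs - 1)] <- -10  # 10 pA for 10 ms
  k <- event_kinetics(ephys_trace(x, fs), 1)
  expect_equal(k$charge_pA_ms, 100, tolerance = 1)
  expect_equal(k$peak_amplitude_pA, 10)
})

test_that("ensemble averaging reproduces templates and mixes linearly", {
  sim <- gen_mepsc_trace(10, 0, amp_median_pA = 20, amp_sigma = 0,
                         noise_sd_pA = 0, onset_times = c(1, 3, 5, 7))
  avg <- ensemble_average(sim$trace, sim$events$onset_s)
  single <- ensemble_average(sim$trace, sim$events$onset_s[1])
  expect_equal(avg$mean_pA, single$mean_pA, tolerance = 1e-9)
  expect_identical(avg$n, 4L)
  mix <- gen_mepsc_trace(10, 0, noise_sd_pA = 0, onset_times = c(1, 5))
  mix$trace$samples <- with(gen_mepsc_trace(10, 0, amp_median_pA = 10,
                                            amp_sigma = 0, noise_sd_pA = 0,
                                            onset_times = 1),
                            trace$samples) +
    with(gen_mepsc_trace(10, 0, amp_median_pA = 30, amp_sigma = 0,
                         noise_sd_pA = 0, onset_times = 5), trace$samples)
  avg2 <- ensemble_average(mix$trace, c(1, 5))
  expect_equal(min(avg2$mean_pA), -20, tolerance = 0.1)
  # under zero-mean noise the average concentrates around the template
  set.seed(32)
  n_ev <- 400
  ons <- seq(1, 399, length.out = n_ev)
  simn <- gen_mepsc_trace(400, 0, amp_median_pA = 20, amp_sigma = 0,
                          noise_sd_pA = 3, onset_times = ons, seed = 33)
  avgn <- ensemble_average(simn$trace, ons)
  clean <- gen_mepsc_trace(400, 0, amp_median_pA = 20, amp_sigma = 0,
                           noise_sd_pA = 0, onset_times = ons)
  avgc <- ensemble_average(clean$trace, ons)
  expect_lt(max(abs(avgn$mean_pA - avgc$mean_pA)), 3 * 3 / sqrt(n_ev) * 2)
})

test_that("junction potential correction is a plain subtraction", {
  expect_equal(correct_junction_potential(0), -18)
  expect_equal(correct_junction_potential(10, ljp_mv = 0), 10)
  expect_equal(correct_junction_potential(c(-60, 0, 60)),
               c(-78, -18, 42))
})

test_that("rectification analysis recovers the model RI", {
  lin <- gen_iv_sweeps(rectification_model(block_depth = 0),
                       seq(-60, 60, 20), noise_sd_pA = 0)
  ra <- rectification_analysis(lin$sweeps)
  expect_equal(ra$RI, 1, tolerance = 0.001)
  m <- rectification_model(g0 = 1, v_rev = 3, v_half = 20, k_block = 10,
                           block_depth = 0.8)
  sim <- gen_iv_sweeps(m, seq(-60, 60, 20), noise_sd_pA = 0)
  ra2 <- rectification_analysis(sim$sweeps)
  expect_equal(ra2$RI, sim$true_RI, tolerance = 0.01 * sim$true_RI)
  # scaling all currents leaves RI unchanged
  scaled <- lapply(sim$sweeps, function(s) { s$samples <- 2 * s$samples; s })
  expect_equal(rectification_analysis(scaled)$RI, ra2$RI,
               tolerance = 1e-9)
  # normalization anchors the most negative potential
  expect_equal(ra2$normalized_currents[1], -1)
})

test_that("rectification analysis demands a spanned reversal and full branches", {
  m <- rectification_model()
  full <- gen_iv_sweeps(m, c(-80, -60, -40, -20, 20, 40), noise_sd_pA = 0)
  short <- full$sweeps[1:4]  # all potentials below the reversal
  expect_error(rectification_analysis(short), "span")
  one_pos <- full$sweeps[c(1:4, 5)]  # a single depolarized point
  ra <- rectification_analysis(one_pos)
  expect_true(is.na(ra$RI))
})

test_that("RI is consistent under noise", {
  m <- rectification_model(block_depth = 0.8)
  truth <- model_true_iv(m, seq(-60, 60, 20))
  peak_scale <- max(abs(truth$iv$peak_pA))
  ris <- vapply(1:200, function(s) {
    sim <- gen_iv_sweeps(m, seq(-60, 60, 20),
                         noise_sd_pA = 0.05 * peak_scale, seed = 400 + s)
    rectification_analysis(sim$sweeps)$RI
  }, numeric(1))
  expect_lt(abs(median(ris) - truth$RI) / truth$RI, 0.05)
})

test_that("series resistance QC applies the 20 percent rule", {
  expect_identical(qc_series_resistance(c(10, 11)), "pass")
  expect_identical(qc_series_resistance(c(10, 12.5)), "fail")
  expect_identical(qc_series_resistance(rep(8, 5)), "pass")
  expect_error(qc_series_resistance(10), "at least 2")
  expect_error(qc_series_resistance(c(10, -1)), "positive")
})

test_that("trace CSV round trip preserves samples and metadata", {
  tr <- ephys_trace(rnorm(1000), 20000, holding_potential = -60,
                    cell_id = "c1", condition = "baseline")
  path <- tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  back <- read_trace_csv(path)
  expect_equal(back$samples, tr$samples, tolerance = 1e-9)
  expect_equal(back$fs, 20000)
  expect_identical(back$cell_id, "c1")
})
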
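# Generators: exact ground truth, programmed coincidence, event statistics,
# analytic I/V truth, and seed determinism.

test_that("noiseless unblurred stacks contain exactly the programmed puncta", {
  sim <- gen_dendrite_stack(length_um = 20, n_puncta = 5, coincidence = 0,
                            psf_sigma_um = 0, noise_sd = 0,
                            min_separation_um = 1.5, seed = 3)
  a <- get_channel(sim$stack, "A")
  comps <- label_components_26(a > 0)
  expect_identical(comps$n_puncta, 5L)
  expect_equal(nrow(sim$truth$A), 5)
  # centers lie inside the stack bounds
  d <- dim(a)
  expect_true(all(sim$truth$A$z >= 0 & sim$truth$A$z <= d[1] - 1))
  expect_true(all(sim$truth$A$x >= 0 & sim$truth$A$x <= d[3] - 1))
})

test_that("programmed coincidence is realized exactly and links are symmetric", {
  sim <- gen_dendrite_stack(length_um = 60, n_puncta = 60,
                            coincidence = 0.5, seed = 7, noise_sd = 0)
  expect_identical(sim$n_coincident, 30)
  expect_identical(sum(!is.na(sim$truth$A$coincident_with)), 30L)
  linked_a <- which(!is.na(sim$truth$A$coincident_with))
  partners <- sim$truth$A$coincident_with[linked_a]
  expect_identical(sim$truth$B$coincident_with[partners], linked_a)
  # full coincidence: every A center within one punctum radius of a B center
  sim1 <- gen_dendrite_stack(length_um = 30, n_puncta = 20,
                             coincidence = 1, seed = 9, noise_sd = 0)
  vs <- sim1$stack$voxel_size
  ta <- sim1$truth$A; tb <- sim1$truth$B
  d <- sqrt((ta$z * vs[1] - tb$z[ta$coincident_with] * vs[1])^2 +
              (ta$y * vs[2] - tb$y[ta$coincident_with] * vs[2])^2 +
              (ta$x * vs[3] - tb$x[ta$coincident_with] * vs[3])^2)
  expect_true(all(d <= ta$radius_um))
})

test_that("stack generation validates inputs", {
  expect_error(gen_dendrite_stack(coincidence = 1.2), "coincidence")
  expect_error(gen_dendrite_stack(length_um = 3, n_puncta = 200, seed = 1),
               "too small")
})

test_that("generators are bit-reproducible under a fixed seed", {
  s1 <- gen_dendrite_stack(length_um = 15, n_puncta = 8, noise_sd = 3,
                           poisson = TRUE, seed = 42)
  s2 <- gen_dendrite_stack(length_um = 15, n_puncta = 8, noise_sd = 3,
                           poisson = TRUE, seed = 42)
  expect_identical(s1$stack$voxels, s2$stack$voxels)
  expect_identical(s1$truth, s2$truth)
  m1 <- gen_mepsc_trace(5, 2, seed = 11)
  m2 <- gen_mepsc_trace(5, 2, seed = 11)
  expect_identical(m1$trace$samples, m2$trace$samples)
  iv1 <- gen_iv_sweeps(rectification_model(), noise_sd_pA = 3, seed = 4)
  iv2 <- gen_iv_sweeps(rectification_model(), noise_sd_pA = 3, seed = 4)
  expect_identical(iv1$sweeps[[1]]$samples, iv2$sweeps[[1]]$samples)
  t1 <- gen_spine_timelapse(noise_sd_frac = 0.05, seed = 2)
  t2 <- gen_spine_timelapse(noise_sd_frac = 0.05, seed = 2)
  expect_identical(t1$series[[3]]$mean_intensity,
                   t2$series[[3]]$mean_intensity)
})

test_that("mEPSC traces have events of the programmed shape and polarity", {
  flat <- gen_mepsc_trace(2, 0, noise_sd_pA = 0, seed = 1)
  expect_identical(flat$trace$samples, rep(0, 40000))
  expect_identical(nrow(flat$events), 0L)
  one <- gen_mepsc_trace(2, 0, amp_median_pA = 20, amp_sigma = 0,
                         noise_sd_pA = 0, onset_times = 0.7, seed = 1)
  expect_equal(min(one$trace$samples), -20, tolerance = 1e-3)
  expect_true(all(diff(one$events$onset_s) > 0) || nrow(one$events) <= 1)
  expect_error(gen_mepsc_trace(2, 1, rise_tau_ms = 5, decay_tau_ms = 4),
               "decay_tau")
})

test_that("mEPSC event counts follow the programmed Poisson rate", {
  counts <- vapply(1:300, function(s)
    nrow(gen_mepsc_trace(60, 1, noise_sd_pA = 0, seed = 1000 + s)$events),
    numeric(1))
  se <- sqrt(60 / 300)  # SE of the mean of Poisson(60) counts
  expect_lt(abs(mean(counts) - 60), 3 * se)
})

test_that("I/V truth: ohmic limit, deep block, and analytic-vs-numeric slopes", {
  pots <- seq(-60, 60, by = 20)
  expect_equal(model_true_iv(rectification_model(block_depth = 0),
                             pots)$RI, 1)
  # rectification deepens monotonically with block depth while the
  # depolarized branch stays conductive
  ris <- vapply(c(0, 0.4, 0.8), function(d)
    model_true_iv(rectification_model(block_depth = d), pots)$RI,
    numeric(1))
  expect_true(all(diff(ris) > 0))
  expect_gt(ris[3], 1)
  m <- rectification_model(g0 = 1, v_rev = 3, v_half = 20, k_block = 10,
                           block_depth = 0.8)
  truth <- model_true_iv(m, pots)
  # independent numeric oracle: lm on the noiseless peak currents
  iv <- truth$iv
  neg <- iv$potential_mV < m$v_rev
  s_neg <- unname(coef(lm(peak_pA ~ potential_mV, iv[neg, ]))[2])
  s_pos <- unname(coef(lm(peak_pA ~ potential_mV, iv[!neg, ]))[2])
  expect_equal(truth$RI, s_neg / s_pos, tolerance = 1e-12)
  expect_error(model_true_iv(m, c(10, 20, 30, 40)), "each side")
  expect_error(rectification_model(k_block = 0), "k_block")
  expect_error(rectification_model(block_depth = 1.5), "block_depth")
})

test_that("noiseless sweeps peak at the model current", {
  m <- rectification_model(block_depth = 0.6)
  sim <- gen_iv_sweeps(m, seq(-60, 60, 20), noise_sd_pA = 0)
  peaks <- vapply(sim$sweeps, function(s) {
    i <- which.max(abs(s$samples))
    s$samples[i]
  }, numeric(1))
  expect_equal(peaks, sim$true_iv$peak_pA, tolerance = 1e-3)
})

test_that("spine time-lapses carry the programmed transient and washout", {
  zero <- gen_spine_timelapse(n_spines = 2, transient_pct = 0,
                              noise_sd_frac = 0, seed = 1)
  expect_true(all(zero$series[[1]]$mean_intensity == 100))
  tl <- gen_spine_timelapse(n_spines = 2, transient_pct = 50,
                            noise_sd_frac = 0, seed = 1)
  f <- tl$series[[1]]$mean_intensity
  expect_equal(max(f) / f[1] - 1, 0.5, tolerance = 1e-12)
  # back to baseline in the wash window
  t <- tl$series[[1]]$frame_times
  wash <- t >= tl$series[[1]]$wash_window[1]
  expect_true(all(f[wash] == 100))
  expect_error(gen_spine_timelapse(stim_window = c(800, 1000),
                                   duration = 900), "inside the recording")
  expect_error(gen_spine_timelapse(frame_interval = 30), "frame_interval")
})

test_that("per-ROI baseline means track F0 under noise", {
  tl <- gen_spine_timelapse(n_spines = 17, transient_pct = 47,
                            noise_sd_frac = 0.05, seed = 6)
  for (s in tl$series) {
    base <- s$mean_intensity[s$frame_times < s$baseline_window[2]]
    se <- 0.05 * 100 / sqrt(length(base))
    expect_lt(abs(mean(base) - 100), 3 * se)
  }
})
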
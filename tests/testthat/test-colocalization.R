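# Object-based colocalization, enrichment ratio, and puncta regression.

test_that("overlap fraction handles self, disjoint and empty cases", {
  set.seed(20)
  m <- array(runif(512) < 0.25, c(8, 8, 8))
  lm <- label_components_26(m)
  self <- overlap_fraction(lm, lm)
  expect_equal(self$fraction_A_with_B, 1)
  expect_equal(self$fraction_B_with_A, 1)
  empty <- label_map(array(0L, c(8, 8, 8)), 0L)
  disj <- overlap_fraction(lm, empty)
  expect_equal(disj$fraction_A_with_B, 0)
  expect_true(is.na(disj$fraction_B_with_A))  # n = 0: undefined, not 0
})

test_that("a constructed 6-of-10 overlap yields fraction 0.6", {
  lab_a <- array(0L, c(1, 1, 40))
  lab_b <- array(0L, c(1, 1, 40))
  for (i in 1:10) lab_a[1, 1, (4 * i - 3):(4 * i - 2)] <- i
  for (i in 1:6) lab_b[1, 1, (4 * i - 2)] <- i        # touch A puncta 1..6
  for (i in 7:10) lab_b[1, 1, (4 * i - 1)] <- i       # miss A puncta 7..10
  res <- overlap_fraction(label_map(lab_a, 10L), label_map(lab_b, 10L))
  expect_equal(res$fraction_A_with_B, 0.6)
  oracle <- overlap_oracle(lab_a, lab_b)
  expect_identical(res$overlapping_ids_A, sort(oracle$ids))
  expect_equal(res$fraction_A_with_B, oracle$fraction)
})

test_that("overlap fraction is asymmetric with its own denominators", {
  set.seed(21)
  pair <- random_label_pair(c(12, 12, 12), p = 0.25)
  ab <- overlap_fraction(pair$A, pair$B)
  ba <- overlap_fraction(pair$B, pair$A)
  expect_equal(ab$fraction_A_with_B, ba$fraction_B_with_A)
  expect_equal(ab$fraction_B_with_A, ba$fraction_A_with_B)
})

test_that("the min-shared-voxels criterion is honored", {
  lab_a <- array(0L, c(1, 2, 6)); lab_a[1, 1, 1:3] <- 1L
  lab_b <- array(0L, c(1, 2, 6)); lab_b[1, 1, 3:5] <- 1L
  one <- overlap_fraction(label_map(lab_a, 1L), label_map(lab_b, 1L),
                          min_shared_voxels = 1)
  two <- overlap_fraction(label_map(lab_a, 1L), label_map(lab_b, 1L),
                          min_shared_voxels = 2)
  expect_equal(one$fraction_A_with_B, 1)
  expect_equal(two$fraction_A_with_B, 0)
})

test_that("overlap metrics report density per 100 um and raw-image stats", {
  lab_a <- array(0L, c(1, 1, 60))
  lab_b <- array(0L, c(1, 1, 60))
  for (i in 1:12) {
    lab_a[1, 1, 5 * i - 4] <- i
    lab_b[1, 1, 5 * i - 4] <- i
  }
  raw <- array(7, c(1, 1, 60))
  res <- overlap_metrics(label_map(lab_a, 12L), label_map(lab_b, 12L),
                         raw, raw, dendrite_length_um = 60,
                         voxel_size = c(0.3, 0.1, 0.1))
  expect_equal(res$overlap_density_per_100um, 20)
  expect_equal(res$overlap_mean_intensity_A, rep(7, 12))
  expect_equal(res$overlap_volume_um3, rep(0.003, 12))
  none <- overlap_metrics(label_map(lab_a, 12L),
                          label_map(array(0L, c(1, 1, 60)), 0L),
                          raw, raw, 60, c(0.3, 0.1, 0.1))
  expect_equal(none$overlap_density_per_100um, 0)
  expect_length(none$overlap_mean_intensity_A, 0)
  expect_error(overlap_metrics(label_map(lab_a, 12L), label_map(lab_b, 12L),
                               raw, raw, 0, c(0.3, 0.1, 0.1)), "> 0")
})

test_that("triple colocalization and the partition are exact complements", {
  set.seed(22)
  pair <- random_label_pair(c(10, 10, 10), p = 0.25)
  part <- overlap_partition(pair$A, pair$B)
  expect_identical(sort(c(part$overlapping, part$non_overlapping)),
                   seq_len(pair$A$n_puncta))
  tri <- triple_overlap(pair$A, pair$B, pair$B)
  expect_identical(tri$ids_A, part$overlapping)
})

test_that("spine/shaft ratio integrates programmed intensities", {
  img <- matrix(0, 30, 80)
  img[5:8, 10:13] <- 25    # spine ROI content
  img[20:23, 10:13] <- 25  # shaft ROI content
  spine <- list(c(4, 9, 9, 14))
  shaft <- list(c(19, 24, 9, 14))
  eq <- spine_shaft_ratio(img, spine, shaft)
  expect_equal(eq$ratio, 1)
  img2 <- img; img2[5:8, 10:13] <- 50
  expect_equal(spine_shaft_ratio(img2, spine, shaft)$ratio, 2)
  img3 <- img; img3[5:8, 10:13] <- 0
  expect_equal(spine_shaft_ratio(img3, spine, shaft)$ratio, 0)
  img4 <- img; img4[20:23, 10:13] <- 0
  expect_true(is.na(spine_shaft_ratio(img4, spine, shaft)$ratio))
  expect_error(spine_shaft_ratio(img, spine, spine), "disjoint")
  expect_error(spine_shaft_ratio(img, list(), shaft), "non-empty")
})

test_that("puncta regression recovers exact and null relations", {
  x <- c(1, 2, 3, 4, 5, 6)
  fit <- puncta_regression(x, 2 * x)
  expect_equal(fit$slope, 2)
  expect_equal(fit$r2, 1)
  # duplicated points leave the slope unchanged
  fit2 <- puncta_regression(c(x, x), c(2 * x, 2 * x))
  expect_equal(fit2$slope, fit$slope)
  set.seed(23)
  xn <- rnorm(200); yn <- rnorm(200)
  null_fit <- puncta_regression(xn, yn)
  se <- sqrt(1 / sum((xn - mean(xn))^2))
  expect_lt(abs(null_fit$slope), 3 * se)
  expect_error(puncta_regression(rep(1, 5), rnorm(5)), "variance")
  expect_error(puncta_regression(1:2, 1:2), "3")
})

test_that("intensity scaling behaves as expected across the module", {
  set.seed(24)
  pair <- random_label_pair(c(10, 10, 10), p = 0.25)
  raw <- array(runif(1000, 1, 10), c(10, 10, 10))
  r1 <- overlap_metrics(pair$A, pair$B, raw, raw, 30, c(0.3, 0.1, 0.1))
  r2 <- overlap_metrics(pair$A, pair$B, raw * 3, raw * 3, 30,
                        c(0.3, 0.1, 0.1))
  expect_equal(r1$fraction_A_with_B, r2$fraction_A_with_B)
  expect_equal(r2$overlap_mean_intensity_A, 3 * r1$overlap_mean_intensity_A)
  x <- runif(50); y <- 1.5 * x + rnorm(50, 0, 0.1)
  expect_equal(puncta_regression(x, 2 * y)$slope,
               2 * puncta_regression(x, y)$slope)
})
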
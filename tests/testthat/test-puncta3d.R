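# Segmentation core: 26-connectivity semantics, watershed splitting,
# per-punctum properties, 2D cluster detection and the selection filter.

test_that("26-connectivity joins corner contacts and respects gaps", {
  m <- array(FALSE, c(3, 3, 3))
  m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE
  expect_identical(label_components_26(m)$n_puncta, 1L)
  m2 <- array(FALSE, c(1, 1, 5))
  m2[1, 1, c(1, 3)] <- TRUE
  expect_identical(label_components_26(m2)$n_puncta, 2L)
  expect_identical(label_components_26(array(FALSE, c(4, 4, 4)))$n_puncta,
                   0L)
})

test_that("labels are gapless 1..n and 26-connected per component", {
  set.seed(10)
  for (i in 1:20) {
    m <- array(runif(16^3) < 0.3, c(16, 16, 16))
    lm <- label_components_26(m)
    labs <- lm$labels[lm$labels > 0]
    expect_identical(sort(unique(labs)), seq_len(lm$n_puncta))
    expect_true(same_partition(lm$labels, bfs_label_oracle(m)))
  }
})

test_that("well-separated puncta segment to distinct labels", {
  vol <- gaussian_blob(c(9, 24, 60), c(4, 11, 15), c(1, 2, 2)) +
    gaussian_blob(c(9, 24, 60), c(4, 11, 45), c(1, 2, 2))
  lm <- segment_puncta_3d(vol, threshold = 10)
  expect_identical(lm$n_puncta, 2L)
  expect_identical(segment_puncta_3d(array(0, c(4, 8, 8)),
                                     threshold = 1)$n_puncta, 0L)
})

test_that("watershed splits fused puncta that plain labeling merges", {
  fused <- gaussian_blob(c(9, 24, 40), c(4, 11, 16), c(1, 2, 2)) +
    gaussian_blob(c(9, 24, 40), c(4, 11, 22), c(1, 2, 2))
  with_ws <- segment_puncta_3d(fused, threshold = 20, watershed = TRUE)
  without <- segment_puncta_3d(fused, threshold = 20, watershed = FALSE)
  expect_identical(with_ws$n_puncta, 2L)
  expect_identical(without$n_puncta, 1L)
  # split conserves the voxel partition and never merges
  expect_identical(sum(with_ws$labels > 0), sum(without$labels > 0))
})

test_that("raising the threshold never increases labeled voxel count", {
  set.seed(11)
  vol <- gaussian_blob(c(7, 20, 40), c(3, 10, 12), c(1, 2, 2)) +
    gaussian_blob(c(7, 20, 40), c(3, 10, 30), c(1, 2, 2)) +
    array(runif(7 * 20 * 40, 0, 5), c(7, 20, 40))
  counts <- vapply(c(10, 20, 30, 50), function(th)
    sum(segment_puncta_3d(vol, th)$labels > 0), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("punctum properties do the arithmetic on the raw image", {
  lab <- array(0L, c(1, 1, 5))
  lab[1, 1, 1:3] <- 1L
  raw <- array(0, c(1, 1, 5))
  raw[1, 1, 1:3] <- c(10, 20, 30)
  ps <- puncta_properties(label_map(lab, 1L), raw,
                          voxel_size = c(0.3, 0.1, 0.1))
  expect_equal(ps$puncta$integrated_intensity, 60)
  expect_equal(ps$puncta$mean_intensity, 20)
  expect_equal(ps$puncta$voxel_count, 3L)
  lab5 <- array(0L, c(5, 1, 1)); lab5[1:5, 1, 1] <- 1L
  ps5 <- puncta_properties(label_map(lab5, 1L), array(1, c(5, 1, 1)),
                           voxel_size = c(0.3, 0.1, 0.1))
  expect_equal(ps5$puncta$volume_um3, 5 * 0.3 * 0.1 * 0.1)
  expect_error(puncta_properties(label_map(lab, 1L), raw, NULL),
               "voxel_size")
})

test_that("centroids of symmetric puncta recover generator centers", {
  sim <- gen_dendrite_stack(length_um = 20, n_puncta = 6, coincidence = 0,
                            psf_sigma_um = 0.2, noise_sd = 0, seed = 21)
  a <- get_channel(sim$stack, "A")
  lm <- segment_puncta_3d(a, threshold_background(a))
  ps <- puncta_properties(lm, a, sim$stack$voxel_size)
  expect_identical(nrow(ps$puncta), 6L)
  vs <- sim$stack$voxel_size
  for (i in seq_len(6)) {
    tc <- c(sim$truth$A$z[i] * vs[1], sim$truth$A$y[i] * vs[2],
            sim$truth$A$x[i] * vs[3])
    d <- sqrt(colSums((t(cbind(ps$puncta$centroid_z_um,
                               ps$puncta$centroid_y_um,
                               ps$puncta$centroid_x_um)) - tc)^2))
    expect_lt(min(d), 0.5 * max(vs))
  }
})

test_that("2D detection enforces the four-pixel cluster rule", {
  img <- matrix(0, 20, 20)
  img[3, 3:5] <- 10  # 3 pixels: below the minimum
  expect_identical(nrow(detect_puncta_2d(img, 5)$puncta), 0L)
  img[3, 6] <- 10    # now 4 adjacent pixels
  expect_identical(nrow(detect_puncta_2d(img, 5)$puncta), 1L)
  img2 <- matrix(0, 30, 30)
  for (k in 0:3) img2[5 + 6 * k, 10:14] <- 10  # 4 disjoint 5-pixel clusters
  expect_identical(nrow(detect_puncta_2d(img2, 5)$puncta), 4L)
  # diagonal adjacency counts (8-connectivity in 2D)
  img3 <- matrix(0, 10, 10)
  img3[cbind(c(2, 3, 4, 5), c(2, 3, 4, 5))] <- 10
  expect_identical(nrow(detect_puncta_2d(img3, 5)$puncta), 1L)
})

test_that("synaptic punctum selection applies all three criteria", {
  img <- matrix(0, 40, 60)
  mask <- matrix(FALSE, 40, 60)
  mask[18:22, ] <- TRUE  # dendrite band
  put <- function(im, y, x, v = 20) { im[y:(y + 1), x:(x + 1)] <- v; im }
  img <- put(img, 20, 10)          # on the dendrite
  img <- put(img, 28, 30)          # 5 px outside the 4-px reach
  img <- put(img, 20, 50, v = 2)   # on dendrite but dim
  partner <- matrix(10, 40, 60)
  det <- detect_puncta_2d(img, 1, min_pixels = 4)
  sel <- select_synaptic_puncta(det, partner, mask, max_dist_px = 4,
                                background_levels = c(primary = 5,
                                                      partner = 5))
  expect_identical(nrow(sel$puncta), 1L)
  expect_lt(abs(sel$puncta$centroid_x_px - 9.5), 1)
  expect_error(select_synaptic_puncta(det, partner, NULL), "mask")
})

test_that("selection retains the programmed on-dendrite fraction", {
  set.seed(12)
  img <- matrix(0, 60, 200)
  mask <- matrix(FALSE, 60, 200)
  mask[28:32, ] <- TRUE
  n_on <- 14; n_off <- 6  # programmed 30% off-dendrite
  xs <- seq(5, 195, length.out = n_on + n_off)
  for (i in seq_len(n_on)) img[29:30, xs[i]:(xs[i] + 1)] <- 20
  for (i in seq_len(n_off)) {
    x <- xs[n_on + i]
    img[45:46, x:(x + 1)] <- 20  # 13+ px from the dendrite band
  }
  det <- detect_puncta_2d(img, 5)
  sel <- select_synaptic_puncta(det, matrix(10, 60, 200), mask,
                                background_levels = c(primary = 1,
                                                      partner = 1))
  expect_equal(nrow(sel$puncta) / nrow(det$puncta), 0.7, tolerance = 0.05)
})
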
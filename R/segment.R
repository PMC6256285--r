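# Puncta segmentation: 3D watershed segmentation with 26-connectivity
# labeling, per-punctum properties, and the 2D cluster detector plus the
# synaptic-punctum selection filter.

#' Label map of segmented puncta
#'
#' @param labels Integer array, 0 for background, 1..n for puncta; each
#'   label's voxel set is 26-connected.
#' @param n_puncta Number of distinct labels.
#' @param threshold Threshold used to build the mask (provenance).
#' @return A `label_map` object.
#' @export
label_map <- function(labels, n_puncta, threshold = NA_real_) {
  structure(list(labels = labels, n_puncta = as.integer(n_puncta),
                 threshold = threshold),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d puncta over %s grid\n", x$n_puncta,
              paste(dim(x$labels), collapse = " x ")))
  invisible(x)
}

#' 26-connected component labeling
#'
#' Labels groups of connected foreground voxels using 26-connectivity in 3D
#' (voxels sharing a face, edge or corner belong to the same component). A 2D
#' input is treated as a single z slice, which reduces to 8-connectivity.
#'
#' @param binary Logical (or 0/1 numeric) matrix or 3D array `(z, y, x)`.
#' @return A [label_map()]; labels are assigned in scan order, 1..n with no
#'   gaps.
#' @export
label_components_26 <- function(binary) {
  if (is.matrix(binary)) dim(binary) <- c(1L, dim(binary))
  d <- dim(binary)
  if (length(d) != 3L) stop("input must be 2D or 3D", call. = FALSE)
  mask <- as.logical(binary)
  mask[is.na(mask)] <- FALSE
  lab <- .label26_cpp(mask, as.integer(d))
  n <- attr(lab, "n")
  dim(lab) <- d
  label_map(lab, n)
}

#' Segment fluorescent puncta in a 3D volume
#'
#' The segmentation core: the channel is optionally sharpened (unsharp mask,
#' Gaussian sigma 1 px, amount 0.6) for segmentation geometry only, a binary
#' mask is formed by thresholding, and touching puncta are separated by a
#' marker-based 3D watershed seeded at local maxima of the Gaussian-smoothed
#' (sigma 1 px) intensity. With watershed off, the mask components are
#' labeled directly with 26-connectivity. Intensity statistics downstream are
#' always measured on the raw image.
#'
#' @param channel 3D array `(z, y, x)` (or 2D matrix) of raw intensities.
#' @param threshold Intensity threshold; voxels with (post-sharpen) intensity
#'   `>= threshold` enter the mask. If `NULL`, [threshold_background()] on
#'   the channel is used. A threshold chosen once per experiment should be
#'   passed explicitly to every image (frozen-threshold convention).
#' @param sharpen Apply the unsharp mask before thresholding (default TRUE).
#' @param watershed Split touching puncta at intensity saddles (default
#'   TRUE). Watershed may split but never merges threshold-connected
#'   components.
#' @param min_voxels Minimum punctum size in voxels (default 4, mirroring
#'   the 2D four-pixel cluster convention); smaller components are dropped
#'   and labels renumbered.
#' @return A [label_map()]. An empty above-threshold set yields a valid map
#'   with `n_puncta = 0`.
#' @export
segment_puncta_3d <- function(channel, threshold = NULL, sharpen = TRUE,
                              watershed = TRUE, min_voxels = 4L) {
  if (is.matrix(channel)) dim(channel) <- c(1L, dim(channel))
  d <- dim(channel)
  if (length(d) != 3L) stop("channel must be 2D or 3D", call. = FALSE)
  if (is.null(threshold)) threshold <- threshold_background(channel)
  geom <- channel
  if (sharpen) {
    blur <- gauss_blur3d(channel, c(1, 1, 1))
    geom <- channel + 0.6 * (channel - blur)
  }
  mask <- geom >= threshold
  if (!any(mask)) {
    return(label_map(array(0L, d), 0L, threshold))
  }
  if (!watershed) {
    lm <- label_components_26(mask)
    out <- filter_small_labels(lm$labels, lm$n_puncta, min_voxels)
    return(label_map(out$labels, out$n, threshold))
  }
  smooth <- gauss_blur3d(channel, c(1, 1, 1))
  maxima <- .local_maxima3d_cpp(as.numeric(smooth), as.logical(mask),
                                as.integer(d))
  dim(maxima) <- d
  markers <- label_components_26(maxima)  # one marker per maximum plateau
  lab <- .watershed3d_cpp(as.numeric(smooth), as.logical(mask),
                          as.integer(markers$labels), as.integer(d))
  dim(lab) <- d
  out <- filter_small_labels(lab, markers$n_puncta, min_voxels)
  label_map(out$labels, out$n, threshold)
}

# Drop labels smaller than min_voxels and renumber 1..n in scan order.
filter_small_labels <- function(lab, n, min_voxels) {
  if (n == 0L || min_voxels <= 1L) return(list(labels = lab, n = n))
  cnt <- tabulate(lab[lab > 0L], nbins = n)
  keep <- which(cnt >= min_voxels)
  remap <- integer(n)
  pos <- which(lab > 0L)
  first <- vapply(split(pos, lab[pos]), min, numeric(1))
  keep <- keep[order(first[keep])]
  remap[keep] <- seq_along(keep)
  newlab <- lab
  newlab[pos] <- remap[lab[pos]]
  list(labels = newlab, n = length(keep))
}

#' Per-punctum properties
#'
#' Measures every labeled punctum on the raw (pre-sharpen) image: voxel
#' count, physical volume, integrated and mean intensity, and
#' intensity-weighted centroid in micrometres.
#'
#' @param label_map A [label_map()].
#' @param raw Raw intensity array, same shape as the label grid.
#' @param voxel_size `(dz, dy, dx)` in micrometres; required.
#' @param dendrite_length_um Optional dendrite length for density reporting.
#' @param channel Optional channel name recorded for provenance.
#' @return A `puncta_set`: a data frame of puncta plus segmentation
#'   provenance.
#' @export
puncta_properties <- function(label_map, raw, voxel_size,
                              dendrite_length_um = NA_real_,
                              channel = NA_character_) {
  stopifnot(inherits(label_map, "label_map"))
  if (is.matrix(raw)) dim(raw) <- c(1L, dim(raw))
  lab <- label_map$labels
  if (!identical(dim(lab), dim(raw)))
    stop("label map and raw image shapes differ", call. = FALSE)
  if (missing(voxel_size) || is.null(voxel_size))
    stop("voxel_size (dz, dy, dx) in um is required", call. = FALSE)
  d <- dim(lab)
  n <- label_map$n_puncta
  if (n == 0L) {
    df <- data.frame(id = integer(), voxel_count = integer(),
                     volume_um3 = numeric(), integrated_intensity = numeric(),
                     mean_intensity = numeric(), centroid_z_um = numeric(),
                     centroid_y_um = numeric(), centroid_x_um = numeric())
    return(puncta_set(df, voxel_size, dendrite_length_um, channel,
                      label_map$threshold, label_map))
  }
  sel <- which(lab > 0L)
  labs <- lab[sel]
  vals <- as.numeric(raw[sel])
  # 0-based voxel coordinates from the linear index
  z <- (sel - 1L) %% d[1]
  y <- ((sel - 1L) %/% d[1]) %% d[2]
  x <- (sel - 1L) %/% (d[1] * d[2])
  cnt <- tabulate(labs, nbins = n)
  tot <- as.numeric(rowsum(vals, labs))
  wz <- as.numeric(rowsum(vals * z, labs))
  wy <- as.numeric(rowsum(vals * y, labs))
  wx <- as.numeric(rowsum(vals * x, labs))
  w <- ifelse(tot > 0, tot, cnt)
  cz <- ifelse(tot > 0, wz / w, as.numeric(rowsum(z, labs)) / cnt)
  cy <- ifelse(tot > 0, wy / w, as.numeric(rowsum(y, labs)) / cnt)
  cx <- ifelse(tot > 0, wx / w, as.numeric(rowsum(x, labs)) / cnt)
  df <- data.frame(
    id = seq_len(n), voxel_count = cnt,
    volume_um3 = cnt * prod(voxel_size),
    integrated_intensity = tot, mean_intensity = tot / cnt,
    centroid_z_um = cz * voxel_size[1], centroid_y_um = cy * voxel_size[2],
    centroid_x_um = cx * voxel_size[3])
  puncta_set(df, voxel_size, dendrite_length_um, channel,
             label_map$threshold, label_map)
}

puncta_set <- function(puncta, voxel_size, dendrite_length_um = NA_real_,
                       channel = NA_character_, threshold = NA_real_,
                       label_map = NULL) {
  structure(list(puncta = puncta, voxel_size = as.numeric(voxel_size),
                 dendrite_length_um = dendrite_length_um, channel = channel,
                 threshold_used = threshold, label_map = label_map),
            class = "puncta_set")
}

#' @export
print.puncta_set <- function(x, ...) {
  cat(sprintf("<puncta_set> %d puncta (channel %s, threshold %s)\n",
              nrow(x$puncta), x$channel, format(x$threshold_used)))
  if (!is.na(x$dendrite_length_um))
    cat(sprintf("  dendrite length %.1f um, density %.1f puncta per 100 um\n",
                x$dendrite_length_um, puncta_density(x)))
  invisible(x)
}

#' Linear puncta density
#'
#' @param x A `puncta_set` with a known dendrite length.
#' @param per Normalisation length in micrometres; the conventional report is
#'   puncta per 100 um (default), set `per = 1` for raw per-um density.
#' @return Puncta per `per` micrometres of dendrite.
#' @export
puncta_density <- function(x, per = 100) {
  stopifnot(inherits(x, "puncta_set"))
  if (is.na(x$dendrite_length_um) || x$dendrite_length_um <= 0)
    stop("dendrite length unknown or nonpositive", call. = FALSE)
  nrow(x$puncta) / x$dendrite_length_um * per
}

#' Detect 2D puncta as above-threshold pixel clusters
#'
#' Detection on a projected image by thresholding and counting distinct
#' clusters of `min_pixels` or more adjacent (8-connected) pixels above the
#' intensity threshold.
#'
#' @param image 2D `(y, x)` matrix.
#' @param threshold Intensity threshold (pixels `>= threshold` count).
#' @param min_pixels Minimum cluster size in pixels, default 4.
#' @param pixel_size `(dy, dx)` in micrometres (default 1 px).
#' @param dendrite_length_um Optional length for density reporting.
#' @return A `puncta_set` whose data frame has 2D properties (`area_px`,
#'   centroids in pixels); the filtered label map is kept for downstream
#'   selection.
#' @export
detect_puncta_2d <- function(image, threshold, min_pixels = 4L,
                             pixel_size = c(1, 1),
                             dendrite_length_um = NA_real_) {
  if (!is.matrix(image)) stop("image must be a 2D matrix", call. = FALSE)
  mask <- image >= threshold
  lm <- label_components_26(mask)
  lab2 <- lm$labels[1, , ]
  keep <- which(tabulate(lab2[lab2 > 0L], nbins = lm$n_puncta) >=
                  min_pixels)
  remap <- integer(lm$n_puncta)
  remap[keep] <- seq_along(keep)
  new_lab <- array(0L, dim = dim(lab2))
  pos <- lab2 > 0L
  new_lab[pos] <- remap[lab2[pos]]
  n <- length(keep)
  if (n == 0L) {
    df <- data.frame(id = integer(), area_px = integer(),
                     integrated_intensity = numeric(),
                     mean_intensity = numeric(),
                     centroid_y_px = numeric(), centroid_x_px = numeric())
  } else {
    sel <- which(new_lab > 0L)
    labs <- new_lab[sel]
    vals <- as.numeric(image[sel])
    y <- (sel - 1L) %% nrow(image)
    x <- (sel - 1L) %/% nrow(image)
    cnt <- tabulate(labs, nbins = n)
    tot <- as.numeric(rowsum(vals, labs))
    df <- data.frame(
      id = seq_len(n), area_px = cnt,
      integrated_intensity = tot, mean_intensity = tot / cnt,
      centroid_y_px = as.numeric(rowsum(vals * y, labs)) / tot,
      centroid_x_px = as.numeric(rowsum(vals * x, labs)) / tot)
  }
  out <- puncta_set(df, c(NA_real_, pixel_size), dendrite_length_um,
                    threshold = threshold)
  out$label_map <- label_map(new_lab, n, threshold)
  out
}

#' Mexican-hat (Laplacian-of-Gaussian) punctum enhancement
#'
#' Convolves a 2D image with a negated Laplacian of Gaussian, the classic
#' center-surround filter used to box punctate signal before selection.
#'
#' @param image 2D matrix.
#' @param sigma Center scale in pixels (default 2).
#' @return Filtered image (negative responses clipped to 0).
#' @export
mexican_hat_filter <- function(image, sigma = 2) {
  r <- ceiling(4 * sigma)
  ax <- seq(-r, r)
  g <- exp(-ax^2 / (2 * sigma^2))
  gauss2 <- outer(g, g)
  gauss2 <- gauss2 / sum(gauss2)
  d2 <- outer(ax^2, ax^2, `+`)
  log_kern <- gauss2 * (d2 - 2 * sigma^2) / sigma^4
  log_kern <- log_kern - mean(log_kern)
  out <- EBImage::filter2(image, -log_kern)
  matrix(pmax(as.numeric(out), 0), nrow = nrow(image))
}

#' Select synaptic puncta near a dendrite marker
#'
#' Filters detected 2D puncta by the three selection criteria used for
#' surface-receptor punctum analysis: the punctum must be above background in
#' its own channel and in the partner channel, its bounding box must be
#' discrete (non-overlapping with any other punctum's box), and it must lie
#' within `max_dist_px` pixels of the positive region of a dendrite marker
#' mask (e.g. MAP2).
#'
#' @param puncta_2d Output of [detect_puncta_2d()] (label map required).
#' @param partner_channel_image Co-registered partner-channel image.
#' @param mask_image Logical (or 0/1) dendrite marker mask; required.
#' @param max_dist_px Maximum centroid distance to the mask, default 4 px.
#' @param background_levels Named numeric `c(primary = , partner = )`
#'   background intensity levels.
#' @param box_pad_px Padding added to each punctum bounding box before the
#'   overlap check (default 1 px).
#' @return A `puncta_set` restricted to retained puncta, with the per-punctum
#'   criterion columns kept for bookkeeping.
#' @export
select_synaptic_puncta <- function(puncta_2d, partner_channel_image,
                                   mask_image, max_dist_px = 4,
                                   background_levels = c(primary = 0,
                                                         partner = 0),
                                   box_pad_px = 1L) {
  stopifnot(inherits(puncta_2d, "puncta_set"))
  if (missing(mask_image) || is.null(mask_image))
    stop("a dendrite marker mask is required", call. = FALSE)
  lm <- puncta_2d$label_map
  if (is.null(lm)) stop("puncta_2d lacks a label map", call. = FALSE)
  df <- puncta_2d$puncta
  if (nrow(df) == 0L) return(puncta_2d)
  lab <- lm$labels
  mask <- mask_image > 0
  # distance of every pixel to the nearest mask-positive pixel
  dist_to_mask <- as.matrix(EBImage::distmap(1 - mask))
  n <- nrow(df)
  above_primary <- df$mean_intensity > background_levels[["primary"]]
  partner_mean <- numeric(n)
  bbox <- matrix(0L, n, 4)  # y0, y1, x0, x1 (padded)
  for (i in seq_len(n)) {
    sel <- which(lab == df$id[i])
    partner_mean[i] <- mean(partner_channel_image[sel])
    y <- (sel - 1L) %% nrow(lab)
    x <- (sel - 1L) %/% nrow(lab)
    bbox[i, ] <- c(min(y) - box_pad_px, max(y) + box_pad_px,
                   min(x) - box_pad_px, max(x) + box_pad_px)
  }
  above_partner <- partner_mean > background_levels[["partner"]]
  cy <- pmin(pmax(round(df$centroid_y_px) + 1L, 1L), nrow(lab))
  cx <- pmin(pmax(round(df$centroid_x_px) + 1L, 1L), ncol(lab))
  near_mask <- dist_to_mask[cbind(cy, cx)] <= max_dist_px
  discrete <- rep(TRUE, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      if (bbox[i, 1] <= bbox[j, 2] && bbox[j, 1] <= bbox[i, 2] &&
          bbox[i, 3] <= bbox[j, 4] && bbox[j, 3] <= bbox[i, 4]) {
        discrete[i] <- FALSE
        discrete[j] <- FALSE
      }
    }
  }
  keep <- above_primary & above_partner & near_mask & discrete
  out <- puncta_2d
  out$puncta <- cbind(df[keep, , drop = FALSE],
                      partner_mean = partner_mean[keep])
  rownames(out$puncta) <- NULL
  out$selection <- data.frame(id = df$id, above_primary = above_primary,
                              above_partner = above_partner,
                              near_mask = near_mask, discrete = discrete,
                              retained = keep)
  out
}
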
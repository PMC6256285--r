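# Object-based colocalization between labeled channels, spine-vs-shaft
# enrichment, and puncta-by-puncta intensity regression.

# Shared-voxel counts between two label maps as a data frame (a, b, voxels).
shared_voxel_table <- function(labels_A, labels_B) {
  la <- labels_A$labels; lb <- labels_B$labels
  if (!identical(dim(la), dim(lb)))
    stop("label maps must share the same grid", call. = FALSE)
  sel <- la > 0L & lb > 0L
  if (!any(sel))
    return(data.frame(a = integer(), b = integer(), voxels = integer()))
  tab <- table(a = la[sel], b = lb[sel])
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df) <- c("a", "b", "voxels")
  df$a <- as.integer(df$a); df$b <- as.integer(df$b)
  df[df$voxels > 0, , drop = FALSE]
}

#' Object-based overlap fraction between two channels
#'
#' The colocalization statistic: the fraction of channel-A puncta that share
#' at least `min_shared_voxels` voxels with any channel-B punctum —
#' "overlapping A and B puncta" over "all A puncta". The converse fraction
#' (B with A, its own denominator) is always reported too, since the measure
#' is asymmetric.
#'
#' @param labels_A,labels_B [label_map()]s on the same grid.
#' @param min_shared_voxels Overlap criterion, default 1 voxel (the weakest
#'   reading; recorded in the result for provenance).
#' @return A `coloc_result`: `fraction_A_with_B`, `fraction_B_with_A`,
#'   `n_overlap` (overlapping A puncta), `n_A`, `n_B`, the overlapping
#'   punctum ids per channel, and the criterion used. With `n_A = 0` the
#'   fraction is `NA` (undefined, not 0).
#' @export
overlap_fraction <- function(labels_A, labels_B, min_shared_voxels = 1L) {
  stopifnot(inherits(labels_A, "label_map"), inherits(labels_B, "label_map"))
  tab <- shared_voxel_table(labels_A, labels_B)
  tab <- tab[tab$voxels >= min_shared_voxels, , drop = FALSE]
  ids_a <- sort(unique(tab$a))
  ids_b <- sort(unique(tab$b))
  n_a <- labels_A$n_puncta; n_b <- labels_B$n_puncta
  structure(list(
    fraction_A_with_B = if (n_a > 0) length(ids_a) / n_a else NA_real_,
    fraction_B_with_A = if (n_b > 0) length(ids_b) / n_b else NA_real_,
    n_overlap = length(ids_a), n_A = n_a, n_B = n_b,
    overlapping_ids_A = ids_a, overlapping_ids_B = ids_b,
    min_shared_voxels = as.integer(min_shared_voxels)),
    class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "<coloc_result> %d/%d A puncta overlap B (%.1f%%); %d/%d B with A (%.1f%%)\n",
    x$n_overlap, x$n_A, 100 * x$fraction_A_with_B,
    length(x$overlapping_ids_B), x$n_B, 100 * x$fraction_B_with_A))
  invisible(x)
}

#' Overlap metrics per dendrite
#'
#' Extends [overlap_fraction()] with the per-dendrite summaries: overlap
#' density (overlapping A puncta per 100 um of dendrite) and the mean
#' intensity and volume of the overlapping A puncta measured on the raw
#' images.
#'
#' @inheritParams overlap_fraction
#' @param raw_A,raw_B Raw intensity arrays for the two channels.
#' @param dendrite_length_um Dendrite length in micrometres, > 0.
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @return A `coloc_result` with `overlap_density_per_100um`,
#'   `overlap_mean_intensity_A`, `overlap_mean_intensity_B` and
#'   `overlap_volume_um3` (empty stats when there is no overlap).
#' @export
overlap_metrics <- function(labels_A, labels_B, raw_A, raw_B,
                            dendrite_length_um, voxel_size,
                            min_shared_voxels = 1L) {
  if (dendrite_length_um <= 0)
    stop("dendrite length must be > 0", call. = FALSE)
  res <- overlap_fraction(labels_A, labels_B, min_shared_voxels)
  res$overlap_density_per_100um <- res$n_overlap / dendrite_length_um * 100
  ids <- res$overlapping_ids_A
  if (length(ids) > 0) {
    la <- labels_A$labels
    sel <- la %in% ids
    labs <- la[sel]
    cnt <- tabulate(labs, nbins = labels_A$n_puncta)[ids]
    res$overlap_mean_intensity_A <-
      as.numeric(rowsum(as.numeric(raw_A[sel]), labs)) / cnt
    res$overlap_mean_intensity_B <-
      as.numeric(rowsum(as.numeric(raw_B[sel]), labs)) / cnt
    res$overlap_volume_um3 <- cnt * prod(voxel_size)
  } else {
    res$overlap_mean_intensity_A <- numeric()
    res$overlap_mean_intensity_B <- numeric()
    res$overlap_volume_um3 <- numeric()
  }
  res$dendrite_length_um <- dendrite_length_um
  res
}

#' Triple colocalization
#'
#' Channel-A puncta overlapping both a B and a C punctum (chained pairwise
#' intersection).
#'
#' @inheritParams overlap_fraction
#' @param labels_C Third channel label map.
#' @return List with the triple-positive A punctum ids and the fraction of A
#'   puncta that are triple-positive.
#' @export
triple_overlap <- function(labels_A, labels_B, labels_C,
                           min_shared_voxels = 1L) {
  ab <- overlap_fraction(labels_A, labels_B, min_shared_voxels)
  ac <- overlap_fraction(labels_A, labels_C, min_shared_voxels)
  ids <- intersect(ab$overlapping_ids_A, ac$overlapping_ids_A)
  list(ids_A = ids,
       fraction = if (ab$n_A > 0) length(ids) / ab$n_A else NA_real_)
}

#' Partition A puncta by overlap with B
#'
#' Splits the channel-A puncta into those overlapping B and their exact
#' complement (e.g. scaffold-positive vs scaffold-negative synaptic sites),
#' guaranteeing the two sets partition A.
#'
#' @inheritParams overlap_fraction
#' @return List with `overlapping` and `non_overlapping` A punctum ids.
#' @export
overlap_partition <- function(labels_A, labels_B, min_shared_voxels = 1L) {
  res <- overlap_fraction(labels_A, labels_B, min_shared_voxels)
  all_ids <- seq_len(res$n_A)
  list(overlapping = res$overlapping_ids_A,
       non_overlapping = setdiff(all_ids, res$overlapping_ids_A))
}

roi_pixels <- function(image, roi) {
  if (is.matrix(roi) && is.logical(roi)) return(which(roi))
  if (length(roi) == 4) {
    # 0-based inclusive box (y0, y1, x0, x1)
    ys <- (roi[1]:roi[2]) + 1
    xs <- (roi[3]:roi[4]) + 1
    if (min(ys) < 1 || max(ys) > nrow(image) ||
        min(xs) < 1 || max(xs) > ncol(image))
      stop("ROI exits the image", call. = FALSE)
    return(as.vector(outer(ys, (xs - 1) * nrow(image), `+`)))
  }
  stop("an ROI must be a logical mask or a (y0, y1, x0, x1) box",
       call. = FALSE)
}

#' Spine-versus-shaft enrichment ratio
#'
#' Integrates background-subtracted intensity (area-under-the-curve sum) over
#' a set of spine ROIs and a set of dendritic-shaft punctum ROIs on a
#' straightened sum projection, and reports the spine/shaft ratio: 0 means
#' the protein occupies the shaft exclusively, 1 means equal contribution to
#' shaft and spine synapses.
#'
#' @param image Straightened 2D sum projection.
#' @param spine_rois,shaft_rois Non-empty, disjoint lists of ROIs (logical
#'   masks or 0-based inclusive `(y0, y1, x0, x1)` boxes).
#' @param background Constant background level subtracted before
#'   integration (default 0).
#' @return An `enrichment_ratio` list: `spine_intensity`, `shaft_intensity`,
#'   `ratio` (`NA` when the shaft intensity is 0).
#' @export
spine_shaft_ratio <- function(image, spine_rois, shaft_rois,
                              background = 0) {
  if (length(spine_rois) == 0 || length(shaft_rois) == 0)
    stop("spine and shaft ROI sets must be non-empty", call. = FALSE)
  spine_px <- unlist(lapply(spine_rois, roi_pixels, image = image))
  shaft_px <- unlist(lapply(shaft_rois, roi_pixels, image = image))
  if (length(intersect(spine_px, shaft_px)) > 0)
    stop("spine and shaft ROIs must be disjoint", call. = FALSE)
  spine <- sum(pmax(image[spine_px] - background, 0))
  shaft <- sum(pmax(image[shaft_px] - background, 0))
  structure(list(spine_intensity = spine, shaft_intensity = shaft,
                 ratio = if (shaft > 0) spine / shaft else NA_real_),
            class = "enrichment_ratio")
}

#' @export
print.enrichment_ratio <- function(x, ...) {
  cat(sprintf("<enrichment_ratio> spine/shaft = %s (spine %.4g, shaft %.4g)\n",
              format(x$ratio, digits = 4), x$spine_intensity,
              x$shaft_intensity))
  invisible(x)
}

#' Puncta-by-puncta intensity regression
#'
#' Ordinary least-squares regression of per-punctum intensities in one
#' channel on the paired intensities of the same (colocalized) puncta in
#' another channel; slopes are compared across conditions downstream.
#'
#' @param x_intensities,y_intensities Paired per-punctum intensities, same
#'   length, n >= 3.
#' @return A `regression_slope` list: `slope`, `intercept`, `r2`,
#'   `n_points`.
#' @export
puncta_regression <- function(x_intensities, y_intensities) {
  if (length(x_intensities) != length(y_intensities))
    stop("x and y must be paired (equal length)", call. = FALSE)
  ok <- complete.cases(x_intensities, y_intensities)
  x <- x_intensities[ok]; y <- y_intensities[ok]
  if (length(x) < 3) stop("need at least 3 paired points", call. = FALSE)
  if (stats::var(x) == 0)
    stop("zero variance in x: slope undefined", call. = FALSE)
  fit <- lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 1
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r2 = r2, n_points = length(x)),
            class = "regression_slope")
}

#' @export
print.regression_slope <- function(x, ...) {
  cat(sprintf("<regression_slope> slope %.4g, intercept %.4g, r2 %.3f, n %d\n",
              x$slope, x$intercept, x$r2, x$n_points))
  invisible(x)
}
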
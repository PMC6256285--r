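# ROI time-series extraction and dF/F transient quantification for spine
# zinc imaging.

#' ROI fluorescence time series
#'
#' @param roi_id Identifier.
#' @param frame_times Frame times in seconds, strictly increasing.
#' @param mean_intensity Mean ROI intensity per frame.
#' @param baseline_window,stim_window,wash_window `(t0, t1)` second windows;
#'   baseline must precede the stimulus, which must precede the wash, and
#'   all must lie inside the recording.
#' @return An `roi_series` object.
#' @export
roi_series <- function(roi_id, frame_times, mean_intensity,
                       baseline_window, stim_window, wash_window) {
  if (any(diff(frame_times) <= 0))
    stop("frame times must be strictly increasing", call. = FALSE)
  if (length(frame_times) != length(mean_intensity))
    stop("one intensity per frame required", call. = FALSE)
  t0 <- frame_times[1]; t1 <- frame_times[length(frame_times)]
  for (w in list(baseline_window, stim_window, wash_window))
    if (w[1] < t0 - 1e-9 || w[2] > t1 + 1e-9)
      stop("analysis windows must lie within the recording", call. = FALSE)
  if (!(baseline_window[2] <= stim_window[1] &&
        stim_window[2] <= wash_window[1] + 1e-9))
    stop("windows must be ordered baseline < stimulus < wash",
         call. = FALSE)
  structure(list(roi_id = roi_id, frame_times = frame_times,
                 mean_intensity = mean_intensity,
                 baseline_window = baseline_window,
                 stim_window = stim_window, wash_window = wash_window),
            class = "roi_series")
}

#' Extract ROI time series from an image sequence
#'
#' Per-frame mean over each ROI box after background subtraction — the
#' standard readout for spine fluorescence from sum-projected time-lapse
#' frames.
#'
#' @param frames 3D array `(t, y, x)` or list of 2D matrices.
#' @param boxes List of 0-based inclusive `(y0, y1, x0, x1)` boxes, one per
#'   ROI; an empty box is an error.
#' @param frame_times Frame times in seconds (default frame index).
#' @param baseline_window,stim_window,wash_window Passed to [roi_series()].
#' @param background Constant background subtracted before averaging
#'   (default 0).
#' @return List of [roi_series()], one per box.
#' @export
extract_roi_timeseries <- function(frames, boxes, frame_times = NULL,
                                   baseline_window, stim_window,
                                   wash_window, background = 0) {
  if (is.list(frames)) {
    arr <- array(0, dim = c(length(frames), dim(frames[[1]])))
    for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]
    frames <- arr
  }
  d <- dim(frames)
  if (is.null(frame_times)) frame_times <- seq_len(d[1]) - 1
  lapply(seq_along(boxes), function(b) {
    box <- boxes[[b]]
    if (box[1] > box[2] || box[3] > box[4])
      stop("empty ROI box", call. = FALSE)
    if (box[1] < 0 || box[2] > d[2] - 1 || box[3] < 0 || box[4] > d[3] - 1)
      stop("ROI box exits the frame", call. = FALSE)
    vals <- vapply(seq_len(d[1]), function(t)
      mean(frames[t, (box[1]:box[2]) + 1, (box[3]:box[4]) + 1] -
             background), numeric(1))
    roi_series(b, frame_times, vals, baseline_window, stim_window,
               wash_window)
  })
}

#' dF/F transient quantification
#'
#' Computes the fractional fluorescence change relative to the pre-stimulus
#' baseline, the transient amplitude read at the first frame at or after the
#' stimulus end (the "immediately post-stimulus" frame, once solution
#' exchange is complete — a single-frame readout, so noise does not bias it
#' upward the way a max over frames would), and whether the transient
#' reversed during the wash.
#'
#' @param series An [roi_series()] with at least 3 baseline frames.
#' @param reversible_tol_sd Wash criterion: reversible when the absolute
#'   mean wash dF/F is at most this many baseline dF/F SDs (default 2).
#' @return List with `dff` (per frame), `peak_pct` (percent) and
#'   `reversible` (logical).
#' @export
dff_transient <- function(series, reversible_tol_sd = 2) {
  stopifnot(inherits(series, "roi_series"))
  t <- series$frame_times
  f <- series$mean_intensity
  base_idx <- which(t >= series$baseline_window[1] &
                      t < series$baseline_window[2])
  if (length(base_idx) < 3)
    stop("baseline window must contain at least 3 frames", call. = FALSE)
  f0 <- mean(f[base_idx])
  if (f0 <= 0) stop("baseline F0 must be positive", call. = FALSE)
  dff <- (f - f0) / f0
  post_idx <- which(t >= series$stim_window[2])[1]
  if (is.na(post_idx)) post_idx <- length(t)
  peak_pct <- 100 * dff[post_idx]
  wash_idx <- which(t >= series$wash_window[1] & t <= series$wash_window[2])
  base_sd <- sd(dff[base_idx])
  reversible <- abs(mean(dff[wash_idx])) <= reversible_tol_sd * base_sd +
    1e-12
  list(dff = dff, peak_pct = peak_pct, reversible = reversible,
       F0 = f0)
}
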
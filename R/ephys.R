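# Miniature-EPSC detection and kinetics, and evoked I/V rectification
# analysis.

#' Voltage-clamp current trace
#'
#' @param samples Current samples in pA (inward currents negative).
#' @param fs Sampling rate in Hz.
#' @param holding_potential Holding potential in mV (optional).
#' @param cell_id,condition Provenance labels (optional).
#' @param stim_time_s Stimulus time within the sweep, if any.
#' @return An `ephys_trace` object.
#' @export
ephys_trace <- function(samples, fs, holding_potential = NA_real_,
                        cell_id = NA_character_, condition = NA_character_,
                        stim_time_s = NA_real_) {
  stopifnot_scalar(fs, "fs", positive = TRUE)
  if (any(!is.finite(samples))) stop("samples must be finite", call. = FALSE)
  structure(list(samples = as.numeric(samples), fs = fs,
                 holding_potential = holding_potential, cell_id = cell_id,
                 condition = condition, stim_time_s = stim_time_s),
            class = "ephys_trace")
}

#' @export
print.ephys_trace <- function(x, ...) {
  cat(sprintf("<ephys_trace> %.3f s at %g kHz%s\n",
              length(x$samples) / x$fs, x$fs / 1000,
              if (is.na(x$holding_potential)) "" else
                sprintf(", held at %g mV", x$holding_potential)))
  invisible(x)
}

#' Write / read traces as CSV with a JSON header
#'
#' Columns `time_s` and `current_pA`; sampling rate and labels travel in a
#' JSON sidecar.
#'
#' @param trace An [ephys_trace()].
#' @param path CSV path.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "ephys_trace"))
  t <- (seq_along(trace$samples) - 1) / trace$fs
  utils::write.csv(data.frame(time_s = t, current_pA = trace$samples),
                   path, row.names = FALSE)
  jsonlite::write_json(
    list(fs = trace$fs, holding_potential = trace$holding_potential,
         cell_id = trace$cell_id, condition = trace$condition,
         stim_time_s = trace$stim_time_s),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- if (file.exists(sidecar_path(path)))
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  else list()
  fs <- meta$fs %||% (1 / median(diff(df$time_s)))
  ephys_trace(df$current_pA, fs,
              holding_potential = meta$holding_potential %||% NA_real_,
              cell_id = meta$cell_id %||% NA_character_,
              condition = meta$condition %||% NA_character_,
              stim_time_s = meta$stim_time_s %||% NA_real_)
}

#' Detect miniature synaptic events
#'
#' Template-free threshold detector for inward (negative-going) synaptic
#' currents: the trace is low-pass filtered (zero-phase Butterworth), the
#' noise SD is estimated robustly as 1.4826 x MAD of the high-pass residual
#' (raw minus low-pass), and events are deflections of the median-centred
#' filtered trace beyond `threshold_sd` noise SDs, separated by at least
#' `min_interval_ms`. The event onset is located by walking back from the
#' peak to the 10-percent-of-peak crossing.
#'
#' @param trace An [ephys_trace()] of at least 1 s (for noise estimation).
#' @param threshold_sd Detection threshold in noise SDs (default 3.5).
#' @param min_interval_ms Minimum separation between event peaks (default 5).
#' @param lp_cutoff_hz Low-pass cutoff in Hz (default 1000); requires
#'   `fs >= 2 * lp_cutoff_hz`.
#' @return Data frame of detections (`onset_s`, `peak_s`,
#'   `peak_amplitude_pA` as positive magnitudes) with the estimated
#'   `noise_sd` as an attribute.
#' @export
detect_minis <- function(trace, threshold_sd = 3.5, min_interval_ms = 5,
                         lp_cutoff_hz = 1000) {
  stopifnot(inherits(trace, "ephys_trace"))
  fs <- trace$fs
  if (fs < 2 * lp_cutoff_hz)
    stop("fs must be at least twice the low-pass cutoff", call. = FALSE)
  if (length(trace$samples) < fs)
    stop("trace must be at least 1 s long for noise estimation",
         call. = FALSE)
  bf <- signal::butter(4, lp_cutoff_hz / (fs / 2), type = "low")
  # centre before filtering: a DC offset otherwise produces filter edge
  # transients that masquerade as events
  centred <- trace$samples - median(trace$samples)
  lp <- signal::filtfilt(bf, centred)
  noise_sd <- stats::mad(centred - lp)
  det <- lp - median(lp)
  thr <- max(threshold_sd * noise_sd, 1e-8)
  below <- det < -thr
  if (!any(below)) {
    out <- data.frame(onset_s = numeric(), peak_s = numeric(),
                      peak_amplitude_pA = numeric())
    attr(out, "noise_sd") <- noise_sd
    return(out)
  }
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  regions <- cbind(starts[r$values], ends[r$values])
  peaks <- apply(regions, 1, function(rg)
    rg[1] - 1 + which.min(det[rg[1]:rg[2]]))
  depths <- -det[peaks]
  # enforce the refractory interval, keeping the deeper peak
  ord <- order(peaks)
  peaks <- peaks[ord]; depths <- depths[ord]
  min_gap <- min_interval_ms / 1000 * fs
  keep <- logical(length(peaks))
  last <- -Inf; last_i <- 0
  for (i in seq_along(peaks)) {
    if (peaks[i] - last >= min_gap) {
      keep[i] <- TRUE
      last <- peaks[i]; last_i <- i
    } else if (depths[i] > depths[last_i]) {
      keep[last_i] <- FALSE
      keep[i] <- TRUE
      last <- peaks[i]; last_i <- i
    }
  }
  peaks <- peaks[keep]; depths <- depths[keep]
  onset <- vapply(seq_along(peaks), function(i) {
    j <- peaks[i]
    lim <- -0.1 * depths[i]
    while (j > 1 && det[j] < lim) j <- j - 1
    j
  }, numeric(1))
  # secondary peaks in a decay tail walk back to the same onset: cluster
  # detections whose onsets fall within the refractory interval and keep
  # the deepest of each cluster
  ord <- order(onset)
  onset <- onset[ord]; peaks <- peaks[ord]; depths <- depths[ord]
  cluster <- cumsum(c(TRUE, diff(onset) >= min_gap))
  best <- vapply(split(seq_along(onset), cluster),
                 function(ix) ix[which.max(depths[ix])], integer(1))
  onset <- onset[best]; peaks <- peaks[best]; depths <- depths[best]
  out <- data.frame(onset_s = (onset - 1) / fs, peak_s = (peaks - 1) / fs,
                    peak_amplitude_pA = depths)
  attr(out, "noise_sd") <- noise_sd
  out
}

#' Kinetics of a single synaptic event
#'
#' Measures one event at a known onset: amplitude (baseline minus trough,
#' reported as a positive magnitude), 10-90 percent rise time, decay time
#' constant from a single-exponential fit from the peak toward baseline
#' (initial tau from the 37-percent crossing, fit window 5 x that guess; the
#' 37-percent crossing time is also reported), and charge as the integral of
#' (baseline - I) from onset to the return to baseline.
#'
#' @param trace An [ephys_trace()].
#' @param onset_s Event onset in seconds; needs `window_ms` of following
#'   context inside the trace.
#' @param window_ms Analysis window after onset (default 50 ms); truncated at
#'   `next_onset_s` when the following event overlaps.
#' @param next_onset_s Onset of the next event, if any.
#' @return One-row data frame: `onset_s`, `baseline_pA`,
#'   `peak_amplitude_pA`, `rise_time_10_90_ms`, `decay_tau_ms`,
#'   `decay_t37_ms`, `charge_pA_ms`. A failed decay fit gives `NA` tau with
#'   the event retained.
#' @export
event_kinetics <- function(trace, onset_s, window_ms = 50,
                           next_onset_s = NULL) {
  stopifnot(inherits(trace, "ephys_trace"))
  fs <- trace$fs
  x <- trace$samples
  i_on <- floor(onset_s * fs) + 1
  win_end <- i_on + round(window_ms / 1000 * fs)
  if (!is.null(next_onset_s) && is.finite(next_onset_s))
    win_end <- min(win_end, floor(next_onset_s * fs))
  if (i_on < 1 || win_end > length(x))
    stop("event window extends beyond the trace", call. = FALSE)
  b0 <- max(1, i_on - round(0.002 * fs))
  baseline <- mean(x[b0:max(b0, i_on - 1)])  # up to, not including, onset
  seg <- x[i_on:win_end]
  tseg <- (seq_along(seg) - 1) / fs * 1000  # ms from onset
  ipk <- which.min(seg)
  amp <- baseline - seg[ipk]
  y <- baseline - seg  # positive-going event
  # 10-90% rise by linear interpolation on the rising limb
  rise <- NA_real_
  if (ipk > 1 && amp > 0) {
    t10 <- crossing_time(tseg[1:ipk], y[1:ipk], 0.1 * amp)
    t90 <- crossing_time(tseg[1:ipk], y[1:ipk], 0.9 * amp)
    rise <- t90 - t10
  }
  # decay: 37% crossing and single-exponential tau
  decay_tau <- NA_real_
  t37 <- NA_real_
  if (ipk < length(y) && amp > 0) {
    post <- y[ipk:length(y)]
    tpost <- tseg[ipk:length(y)] - tseg[ipk]
    below <- which(post < 0.37 * amp)
    if (length(below) > 0) {
      j <- below[1]
      t37 <- crossing_time(tpost[max(1, j - 1):j],
                           post[max(1, j - 1):j], 0.37 * amp,
                           falling = TRUE)
      fit_end <- min(length(post), ceiling(5 * t37 / 1000 * fs) + 1)
      # start one onset-to-peak delay after the peak, where the rising
      # exponential has died away and the tail is single-exponential
      fit_start <- min(ipk, max(1, fit_end - 4))
      if (fit_end - fit_start + 1 >= 4) {
        df <- data.frame(t = tpost[fit_start:fit_end],
                         y = post[fit_start:fit_end])
        fit <- tryCatch(
          minpack.lm::nlsLM(y ~ A * exp(-t / tau), data = df,
                            start = list(A = amp, tau = max(t37, 0.1)),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 100)),
          error = function(e) NULL)
        if (!is.null(fit)) decay_tau <- coef(fit)[["tau"]]
      }
    }
  }
  # charge: onset to first return to baseline after the peak
  ret <- which(y[ipk:length(y)] <= 0)
  iend <- if (length(ret) > 0) ipk + ret[1] - 1 else length(y)
  charge <- trapz(tseg[1:iend], pmax(y[1:iend], 0))
  data.frame(onset_s = onset_s, baseline_pA = baseline,
             peak_amplitude_pA = amp, rise_time_10_90_ms = rise,
             decay_tau_ms = decay_tau, decay_t37_ms = t37,
             charge_pA_ms = charge)
}

# First time y crosses `level` (first y >= level, or first y < level when
# falling), linearly interpolated between the bracketing samples.
crossing_time <- function(t, y, level, falling = FALSE) {
  idx <- if (falling) which(y < level) else which(y >= level)
  if (length(idx) == 0) return(NA_real_)
  i <- idx[1]
  if (i == 1) return(t[1])
  y0 <- y[i - 1]; y1 <- y[i]
  if (y1 == y0) return(t[i])
  t[i - 1] + (level - y0) / (y1 - y0) * (t[i] - t[i - 1])
}

#' Detect events and measure their kinetics
#'
#' Convenience wrapper running [detect_minis()] then [event_kinetics()] per
#' detection, truncating each analysis window at the next event.
#'
#' @inheritParams detect_minis
#' @param ... Passed to [detect_minis()].
#' @return Data frame of per-event kinetics (a mini-event table).
#' @export
analyze_minis <- function(trace, ...) {
  det <- detect_minis(trace, ...)
  if (nrow(det) == 0) return(det)
  nxt <- c(det$onset_s[-1], NA_real_)
  max_on <- (length(trace$samples) - 1) / trace$fs - 0.051
  rows <- lapply(seq_len(nrow(det)), function(i) {
    if (det$onset_s[i] > max_on) return(NULL)
    event_kinetics(trace, det$onset_s[i], next_onset_s = nxt[i])
  })
  out <- do.call(rbind, rows)
  attr(out, "noise_sd") <- attr(det, "noise_sd")
  out
}

#' Ensemble average of onset-aligned events
#'
#' Pointwise mean of baseline-subtracted snippets aligned at their onsets.
#'
#' @param trace An [ephys_trace()].
#' @param onsets_s Event onsets in seconds (>= 1).
#' @param pre_ms,post_ms Snippet extent around the onset.
#' @return List with `time_ms` (relative to onset), `mean_pA` and `n`.
#' @export
ensemble_average <- function(trace, onsets_s, pre_ms = 5, post_ms = 50) {
  stopifnot(inherits(trace, "ephys_trace"))
  if (length(onsets_s) < 1) stop("at least one event required",
                                 call. = FALSE)
  fs <- trace$fs
  npre <- round(pre_ms / 1000 * fs)
  npost <- round(post_ms / 1000 * fs)
  x <- trace$samples
  keep <- onsets_s * fs - npre >= 0 &
    onsets_s * fs + npost <= length(x) - 1
  onsets_s <- onsets_s[keep]
  snips <- vapply(onsets_s, function(on) {
    i0 <- floor(on * fs) + 1
    snip <- x[(i0 - npre):(i0 + npost)]
    snip - mean(snip[1:max(npre, 1)])
  }, numeric(npre + npost + 1))
  list(time_ms = (seq_len(npre + npost + 1) - npre - 1) / fs * 1000,
       mean_pA = rowMeans(snips), n = length(onsets_s))
}

#' Liquid junction potential correction
#'
#' @param command_potentials Command potentials in mV (vectorised).
#' @param ljp_mv Liquid junction potential in mV (default 18).
#' @return `command_potentials - ljp_mv`.
#' @export
correct_junction_potential <- function(command_potentials, ljp_mv = 18) {
  command_potentials - ljp_mv
}

#' Rectification analysis of an evoked I/V family
#'
#' Builds the current/voltage relation from one sweep per holding potential
#' and computes the rectification index, defined as the ratio of the I/V
#' regression slope over the hyperpolarized (negative) branch to the slope
#' over the depolarized (positive) branch, with the branch split at the
#' interpolated reversal potential. The peak current of each sweep is the
#' mean of samples in a symmetric window about the peak (default +/- 1.5 ms),
#' constrained to 3-6 ms after the stimulus when a stimulus time is known;
#' alternatively the plain 3-6 ms post-stimulus average can be selected.
#'
#' @param sweeps List of [ephys_trace()] objects, each with a holding
#'   potential (and ideally a stimulus time).
#' @param potentials Optional holding potentials overriding those in the
#'   sweeps (mV; pass junction-corrected values, see
#'   [correct_junction_potential()]).
#' @param peak_window_ms Post-stimulus band for the peak measurement
#'   (default `c(3, 6)`).
#' @param window_mode `"about_peak"` (default: +/- half of
#'   `peak_halfwidth_ms` around the detected peak, clipped to the band) or
#'   `"post_stim"` (average over the whole band).
#' @param peak_halfwidth_ms Half-width of the peak window (default 1.5).
#' @return An `iv_analysis` list: `potentials`, `peak_currents`,
#'   `normalized_currents` (relative to the most negative potential),
#'   `v_rev_est`, `slope_neg`, `slope_pos` (nS) and `RI`. `RI` is `NA` when
#'   a branch has fewer than 2 points.
#' @export
rectification_analysis <- function(sweeps, potentials = NULL,
                                   peak_window_ms = c(3, 6),
                                   window_mode = c("about_peak",
                                                   "post_stim"),
                                   peak_halfwidth_ms = 1.5) {
  window_mode <- match.arg(window_mode)
  if (is.null(potentials))
    potentials <- vapply(sweeps, function(s) s$holding_potential, numeric(1))
  if (any(is.na(potentials)))
    stop("holding potentials are required for every sweep", call. = FALSE)
  peaks <- vapply(seq_along(sweeps), function(i) {
    tr <- sweeps[[i]]
    fs <- tr$fs
    x <- tr$samples
    stim <- tr$stim_time_s
    if (is.na(stim)) stim <- 0
    i_stim <- floor(stim * fs) + 1
    baseline <- mean(x[1:max(i_stim - 1, 1)])
    resp <- x - baseline
    band <- i_stim + round(peak_window_ms / 1000 * fs)
    band[2] <- min(band[2], length(x))
    if (window_mode == "post_stim") return(mean(resp[band[1]:band[2]]))
    # peak located inside the post-stimulus band, averaged over a symmetric
    # window clipped to that band
    ipk <- band[1] - 1 + which.max(abs(resp[band[1]:band[2]]))
    half <- round(peak_halfwidth_ms / 1000 * fs)
    w0 <- max(ipk - half, band[1])
    w1 <- min(ipk + half, band[2])
    mean(resp[w0:w1])
  }, numeric(1))
  ord <- order(potentials)
  v <- potentials[ord]; i_pk <- peaks[ord]
  # reversal by linear interpolation of the zero crossing
  sgn <- sign(i_pk)
  cross <- which(sgn[-length(sgn)] <= 0 & sgn[-1] > 0)
  if (length(cross) == 0)
    stop("I/V does not cross zero: potentials must span the reversal",
         call. = FALSE)
  k <- cross[1]
  v_rev <- if (i_pk[k] == 0) v[k] else
    v[k] + (0 - i_pk[k]) / (i_pk[k + 1] - i_pk[k]) * (v[k + 1] - v[k])
  neg <- v < v_rev
  pos <- v > v_rev
  slope_neg <- if (sum(neg) >= 2) ols_slope(v[neg], i_pk[neg]) else NA_real_
  slope_pos <- if (sum(pos) >= 2) ols_slope(v[pos], i_pk[pos]) else NA_real_
  ri <- if (is.na(slope_neg) || is.na(slope_pos)) NA_real_ else
    slope_neg / slope_pos
  norm <- i_pk / abs(i_pk[1])
  structure(list(potentials = v, peak_currents = i_pk,
                 normalized_currents = norm, v_rev_est = v_rev,
                 slope_neg = slope_neg, slope_pos = slope_pos, RI = ri),
            class = "iv_analysis")
}

#' @export
print.iv_analysis <- function(x, ...) {
  cat(sprintf(
    "<iv_analysis> %d potentials, v_rev ~ %.2f mV, RI = %.3f (neg %.3f / pos %.3f nS)\n",
    length(x$potentials), x$v_rev_est, x$RI, x$slope_neg, x$slope_pos))
  invisible(x)
}

#' Series-resistance quality control
#'
#' A recording fails when the series resistance rises by more than 20
#' percent over its initial value.
#'
#' @param rs_track Series resistance readings in megaohms over time (>= 2).
#' @param max_increase Allowed fractional increase (default 0.20).
#' @return `"pass"` or `"fail"`.
#' @export
qc_series_resistance <- function(rs_track, max_increase = 0.20) {
  if (length(rs_track) < 2) stop("need at least 2 Rs readings",
                                 call. = FALSE)
  if (any(rs_track <= 0)) stop("Rs readings must be positive", call. = FALSE)
  if (max(rs_track) / rs_track[1] > 1 + max_increase) "fail" else "pass"
}
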
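# Ground-truthed synthetic fluorescence data: two-channel dendrite stacks
# with controlled colocalization, and spine time-lapses with a
# depolarization-locked transient. Generators are exact bookkeepers: every
# rendered punctum / transient is returned as ground truth, nothing is
# estimated.

#' Synthetic two-channel dendrite stack with known puncta
#'
#' Renders two channels of fluorescent puncta scattered along a dendrite
#' shaft and its spine heads, with a programmed fraction of channel-A puncta
#' coincident with a channel-B punctum. Puncta are 3D Gaussians (sigma =
#' radius / 2) allowing sub-voxel positioning; the stack is then blurred with
#' a Gaussian PSF, optionally Poisson-resampled (camera shot noise) and
#' finally Gaussian read noise is added. Coincident partners are jittered at
#' most one voxel from each other; all other inter-punctum distances respect
#' `min_separation_um`, so programmed coincidence is the only source of
#' overlap.
#'
#' @param length_um Dendrite length in micrometres (default 40).
#' @param spine_count Number of spines along the dendrite (default 10).
#' @param n_puncta Puncta per channel, `c(A = , B = )` or a scalar used for
#'   both (default 30).
#' @param amplitude Mean peak intensity per punctum before blur (arbitrary
#'   photon-scale units, default 150).
#' @param amplitude_cv Lognormal coefficient of variation of amplitudes
#'   (default 0.2).
#' @param radius_um Mean punctum radius in micrometres (default 0.35).
#' @param radius_cv Lognormal CV of radii (default 0.1).
#' @param coincidence Target fraction of channel-A puncta with a coincident
#'   channel-B partner, in `[0, 1]`. Exactly `round(coincidence * n_A)`
#'   coincident pairs are created.
#' @param psf_sigma_um Gaussian PSF sigma in micrometres; scalar (isotropic
#'   in physical units) or `(z, y, x)` vector. 0 disables blurring.
#' @param noise_sd Gaussian noise SD added after rendering (default 0).
#' @param poisson Apply Poisson resampling of the signal before Gaussian
#'   noise (default FALSE).
#' @param voxel_size `(dz, dy, dx)` in micrometres, default `c(0.3, 0.1,
#'   0.1)`.
#' @param min_separation_um Minimum distance between non-partner punctum
#'   centers in micrometres (default 1).
#' @param seed Integer seed; with the seed fixed the output is
#'   bit-reproducible.
#' @return A list with `stack` (two-channel [image_stack()]), `truth` (per
#'   channel data frames of centers in 0-based voxel coordinates,
#'   amplitudes, radii and symmetric `coincident_with` links), and
#'   `n_coincident`.
#' @export
gen_dendrite_stack <- function(length_um = 40, spine_count = 10,
                               n_puncta = 30, amplitude = 150,
                               amplitude_cv = 0.2, radius_um = 0.35,
                               radius_cv = 0.1, coincidence = 0.5,
                               psf_sigma_um = 0.2, noise_sd = 0,
                               poisson = FALSE,
                               voxel_size = c(0.3, 0.1, 0.1),
                               min_separation_um = 1, seed = NULL) {
  if (coincidence < 0 || coincidence > 1)
    stop("coincidence must be in [0, 1]", call. = FALSE)
  if (length(n_puncta) == 1L) n_puncta <- c(A = n_puncta, B = n_puncta)
  n_a <- as.integer(n_puncta[[1]]); n_b <- as.integer(n_puncta[[2]])
  n_c <- round(coincidence * n_a)
  if (n_c > n_b) stop("coincident pairs exceed channel-B puncta count",
                      call. = FALSE)
  margin_um <- 0.8
  nz <- 9L
  ny <- as.integer(ceiling(5 / voxel_size[2]))
  nx <- as.integer(ceiling((length_um + 2 * margin_um) / voxel_size[3]))
  # rough capacity check before attempting placement; the shaft offers about
  # three lateral lanes at the minimum separation, plus one site per spine
  capacity <- 3 * length_um / min_separation_um + spine_count
  if (n_a + n_b - n_c > capacity)
    stop("dendrite geometry too small for the requested puncta count",
         call. = FALSE)
  with_seed(seed, {
    z0 <- (nz - 1) / 2 * voxel_size[1]
    y0 <- (ny - 1) / 2 * voxel_size[2]
    spine_x <- runif(spine_count, margin_um, margin_um + length_um)
    spine_side <- rep_len(c(1, -1), spine_count)
    spine_dy <- runif(spine_count, 1.1, 1.5) * spine_side
    draw_center <- function() {
      on_spine <- spine_count > 0 && runif(1) < 0.25
      if (on_spine) {
        s <- sample.int(spine_count, 1)
        c(z0 + runif(1, -0.3, 0.3),
          y0 + spine_dy[s] + runif(1, -0.15, 0.15),
          spine_x[s] + runif(1, -0.15, 0.15))
      } else {
        c(z0 + runif(1, -0.45, 0.45), y0 + runif(1, -1, 1),
          runif(1, margin_um, margin_um + length_um))
      }
    }
    place <- function(n, existing) {
      out <- matrix(NA_real_, n, 3)
      k <- 0L; tries <- 0L
      while (k < n) {
        tries <- tries + 1L
        if (tries > 20000L + 2000L * n)
          stop("dendrite geometry too small for the requested puncta count",
               call. = FALSE)
        p <- draw_center()
        all_pts <- rbind(existing, out[seq_len(k), , drop = FALSE])
        if (nrow(all_pts) > 0) {
          dmin <- min(sqrt(colSums((t(all_pts) - p)^2)))
          if (dmin < min_separation_um) next
        }
        k <- k + 1L
        out[k, ] <- p
      }
      out
    }
    centers_a <- place(n_a, matrix(numeric(0), 0, 3))
    # coincident partners: first n_c A puncta, jitter <= 1 voxel
    partners <- matrix(NA_real_, 0, 3)
    if (n_c > 0) {
      jitter <- matrix(runif(n_c * 3, -0.5, 0.5), n_c, 3) *
        matrix(voxel_size, n_c, 3, byrow = TRUE)
      partners <- centers_a[seq_len(n_c), , drop = FALSE] + jitter
    }
    free_b <- place(n_b - n_c, rbind(centers_a, partners))
    centers_b <- rbind(partners, free_b)
    truth <- list(
      A = data.frame(id = seq_len(n_a),
                     z = centers_a[, 1] / voxel_size[1],
                     y = centers_a[, 2] / voxel_size[2],
                     x = centers_a[, 3] / voxel_size[3],
                     amplitude = rlnorm2(n_a, amplitude, amplitude_cv),
                     radius_um = rlnorm2(n_a, radius_um, radius_cv),
                     coincident_with = c(seq_len(n_c),
                                         rep(NA_integer_, n_a - n_c))),
      B = data.frame(id = seq_len(n_b),
                     z = centers_b[, 1] / voxel_size[1],
                     y = centers_b[, 2] / voxel_size[2],
                     x = centers_b[, 3] / voxel_size[3],
                     amplitude = rlnorm2(n_b, amplitude, amplitude_cv),
                     radius_um = rlnorm2(n_b, radius_um, radius_cv),
                     coincident_with = c(seq_len(n_c),
                                         rep(NA_integer_, n_b - n_c))))
    render <- function(df) {
      vol <- array(0, dim = c(nz, ny, nx))
      for (i in seq_len(nrow(df)))
        vol <- add_gaussian_punctum(vol, c(df$z[i], df$y[i], df$x[i]),
                                    df$amplitude[i],
                                    df$radius_um[i] / 2 / voxel_size)
      if (any(psf_sigma_um > 0)) {
        sig <- rep(psf_sigma_um, length.out = 3) / voxel_size
        vol <- gauss_blur3d(vol, sig)
      }
      if (poisson) {
        vol[] <- rpois(length(vol), pmax(vol, 0))
      }
      if (noise_sd > 0) vol <- vol + rnorm(length(vol), 0, noise_sd)
      pmax(vol, 0)
    }
    vox <- array(0, dim = c(nz, ny, nx, 2))
    vox[, , , 1] <- render(truth$A)
    vox[, , , 2] <- render(truth$B)
    list(stack = image_stack(vox, voxel_size, c("A", "B")),
         truth = truth, n_coincident = n_c,
         dendrite_length_um = length_um)
  })
}

# Lognormal draws parameterised by mean and coefficient of variation.
rlnorm2 <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# Add one 3D Gaussian blob (sigma per axis in voxels) truncated at 3 sigma.
add_gaussian_punctum <- function(vol, center, amplitude, sigma_vox) {
  d <- dim(vol)
  lo <- pmax(floor(center - 3 * sigma_vox), 0)
  hi <- pmin(ceiling(center + 3 * sigma_vox), d - 1)
  if (any(lo > hi)) return(vol)
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  gz <- exp(-(zi - center[1])^2 / (2 * sigma_vox[1]^2))
  gy <- exp(-(yi - center[2])^2 / (2 * sigma_vox[2]^2))
  gx <- exp(-(xi - center[3])^2 / (2 * sigma_vox[3]^2))
  blob <- amplitude * outer(outer(gz, gy), gx)
  blob[blob < amplitude * exp(-4.5)] <- 0
  vol[zi + 1, yi + 1, xi + 1] <- vol[zi + 1, yi + 1, xi + 1] + blob
  vol
}

#' Synthetic spine fluorescence time-lapse
#'
#' Emulates zinc-indicator imaging of dendritic spines during a brief
#' high-potassium depolarization: frames every `frame_interval` seconds, a
#' stable baseline, a stimulus-locked plateau of `transient_pct` percent
#' above baseline that persists through the first frame after the stimulus
#' window (full solution exchange), and complete washout back to baseline.
#'
#' @param n_spines Number of spine ROIs (default 17).
#' @param baseline_F0 Baseline fluorescence per ROI (arbitrary units).
#' @param transient_pct Plateau amplitude as percent dF/F0 (default 50).
#' @param stim_window `(t0, t1)` in seconds of the depolarization.
#' @param frame_interval Seconds between frames; must lie in `[40, 60]`.
#' @param duration Total recording length in seconds (default 900).
#' @param noise_sd_frac Gaussian noise SD as a fraction of `baseline_F0`.
#' @param seed Integer seed.
#' @return A list with `series` (a list of [roi_series()]) and `truth`
#'   (per-ROI programmed peak dF/F0 percent).
#' @export
gen_spine_timelapse <- function(n_spines = 17, baseline_F0 = 100,
                                transient_pct = 50,
                                stim_window = c(300, 450),
                                frame_interval = 50, duration = 900,
                                noise_sd_frac = 0, seed = NULL) {
  if (frame_interval < 40 || frame_interval > 60)
    stop("frame_interval must lie in [40, 60] seconds", call. = FALSE)
  if (stim_window[1] < 0 || stim_window[2] > duration ||
      stim_window[1] >= stim_window[2])
    stop("stimulus window must lie inside the recording", call. = FALSE)
  times <- seq(0, duration, by = frame_interval)
  if (!any(times < stim_window[1]))
    stop("no baseline frames before the stimulus", call. = FALSE)
  post_idx <- which(times >= stim_window[2])[1]
  if (is.na(post_idx)) stop("recording ends before stimulus washout",
                            call. = FALSE)
  plateau_until <- times[post_idx]
  clean <- ifelse(times >= stim_window[1] & times <= plateau_until,
                  baseline_F0 * (1 + transient_pct / 100), baseline_F0)
  wash_start <- min(plateau_until + 2 * frame_interval, duration)
  with_seed(seed, {
    series <- lapply(seq_len(n_spines), function(i) {
      f <- clean
      if (noise_sd_frac > 0)
        f <- f + rnorm(length(f), 0, noise_sd_frac * baseline_F0)
      roi_series(roi_id = i, frame_times = times, mean_intensity = f,
                 baseline_window = c(0, stim_window[1]),
                 stim_window = stim_window,
                 wash_window = c(wash_start, duration))
    })
    list(series = series,
         truth = data.frame(roi_id = seq_len(n_spines),
                            peak_dff_pct = transient_pct,
                            baseline_F0 = baseline_F0))
  })
}
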
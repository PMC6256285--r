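# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2)
}

#' Otsu intensity threshold
#'
#' Histogram-based threshold maximising between-class variance, used as the
#' default frozen per-channel threshold for puncta segmentation when no manual
#' value is supplied.
#'
#' @param x Numeric vector or array of intensities.
#' @param n_bins Number of histogram bins (default 256).
#' @return A single threshold on the intensity scale of `x`.
#' @export
threshold_otsu <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

#' Robust background threshold
#'
#' Background-statistics threshold for sparse punctate images: median plus
#' `k` robust SDs of the whole image, which tracks the noise floor when
#' puncta occupy a small fraction of the volume. The SD is estimated as the
#' distance from the median to the 84.1st percentile (one Gaussian SD),
#' which stays valid when the background is clipped at zero — the case where
#' the MAD collapses. Falls back to [threshold_otsu()] for images with no
#' background spread (e.g. noiseless renders).
#'
#' @param x Numeric vector or array of intensities.
#' @param k Number of robust SDs above the background median (default 5).
#' @return A single threshold on the intensity scale of `x`.
#' @export
threshold_background <- function(x, k = 5) {
  med <- median(x)
  sigma <- quantile(x, 0.841, names = FALSE) - med
  if (sigma <= 0) return(threshold_otsu(x))
  med + k * sigma
}

# Difference-of-exponentials synaptic-current template, normalised to unit
# peak. `t` in seconds, taus in seconds. Zero before onset.
biexp_template <- function(t, rise_tau, decay_tau) {
  if (decay_tau <= rise_tau)
    stop("decay_tau must exceed rise_tau", call. = FALSE)
  v <- ifelse(t < 0, 0, exp(-t / decay_tau) - exp(-t / rise_tau))
  t_peak <- rise_tau * decay_tau / (decay_tau - rise_tau) *
    log(decay_tau / rise_tau)
  peak <- exp(-t_peak / decay_tau) - exp(-t_peak / rise_tau)
  v / peak
}
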
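# Preprocessing chain applied before puncta analysis: rolling-ball background
# subtraction, dendrite straightening, optional deconvolution stand-in.

#' Rolling-ball background subtraction
#'
#' Estimates a smooth background as the grayscale morphological opening with a
#' disc structuring element of the given radius (the de-facto ImageJ
#' rolling-ball semantics, radius in pixels) and subtracts it. 3D inputs are
#' processed slice-by-slice in z, channels independently.
#'
#' @param x A `(y, x)` matrix, `(z, y, x)` array or `image_stack`.
#' @param radius_px Ball radius in pixels; must be >= 1 and fit inside the
#'   image plane. Default 50.
#' @return Same shape and class as `x`; voxelwise `0 <= out <= x`.
#' @export
subtract_background_rolling_ball <- function(x, radius_px = 50) {
  stopifnot_scalar(radius_px, "radius_px")
  if (radius_px < 1) stop("radius_px must be >= 1", call. = FALSE)
  if (inherits(x, "image_stack")) {
    out <- x
    d <- dim(x$voxels)
    for (ch in seq_len(d[4])) for (z in seq_len(d[1]))
      out$voxels[z, , , ch] <-
        rolling_ball_2d(x$voxels[z, , , ch], radius_px)
    return(out)
  }
  nd <- length(dim(x))
  if (is.matrix(x)) return(rolling_ball_2d(x, radius_px))
  if (nd == 3L) {
    out <- x
    for (z in seq_len(dim(x)[1])) out[z, , ] <- rolling_ball_2d(x[z, , ],
                                                                radius_px)
    return(out)
  }
  stop("unsupported input type", call. = FALSE)
}

rolling_ball_2d <- function(img, radius_px) {
  size <- 2L * as.integer(radius_px) + 1L
  if (size > min(dim(img)))
    stop("rolling-ball radius exceeds image extent", call. = FALSE)
  m <- max(img)
  if (m <= 0) return(img)
  kern <- EBImage::makeBrush(size, shape = "disc")
  # EBImage grayscale morphology clips to [0, 1]: normalise and restore
  bg <- as.matrix(EBImage::opening(img / m, kern)) * m
  pmax(img - bg, 0)
}

#' Dendrite path for straightening
#'
#' @param points Matrix (or list of pairs) of ordered `(y, x)` pixel
#'   coordinates (0-based) tracing the dendrite midline.
#' @param width Across-path width of the straightened image, in pixels.
#' @param dx Pixel size along x in micrometres, used to report the physical
#'   path length.
#' @return A `dendrite_path` with the derived `length_um`.
#' @export
dendrite_path <- function(points, width, dx = NULL) {
  points <- do.call(rbind, lapply(seq_len(NROW(points)), function(i)
    as.numeric(points[i, ])))
  if (nrow(points) < 2L) stop("a path needs at least 2 points", call. = FALSE)
  if (width < 1) stop("width must be >= 1 pixel", call. = FALSE)
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  structure(list(points = points, width = as.integer(width),
                 length_px = sum(seg),
                 length_um = if (is.null(dx)) NA_real_ else sum(seg) * dx),
            class = "dendrite_path")
}

#' Straighten a dendrite along a polyline path
#'
#' Resamples the image at 1-pixel steps along the path and along its local
#' normal with bilinear interpolation, producing an axis-aligned straightened
#' image of the dendrite (the ImageJ Straighten behaviour, close enough for
#' ratio metrics).
#'
#' @param image A `(y, x)` matrix, or a 3D `(z, y, x)` array (straightened
#'   slice-wise).
#' @param path A [dendrite_path()].
#' @return Matrix of dimension `width x (round(L) + 1)` where `L` is the path
#'   length in pixels; rows run across the dendrite, columns along it.
#' @export
straighten_dendrite <- function(image, path) {
  stopifnot(inherits(path, "dendrite_path"))
  if (length(dim(image)) == 3L) {
    slices <- lapply(seq_len(dim(image)[1]), function(z)
      straighten_dendrite(image[z, , ], path))
    out <- array(0, dim = c(length(slices), dim(slices[[1]])))
    for (z in seq_along(slices)) out[z, , ] <- slices[[z]]
    return(out)
  }
  pts <- path$points
  seg <- cbind(pts[-1, 1] - pts[-nrow(pts), 1],
               pts[-1, 2] - pts[-nrow(pts), 2])
  seg_len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  s <- seq(0, round(total), by = 1)
  # position and unit tangent at each arc-length sample
  idx <- pmin(findInterval(pmin(s, total), cum, rightmost.closed = TRUE),
              nrow(seg))
  frac <- (pmin(s, total) - cum[idx]) / seg_len[idx]
  py <- pts[idx, 1] + frac * seg[idx, 1]
  px <- pts[idx, 2] + frac * seg[idx, 2]
  ty <- seg[idx, 1] / seg_len[idx]
  tx <- seg[idx, 2] / seg_len[idx]
  offs <- seq_len(path$width) - (path$width + 1) / 2
  qy <- outer(offs, tx) + matrix(py, nrow = length(offs), ncol = length(s),
                                 byrow = TRUE)
  qx <- outer(offs, -ty) + matrix(px, nrow = length(offs), ncol = length(s),
                                  byrow = TRUE)
  eps <- 1e-9
  if (any(qy < -eps) || any(qy > nrow(image) - 1 + eps) ||
      any(qx < -eps) || any(qx > ncol(image) - 1 + eps))
    stop("path (plus width) exits the image bounds", call. = FALSE)
  out <- bilinear_sample(image, qy, qx)
  dim(out) <- dim(qy)
  pmax(out, 0)
}

# Bilinear interpolation at 0-based continuous (y, x) positions.
bilinear_sample <- function(img, y, x) {
  ny <- nrow(img); nx <- ncol(img)
  y <- pmin(pmax(as.vector(y), 0), ny - 1)
  x <- pmin(pmax(as.vector(x), 0), nx - 1)
  y0 <- pmin(floor(y), ny - 2); x0 <- pmin(floor(x), nx - 2)
  y0 <- pmax(y0, 0); x0 <- pmax(x0, 0)
  fy <- y - y0; fx <- x - x0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1); i11 <- cbind(y0 + 2, x0 + 2)
  img[i00] * (1 - fy) * (1 - fx) + img[i01] * (1 - fy) * fx +
    img[i10] * fy * (1 - fx) + img[i11] * fy * fx
}

#' Richardson-Lucy deconvolution (stand-in)
#'
#' Iterative Richardson-Lucy restoration against a Gaussian PSF. This is a
#' stand-in for the commercial CMLE deconvolution used in many imaging
#' pipelines: same intent (restoring puncta contrast), not the same
#' implementation, and it is off by default in the analysis pipeline.
#'
#' @param x 3D array `(z, y, x)` or `image_stack`.
#' @param psf_sigma Gaussian PSF sigma in micrometres (scalar, isotropic in
#'   physical units) when `voxel_size` is known, else in voxels.
#' @param iterations Number of RL iterations, >= 1.
#' @param voxel_size `(dz, dy, dx)` in um; required for arrays when
#'   `psf_sigma` is in micrometres. Taken from the stack otherwise.
#' @return Restored input of the same shape; nonnegative, total intensity
#'   conserved to within about 1 percent.
#' @export
deconvolve_stand_in <- function(x, psf_sigma, iterations = 10L,
                                voxel_size = NULL) {
  stopifnot_scalar(psf_sigma, "psf_sigma", positive = TRUE)
  if (iterations < 1) stop("iterations must be >= 1", call. = FALSE)
  if (inherits(x, "image_stack")) {
    out <- x
    for (ch in seq_len(dim(x$voxels)[4]))
      out$voxels[, , , ch] <- deconvolve_stand_in(
        x$voxels[, , , ch, drop = TRUE], psf_sigma, iterations,
        voxel_size = x$voxel_size)
    return(out)
  }
  sig <- if (is.null(voxel_size)) rep(psf_sigma, 3) else psf_sigma / voxel_size
  obs <- pmax(x, 0)
  est <- obs
  eps <- 1e-12
  # boundary weight: in-bounds kernel mass per voxel, so flux lost over the
  # image edge is accounted for (the blur itself renormalises at borders)
  w <- boundary_weight(dim(obs), sig)
  for (i in seq_len(iterations)) {
    blurred <- w * gauss_blur3d(est, sig)
    ratio <- obs / pmax(blurred, eps)
    est <- est * gauss_blur3d(ratio, sig)
  }
  est
}

# Separable in-bounds Gaussian kernel mass for each voxel of a (z,y,x) grid.
boundary_weight <- function(dims, sigma) {
  axis_w <- function(len, s) {
    if (s <= 0 || len == 1) return(rep(1, len))
    r <- ceiling(3 * s)
    k <- exp(-0.5 * (-r:r)^2 / s^2)
    k <- k / sum(k)
    vapply(seq_len(len), function(i) {
      lo <- max(-r, 1 - i); hi <- min(r, len - i)
      sum(k[(lo:hi) + r + 1])
    }, numeric(1))
  }
  outer(outer(axis_w(dims[1], sigma[1]), axis_w(dims[2], sigma[2])),
        axis_w(dims[3], sigma[3]))
}

# Separable Gaussian blur of a 3D (z,y,x) array; sigma per axis in voxels.
gauss_blur3d <- function(arr, sigma) {
  d <- dim(arr)
  out <- .gauss_blur3d_cpp(as.numeric(arr), as.integer(d), as.numeric(sigma))
  dim(out) <- d
  out
}
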
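#' Multi-channel 3D image stack
#'
#' The substrate of all imaging operations: a channel-resolved voxel grid with
#' a physical voxel size. Voxels are stored as a 4D array with
#' `dim = c(nz, ny, nx, n_channels)`; all coordinates in this package are
#' 0-based `(z, y, x)` with half-open ranges.
#'
#' @param voxels 3D array `(z, y, x)` (single channel) or 4D array
#'   `(z, y, x, channel)` of nonnegative intensities.
#' @param voxel_size Numeric length-3 `(dz, dy, dx)` in micrometres, all > 0.
#' @param channel_names Optional character vector, one per channel.
#' @param bit_depth 8 or 16; governs the integer range used on disk.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, voxel_size, channel_names = NULL,
                        bit_depth = 16L) {
  if (length(dim(voxels)) == 3L) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 4L)
    stop("`voxels` must be a 3D or 4D array", call. = FALSE)
  if (any(voxels < 0)) stop("intensities must be nonnegative", call. = FALSE)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be 3 strictly positive values (dz, dy, dx) in um",
         call. = FALSE)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16",
                                       call. = FALSE)
  nc <- dim(voxels)[4]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc)
    stop("one channel name per channel required", call. = FALSE)
  structure(list(voxels = voxels, voxel_size = as.numeric(voxel_size),
                 channel_names = as.character(channel_names),
                 bit_depth = as.integer(bit_depth)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<image_stack> %d channel(s) [%s], %d x %d x %d (z,y,x), voxel %s um, %d-bit\n",
    d[4], paste(x$channel_names, collapse = ", "), d[1], d[2], d[3],
    paste(signif(x$voxel_size, 3), collapse = " x "), x$bit_depth))
  invisible(x)
}

#' Extract one channel of a stack as a 3D array
#'
#' @param stack An `image_stack`.
#' @param channel Channel index or name.
#' @return 3D numeric array `(z, y, x)`.
#' @export
get_channel <- function(stack, channel = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.character(channel)) {
    channel <- match(channel, stack$channel_names)
    if (is.na(channel)) stop("unknown channel name", call. = FALSE)
  }
  stack$voxels[, , , channel, drop = TRUE]
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read image stacks as multi-page TIFF
#'
#' Stacks are written as ImageJ-style multi-page TIFFs with pages ordered
#' z-major and channels interleaved within each z plane (c1z1, c2z1, c1z2,
#' ...). Voxel size, channel names and bit depth travel in a JSON sidecar
#' (`<path>.json`) because baseline TIFF has no reliable slot for them.
#' Integer data round-trips losslessly.
#'
#' @param stack An `image_stack`.
#' @param path Output TIFF path.
#' @return `write_stack` returns `path` invisibly; `read_stack` returns an
#'   `image_stack`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  maxval <- 2^stack$bit_depth - 1
  v <- round(stack$voxels)
  if (any(v > maxval))
    stop(sprintf("intensities exceed %d-bit range", stack$bit_depth),
         call. = FALSE)
  pages <- vector("list", d[1] * d[4])
  k <- 1L
  for (z in seq_len(d[1])) {
    for (ch in seq_len(d[4])) {
      pages[[k]] <- v[z, , , ch] / maxval
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth)
  jsonlite::write_json(
    list(voxel_size = stack$voxel_size, channel_names = stack$channel_names,
         bit_depth = stack$bit_depth, n_channels = d[4], n_z = d[1]),
    sidecar_path(path), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @param voxel_size Required when no JSON sidecar is present: `(dz, dy, dx)`
#'   in micrometres. There is no silent default.
#' @param n_channels,channel_names,bit_depth Layout metadata; taken from the
#'   sidecar when present.
#' @export
read_stack <- function(path, voxel_size = NULL, n_channels = NULL,
                       channel_names = NULL, bit_depth = NULL) {
  meta <- NULL
  if (file.exists(sidecar_path(path)))
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  voxel_size <- voxel_size %||% meta$voxel_size
  if (is.null(voxel_size))
    stop("voxel size unknown: supply `voxel_size = c(dz, dy, dx)` in um ",
         "explicitly or provide the JSON sidecar", call. = FALSE)
  n_channels <- as.integer(n_channels %||% meta$n_channels %||% 1L)
  channel_names <- channel_names %||% meta$channel_names
  bit_depth <- as.integer(bit_depth %||% meta$bit_depth %||% 16L)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  n_pages <- length(pages)
  if (n_pages %% n_channels != 0)
    stop("page count is not a multiple of the channel count", call. = FALSE)
  nz <- n_pages %/% n_channels
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  v <- array(0, dim = c(nz, ny, nx, n_channels))
  k <- 1L
  for (z in seq_len(nz)) {
    for (ch in seq_len(n_channels)) {
      v[z, , , ch] <- pages[[k]]
      k <- k + 1L
    }
  }
  image_stack(v, voxel_size, channel_names, bit_depth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Z-projection of a stack
#'
#' Collapses the z axis by sum or average intensity. Sum projection conserves
#' total intensity per channel exactly.
#'
#' @param stack An `image_stack` or a 3D array `(z, y, x)`.
#' @param mode `"sum"` or `"average"`.
#' @return A `(y, x)` matrix for single-channel input, else a
#'   `(y, x, channel)` array.
#' @export
z_project <- function(stack, mode = c("sum", "average")) {
  mode <- match.arg(mode)
  v <- if (inherits(stack, "image_stack")) stack$voxels else stack
  if (length(dim(v)) == 3L) dim(v) <- c(dim(v), 1L)
  d <- dim(v)
  out <- array(0, dim = d[2:4])
  for (ch in seq_len(d[4])) {
    proj <- apply(v[, , , ch, drop = FALSE], c(2, 3), sum)
    if (mode == "average") proj <- proj / d[1]
    out[, , ch] <- proj
  }
  if (d[4] == 1L) out[, , 1] else out
}
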
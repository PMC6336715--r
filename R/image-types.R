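#' Multi-channel z-stack image
#'
#' The unit of processing for the cleaning pipeline: an integer voxel array
#' with physical pixel size and an optional designated autofluorescence (AF)
#' channel. The canonical in-memory layout is a 4-d array indexed
#' `[y, x, z, channel]` (1-based); readers normalize any on-disk page order
#' to this layout.
#'
#' @param voxels 4-d numeric array `[y, x, z, channel]` of non-negative
#'   integer-valued intensities, or a 2-d/3-d array which is promoted
#'   (a matrix becomes a single-channel, single-slice stack; a 3-d array is
#'   taken as `[y, x, z]` with one channel).
#' @param bit_depth 8 or 16; all intensities must lie in
#'   `[0, 2^bit_depth - 1]`.
#' @param geometry A [pixel_geometry()].
#' @param channel_names Character vector, one per channel.
#' @param af_channel Index (or name) of the autofluorescence channel, or
#'   `NULL` when no AF channel was acquired.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, bit_depth, geometry,
                        channel_names = NULL, af_channel = NULL) {
  if (is.matrix(voxels)) dim(voxels) <- c(dim(voxels), 1L, 1L)
  if (length(dim(voxels)) == 3L) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 4L) {
    stop("voxels must be a [y, x, z, channel] array", call. = FALSE)
  }
  check_bit_depth(bit_depth)
  check_intensities(voxels, bit_depth)
  stopifnot(is_pixel_geometry(geometry))
  nc <- dim(voxels)[4L]
  if (is.null(channel_names)) {
    channel_names <- sprintf("ch%d", seq_len(nc))
  }
  if (length(channel_names) != nc) {
    stop(sprintf("channel_names has length %d but stack has %d channels",
                 length(channel_names), nc), call. = FALSE)
  }
  af_channel <- resolve_channel(af_channel, channel_names, allow_null = TRUE)
  structure(list(voxels = voxels, bit_depth = as.integer(bit_depth),
                 geometry = geometry,
                 channel_names = as.character(channel_names),
                 af_channel = af_channel),
            class = "image_stack")
}

#' Single-plane image
#'
#' A single-channel 2-d image (typically a maximum intensity projection)
#' with physical pixel size. This is the input unit for fiber
#' quantification and the output unit of the cleaning pipeline.
#'
#' @param pixels Numeric matrix `[y, x]` of non-negative integer-valued
#'   intensities.
#' @param bit_depth 8 or 16.
#' @param geometry A [pixel_geometry()].
#' @param name Optional identifier used when the image is written to disk.
#' @return An object of class `plane_image`.
#' @export
plane_image <- function(pixels, bit_depth, geometry, name = NULL) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix", call. = FALSE)
  check_bit_depth(bit_depth)
  check_intensities(pixels, bit_depth)
  stopifnot(is_pixel_geometry(geometry))
  structure(list(pixels = pixels, bit_depth = as.integer(bit_depth),
                 geometry = geometry,
                 name = if (is.null(name)) NULL else as.character(name)),
            class = "plane_image")
}

#' Binary mask
#'
#' A logical pixel grid with the geometry of the image it was derived from.
#'
#' @param on Logical matrix `[y, x]`; `TRUE` marks foreground.
#' @param geometry A [pixel_geometry()].
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(on, geometry) {
  if (!is.matrix(on) || !is.logical(on)) {
    stop("on must be a logical matrix", call. = FALSE)
  }
  if (anyNA(on)) stop("mask may not contain NA", call. = FALSE)
  stopifnot(is_pixel_geometry(geometry))
  structure(list(on = on, geometry = geometry), class = "binary_mask")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  af <- if (is.null(x$af_channel)) "none" else
    sprintf("%d (%s)", x$af_channel, x$channel_names[x$af_channel])
  cat(sprintf(
    "<image_stack> %d x %d px, %d z-slice(s), %d channel(s) [%s], %d-bit\n",
    d[1], d[2], d[3], d[4], paste(x$channel_names, collapse = ", "),
    x$bit_depth))
  cat(sprintf("  pixel size: %g x %g um/px; AF channel: %s\n",
              x$geometry$x_um, x$geometry$y_um, af))
  invisible(x)
}

#' @export
print.plane_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<plane_image>%s %d x %d px, %d-bit, %g x %g um/px\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              d[1], d[2], x$bit_depth, x$geometry$x_um, x$geometry$y_um))
  invisible(x)
}

#' Number of channels / z-slices of a stack
#' @param stack An `image_stack`.
#' @export
n_channels <- function(stack) dim(stack$voxels)[4L]

#' @rdname n_channels
#' @export
n_slices <- function(stack) dim(stack$voxels)[3L]

#' Extract one z-plane of one channel as a `plane_image`
#' @param stack An `image_stack`.
#' @param channel Channel index or name.
#' @param z Slice index.
#' @export
get_plane <- function(stack, channel, z = 1L) {
  channel <- resolve_channel(channel, stack$channel_names)
  if (z < 1L || z > n_slices(stack)) stop("z out of range", call. = FALSE)
  plane_image(slice_matrix(stack, z, channel),
              stack$bit_depth, stack$geometry,
              name = sprintf("%s_z%d", stack$channel_names[channel], z))
}

# one (y, x) plane as a matrix, shape-safe for 1-pixel-wide stacks
slice_matrix <- function(stack, z, channel) {
  d <- dim(stack$voxels)
  matrix(stack$voxels[, , z, channel], d[1L], d[2L])
}

#' Indices of the signal (non-autofluorescence) channels
#' @param stack An `image_stack`.
#' @export
signal_channels <- function(stack) {
  setdiff(seq_len(n_channels(stack)), stack$af_channel)
}

# -- internal validation helpers ---------------------------------------------

check_bit_depth <- function(bit_depth) {
  if (!bit_depth %in% c(8L, 16L)) {
    stop("bit_depth must be 8 or 16", call. = FALSE)
  }
}

check_intensities <- function(x, bit_depth) {
  if (!is.numeric(x)) {
    stop("intensities must be numeric; convert float images to integer counts",
         call. = FALSE)
  }
  if (anyNA(x)) stop("intensities may not contain NA", call. = FALSE)
  r <- range(x)
  if (r[1] < 0 || r[2] > 2^bit_depth - 1) {
    stop(sprintf("intensities out of range [0, %d] for %d-bit data",
                 2^bit_depth - 1, bit_depth), call. = FALSE)
  }
  if (any(x %% 1 != 0)) {
    stop("intensities must be integer-valued; convert float-typed pixel data",
         call. = FALSE)
  }
}

resolve_channel <- function(channel, channel_names, allow_null = FALSE) {
  if (is.null(channel)) {
    if (allow_null) return(NULL)
    stop("channel must be given", call. = FALSE)
  }
  if (is.character(channel)) {
    idx <- match(channel, channel_names)
    if (is.na(idx)) {
      stop(sprintf("unknown channel '%s' (channels: %s)", channel,
                   paste(channel_names, collapse = ", ")), call. = FALSE)
    }
    return(as.integer(idx))
  }
  channel <- as.integer(channel)
  if (length(channel) != 1L || is.na(channel) || channel < 1L ||
      channel > length(channel_names)) {
    stop("channel index out of range", call. = FALSE)
  }
  channel
}
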
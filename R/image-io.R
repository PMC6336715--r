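#' Read a multi-channel z-stack from a TIFF file
#'
#' Pages are normalized to the canonical `[y, x, z, channel]` layout
#' regardless of the on-disk page order. Pixel-size metadata is resolved
#' with the precedence: explicit `geometry_override` > YAML sidecar written
#' by [write_stack()] > TIFF resolution tags (X/YResolution with a cm or
#' inch unit). A file without any usable pixel size and no override is an
#' error, because every downstream size criterion is physical (um^2).
#'
#' @param path Path to a TIFF file.
#' @param geometry_override Optional [pixel_geometry()] taking precedence
#'   over any metadata.
#' @param channels Number of channels when no sidecar is present (default 1:
#'   all pages are z-slices).
#' @param page_order `"zc"` (z varies fastest; channel-interleaved) or
#'   `"cz"` (channel blocks, z within; planar) for sidecar-less
#'   multi-channel files.
#' @param channel_names,af_channel Optional overrides for sidecar-less files.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, geometry_override = NULL, channels = NULL,
                       page_order = NULL, channel_names = NULL,
                       af_channel = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 1L) {
    stop(sprintf("no image pages in %s", path), call. = FALSE)
  }
  meta <- read_sidecar(path)

  bits <- attr(pages[[1L]], "bits.per.sample")
  if (is.null(bits)) bits <- if (max(pages[[1L]]) > 255) 16L else 8L
  if (!bits %in% c(8L, 16L)) {
    stop(sprintf(
      "%s: unsupported bit depth %s; convert the image to 8- or 16-bit integers",
      path, bits), call. = FALSE)
  }
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1L)))) {
    stop(sprintf(
      "%s: multi-sample (RGB) pages are not supported; save one channel per page",
      path), call. = FALSE)
  }
  if (any(vapply(pages, function(p) any(p %% 1 != 0), logical(1L)))) {
    stop(sprintf(
      "%s: float-typed pixel data; convert the image to 8- or 16-bit integers",
      path), call. = FALSE)
  }

  geometry <- resolve_geometry(path, geometry_override, meta, pages[[1L]])

  nc <- channels %||% meta$channels %||% 1L
  order <- page_order %||% meta$page_order %||% "cz"
  np <- length(pages)
  if (np %% nc != 0L) {
    stop(sprintf("%s: %d pages do not divide into %d channels", path, np, nc),
         call. = FALSE)
  }
  nz <- np %/% nc
  dims <- dim(pages[[1L]])
  vox <- array(0, dim = c(dims[1L], dims[2L], nz, nc))
  for (p in seq_len(np)) {
    if (!identical(dim(pages[[p]]), dims)) {
      stop(sprintf("%s: page %d has a different shape", path, p),
           call. = FALSE)
    }
    if (order == "cz") {        # channel blocks: pages c1z1..c1zZ, c2z1, ...
      ch <- (p - 1L) %/% nz + 1L
      z  <- (p - 1L) %% nz + 1L
    } else if (order == "zc") { # interleaved: pages z1c1, z1c2, z2c1, ...
      z  <- (p - 1L) %/% nc + 1L
      ch <- (p - 1L) %% nc + 1L
    } else {
      stop("page_order must be 'cz' or 'zc'", call. = FALSE)
    }
    vox[, , z, ch] <- pages[[p]]
  }

  image_stack(vox, bit_depth = bits, geometry = geometry,
              channel_names = channel_names %||% meta$channel_names,
              af_channel = af_channel %||% meta$af_channel)
}

#' Write a z-stack as a multi-page TIFF plus a YAML metadata sidecar
#'
#' The sidecar (`<path minus extension>.yml`) records pixel size, channel
#' names, AF-channel assignment, bit depth and page order, so that
#' [read_stack()] round-trips the stack exactly. Pages are written in
#' channel-major (`"cz"`) or z-major interleaved (`"zc"`) order.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @param page_order `"cz"` (default) or `"zc"`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, page_order = c("cz", "zc")) {
  stopifnot(inherits(stack, "image_stack"))
  page_order <- match.arg(page_order)
  d <- dim(stack$voxels)
  scale <- 2^stack$bit_depth - 1
  pages <- list()
  if (page_order == "cz") {
    for (ch in seq_len(d[4L])) for (z in seq_len(d[3L])) {
      pages[[length(pages) + 1L]] <- stack$voxels[, , z, ch] / scale
    }
  } else {
    for (z in seq_len(d[3L])) for (ch in seq_len(d[4L])) {
      pages[[length(pages) + 1L]] <- stack$voxels[, , z, ch] / scale
    }
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth,
                  compression = "LZW")
  write_sidecar(path, list(
    x_um_per_px = stack$geometry$x_um, y_um_per_px = stack$geometry$y_um,
    bit_depth = stack$bit_depth, channels = d[4L], z = d[3L],
    page_order = page_order, channel_names = as.list(stack$channel_names),
    af_channel = stack$af_channel))
  invisible(path)
}

#' Read / write a single-plane image
#'
#' Same metadata conventions as [read_stack()] / [write_stack()], for
#' single-channel images such as maximum intensity projections.
#'
#' @param path TIFF path.
#' @param geometry_override Optional [pixel_geometry()].
#' @return A [plane_image()] (for `read_plane`); `path` invisibly (for
#'   `write_plane`).
#' @export
read_plane <- function(path, geometry_override = NULL) {
  stack <- read_stack(path, geometry_override = geometry_override)
  if (n_slices(stack) != 1L || n_channels(stack) != 1L) {
    stop(sprintf("%s is not a single-channel single-plane image", path),
         call. = FALSE)
  }
  plane_image(slice_matrix(stack, 1L, 1L), stack$bit_depth,
              stack$geometry, name = tools::file_path_sans_ext(basename(path)))
}

#' @rdname read_plane
#' @param plane A [plane_image()].
#' @export
write_plane <- function(plane, path) {
  stopifnot(inherits(plane, "plane_image"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(plane$pixels / (2^plane$bit_depth - 1), path,
                  bits.per.sample = plane$bit_depth, compression = "LZW")
  write_sidecar(path, list(
    x_um_per_px = plane$geometry$x_um, y_um_per_px = plane$geometry$y_um,
    bit_depth = plane$bit_depth, channels = 1L, z = 1L, page_order = "cz"))
  invisible(path)
}

#' Crop z-slices from a stack
#'
#' Stacks should be cropped to the slices that actually image tissue:
#' slices acquired above or below the section carry no signal but do carry
#' noise and coverslip debris, and they distort the per-slice threshold
#' statistics of the cleaning pipeline.
#'
#' @param stack An [image_stack()].
#' @param z_first,z_last First and last slice to keep (1-based, inclusive).
#' @return The cropped [image_stack()].
#' @export
crop_z <- function(stack, z_first, z_last) {
  stopifnot(inherits(stack, "image_stack"))
  nz <- n_slices(stack)
  if (z_first < 1L || z_last > nz || z_first > z_last) {
    stop(sprintf("invalid z range [%d, %d] for a %d-slice stack",
                 z_first, z_last, nz), call. = FALSE)
  }
  out <- stack
  out$voxels <- stack$voxels[, , z_first:z_last, , drop = FALSE]
  out
}

#' Write cleaned or quantified images into a dated output folder
#'
#' Follows the pipeline's folder conventions: cleaned channels go to
#' `DEFiNE_Processed_Images_MM-DD-YYYY`, quantification masks to
#' `DEFiNE_Quantified_Fibers_MM-DD-YYYY`. Each image is written as its own
#' single-plane TIFF named after its `name` field.
#'
#' @param images List of [plane_image()] objects.
#' @param run_date A `Date` (default today).
#' @param kind `"processed"` or `"quantified"`.
#' @param out_root Directory under which the dated folder is created.
#' @return Character vector of written file paths, in input order.
#' @export
write_outputs <- function(images, run_date = Sys.Date(),
                          kind = c("processed", "quantified"),
                          out_root = ".") {
  kind <- match.arg(kind)
  stopifnot(inherits(run_date, "Date"))
  folder <- file.path(out_root, define_folder_name(kind, run_date))
  dir.create(folder, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(folder)) {
    stop(sprintf("cannot create output folder %s", folder), call. = FALSE)
  }
  paths <- character(0)
  for (i in seq_along(images)) {
    img <- images[[i]]
    stopifnot(inherits(img, "plane_image"))
    nm <- img$name %||% names(images)[i]
    if (is.null(nm) || is.na(nm) || !nzchar(nm)) nm <- sprintf("image_%03d", i)
    p <- file.path(folder, paste0(nm, ".tif"))
    write_plane(img, p)
    paths <- c(paths, p)
  }
  paths
}

#' @rdname write_outputs
#' @export
define_folder_name <- function(kind = c("processed", "quantified"),
                               run_date = Sys.Date()) {
  kind <- match.arg(kind)
  prefix <- switch(kind, processed = "DEFiNE_Processed_Images_",
                   quantified = "DEFiNE_Quantified_Fibers_")
  paste0(prefix, format(run_date, "%m-%d-%Y"))
}

#' Convert a binary mask to a writable 8-bit image (0 / 255)
#' @param mask A [binary_mask()].
#' @param name Optional image name.
#' @export
mask_to_plane <- function(mask, name = NULL) {
  stopifnot(inherits(mask, "binary_mask"))
  plane_image(matrix(ifelse(mask$on, 255, 0), nrow = nrow(mask$on)),
              bit_depth = 8L, geometry = mask$geometry, name = name)
}

# -- sidecar + metadata helpers ----------------------------------------------

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".yml")
}

write_sidecar <- function(path, meta) {
  yaml::write_yaml(meta, sidecar_path(path))
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  meta <- yaml::read_yaml(sp)
  if (!is.null(meta$channel_names)) {
    meta$channel_names <- as.character(unlist(meta$channel_names))
  }
  meta
}

resolve_geometry <- function(path, override, meta, first_page) {
  if (!is.null(override)) {
    stopifnot(is_pixel_geometry(override))
    return(override)
  }
  if (!is.null(meta$x_um_per_px)) {
    return(pixel_geometry(meta$x_um_per_px,
                          meta$y_um_per_px %||% meta$x_um_per_px))
  }
  xres <- attr(first_page, "x.resolution")
  yres <- attr(first_page, "y.resolution")
  unit <- attr(first_page, "resolution.unit") %||% "inch"
  if (!is.null(xres) && is.finite(xres) && xres > 0) {
    um_per_unit <- switch(as.character(unit),
                          cm = 1e4, centimeter = 1e4, inch = 25400,
                          NA_real_)
    if (is.finite(um_per_unit)) {
      if (is.null(yres) || !is.finite(yres) || yres <= 0) yres <- xres
      return(pixel_geometry(um_per_unit / xres, um_per_unit / yres))
    }
  }
  stop(sprintf(
    paste0("%s: no pixel-size metadata (no sidecar, no usable TIFF ",
           "resolution tags); pass geometry_override = pixel_geometry(...)"),
    path), call. = FALSE)
}
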
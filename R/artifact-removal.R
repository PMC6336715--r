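#' Large-particle removal on a single plane
#'
#' Iteratively subtracts bright particles whose size and circularity mark
#' them as artifacts rather than axons. For each threshold multiplier `k`
#' (default 1.5, 2, 2.5, 3), the *current* image is thresholded at
#' `mean + k * SD` (statistics recomputed each iteration, since removal
#' changes them), binarized, and every particle satisfying any
#' (min area, min circularity) criterion is zeroed. Output pixels are
#' either 0 or identical to the input.
#'
#' @param plane A [plane_image()].
#' @param criteria Criteria table as in [clean_settings()].
#' @param iteration_ks Threshold multipliers, strictly increasing.
#' @param recorder Optional environment collecting removed particles (see
#'   [preview_processing()]); internal.
#' @param context Named list tagging recorder rows (channel, z); internal.
#' @return The cleaned [plane_image()].
#' @export
remove_large_particles <- function(plane, criteria = default_criteria(),
                                   iteration_ks = c(1.5, 2, 2.5, 3),
                                   recorder = NULL, context = list()) {
  stopifnot(inherits(plane, "plane_image"))
  criteria <- as_criteria(criteria)
  if (nrow(criteria) < 1L) stop("at least one criterion required",
                                call. = FALSE)
  px_area <- pixel_area_um2(plane$geometry)
  min_px <- floor(min(criteria$min_area_um2) / px_area)
  for (k in iteration_ks) {
    th <- sd_threshold(plane$pixels, k)
    mask <- binarize(plane$pixels, th, plane$geometry)
    if (!any(mask$on)) next
    parts <- label_particles(mask, min_area_px = max(1L, min_px))
    hit <- matches_criteria(parts, criteria)
    if (!any(hit)) next
    rm_idx <- unlist(parts$pixels[hit], use.names = FALSE)
    record_removals(recorder, parts[hit, , drop = FALSE],
                    stage = "large", k = k, context = context)
    plane$pixels[rm_idx] <- 0
  }
  plane
}

matches_criteria <- function(parts, criteria) {
  if (nrow(parts) == 0L) return(logical(0))
  hit <- rep(FALSE, nrow(parts))
  for (i in seq_len(nrow(criteria))) {
    hit <- hit | (parts$area_um2 >= criteria$min_area_um2[i] &
                    !is.na(parts$circularity) &
                    parts$circularity >= criteria$min_circularity[i])
  }
  hit
}

#' Large-particle removal over a z-stack
#'
#' Applies [remove_large_particles()] independently to every z-plane of
#' every signal channel, with per-slice threshold statistics (per-slice
#' statistics absorb depth-dependent brightness falloff). The
#' autofluorescence channel passes through untouched: it is a noise
#' reference and must stay intact until subtraction.
#'
#' @param stack An [image_stack()].
#' @inheritParams remove_large_particles
#' @return The processed [image_stack()].
#' @export
remove_large_particles_stack <- function(stack,
                                         criteria = default_criteria(),
                                         iteration_ks = c(1.5, 2, 2.5, 3),
                                         recorder = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  for (ch in signal_channels(stack)) {
    for (z in seq_len(n_slices(stack))) {
      pl <- plane_image(slice_matrix(stack, z, ch),
                        stack$bit_depth, stack$geometry)
      pl <- remove_large_particles(pl, criteria, iteration_ks,
                                   recorder = recorder,
                                   context = list(channel = ch, z = z))
      stack$voxels[, , z, ch] <- pl$pixels
    }
  }
  stack
}

#' Subtract the autofluorescence channel from the signal channels
#'
#' Each z-slice of the AF channel is binarized at `mean + af_k * SD`
#' (per-slice statistics; default `af_k = 1`), and the resulting mask is
#' digitally subtracted from the same slice of every signal channel:
#' structures that fluoresce in the AF band — where no label emits — are
#' artifacts by construction. The AF channel itself is returned unchanged.
#' A blank AF slice (SD 0) yields an empty mask and is a no-op.
#'
#' @param stack An [image_stack()] with `af_channel` set.
#' @param af_k Threshold multiplier.
#' @return The processed [image_stack()].
#' @export
subtract_autofluorescence <- function(stack, af_k = 1) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(stack$af_channel)) {
    stop(paste("no autofluorescence channel is assigned; set af_channel on",
               "the stack, or disable AF subtraction",
               "(use_af_subtraction = FALSE) to clean by morphology only"),
         call. = FALSE)
  }
  af <- stack$af_channel
  for (z in seq_len(n_slices(stack))) {
    af_slice <- slice_matrix(stack, z, af)
    th <- sd_threshold(af_slice, af_k)
    on <- af_slice > th
    if (!any(on)) next
    for (ch in signal_channels(stack)) {
      sl <- slice_matrix(stack, z, ch)
      sl[on] <- 0
      stack$voxels[, , z, ch] <- sl
    }
  }
  stack
}

#' Maximum intensity projection of one channel
#'
#' @param stack An [image_stack()].
#' @param channel Channel index or name.
#' @return A [plane_image()] whose pixel (y, x) is the exact integer
#'   maximum over z of that channel.
#' @export
max_intensity_projection <- function(stack, channel) {
  stopifnot(inherits(stack, "image_stack"))
  channel <- resolve_channel(channel, stack$channel_names)
  mip <- slice_matrix(stack, 1L, channel)
  for (z in seq_len(n_slices(stack))[-1L]) {
    mip <- pmax(mip, slice_matrix(stack, z, channel))
  }
  plane_image(mip, stack$bit_depth, stack$geometry,
              name = stack$channel_names[channel])
}

#' Project every channel of a stack to a single-slice stack
#'
#' Utility for comparing z-stack processing against processing of the
#' pre-projected image: each channel (AF included) is replaced by its
#' maximum intensity projection.
#'
#' @param stack An [image_stack()].
#' @return An [image_stack()] with one z-slice.
#' @export
project_stack <- function(stack) {
  d <- dim(stack$voxels)
  vox <- array(0, dim = c(d[1L], d[2L], 1L, d[4L]))
  for (ch in seq_len(d[4L])) {
    vox[, , 1L, ch] <- max_intensity_projection(stack, ch)$pixels
  }
  image_stack(vox, stack$bit_depth, stack$geometry, stack$channel_names,
              stack$af_channel)
}

#' Small-particle removal on a projection
#'
#' Removes objects too small to be axons — residual single-pixel noise and
#' fragments left by the earlier stages. One pass: the image is thresholded
#' at `mean + small_k * SD`, and particles with area at most
#' `small_max_area_um2` *and* circularity inside `small_circ_range`
#' (closed interval) are zeroed.
#'
#' @param mip A [plane_image()] (typically a maximum intensity projection).
#' @param small_max_area_um2 Maximum removable area (default 1 um^2).
#' @param small_circ_range Closed circularity interval (default
#'   `c(0.99, 1)`; 1.0 is inside, so perfect specks are removable).
#' @param small_k Threshold multiplier (default 1).
#' @param recorder,context Internal; see [remove_large_particles()].
#' @return The cleaned [plane_image()].
#' @export
remove_small_particles <- function(mip, small_max_area_um2 = 1,
                                   small_circ_range = c(0.99, 1),
                                   small_k = 1, recorder = NULL,
                                   context = list()) {
  stopifnot(inherits(mip, "plane_image"))
  th <- sd_threshold(mip$pixels, small_k)
  mask <- binarize(mip$pixels, th, mip$geometry)
  if (!any(mask$on)) return(mip)
  px_area <- pixel_area_um2(mip$geometry)
  max_px <- ceiling(small_max_area_um2 / px_area)
  parts <- label_particles(mask, max_area_px = max_px)
  hit <- parts$area_um2 <= small_max_area_um2 &
    !is.na(parts$circularity) &
    parts$circularity >= small_circ_range[1] &
    parts$circularity <= small_circ_range[2]
  if (any(hit)) {
    record_removals(recorder, parts[hit, , drop = FALSE],
                    stage = "small", k = small_k, context = context)
    mip$pixels[unlist(parts$pixels[hit], use.names = FALSE)] <- 0
  }
  mip
}

#' Clean a multi-channel z-stack
#'
#' The full three-stage pipeline: (1) large-particle removal on every
#' signal-channel z-slice, (2) optional autofluorescence-channel
#' subtraction per z-slice, (3) maximum intensity projection of each signal
#' channel, then small-particle removal on the projection. Working on the
#' z-stack (rather than a projection) preserves fibers that pass above or
#' below an artifact that occupies only part of the section thickness.
#'
#' @param stack An [image_stack()]; `af_channel` must be set when
#'   `settings$use_af_subtraction` is `TRUE`.
#' @param settings A [clean_settings()].
#' @param recorder Optional removal recorder; see [preview_processing()].
#' @return Named list of cleaned [plane_image()] projections, one per
#'   signal channel (the AF channel is not part of the output).
#' @export
clean_images <- function(stack, settings = clean_settings(),
                         recorder = NULL) {
  stopifnot(inherits(stack, "image_stack"),
            inherits(settings, "clean_settings"))
  stack <- remove_large_particles_stack(stack, settings$criteria,
                                        settings$iteration_ks,
                                        recorder = recorder)
  if (settings$use_af_subtraction) {
    stack <- subtract_autofluorescence(stack, settings$af_k)
  }
  out <- list()
  for (ch in signal_channels(stack)) {
    mip <- max_intensity_projection(stack, ch)
    mip <- remove_small_particles(mip, settings$small_max_area_um2,
                                  settings$small_circ_range,
                                  settings$small_k, recorder = recorder,
                                  context = list(channel = ch, z = NA))
    out[[stack$channel_names[ch]]] <- mip
  }
  out
}

#' Fraction of non-blank pixels of each z-slice
#'
#' Helper used by the batch front end to warn about near-blank slices,
#' which should be cropped away with [crop_z()] before processing.
#'
#' @param stack An [image_stack()].
#' @param channel Channel to inspect (default: first signal channel).
#' @return Numeric vector, one fraction per slice.
#' @export
slice_fill_fraction <- function(stack, channel = NULL) {
  channel <- channel %||% signal_channels(stack)[1L]
  channel <- resolve_channel(channel, stack$channel_names)
  vapply(seq_len(n_slices(stack)), function(z) {
    mean(slice_matrix(stack, z, channel) > 0)
  }, numeric(1L))
}

# -- removal recording (used by settings optimization / run logs) -----------

new_recorder <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env
}

record_removals <- function(recorder, parts, stage, k, context) {
  if (is.null(recorder) || nrow(parts) == 0L) return(invisible(NULL))
  parts$stage <- stage
  parts$k <- k
  parts$channel <- context$channel %||% NA_integer_
  parts$z <- context$z %||% NA_integer_
  recorder$rows[[length(recorder$rows) + 1L]] <- parts
  invisible(NULL)
}

recorded_removals <- function(recorder) {
  if (is.null(recorder) || length(recorder$rows) == 0L) {
    out <- data.frame(label = integer(0), n_px = integer(0),
                      area_um2 = numeric(0), perimeter_um = numeric(0),
                      circularity = numeric(0), stage = character(0),
                      k = numeric(0), channel = integer(0), z = integer(0))
    out$pixels <- list()
    return(out)
  }
  do.call(rbind, recorder$rows)
}
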
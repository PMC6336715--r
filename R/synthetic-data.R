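#' Phantom specification
#'
#' Parameterizes a synthetic multi-channel z-stack emulating the scene
#' classes the cleaning pipeline must separate: thin curvilinear bright
#' fibers (the structures to preserve), compact high-circularity bright
#' granules that bleed into the autofluorescence channel
#' (lipofuscin-like), large elongated vessel-like ribbons, and additive
#' Gaussian background noise. The last channel is the AF channel.
#'
#' Defaults emulate a 20x confocal acquisition (0.83 um/px, 8-bit) of
#' sparsely labeled noradrenergic axons in aging tissue: a handful of
#' fibers barely brighter than the granule artifacts, granules confined to
#' a few z-slices, strong granule bleed-through into the AF channel, and
#' moderate detector noise.
#'
#' @param channels Total channels including the AF channel (>= 2 unless
#'   `af = FALSE`).
#' @param z,y,x Stack dimensions.
#' @param geometry A [pixel_geometry()].
#' @param bit_depth 8 or 16.
#' @param n_fibers,fiber_width_px,fiber_intensity,fiber_tortuosity Fiber
#'   count, stroke width (px), intensity range, and heading jitter (rad per
#'   step; 0 = straight).
#' @param n_granules,granule_area_um2,granule_intensity,granule_bleedthrough
#'   Granule count, area range (um^2), intensity range, and the fraction of
#'   artifact intensity appearing in the AF channel (applies to granules
#'   and vessels — both are autofluorescent).
#' @param n_vessels,vessel_width_px,vessel_intensity Vessel-like ribbon
#'   count, width and intensity range. Vessels are too elongated for the
#'   default morphology gates; they are removed by AF subtraction.
#' @param background_mean,background_sd Gaussian background noise
#'   parameters (applied to every channel, integer-rounded, clipped).
#' @param af `FALSE` generates a stack without an AF channel.
#' @param cross_class_overlap Allow objects of different classes to overlap
#'   (a fiber may cross a granule — the hard case AF subtraction exists
#'   for). Same-class merging is always prevented.
#' @param seed Integer seed; fixed seed gives bit-identical phantoms.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(channels = 2L, z = 6L, y = 160L, x = 160L,
                         geometry = pixel_geometry(0.83),
                         bit_depth = 8L,
                         n_fibers = 6L, fiber_width_px = 1.4,
                         fiber_intensity = c(120, 180),
                         fiber_tortuosity = 0.25,
                         n_granules = 8L,
                         granule_area_um2 = c(8, 40),
                         granule_intensity = c(160, 230),
                         granule_bleedthrough = 0.85,
                         n_vessels = 1L, vessel_width_px = 5,
                         vessel_intensity = c(90, 140),
                         background_mean = 20, background_sd = 4,
                         af = TRUE, cross_class_overlap = TRUE,
                         seed = 1L) {
  stopifnot(z >= 1L, y >= 16L, x >= 16L, channels >= if (af) 2L else 1L,
            n_fibers >= 0L, n_granules >= 0L, n_vessels >= 0L,
            background_sd >= 0, background_mean >= 0,
            granule_bleedthrough >= 0, granule_bleedthrough <= 1)
  check_bit_depth(bit_depth)
  structure(as.list(environment()), class = "phantom_spec")
}

#' Generate a synthetic phantom with ground truth
#'
#' Renders the scene described by a [phantom_spec()] and returns both the
#' stack and per-class ground-truth masks plus an object table with each
#' object's class, channel, z-extent and its area/circularity as measured
#' by [label_particles()] on the object's own isolated footprint.
#'
#' Fibers are smooth random-walk curves spanning 1-3 adjacent z-slices,
#' rendered in one signal channel each. Granules are convex elliptical
#' blobs spanning up to 3 adjacent slices, rendered in every signal
#' channel and — scaled by the bleed-through fraction — in the AF channel.
#' Vessels are long, wide, low-circularity ribbons in the signal channels.
#' Same-class placements that would merge in the (y, x) projection are
#' re-drawn, so labeling a class's projected ground-truth mask recovers
#' the requested object count.
#'
#' @param spec A [phantom_spec()].
#' @return `list(stack =, truth =)`: `stack` an [image_stack()]; `truth` a
#'   list with `fiber_mask` (`[y, x, z, channel]` logical), `granule_mask`
#'   and `vessel_mask` (`[y, x, z]` logical), and `objects` (data frame).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  nch <- spec$channels
  af_ch <- if (spec$af) nch else NULL
  sig_ch <- setdiff(seq_len(nch), af_ch)
  dims <- c(spec$y, spec$x, spec$z, nch)
  canvas <- array(0, dim = dims)
  fiber_mask <- array(FALSE, dim = dims)
  granule_mask <- array(FALSE, dim = dims[1:3])
  vessel_mask <- array(FALSE, dim = dims[1:3])
  objects <- list()

  proj <- function(mask4or3) {
    if (length(dim(mask4or3)) == 4L) {
      apply(mask4or3, c(1L, 2L), any)
    } else {
      apply(mask4or3, c(1L, 2L), any)
    }
  }
  blocked_same <- function(fp, class_proj) {
    any(dilate1(fp) & class_proj)
  }
  blocked_cross <- function(fp, other_proj) {
    !spec$cross_class_overlap && any(dilate1(fp) & other_proj)
  }

  place <- function(draw_fn, class_proj, other_proj, max_tries = 60L) {
    for (t in seq_len(max_tries)) {
      fp <- draw_fn()
      if (is.null(fp)) next
      if (blocked_same(fp, class_proj) || blocked_cross(fp, other_proj)) next
      return(fp)
    }
    stop("phantom too small to place the requested objects without merging",
         call. = FALSE)
  }

  # --- granules --------------------------------------------------------------
  gr_proj <- matrix(FALSE, spec$y, spec$x)
  for (i in seq_len(spec$n_granules)) {
    fp <- place(function() draw_granule(spec), gr_proj,
                proj(fiber_mask) | proj(vessel_mask))
    z0 <- sample.int(spec$z, 1L)
    zext <- min(spec$z, z0 + sample.int(3L, 1L) - 1L)
    intensity <- stats::runif(1, spec$granule_intensity[1],
                              spec$granule_intensity[2])
    for (z in z0:zext) {
      granule_mask[, , z][fp] <- TRUE
      for (ch in sig_ch) {
        sl <- canvas[, , z, ch]; sl[fp] <- pmax(sl[fp], intensity)
        canvas[, , z, ch] <- sl
      }
      if (!is.null(af_ch)) {
        sl <- canvas[, , z, af_ch]
        sl[fp] <- pmax(sl[fp], intensity * spec$granule_bleedthrough)
        canvas[, , z, af_ch] <- sl
      }
    }
    gr_proj <- gr_proj | fp
    objects[[length(objects) + 1L]] <-
      object_record(i, "granule", NA_integer_, z0, zext, fp, spec$geometry)
  }

  # --- vessels ---------------------------------------------------------------
  vs_proj <- matrix(FALSE, spec$y, spec$x)
  for (i in seq_len(spec$n_vessels)) {
    fp <- place(function() draw_ribbon(spec, spec$vessel_width_px,
                                       len_frac = 0.9, tortuosity = 0.08),
                vs_proj, gr_proj | proj(fiber_mask))
    z0 <- sample.int(spec$z, 1L)
    zext <- min(spec$z, z0 + sample.int(3L, 1L))
    intensity <- stats::runif(1, spec$vessel_intensity[1],
                              spec$vessel_intensity[2])
    for (z in z0:zext) {
      vessel_mask[, , z][fp] <- TRUE
      for (ch in sig_ch) {
        sl <- canvas[, , z, ch]; sl[fp] <- pmax(sl[fp], intensity)
        canvas[, , z, ch] <- sl
      }
      if (!is.null(af_ch)) {
        # vessels are autofluorescent: too elongated for the morphology
        # gates, they are exactly what the AF channel is there to catch
        sl <- canvas[, , z, af_ch]
        sl[fp] <- pmax(sl[fp], intensity * spec$granule_bleedthrough)
        canvas[, , z, af_ch] <- sl
      }
    }
    vs_proj <- vs_proj | fp
    objects[[length(objects) + 1L]] <-
      object_record(i, "vessel", NA_integer_, z0, zext, fp, spec$geometry)
  }

  # --- fibers ----------------------------------------------------------------
  fb_proj <- matrix(FALSE, spec$y, spec$x)
  for (i in seq_len(spec$n_fibers)) {
    fp <- place(function() draw_ribbon(spec, spec$fiber_width_px,
                                       len_frac = 0.45,
                                       tortuosity = spec$fiber_tortuosity),
                fb_proj, gr_proj | vs_proj)
    ch <- if (length(sig_ch) == 1L) sig_ch else sample(sig_ch, 1L)
    z0 <- sample.int(spec$z, 1L)
    zext <- min(spec$z, z0 + sample.int(3L, 1L) - 1L)
    intensity <- stats::runif(1, spec$fiber_intensity[1],
                              spec$fiber_intensity[2])
    for (z in z0:zext) {
      fiber_mask[, , z, ch][fp] <- TRUE
      sl <- canvas[, , z, ch]; sl[fp] <- pmax(sl[fp], intensity)
      canvas[, , z, ch] <- sl
    }
    fb_proj <- fb_proj | fp
    objects[[length(objects) + 1L]] <-
      object_record(i, "fiber", ch, z0, zext, fp, spec$geometry)
  }

  # --- background noise ------------------------------------------------------
  maxv <- 2^spec$bit_depth - 1
  noise <- stats::rnorm(length(canvas), spec$background_mean,
                        spec$background_sd)
  canvas <- round(pmin(pmax(canvas + noise, 0), maxv))

  nm <- c(sprintf("signal%d", seq_along(sig_ch)),
          if (!is.null(af_ch)) "AF")
  stack <- image_stack(canvas, bit_depth = spec$bit_depth,
                       geometry = spec$geometry, channel_names = nm,
                       af_channel = af_ch)
  truth <- list(fiber_mask = fiber_mask, granule_mask = granule_mask,
                vessel_mask = vessel_mask,
                objects = if (length(objects)) {
                  do.call(rbind, c(objects, make.row.names = FALSE))
                })
  list(stack = stack, truth = truth)
}

object_record <- function(id, class, channel, z0, z1, fp, geometry) {
  p <- label_particles(binary_mask(fp, geometry))
  # footprint is one object by construction, but random walks can
  # self-touch; take the dominant component's shape measurements
  j <- which.max(p$n_px)
  data.frame(id = id, class = class, channel = channel, z0 = z0, z1 = z1,
             n_px = sum(p$n_px),
             area_um2 = sum(p$area_um2),
             circularity = p$circularity[j])
}

# binary dilation by one pixel (8-neighbourhood), used to keep same-class
# objects from merging
dilate1 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  rd <- m
  rd[-1, ] <- rd[-1, ] | m[-nr, ]
  rd[-nr, ] <- rd[-nr, ] | m[-1, ]
  out <- rd
  out[, -1] <- out[, -1] | rd[, -nc]
  out[, -nc] <- out[, -nc] | rd[, -1]
  out
}

draw_granule <- function(spec) {
  px_area <- pixel_area_um2(spec$geometry)
  area <- stats::runif(1, spec$granule_area_um2[1], spec$granule_area_um2[2])
  r_px <- sqrt(area / px_area / pi)
  ecc <- stats::runif(1, 0.75, 1)
  ry <- r_px / sqrt(ecc)
  rx <- r_px * sqrt(ecc)
  cy <- stats::runif(1, ry + 2, spec$y - ry - 1)
  cx <- stats::runif(1, rx + 2, spec$x - rx - 1)
  fp <- outer(seq_len(spec$y), seq_len(spec$x), function(yy, xx) {
    ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1
  })
  if (!any(fp)) NULL else fp
}

draw_ribbon <- function(spec, width_px, len_frac, tortuosity) {
  n_steps <- max(10L, round(len_frac * min(spec$y, spec$x)))
  margin <- width_px + 2
  y <- stats::runif(1, margin, spec$y - margin)
  x <- stats::runif(1, margin, spec$x - margin)
  heading <- stats::runif(1, 0, 2 * pi)
  fp <- matrix(FALSE, spec$y, spec$x)
  r <- max(0, (width_px - 1) / 2)
  off <- which(outer((-3):3, (-3):3,
                     function(a, b) a^2 + b^2 <= r^2 + 1e-9), arr.ind = TRUE)
  off <- off - 4L
  for (s in seq_len(n_steps)) {
    heading <- heading + stats::rnorm(1, 0, tortuosity)
    y <- y + sin(heading)
    x <- x + cos(heading)
    if (y < margin || y > spec$y - margin ||
        x < margin || x > spec$x - margin) {
      heading <- heading + pi / 2        # bounce off the border region
      y <- min(max(y, margin), spec$y - margin)
      x <- min(max(x, margin), spec$x - margin)
    }
    yy <- round(y) + off[, 1L]
    xx <- round(x) + off[, 2L]
    keep <- yy >= 1L & yy <= spec$y & xx >= 1L & xx <= spec$x
    fp[cbind(yy[keep], xx[keep])] <- TRUE
  }
  if (sum(fp) < 4L) NULL else fp
}

#' Canonical artifact-over-fiber scenario
#'
#' A deterministic 2-channel, 6-slice fixture reproducing the
#' z-versus-projection comparison at the heart of the method: an
#' autofluorescent granule occupies a region R of the first three z-slices
#' (in the signal channel and, at full bleed-through, the AF channel), and
#' a labeled fiber crosses the same (y, x) region in the final three
#' slices (signal channel only). Processing the z-stack preserves the
#' fiber; processing the pre-projected image cannot, because projection
#' collapses the fiber onto the artifact.
#'
#' @return As [generate_phantom()]: `list(stack =, truth =)`; the truth
#'   list also carries `artifact_footprint`, the (y, x) region R.
#' @export
overlap_scenario <- function() {
  ny <- 64L; nx <- 64L; nz <- 6L
  g <- pixel_geometry(1)
  canvas <- array(0, dim = c(ny, nx, nz, 2L))
  fiber_mask <- array(FALSE, dim = c(ny, nx, nz, 2L))
  granule_mask <- array(FALSE, dim = c(ny, nx, nz))

  disk <- outer(seq_len(ny), seq_len(nx),
                function(y, x) (y - 32)^2 + (x - 32)^2 <= 5^2)
  for (z in 1:3) {
    granule_mask[, , z] <- disk
    sl <- canvas[, , z, 1L]; sl[disk] <- 200; canvas[, , z, 1L] <- sl
    sl <- canvas[, , z, 2L]; sl[disk] <- 200; canvas[, , z, 2L] <- sl
  }
  fiber <- matrix(FALSE, ny, nx)
  for (x in 5:60) fiber[32L + round(2 * sin(x / 9)), x] <- TRUE
  for (z in 4:6) {
    fiber_mask[, , z, 1L] <- fiber
    sl <- canvas[, , z, 1L]; sl[fiber] <- 150; canvas[, , z, 1L] <- sl
  }
  stack <- image_stack(canvas, bit_depth = 8L, geometry = g,
                       channel_names = c("signal", "AF"), af_channel = 2L)
  truth <- list(fiber_mask = fiber_mask, granule_mask = granule_mask,
                vessel_mask = array(FALSE, dim = c(ny, nx, nz)),
                artifact_footprint = disk,
                objects = data.frame(
                  id = 1:2, class = c("granule", "fiber"),
                  channel = c(NA, 1L), z0 = c(1L, 4L), z1 = c(3L, 6L),
                  n_px = c(sum(disk), sum(fiber)),
                  area_um2 = c(sum(disk), sum(fiber)),
                  circularity = NA_real_))
  list(stack = stack, truth = truth)
}

#' Phantom tailored to morphological discrimination
#'
#' Granules and fibers only, placed without cross-class contact so that
#' every granule *measures* as a compact particle (area >= 5 um^2,
#' circularity >= 0.8) and every fiber as an elongated one (circularity
#' <= 0.3) — the premise under which size/circularity gating alone must
#' separate the classes.
#'
#' @param seed Integer seed.
#' @param n_granules,n_fibers Object counts (default 20 each).
#' @return As [generate_phantom()].
#' @export
discrimination_phantom <- function(seed = 1L, n_granules = 20L,
                                   n_fibers = 20L) {
  spec <- phantom_spec(channels = 2L, z = 3L, y = 300L, x = 300L,
                       n_fibers = n_fibers, n_granules = n_granules,
                       granule_area_um2 = c(8, 30),
                       n_vessels = 0L,
                       cross_class_overlap = FALSE, seed = seed)
  generate_phantom(spec)
}
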
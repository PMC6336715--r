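#' Threshold at k standard deviations above the mean
#'
#' Returns `mean(pixels) + k * SD(pixels)` where SD is the population
#' standard deviation of the whole grid (the grid is the full population of
#' pixel intensities, not a sample). All stage thresholds of the cleaning
#' pipeline and the quantification threshold are of this form.
#'
#' @param pixels Numeric matrix or vector of intensities.
#' @param k Non-negative multiplier.
#' @return The threshold intensity (double).
#' @export
sd_threshold <- function(pixels, k) {
  if (inherits(pixels, "plane_image")) pixels <- pixels$pixels
  if (length(pixels) == 0L) stop("empty pixel grid", call. = FALSE)
  stopifnot(is.numeric(k), length(k) == 1L, k >= 0)
  m <- mean(pixels)
  m + k * pop_sd(pixels)
}

pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

#' Binarize an image at a threshold
#'
#' Foreground is `intensity > threshold` (strictly greater), so a constant
#' image thresholded at its own mean yields an empty mask — a featureless
#' background region must contain no particles.
#'
#' @param pixels A [plane_image()] or numeric matrix.
#' @param threshold Intensity cutoff.
#' @param geometry Required when `pixels` is a bare matrix.
#' @return A [binary_mask()].
#' @export
binarize <- function(pixels, threshold, geometry = NULL) {
  if (inherits(pixels, "plane_image")) {
    geometry <- pixels$geometry
    pixels <- pixels$pixels
  }
  if (is.null(geometry)) stop("geometry required for a bare matrix",
                              call. = FALSE)
  binary_mask(pixels > threshold, geometry)
}

#' Label particles (8-connected components) and measure them
#'
#' The analogue of ImageJ's "Analyze Particles": foreground pixels are
#' grouped into 8-connected components; each component is measured for
#' pixel count, physical area (um^2), outer-boundary perimeter (um) and
#' circularity. Interior holes are not filled (they are excluded from the
#' area; the perimeter is that of the outer contour).
#'
#' @param mask A [binary_mask()].
#' @param measure_perimeter If `FALSE`, skip perimeter/circularity (they
#'   are filled with `NA`); labeling and areas are still computed. Used
#'   internally to avoid tracing particles that no criterion can match.
#' @param min_area_px,max_area_px Trace perimeters only for particles whose
#'   pixel count lies in `[min_area_px, max_area_px]` (others get `NA`
#'   circularity) — a pure optimization; the defaults measure everything.
#' @return A data frame with one row per particle: `label`, `n_px`,
#'   `area_um2`, `perimeter_um`, `circularity`, and a list-column `pixels`
#'   of linear indices into the mask matrix. Labels are 1..N in order of
#'   each particle's first pixel in column-major scan order.
#' @export
label_particles <- function(mask, measure_perimeter = TRUE,
                            min_area_px = 1L, max_area_px = Inf) {
  stopifnot(inherits(mask, "binary_mask"))
  on <- mask$on
  idx <- which(on)
  empty <- data.frame(label = integer(0), n_px = integer(0),
                      area_um2 = numeric(0), perimeter_um = numeric(0),
                      circularity = numeric(0))
  empty$pixels <- list()
  if (length(idx) == 0L) return(empty)

  labels <- label_components(on, idx)
  px_area <- pixel_area_um2(mask$geometry)
  pix <- split(idx, labels)                # labels are 1..N, split sorts
  n_px <- lengths(pix)
  out <- data.frame(label = seq_along(pix), n_px = as.integer(n_px),
                    area_um2 = n_px * px_area,
                    perimeter_um = NA_real_, circularity = NA_real_)
  out$pixels <- unname(pix)
  if (measure_perimeter) {
    nr <- nrow(on)
    gx <- mask$geometry$x_um
    gy <- mask$geometry$y_um
    for (i in seq_len(nrow(out))) {
      if (out$n_px[i] < min_area_px || out$n_px[i] > max_area_px) next
      p <- particle_perimeter_um(out$pixels[[i]], nr, gx, gy)
      out$perimeter_um[i] <- p$perimeter
      out$circularity[i] <- p$circularity %||%
        circularity_from_measurements(out$area_um2[i], p$perimeter)
    }
  }
  out
}

# 8-connected labeling: vectorized neighbour-edge construction + graph
# components (igraph). Returns per-on-pixel labels 1..N ordered by first
# pixel in column-major order.
label_components <- function(on, idx = which(on)) {
  nr <- nrow(on)
  nc <- ncol(on)
  n <- length(idx)
  rank <- integer(nr * nc)
  rank[idx] <- seq_len(n)
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L

  edges <- integer(0)
  # neighbour offsets: S (dr=1,dc=0), E (0,1), SE (1,1), NE (-1,1);
  # each undirected adjacency is generated once
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- row + off[1L]
    c2 <- col + off[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    if (!any(ok)) next
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- on[nb]
    if (!any(hit)) next
    edges <- c(edges, rbind(rank[idx[ok][hit]], rank[nb[hit]]))
  }
  if (length(edges) == 0L) {
    return(seq_len(n))                     # all isolated pixels
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, edges)
  memb <- igraph::components(g)$membership
  # relabel so that label order follows first occurrence in scan order
  first <- match(unique(memb), memb)
  relab <- integer(max(memb))
  relab[memb[sort(first)]] <- seq_along(first)
  relab[memb]
}

#' Circularity of a particle
#'
#' `4 * pi * area / perimeter^2`, clipped to at most 1 (small digital
#' particles can exceed 1 because chain perimeters underestimate short
#' boundaries; ImageJ clips the same way). A single-pixel particle has
#' circularity 1 by convention — it is maximally compact.
#'
#' @param area Area and perimeter in consistent units (e.g. um^2 and um).
#' @param perimeter Outer-boundary perimeter.
#' @return Circularity in `[0, 1]`.
#' @export
circularity_from_measurements <- function(area, perimeter) {
  if (perimeter <= 0) stop("perimeter must be > 0", call. = FALSE)
  min(1, 4 * pi * area / perimeter^2)
}

#' @rdname circularity_from_measurements
#' @param particle One row of a [label_particles()] table.
#' @export
circularity <- function(particle) {
  circularity_from_measurements(particle$area_um2, particle$perimeter_um)
}

#' Zero out masked pixels of an image
#'
#' The digital-subtraction primitive of the pipeline (the ImageJ
#' "Image Calculator AND" role): pixels under the removal mask are set to
#' 0; all other pixels are returned unchanged.
#'
#' @param pixels A [plane_image()] or numeric matrix.
#' @param removal A [binary_mask()] of the same shape.
#' @return Same type as `pixels`.
#' @export
subtract_mask <- function(pixels, removal) {
  stopifnot(inherits(removal, "binary_mask"))
  if (inherits(pixels, "plane_image")) {
    if (!identical(dim(pixels$pixels), dim(removal$on))) {
      stop("image and mask shapes differ", call. = FALSE)
    }
    pixels$pixels[removal$on] <- if (is.integer(pixels$pixels)) 0L else 0
    return(pixels)
  }
  if (!identical(dim(pixels), dim(removal$on))) {
    stop("image and mask shapes differ", call. = FALSE)
  }
  pixels[removal$on] <- if (is.integer(pixels)) 0L else 0
  pixels
}

# -- perimeter estimation -----------------------------------------------------

# Moore-neighbour outer-contour tracing with Jacob's stopping criterion.
# Perimeter = sum over contour steps; a straight step along x costs gx um,
# along y costs gy um, a diagonal step sqrt(gx^2 + gy^2). Single pixels get
# the unit-square perimeter 2*(gx+gy) and circularity 1 by convention.
particle_perimeter_um <- function(pix_idx, nr, gx, gy) {
  n <- length(pix_idx)
  if (n == 1L) {
    return(list(perimeter = 2 * (gx + gy), circularity = 1))
  }
  row <- (pix_idx - 1L) %% nr + 1L
  col <- (pix_idx - 1L) %/% nr + 1L
  r0 <- min(row); c0 <- min(col)
  h <- max(row) - r0 + 1L
  w <- max(col) - c0 + 1L
  # local padded grid: pixel (row, col) -> (row - r0 + 2, col - c0 + 2)
  m <- matrix(FALSE, h + 2L, w + 2L)
  m[cbind(row - r0 + 2L, col - c0 + 2L)] <- TRUE

  # start: topmost row, then leftmost column (its W neighbour is off)
  ord <- order(row, col)
  sr <- row[ord[1L]] - r0 + 2L
  sc <- col[ord[1L]] - c0 + 2L

  # clockwise Moore neighbourhood (y axis points down), 0-based directions
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)  # W NW N NE E SE S SW
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  step_len <- sqrt((dc * gx)^2 + (dr * gy)^2)

  cur_r <- sr; cur_c <- sc
  scan_from <- 0L            # W neighbour of the start pixel is off
  first_move <- NA_integer_
  perimeter <- 0
  max_iter <- 8L * n + 16L
  for (iter in seq_len(max_iter)) {
    found <- NA_integer_
    for (s in 0:7) {
      d <- (scan_from + s) %% 8L
      if (m[cur_r + dr[d + 1L], cur_c + dc[d + 1L]]) { found <- d; break }
    }
    if (is.na(found)) break                # cannot happen for n >= 2
    if (cur_r == sr && cur_c == sc && !is.na(first_move)) {
      if (found == first_move) break       # Jacob's stopping criterion
    }
    if (is.na(first_move)) first_move <- found
    perimeter <- perimeter + step_len[found + 1L]
    cur_r <- cur_r + dr[found + 1L]
    cur_c <- cur_c + dc[found + 1L]
    scan_from <- (found + 6L) %% 8L        # resume two steps back of entry
  }
  list(perimeter = perimeter, circularity = NULL)
}
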
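# Independent brute-force oracles and small fixture builders.
# These deliberately share no code with the package internals they check.

# BFS flood fill, 8-connectivity, labels assigned in column-major scan order
bfs_label <- function(on) {
  nr <- nrow(on)
  nc <- ncol(on)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (x0 in seq_len(nc)) {
    for (y0 in seq_len(nr)) {
      if (!on[y0, x0] || lab[y0, x0] > 0L) next
      cur <- cur + 1L
      qy <- y0; qx <- x0
      lab[y0, x0] <- cur
      while (length(qy) > 0L) {
        y <- qy[1L]; x <- qx[1L]
        qy <- qy[-1L]; qx <- qx[-1L]
        for (dy in -1:1) {
          for (dx in -1:1) {
            if (dy == 0L && dx == 0L) next
            y2 <- y + dy; x2 <- x + dx
            if (y2 < 1L || y2 > nr || x2 < 1L || x2 > nc) next
            if (on[y2, x2] && lab[y2, x2] == 0L) {
              lab[y2, x2] <- cur
              qy <- c(qy, y2); qx <- c(qx, x2)
            }
          }
        }
      }
    }
  }
  lab
}

# elementwise max over z by explicit loops
loop_mip <- function(vox, channel) {
  d <- dim(vox)
  out <- matrix(-Inf, d[1], d[2])
  for (z in seq_len(d[3])) {
    for (x in seq_len(d[2])) {
      for (y in seq_len(d[1])) {
        v <- vox[y, x, z, channel]
        if (v > out[y, x]) out[y, x] <- v
      }
    }
  }
  out
}

# pooled mean/SD by explicit per-region pixel enumeration
enum_background_stats <- function(pixels, regions, ext_y, ext_x) {
  seen <- c()
  vals <- c()
  for (i in seq_len(nrow(regions))) {
    for (dx in 0:(ext_x - 1)) {
      for (dy in 0:(ext_y - 1)) {
        y <- regions$y0[i] + dy
        x <- regions$x0[i] + dx
        key <- paste(y, x)
        if (key %in% seen) next
        seen <- c(seen, key)
        vals <- c(vals, pixels[y, x])
      }
    }
  }
  m <- sum(vals) / length(vals)
  list(mean = m, sd = sqrt(sum((vals - m)^2) / length(vals)))
}

# disk-shaped logical matrix
disk_mask <- function(ny, nx, cy, cx, r) {
  outer(seq_len(ny), seq_len(nx), function(y, x) (y - cy)^2 + (x - cx)^2 <= r^2)
}

# a plane image containing the given footprints at given intensities
plane_with <- function(ny, nx, ..., bit_depth = 8L,
                       geometry = pixel_geometry(1)) {
  objs <- list(...)
  px <- matrix(0, ny, nx)
  for (o in objs) px[o$mask] <- o$value
  plane_image(px, bit_depth, geometry)
}

# single-channel z-stack from a list of pixel matrices
stack_from_slices <- function(slices, bit_depth = 8L,
                              geometry = pixel_geometry(1), ...) {
  arr <- array(0, dim = c(dim(slices[[1]]), length(slices), 1L))
  for (z in seq_along(slices)) arr[, , z, 1L] <- slices[[z]]
  image_stack(arr, bit_depth, geometry, ...)
}

random_mask <- function(ny, nx, p_on = 0.35, geometry = pixel_geometry(1)) {
  binary_mask(matrix(stats::runif(ny * nx) < p_on, ny, nx), geometry)
}
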
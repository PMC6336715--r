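#' Physical pixel geometry
#'
#' Records the physical size of one pixel in micrometers along x and y.
#' All particle areas (um^2), perimeters (um) and background-region sizes
#' are derived from this geometry, so it must come from acquisition metadata
#' or be supplied explicitly. Anisotropic pixels are supported: area uses
#' `x_um * y_um`, perimeter steps are scaled per axis.
#'
#' @param x_um_per_px Pixel width in micrometers (> 0).
#' @param y_um_per_px Pixel height in micrometers; defaults to `x_um_per_px`.
#' @return An object of class `pixel_geometry`.
#' @examples
#' g <- pixel_geometry(0.83)
#' pixel_area_um2(g)
#' @export
pixel_geometry <- function(x_um_per_px, y_um_per_px = x_um_per_px) {
  if (!is.numeric(x_um_per_px) || length(x_um_per_px) != 1L ||
      !is.finite(x_um_per_px) || x_um_per_px <= 0) {
    stop("x_um_per_px must be a single finite value > 0", call. = FALSE)
  }
  if (!is.numeric(y_um_per_px) || length(y_um_per_px) != 1L ||
      !is.finite(y_um_per_px) || y_um_per_px <= 0) {
    stop("y_um_per_px must be a single finite value > 0", call. = FALSE)
  }
  structure(list(x_um = as.numeric(x_um_per_px),
                 y_um = as.numeric(y_um_per_px)),
            class = "pixel_geometry")
}

#' @rdname pixel_geometry
#' @param geometry A `pixel_geometry`.
#' @export
pixel_area_um2 <- function(geometry) {
  stopifnot(inherits(geometry, "pixel_geometry"))
  geometry$x_um * geometry$y_um
}

#' @export
print.pixel_geometry <- function(x, ...) {
  cat(sprintf("<pixel_geometry> %g x %g um/px (pixel area %g um^2)\n",
              x$x_um, x$y_um, pixel_area_um2(x)))
  invisible(x)
}

is_pixel_geometry <- function(x) inherits(x, "pixel_geometry")

`%||%` <- function(a, b) if (is.null(a)) b else a

geometry_equal <- function(a, b, tol = 1e-9) {
  abs(a$x_um - b$x_um) < tol && abs(a$y_um - b$y_um) < tol
}
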
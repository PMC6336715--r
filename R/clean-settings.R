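#' Cleaning-pipeline settings
#'
#' Full parameterization of the three artifact-removal stages. The defaults
#' are the published defaults of the method, optimized on fluorescently
#' labeled noradrenergic axons:
#'
#' * large-particle removal: up to five OR-combined (minimum area um^2,
#'   minimum circularity) gates — defaults 40/0.17, 25/0.32, 15/0.40,
#'   10/0.70, 5/0.80 — applied over four threshold iterations at 1.5, 2,
#'   2.5 and 3 SD above the mean. As circularity decreases the minimum
#'   removable size increases, so elongated fibers are never gated.
#' * autofluorescence subtraction: AF channel binarized per z-slice at 1 SD
#'   above the mean (raise `af_k` if bright fibers bleed into the AF
#'   channel).
#' * small-particle removal on the projection: particles with area <= 1 um^2
#'   and circularity in \[0.99, 1\] at a 1 SD threshold.
#'
#' @param criteria Data frame (or list of 2-vectors) with columns
#'   `min_area_um2`, `min_circularity`; 1 to 5 rows. A particle is removed
#'   when it satisfies *any* row (area >= min_area AND circularity >=
#'   min_circularity).
#' @param iteration_ks Strictly increasing threshold multipliers for the
#'   large-particle iterations.
#' @param af_k Threshold multiplier for AF binarization.
#' @param small_max_area_um2 Maximum area of a removable small particle.
#' @param small_circ_range Closed circularity interval for small-particle
#'   removal.
#' @param small_k Threshold multiplier for the small-particle stage.
#' @param use_af_subtraction Include the AF-subtraction stage?
#' @return An object of class `clean_settings`.
#' @examples
#' s <- clean_settings()           # published defaults
#' s$criteria
#' @export
clean_settings <- function(criteria = default_criteria(),
                           iteration_ks = c(1.5, 2, 2.5, 3),
                           af_k = 1,
                           small_max_area_um2 = 1,
                           small_circ_range = c(0.99, 1),
                           small_k = 1,
                           use_af_subtraction = TRUE) {
  criteria <- as_criteria(criteria)
  if (nrow(criteria) < 1L || nrow(criteria) > 5L) {
    stop("between 1 and 5 size/circularity criteria are allowed",
         call. = FALSE)
  }
  if (any(criteria$min_area_um2 <= 0)) {
    stop("min_area_um2 must be > 0", call. = FALSE)
  }
  if (any(criteria$min_circularity < 0 | criteria$min_circularity > 1)) {
    stop("min_circularity must be in [0, 1]", call. = FALSE)
  }
  if (length(iteration_ks) < 1L || any(diff(iteration_ks) <= 0)) {
    stop("iteration_ks must be strictly increasing", call. = FALSE)
  }
  if (any(iteration_ks < 0) || af_k < 0 || small_k < 0) {
    stop("threshold multipliers must be >= 0", call. = FALSE)
  }
  if (length(small_circ_range) != 2L || small_circ_range[1] > small_circ_range[2] ||
      small_circ_range[1] < 0 || small_circ_range[2] > 1) {
    stop("small_circ_range must be an interval within [0, 1]", call. = FALSE)
  }
  if (small_max_area_um2 <= 0) {
    stop("small_max_area_um2 must be > 0", call. = FALSE)
  }
  structure(list(criteria = criteria,
                 iteration_ks = as.numeric(iteration_ks),
                 af_k = as.numeric(af_k),
                 small_max_area_um2 = as.numeric(small_max_area_um2),
                 small_circ_range = as.numeric(small_circ_range),
                 small_k = as.numeric(small_k),
                 use_af_subtraction = isTRUE(use_af_subtraction)),
            class = "clean_settings")
}

#' @rdname clean_settings
#' @export
default_criteria <- function() {
  data.frame(min_area_um2 = c(40, 25, 15, 10, 5),
             min_circularity = c(0.17, 0.32, 0.40, 0.70, 0.80))
}

as_criteria <- function(criteria) {
  if (is.data.frame(criteria)) {
    stopifnot(all(c("min_area_um2", "min_circularity") %in% names(criteria)))
    return(data.frame(min_area_um2 = as.numeric(criteria$min_area_um2),
                      min_circularity = as.numeric(criteria$min_circularity)))
  }
  if (is.list(criteria)) {
    m <- do.call(rbind, lapply(criteria, function(x) as.numeric(x[1:2])))
    return(data.frame(min_area_um2 = m[, 1], min_circularity = m[, 2]))
  }
  stop("criteria must be a data frame or a list of (area, circularity) pairs",
       call. = FALSE)
}

#' @export
print.clean_settings <- function(x, ...) {
  cat("<clean_settings>\n  large-particle criteria (area um^2 / circularity):\n")
  cat(sprintf("    %g/%g", x$criteria$min_area_um2, x$criteria$min_circularity),
      sep = "\n")
  cat(sprintf("  iteration thresholds: mean + {%s} SD\n",
              paste(x$iteration_ks, collapse = ", ")))
  cat(sprintf("  AF subtraction: %s (af_k = %g)\n",
              if (x$use_af_subtraction) "on" else "off", x$af_k))
  cat(sprintf("  small-particle: area <= %g um^2, circularity [%g, %g], k = %g\n",
              x$small_max_area_um2, x$small_circ_range[1],
              x$small_circ_range[2], x$small_k))
  invisible(x)
}

#' Read / write cleaning settings as YAML
#'
#' Key names mirror the fields of [clean_settings()]; missing keys fall
#' back to the defaults, so a config file only needs the overrides.
#'
#' @param path YAML file path.
#' @return A `clean_settings` (for `read_clean_settings`); `path` invisibly
#'   (for `write_clean_settings`).
#' @export
read_clean_settings <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("settings file not found: %s", path), call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  defaults <- clean_settings()
  crit <- if (is.null(y$criteria)) defaults$criteria else {
    as_criteria(lapply(y$criteria, unlist))
  }
  clean_settings(
    criteria = crit,
    iteration_ks = unlist(y$iteration_ks) %||% defaults$iteration_ks,
    af_k = y$af_k %||% defaults$af_k,
    small_max_area_um2 = y$small_max_area_um2 %||% defaults$small_max_area_um2,
    small_circ_range = unlist(y$small_circ_range) %||% defaults$small_circ_range,
    small_k = y$small_k %||% defaults$small_k,
    use_af_subtraction = y$use_af_subtraction %||% defaults$use_af_subtraction)
}

#' @rdname read_clean_settings
#' @param settings A [clean_settings()].
#' @export
write_clean_settings <- function(settings, path) {
  stopifnot(inherits(settings, "clean_settings"))
  yaml::write_yaml(list(
    criteria = lapply(seq_len(nrow(settings$criteria)), function(i) {
      as.list(settings$criteria[i, ])
    }),
    iteration_ks = settings$iteration_ks,
    af_k = settings$af_k,
    small_max_area_um2 = settings$small_max_area_um2,
    small_circ_range = settings$small_circ_range,
    small_k = settings$small_k,
    use_af_subtraction = settings$use_af_subtraction), path)
  invisible(path)
}
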
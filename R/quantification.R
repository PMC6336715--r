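#' Background calibration regions
#'
#' Fiber quantification is calibrated on small, user-chosen, axon-free
#' patches (by default ten 12 x 12 um squares). Regions are given by the
#' 1-based pixel coordinates of their top-left corner; the pixel extent of
#' a side is `round(side_um / um_per_px)` per axis, at least 1 px.
#'
#' @param y0,x0 Top-left pixel coordinates (vectors allowed).
#' @param side_um Physical side length (default 12 um).
#' @return Data frame of class `background_regions`.
#' @export
background_regions <- function(y0, x0, side_um = 12) {
  stopifnot(length(y0) == length(x0), all(y0 >= 1), all(x0 >= 1))
  out <- data.frame(y0 = as.integer(y0), x0 = as.integer(x0),
                    side_um = as.numeric(side_um))
  class(out) <- c("background_regions", class(out))
  out
}

region_extent_px <- function(side_um, geometry) {
  c(y = max(1L, as.integer(round(side_um / geometry$y_um))),
    x = max(1L, as.integer(round(side_um / geometry$x_um))))
}

region_indices <- function(mip, regions) {
  dims <- dim(mip$pixels)
  idx_list <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    ext <- region_extent_px(regions$side_um[i], mip$geometry)
    y1 <- regions$y0[i] + ext["y"] - 1L
    x1 <- regions$x0[i] + ext["x"] - 1L
    if (regions$y0[i] < 1L || regions$x0[i] < 1L ||
        y1 > dims[1L] || x1 > dims[2L]) {
      stop(sprintf(
        "background region %d (y0=%d, x0=%d, %d x %d px) is out of bounds",
        i, regions$y0[i], regions$x0[i], ext["y"], ext["x"]), call. = FALSE)
    }
    ys <- regions$y0[i]:y1
    xs <- regions$x0[i]:x1
    idx_list[[i]] <- as.vector(outer(ys, (xs - 1L) * dims[1L], `+`))
  }
  idx_list
}

#' Pooled background statistics over calibration regions
#'
#' Mean and population SD over the pooled pixel multiset of all regions
#' (pooling all sampled pixels is better conditioned than averaging
#' per-region means). Overlapping regions raise a warning and overlapping
#' pixels are counted once.
#'
#' @param mip A [plane_image()].
#' @param regions A [background_regions()] table.
#' @param n_required Number of regions demanded (default 10; `NULL`
#'   disables the check).
#' @return `list(mean =, sd =, n_px =)`.
#' @export
background_stats <- function(mip, regions, n_required = 10L) {
  stopifnot(inherits(mip, "plane_image"))
  if (!is.null(n_required) && nrow(regions) != n_required) {
    stop(sprintf("expected %d background regions, got %d (set n_required to change)",
                 n_required, nrow(regions)), call. = FALSE)
  }
  if (nrow(regions) < 1L) stop("at least one region required", call. = FALSE)
  idx_list <- region_indices(mip, regions)
  idx <- unlist(idx_list, use.names = FALSE)
  if (anyDuplicated(idx)) {
    warning("background regions overlap; overlapping pixels counted once",
            call. = FALSE)
    idx <- unique(idx)
  }
  vals <- mip$pixels[idx]
  list(mean = mean(vals), sd = pop_sd(vals), n_px = length(vals))
}

#' Quantify fiber area above a background-calibrated threshold
#'
#' The threshold is set `k` standard deviations (default 4) above the mean
#' intensity of the background regions; the area (um^2) occupied by pixels
#' strictly above the threshold is reported as fiber area, together with
#' the binary fiber mask.
#'
#' @inheritParams background_stats
#' @param k Threshold multiplier (default 4).
#' @param source Identifier stored in the result (defaults to the image
#'   name).
#' @return An object of class `quantify_result`: `background_mean`,
#'   `background_sd`, `threshold`, `fiber_area_um2`, `fiber_mask`
#'   (a [binary_mask()]), `source_image`.
#' @export
quantify_fibers <- function(mip, regions, k = 4, n_required = 10L,
                            source = NULL) {
  stats <- background_stats(mip, regions, n_required = n_required)
  threshold <- stats$mean + k * stats$sd
  mask <- binarize(mip, threshold)
  structure(list(background_mean = stats$mean,
                 background_sd = stats$sd,
                 threshold = threshold,
                 fiber_area_um2 = sum(mask$on) * pixel_area_um2(mip$geometry),
                 fiber_mask = mask,
                 k = k,
                 source_image = source %||% mip$name %||% "<in-memory>"),
            class = "quantify_result")
}

#' @export
print.quantify_result <- function(x, ...) {
  cat(sprintf(
    "<quantify_result> %s\n  background %0.3f +/- %0.3f -> threshold %0.3f (k = %g)\n  fiber area: %0.3f um^2 (%d px)\n",
    x$source_image, x$background_mean, x$background_sd, x$threshold, x$k,
    x$fiber_area_um2, sum(x$fiber_mask$on)))
  invisible(x)
}

#' Propose background regions automatically
#'
#' Convenience extension for headless runs (the reference procedure is
#' interactive): tiles the image with non-overlapping `side_um` squares and
#' proposes the `n` tiles with the lowest mean intensity as background
#' regions. Always review the proposal on images with large dark
#' non-tissue areas.
#'
#' @param mip A [plane_image()].
#' @param n Number of regions (default 10).
#' @param side_um Region side (default 12 um).
#' @return A [background_regions()] table.
#' @export
propose_regions <- function(mip, n = 10L, side_um = 12) {
  stopifnot(inherits(mip, "plane_image"))
  ext <- region_extent_px(side_um, mip$geometry)
  dims <- dim(mip$pixels)
  ys <- seq(1L, dims[1L] - ext["y"] + 1L, by = ext["y"])
  xs <- seq(1L, dims[2L] - ext["x"] + 1L, by = ext["x"])
  if (length(ys) * length(xs) < n) {
    stop("image too small for the requested number of regions", call. = FALSE)
  }
  tiles <- expand.grid(y0 = ys, x0 = xs)
  tiles$mean <- vapply(seq_len(nrow(tiles)), function(i) {
    mean(mip$pixels[tiles$y0[i]:(tiles$y0[i] + ext["y"] - 1L),
                    tiles$x0[i]:(tiles$x0[i] + ext["x"] - 1L)])
  }, numeric(1L))
  tiles <- tiles[order(tiles$mean, tiles$y0, tiles$x0), ][seq_len(n), ]
  background_regions(tiles$y0, tiles$x0, side_um = side_um)
}

#' Read background regions from a sidecar CSV
#'
#' Plain CSV with columns `y0,x0` (and optionally `side_um`), one row per
#' region. Coordinates are 1-based pixels by default; with `units = "um"`
#' they are physical offsets from the image origin and are converted using
#' `geometry`.
#'
#' @param path CSV path.
#' @param units `"px"` or `"um"`.
#' @param geometry Required for `units = "um"`.
#' @param side_um Default side when the file has no `side_um` column.
#' @return A [background_regions()] table.
#' @export
read_regions <- function(path, units = c("px", "um"), geometry = NULL,
                         side_um = 12) {
  units <- match.arg(units)
  df <- utils::read.csv(path)
  stopifnot(all(c("y0", "x0") %in% names(df)))
  if (units == "um") {
    stopifnot(is_pixel_geometry(geometry))
    df$y0 <- round(df$y0 / geometry$y_um) + 1L
    df$x0 <- round(df$x0 / geometry$x_um) + 1L
  }
  background_regions(df$y0, df$x0, side_um = df$side_um %||% side_um)
}

#' Quantify every projection image in a folder
#'
#' Runs [quantify_fibers()] on every single-plane TIFF in `folder`.
#' Regions come either from the `regions` argument (a single table applied
#' to all images, or a named list keyed by file stem) or from per-image
#' sidecar files `<stem>_regions.csv`. Images without regions are skipped
#' with a warning and flagged in the report. Results are written as a
#' tab-delimited report plus per-image binary fiber masks in a dated
#' `DEFiNE_Quantified_Fibers_*` folder.
#'
#' @param folder Directory of single-plane TIFF images.
#' @param regions `NULL` (use sidecars), one [background_regions()] table,
#'   or a named list of tables.
#' @param k Threshold multiplier (default 4).
#' @param n_required Regions demanded per image (default 10).
#' @param out_root Where to create the output folder (default `folder`).
#' @param run_date Date used in the folder name.
#' @param geometry_override Optional [pixel_geometry()] for images without
#'   metadata.
#' @return Invisibly, `list(report, report_path, mask_paths, n_skipped)`;
#'   the report has columns `image`, `background_mean`, `background_sd`,
#'   `threshold`, `fiber_area_um2`, `status`.
#' @export
quantify_batch <- function(folder, regions = NULL, k = 4, n_required = 10L,
                           out_root = folder, run_date = Sys.Date(),
                           geometry_override = NULL) {
  files <- sort(list.files(folder, pattern = "\\.tiff?$", full.names = TRUE,
                           ignore.case = TRUE))
  out_dir <- file.path(out_root, define_folder_name("quantified", run_date))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  masks <- list()
  n_skipped <- 0L
  for (f in files) {
    stem <- tools::file_path_sans_ext(basename(f))
    reg <- lookup_regions(regions, stem, folder)
    if (is.null(reg)) {
      warning(sprintf("no background regions for %s; skipped", basename(f)),
              call. = FALSE)
      rows[[stem]] <- data.frame(image = stem, background_mean = NA,
                                 background_sd = NA, threshold = NA,
                                 fiber_area_um2 = NA, status = "no_regions")
      n_skipped <- n_skipped + 1L
      next
    }
    mip <- read_plane(f, geometry_override = geometry_override)
    res <- quantify_fibers(mip, reg, k = k, n_required = n_required,
                           source = stem)
    rows[[stem]] <- data.frame(image = stem,
                               background_mean = res$background_mean,
                               background_sd = res$background_sd,
                               threshold = res$threshold,
                               fiber_area_um2 = res$fiber_area_um2,
                               status = "ok")
    masks[[paste0(stem, "_fibers")]] <-
      mask_to_plane(res$fiber_mask, name = paste0(stem, "_fibers"))
  }
  report <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
  else data.frame(image = character(0), background_mean = numeric(0),
                  background_sd = numeric(0), threshold = numeric(0),
                  fiber_area_um2 = numeric(0), status = character(0))
  report_path <- file.path(out_dir, "quantified_fibers.tsv")
  write_report(report, report_path)
  mask_paths <- if (length(masks)) {
    write_outputs(masks, run_date = run_date, kind = "quantified",
                  out_root = out_root)
  } else character(0)
  invisible(list(report = report, report_path = report_path,
                 mask_paths = mask_paths, n_skipped = n_skipped))
}

lookup_regions <- function(regions, stem, folder) {
  if (inherits(regions, "background_regions")) return(regions)
  if (is.list(regions) && !is.null(regions[[stem]])) return(regions[[stem]])
  if (is.null(regions)) {
    sidecar <- file.path(folder, paste0(stem, "_regions.csv"))
    if (file.exists(sidecar)) return(read_regions(sidecar))
  }
  NULL
}

write_report <- function(report, path) {
  num <- vapply(report, is.numeric, logical(1L))
  report[num] <- lapply(report[num], function(x) sprintf("%.6g", x))
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
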
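#' Preview cleaning on a representative stack
#'
#' Runs the full cleaning pipeline on one stack while recording every
#' removed particle (with its measured area, circularity, stage and
#' threshold multiplier), and returns the first signal channel's
#' projection before and after. This is the non-interactive counterpart of
#' a settings-optimization preview: inspect `removed_particles`, mark
#' mistakes, and feed the markings to [recommend_settings()].
#'
#' @param stack An [image_stack()].
#' @param settings A [clean_settings()].
#' @return An object of class `clean_preview`: `before` / `after`
#'   ([plane_image()]s), `removed_particles` (data frame with list-column
#'   `pixels` of linear indices), plus the `stack` and `settings` used.
#' @export
preview_processing <- function(stack, settings = clean_settings()) {
  stopifnot(inherits(stack, "image_stack"))
  rec <- new_recorder()
  ch <- signal_channels(stack)[1L]
  before <- max_intensity_projection(stack, ch)
  cleaned <- clean_images(stack, settings, recorder = rec)
  structure(list(before = before,
                 after = cleaned[[stack$channel_names[ch]]],
                 removed_particles = recorded_removals(rec),
                 cleaned = cleaned,
                 stack = stack,
                 settings = settings),
            class = "clean_preview")
}

#' @export
print.clean_preview <- function(x, ...) {
  rp <- x$removed_particles
  cat(sprintf("<clean_preview> %d particle(s) removed (%d large-stage, %d small-stage)\n",
              nrow(rp), sum(rp$stage == "large"), sum(rp$stage == "small")))
  invisible(x)
}

#' User markings of processing mistakes
#'
#' @param kind `"wrongly_removed_fiber"` (an axon the pipeline deleted) or
#'   `"wrongly_kept_artifact"` (an artifact it retained). Vectors allowed.
#' @param y,x Seed-point pixel coordinates inside the object (1-based).
#' @return Data frame of class `markings`.
#' @export
markings <- function(kind, y, x) {
  kind <- match.arg(kind, c("wrongly_removed_fiber", "wrongly_kept_artifact"),
                    several.ok = TRUE)
  kind <- rep_len(kind, length(y))
  stopifnot(length(y) == length(x))
  out <- data.frame(kind = kind, y = as.integer(y), x = as.integer(x))
  class(out) <- c("markings", class(out))
  out
}

#' @rdname markings
#' @param path CSV with columns `kind,y,x`.
#' @export
read_markings <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("kind", "y", "x") %in% names(df)))
  markings(df$kind, df$y, df$x)
}

#' Recommend revised cleaning settings from marked mistakes
#'
#' The recommendation rule (the reference implementation promises
#' recommendations but does not publish its heuristic, so this rule is this
#' package's own, deliberately isolated here):
#'
#' * For each `wrongly_removed_fiber` marking that hits a removed particle
#'   P, every criterion that P satisfied is tightened minimally so P no
#'   longer matches: raise that criterion's minimum area to
#'   `1.01 * P$area_um2` or its minimum circularity to
#'   `1.01 * P$circularity` (capped at 1), whichever is the smaller
#'   relative change.
#' * For each `wrongly_kept_artifact` marking: the particle at that
#'   location is measured in the *after* image binarized at the
#'   least-stringent iteration threshold. If it is found and matches no
#'   criterion, the one criterion needing the smallest relative loosening
#'   is relaxed (with a 1% capture margin). If it is not found (the
#'   artifact is sub-threshold for morphology) or already matches a
#'   criterion, the AF channel is consulted: when the artifact is visible
#'   there above a cutoff lower than the current `af_k`, a reduced `af_k`
#'   is recommended (never below 0.5); otherwise the artifact is reported
#'   as not separable by the available features.
#'
#' @param preview A `clean_preview` from [preview_processing()].
#' @param marks A [markings()] table (must be non-empty).
#' @return A [clean_settings()]; attribute `"notes"` carries one message
#'   per marking describing what was done.
#' @export
recommend_settings <- function(preview, marks) {
  stopifnot(inherits(preview, "clean_preview"), inherits(marks, "markings"))
  if (nrow(marks) == 0L) stop("at least one marking is required",
                              call. = FALSE)
  settings <- preview$settings
  crit <- settings$criteria
  notes <- character(0)
  nr <- nrow(preview$before$pixels)

  for (i in seq_len(nrow(marks))) {
    yx <- c(marks$y[i], marks$x[i])
    lin <- (yx[2L] - 1L) * nr + yx[1L]
    if (marks$kind[i] == "wrongly_removed_fiber") {
      p <- find_removed_particle(preview$removed_particles, lin)
      if (is.null(p)) {
        notes <- c(notes, sprintf(
          "marking %d: no removed particle at (%d, %d); ignored",
          i, yx[1L], yx[2L]))
        next
      }
      upd <- tighten_criteria(crit, p$area_um2, p$circularity)
      crit <- upd$criteria
      notes <- c(notes, sprintf(
        "marking %d: protected fiber (%.3g um^2, circ %.3g); %s",
        i, p$area_um2, p$circularity, upd$note))
    } else {
      res <- handle_kept_artifact(preview, settings, crit, yx, lin)
      crit <- res$criteria
      if (!is.null(res$af_k)) settings$af_k <- res$af_k
      notes <- c(notes, sprintf("marking %d: %s", i, res$note))
    }
  }
  out <- clean_settings(criteria = crit,
                        iteration_ks = settings$iteration_ks,
                        af_k = settings$af_k,
                        small_max_area_um2 = settings$small_max_area_um2,
                        small_circ_range = settings$small_circ_range,
                        small_k = settings$small_k,
                        use_af_subtraction = settings$use_af_subtraction)
  attr(out, "notes") <- notes
  out
}

find_removed_particle <- function(removed, lin) {
  if (nrow(removed) == 0L) return(NULL)
  for (j in seq_len(nrow(removed))) {
    if (lin %in% removed$pixels[[j]]) return(removed[j, , drop = FALSE])
  }
  NULL
}

# Tighten every criterion matched by (area, circ) so it no longer matches,
# choosing per criterion the smaller relative change between raising the
# area floor and raising the circularity floor.
tighten_criteria <- function(crit, area, circ) {
  changed <- character(0)
  for (j in seq_len(nrow(crit))) {
    if (area >= crit$min_area_um2[j] && circ >= crit$min_circularity[j]) {
      area_target <- area * 1.01
      circ_target <- circ * 1.01
      rel_area <- (area_target - crit$min_area_um2[j]) / crit$min_area_um2[j]
      rel_circ <- if (circ_target > 1 || crit$min_circularity[j] <= 0) Inf
      else (circ_target - crit$min_circularity[j]) / crit$min_circularity[j]
      if (rel_circ <= rel_area) {
        crit$min_circularity[j] <- min(1, circ_target)
        changed <- c(changed, sprintf("criterion %d circularity -> %.4g",
                                      j, crit$min_circularity[j]))
      } else {
        crit$min_area_um2[j] <- area_target
        changed <- c(changed, sprintf("criterion %d area -> %.4g um^2",
                                      j, crit$min_area_um2[j]))
      }
    }
  }
  list(criteria = crit,
       note = if (length(changed)) paste(changed, collapse = "; ")
       else "matched no criterion; unchanged")
}

handle_kept_artifact <- function(preview, settings, crit, yx, lin) {
  after <- preview$after
  th <- sd_threshold(after$pixels, min(settings$iteration_ks))
  mask <- binarize(after$pixels, th, after$geometry)
  part <- NULL
  if (mask$on[yx[1L], yx[2L]]) {
    parts <- label_particles(mask)
    for (j in seq_len(nrow(parts))) {
      if (lin %in% parts$pixels[[j]]) { part <- parts[j, , drop = FALSE]; break }
    }
  }
  if (!is.null(part) && !any(part$area_um2 >= crit$min_area_um2 &
                               part$circularity >= crit$min_circularity)) {
    # loosen the criterion needing the smallest total relative decrease
    best <- NULL
    for (j in seq_len(nrow(crit))) {
      rel <- 0
      na <- crit$min_area_um2[j]
      nc <- crit$min_circularity[j]
      if (na > part$area_um2) {
        rel <- rel + (na - part$area_um2) / na
        na <- part$area_um2 * 0.99
      }
      if (nc > part$circularity) {
        rel <- rel + if (nc > 0) (nc - part$circularity) / nc else 0
        nc <- part$circularity * 0.99
      }
      if (is.null(best) || rel < best$rel) {
        best <- list(rel = rel, j = j, na = na, nc = nc)
      }
    }
    crit$min_area_um2[best$j] <- best$na
    crit$min_circularity[best$j] <- max(0, best$nc)
    return(list(criteria = crit, af_k = NULL, note = sprintf(
      "artifact (%.3g um^2, circ %.3g) captured by loosening criterion %d to %.3g/%.3g",
      part$area_um2, part$circularity, best$j, best$na, max(0, best$nc))))
  }
  # morphology cannot separate it: try the AF channel
  stack <- preview$stack
  if (!is.null(stack$af_channel)) {
    k_capture <- af_capture_k(stack, yx)
    if (is.finite(k_capture) && k_capture > 0.5) {
      new_k <- max(0.5, min(settings$af_k, k_capture * 0.99))
      if (new_k < settings$af_k) {
        return(list(criteria = crit, af_k = new_k, note = sprintf(
          "artifact visible in AF channel up to k = %.3g; af_k lowered to %.3g",
          k_capture, new_k)))
      }
    }
  }
  list(criteria = crit, af_k = NULL,
       note = "artifact not separable by size/circularity or AF intensity")
}

# Largest multiplier k at which the AF intensity at (y, x) in some z-slice
# still exceeds that slice's mean + k * SD.
af_capture_k <- function(stack, yx) {
  af <- stack$af_channel
  ks <- vapply(seq_len(n_slices(stack)), function(z) {
    sl <- slice_matrix(stack, z, af)
    s <- pop_sd(sl)
    if (s == 0) return(-Inf)
    (sl[yx[1L], yx[2L]] - mean(sl)) / s
  }, numeric(1L))
  max(ks)
}
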
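# Event slicing and fixation/dwell extraction.
#
# During the LE test the right eye holds the examiner's light, so target
# assignment keys on the *fixating* eye; the tested eye carries the deviation.
# Fixations use dispersion-threshold identification (I-DT): maximal windows
# whose x-range + y-range stays under a threshold for a minimum duration,
# with invalid samples breaking windows.

#' Dwell detection parameters
#'
#' @param radius_cm acceptance radius around a target for the fixating eye
#'   (default 7.5, i.e. 1.5 grid squares)
#' @param min_duration_s minimum dwell duration in seconds (default 0.3)
#' @param min_valid_frac minimum fraction of binocularly valid samples within
#'   a dwell (default 0.8)
#' @param dispersion_max_cm maximum I-DT dispersion (x-range + y-range, cm)
#'   within a dwell (default 6; must exceed the spatial range that the
#'   tracker's own noise produces over `min_duration_s` — see the methods
#'   vignette)
#' @param selection `"last"` (default; the subject's final confirmed placement)
#'   or `"longest"` qualifying window per target
#' @param max_missing_frac fraction of targets allowed to be missing before a
#'   quality error advises re-recording (default 0.5)
#' @return a `dwell_params` list
#' @export
dwell_params <- function(radius_cm = 7.5, min_duration_s = 0.3,
                         min_valid_frac = 0.8, dispersion_max_cm = 6.0,
                         selection = c("last", "longest"),
                         max_missing_frac = 0.5) {
  selection <- match.arg(selection)
  if (radius_cm <= 0 || min_duration_s <= 0 || dispersion_max_cm <= 0)
    hg_config_error("dwell radius, duration and dispersion must be positive")
  if (min_valid_frac <= 0 || min_valid_frac > 1)
    hg_config_error("min_valid_frac must lie in (0, 1]")
  structure(list(radius_cm = radius_cm, min_duration_s = min_duration_s,
                 min_valid_frac = min_valid_frac,
                 dispersion_max_cm = dispersion_max_cm,
                 selection = selection, max_missing_frac = max_missing_frac),
            class = "dwell_params")
}

.hg_other_eye <- function(eye) c(LE = "RE", RE = "LE")[[eye]]

.hg_eye_cols <- function(eye) {
  if (eye == "LE") list(x = "left_x_cm", y = "left_y_cm", v = "left_valid")
  else list(x = "right_x_cm", y = "right_y_cm", v = "right_valid")
}

#' Extract the LE-test or RE-test event from a recording
#'
#' @param recording a [gaze_recording()]
#' @param annotations an [event_annotations()] object
#' @param which `"LE"` or `"RE"`: which eye was under test
#' @return a [gaze_recording()] restricted to the event, with `meta$tested_eye`
#'   set to `which` and `meta$fixating_eye` to the other eye (which held the
#'   examiner's light during that event)
#' @export
slice_event <- function(recording, annotations, which = c("LE", "RE")) {
  which <- match.arg(which)
  iv <- if (which == "LE") annotations$le else annotations$re
  t <- recording$samples$t_s
  span <- range(t)
  if (iv[1] < span[1] - 1e-9 || iv[2] > span[2] + 1e-9)
    hg_segmentation_error(sprintf(
      "%s event [%g, %g] lies outside the recording span [%g, %g]",
      which, iv[1], iv[2], span[1], span[2]))
  keep <- t >= iv[1] & t <= iv[2]
  if (sum(keep) < 2L)
    hg_segmentation_error(sprintf("%s event slice is empty", which))
  meta <- recording$meta
  meta$tested_eye <- which
  meta$fixating_eye <- .hg_other_eye(which)
  gaze_recording(recording$samples[keep, ], subject_id = recording$subject_id,
                 rate_hz = recording$rate_hz, meta = meta)
}

# Greedy I-DT over one run of consecutive valid samples (indices into the
# full sample frame). Dispersion = (max x - min x) + (max y - min y) is
# monotone non-decreasing as a window grows, so the maximal extension of a
# window from a given start is well defined; windows are taken greedily from
# the earliest qualifying start and do not overlap.
.hg_idt_run <- function(x, y, t, idx, dispersion_max, min_duration) {
  n <- length(idx)
  out <- list()
  i <- 1L
  while (i <= n) {
    xmin <- x[i]; xmax <- x[i]; ymin <- y[i]; ymax <- y[i]
    j <- i
    while (j < n) {
      nx <- x[j + 1L]; ny <- y[j + 1L]
      d <- (max(xmax, nx) - min(xmin, nx)) + (max(ymax, ny) - min(ymin, ny))
      if (d > dispersion_max) break
      j <- j + 1L
      xmin <- min(xmin, nx); xmax <- max(xmax, nx)
      ymin <- min(ymin, ny); ymax <- max(ymax, ny)
    }
    if (t[j] - t[i] >= min_duration) {
      out[[length(out) + 1L]] <- c(i_start = idx[i], i_end = idx[j],
                                   t_start = t[i], t_end = t[j])
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Dispersion-threshold (I-DT) fixation identification
#'
#' Finds maximal non-overlapping windows in one eye's gaze stream whose
#' dispersion (x-range + y-range) stays at or below `dispersion_max_cm` for at
#' least `min_duration_s`. Invalid samples break windows: a fixation never
#' spans a tracking gap.
#'
#' @param recording a [gaze_recording()] (typically an event slice)
#' @param dispersion_max_cm dispersion threshold (cm)
#' @param min_duration_s minimum duration (s), measured first-to-last sample
#' @param eye `"LE"` or `"RE"`
#' @return data.frame with columns `t_start`, `t_end`, `i_start`, `i_end`
#'   (sample indices into `recording$samples`); zero rows if none qualify
#' @export
idt_fixations <- function(recording, dispersion_max_cm, min_duration_s,
                          eye = c("LE", "RE")) {
  eye <- match.arg(eye)
  cols <- .hg_eye_cols(eye)
  s <- recording$samples
  valid <- s[[cols$v]]
  if (!any(valid)) hg_segmentation_error(sprintf("no valid %s samples", eye))
  runs <- .hg_valid_runs(valid)
  fixes <- list()
  for (r in seq_len(nrow(runs))) {
    idx <- runs$start[r]:runs$end[r]
    fixes <- c(fixes, .hg_idt_run(s[[cols$x]][idx], s[[cols$y]][idx],
                                  s$t_s[idx], idx,
                                  dispersion_max_cm, min_duration_s))
  }
  if (!length(fixes)) {
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      i_start = integer(0), i_end = integer(0)))
  }
  m <- do.call(rbind, fixes)
  out <- data.frame(t_start = unname(m[, "t_start"]), t_end = unname(m[, "t_end"]),
                    i_start = as.integer(m[, "i_start"]),
                    i_end = as.integer(m[, "i_end"]))
  rownames(out) <- NULL
  out
}

# runs of TRUE in a logical vector -> data.frame(start, end)
.hg_valid_runs <- function(valid) {
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Detect per-target fixation dwells in an event slice
#'
#' For each target in traversal order, candidate windows are I-DT fixations of
#' the fixating eye within `radius_cm` of the target that additionally pass
#' the binocular-validity floor. Per target the last (default) or longest
#' qualifying window is selected — the subject adjusts their light and the
#' examiner records the final placement. Targets with no qualifying window are
#' reported missing, never fabricated.
#'
#' @param event_slice a [slice_event()] result (needs `meta$fixating_eye`)
#' @param grid a `target_grid`
#' @param params a [dwell_params()]
#' @param order traversal order (default: the grid's `traversal_order`)
#' @return data.frame of class `dwell_set`: columns `target_id`, `t_start`,
#'   `t_end`, `i_start`, `i_end`, `valid_frac`, `fixating_eye`; attribute
#'   `missing_ids` lists undetected targets
#' @export
detect_dwells <- function(event_slice, grid, params = dwell_params(),
                          order = NULL) {
  fix_eye <- event_slice$meta$fixating_eye
  if (is.null(fix_eye))
    hg_segmentation_error("event slice has no fixating eye; use slice_event() first")
  if (is.null(order)) order <- attr(grid, "traversal_order")
  order <- intersect(order, grid$id)
  cols <- .hg_eye_cols(fix_eye)
  s <- event_slice$samples
  binoc_valid <- s$left_valid & s$right_valid
  rows <- list()
  missing_ids <- integer(0)
  for (id in order) {
    gx <- grid$x_cm[grid$id == id]
    gy <- grid$y_cm[grid$id == id]
    near <- s[[cols$v]] &
      sqrt((s[[cols$x]] - gx)^2 + (s[[cols$y]] - gy)^2) <= params$radius_cm
    near[is.na(near)] <- FALSE
    runs <- .hg_valid_runs(near)
    qual <- list()
    for (r in seq_len(nrow(runs))) {
      idx <- runs$start[r]:runs$end[r]
      wins <- .hg_idt_run(s[[cols$x]][idx], s[[cols$y]][idx], s$t_s[idx], idx,
                          params$dispersion_max_cm, params$min_duration_s)
      for (w in wins) {
        vf <- mean(binoc_valid[w[["i_start"]]:w[["i_end"]]])
        if (vf >= params$min_valid_frac) qual[[length(qual) + 1L]] <- c(w, valid_frac = vf)
      }
    }
    if (!length(qual)) {
      missing_ids <- c(missing_ids, id)
      next
    }
    pick <- if (params$selection == "longest") {
      which.max(vapply(qual, function(w) w[["t_end"]] - w[["t_start"]], 0))
    } else {
      which.max(vapply(qual, function(w) w[["t_start"]], 0))
    }
    w <- qual[[pick]]
    rows[[length(rows) + 1L]] <- data.frame(
      target_id = id, t_start = w[["t_start"]], t_end = w[["t_end"]],
      i_start = as.integer(w[["i_start"]]), i_end = as.integer(w[["i_end"]]),
      valid_frac = w[["valid_frac"]], fixating_eye = fix_eye,
      stringsAsFactors = FALSE
    )
  }
  if (length(missing_ids) > params$max_missing_frac * length(order))
    hg_quality_error(sprintf(
      "%d of %d targets have no usable dwell; the recording should be repeated",
      length(missing_ids), length(order)))
  if (length(missing_ids))
    hg_warn_quality(sprintf(
      "no qualifying dwell for target(s) %s in %s event; reported missing",
      paste(missing_ids, collapse = ", "),
      event_slice$meta$tested_eye %||% "?"))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(target_id = integer(0), t_start = numeric(0), t_end = numeric(0),
               i_start = integer(0), i_end = integer(0), valid_frac = numeric(0),
               fixating_eye = character(0))
  attr(out, "missing_ids") <- missing_ids
  class(out) <- c("dwell_set", "data.frame")
  out
}

#' Per-eye robust fixation estimate within a dwell
#'
#' Coordinate-wise center (median by default; resists blinks and flicks) over
#' each eye's valid samples inside the dwell window. An eye with zero valid
#' samples gets a missing estimate, flagged rather than fabricated.
#'
#' @param event_slice the [slice_event()] result the dwell indexes into
#' @param dwell one row of a [detect_dwells()] result (or an equivalent list
#'   with `i_start`, `i_end`, `target_id`)
#' @param center `"median"` (default) or `"mean"`
#' @return object of class `fixation_estimate`: per-eye `(x_cm, y_cm)` or `NA`,
#'   `n_valid_le`, `n_valid_re`, `target_id`
#' @export
estimate_fixation <- function(event_slice, dwell, center = c("median", "mean")) {
  center <- match.arg(center)
  cfun <- if (center == "median") stats::median else mean
  idx <- dwell$i_start:dwell$i_end
  s <- event_slice$samples[idx, ]
  one_eye <- function(eye) {
    cols <- .hg_eye_cols(eye)
    v <- s[[cols$v]]
    if (!any(v)) return(list(x = NA_real_, y = NA_real_, n = 0L))
    list(x = cfun(s[[cols$x]][v]), y = cfun(s[[cols$y]][v]), n = sum(v))
  }
  le <- one_eye("LE"); re <- one_eye("RE")
  structure(list(
    target_id = dwell$target_id,
    le_x = le$x, le_y = le$y, n_valid_le = le$n,
    re_x = re$x, re_y = re$y, n_valid_re = re$n,
    le_missing = le$n == 0L, re_missing = re$n == 0L
  ), class = "fixation_estimate")
}
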
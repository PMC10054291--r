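# On-disk artifacts: gaze recordings (CSV), event annotations (JSON),
# subjective examiner templates (CSV) and deviation results (CSV + JSON
# provenance sidecar). All readers validate; all reader/writer pairs are
# lossless round trips for valid data.

#' Binocular gaze recording container
#'
#' One sample per row: time in seconds from recording start and each eye's
#' landing point on the screen plane (cm) with a per-eye validity flag.
#' Coordinates of an invalid eye are `NA` and must never enter a computation.
#'
#' @param samples data.frame with columns `t_s`, `left_x_cm`, `left_y_cm`,
#'   `left_valid`, `right_x_cm`, `right_y_cm`, `right_valid`
#' @param subject_id subject label
#' @param rate_hz nominal sampling frequency (default 250)
#' @param meta free-form named list (provenance, tested eye of a slice, ...)
#' @return object of class `gaze_recording`
#' @export
gaze_recording <- function(samples, subject_id = "S1", rate_hz = 250, meta = list()) {
  need <- c("t_s", "left_x_cm", "left_y_cm", "left_valid",
            "right_x_cm", "right_y_cm", "right_valid")
  missing <- setdiff(need, names(samples))
  if (length(missing))
    hg_format_error(sprintf("gaze samples missing column(s): %s",
                            paste(missing, collapse = ", ")))
  if (nrow(samples) < 2L) hg_format_error("a gaze recording needs at least 2 samples")
  if (!is.numeric(rate_hz) || rate_hz <= 0) hg_format_error("rate_hz must be > 0")
  if (any(samples$t_s < 0)) hg_format_error("timestamps must be >= 0")
  bad <- which(diff(samples$t_s) <= 0)
  if (length(bad))
    hg_format_error(sprintf("timestamps not strictly increasing at row %d", bad[1] + 1L))
  samples$left_valid <- as.logical(samples$left_valid)
  samples$right_valid <- as.logical(samples$right_valid)
  # enforce the validity contract: invalid eye has NA coordinates, and an eye
  # with non-finite coordinates cannot be valid
  samples$left_valid <- samples$left_valid &
    is.finite(samples$left_x_cm) & is.finite(samples$left_y_cm)
  samples$right_valid <- samples$right_valid &
    is.finite(samples$right_x_cm) & is.finite(samples$right_y_cm)
  samples$left_x_cm[!samples$left_valid] <- NA_real_
  samples$left_y_cm[!samples$left_valid] <- NA_real_
  samples$right_x_cm[!samples$right_valid] <- NA_real_
  samples$right_y_cm[!samples$right_valid] <- NA_real_
  rownames(samples) <- NULL
  structure(
    list(subject_id = subject_id, rate_hz = rate_hz,
         samples = samples[, need], meta = meta),
    class = "gaze_recording"
  )
}

#' @export
print.gaze_recording <- function(x, ...) {
  n <- nrow(x$samples)
  span <- x$samples$t_s[n] - x$samples$t_s[1]
  cat(sprintf(
    "Gaze recording '%s': %d samples, %.1f s at %g Hz (LE valid %.1f%%, RE valid %.1f%%)\n",
    x$subject_id, n, span, x$rate_hz,
    100 * mean(x$samples$left_valid), 100 * mean(x$samples$right_valid)
  ))
  invisible(x)
}

#' Gaze CSV dialect description
#'
#' The canonical dialect has columns
#' `t_s,left_x_cm,left_y_cm,left_valid,right_x_cm,right_y_cm,right_valid` with
#' seconds, centimetres, and validity 0/1. Vendor exports with other column
#' names, units (e.g. milliseconds, millimetres) or validity codes are adapted
#' by overriding the mapping here, without code changes.
#'
#' @param columns named character vector mapping canonical names to file
#'   column names
#' @param time_scale multiply file timestamps by this to obtain seconds
#' @param coord_scale multiply file coordinates by this to obtain cm
#' @param valid_values values of the validity column meaning "valid"
#' @param invalid_sentinels coordinate values to treat as invalid (vendor
#'   conventions such as -1)
#' @return a `gaze_dialect` list
#' @export
gaze_dialect <- function(columns = c(
                           t_s = "t_s",
                           left_x_cm = "left_x_cm", left_y_cm = "left_y_cm",
                           left_valid = "left_valid",
                           right_x_cm = "right_x_cm", right_y_cm = "right_y_cm",
                           right_valid = "right_valid"
                         ),
                         time_scale = 1, coord_scale = 1,
                         valid_values = c("1", "TRUE", "true", "Valid"),
                         invalid_sentinels = numeric(0)) {
  structure(list(columns = columns, time_scale = time_scale,
                 coord_scale = coord_scale, valid_values = valid_values,
                 invalid_sentinels = invalid_sentinels),
            class = "gaze_dialect")
}

.hg_parse_num <- function(x) suppressWarnings(as.numeric(as.character(x)))

#' Read a gaze recording from CSV
#'
#' Rows whose coordinates fail to parse become invalid samples for the
#' affected eye (counted and logged), never silently dropped. Timestamps are
#' normalized to seconds from the first sample.
#'
#' @param path CSV file
#' @param dialect a [gaze_dialect()]
#' @param subject_id,rate_hz recording metadata
#' @return a [gaze_recording()]
#' @export
read_gaze <- function(path, dialect = gaze_dialect(), subject_id = "S1",
                      rate_hz = 250) {
  if (!file.exists(path)) hg_io_error(sprintf("gaze file not found: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  cols <- dialect$columns
  # validity columns are optional in vendor exports; all others are required
  required <- cols[setdiff(names(cols), c("left_valid", "right_valid"))]
  missing <- setdiff(required, names(raw))
  if (length(missing))
    hg_format_error(sprintf("gaze file %s missing required column(s): %s",
                            basename(path), paste(missing, collapse = ", ")))
  get_raw <- function(canon) {
    if (!canon %in% names(cols)) return(NULL)
    col <- cols[[canon]]
    if (!col %in% names(raw)) return(NULL)
    .hg_parse_num(raw[[col]])
  }
  # vendor sentinel coordinates (e.g. -1) are matched before unit scaling
  not_sentinel <- function(v) {
    ok <- rep(TRUE, length(v))
    for (snt in dialect$invalid_sentinels) ok <- ok & (is.na(v) | v != snt)
    ok
  }
  get_num <- function(canon, scale) {
    v <- get_raw(canon)
    if (is.null(v)) return(NULL)
    v * scale
  }
  t_s <- get_num("t_s", dialect$time_scale)
  if (anyNA(t_s)) {
    hg_format_error(sprintf("unparseable timestamp at row %d of %s",
                            which(is.na(t_s))[1], basename(path)))
  }
  samples <- data.frame(
    t_s = t_s - t_s[1],
    left_x_cm = get_num("left_x_cm", dialect$coord_scale),
    left_y_cm = get_num("left_y_cm", dialect$coord_scale),
    left_valid = TRUE,
    right_x_cm = get_num("right_x_cm", dialect$coord_scale),
    right_y_cm = get_num("right_y_cm", dialect$coord_scale),
    right_valid = TRUE
  )
  flag <- function(canon) {
    if (!canon %in% names(cols)) return(rep(TRUE, nrow(raw)))
    col <- cols[[canon]]
    if (!col %in% names(raw)) return(rep(TRUE, nrow(raw)))
    trimws(as.character(raw[[col]])) %in% dialect$valid_values
  }
  samples$left_valid <- flag("left_valid") &
    not_sentinel(get_raw("left_x_cm")) & not_sentinel(get_raw("left_y_cm"))
  samples$right_valid <- flag("right_valid") &
    not_sentinel(get_raw("right_x_cm")) & not_sentinel(get_raw("right_y_cm"))
  rec <- gaze_recording(samples, subject_id = subject_id, rate_hz = rate_hz,
                        meta = list(source = path))
  n_inv_le <- sum(!rec$samples$left_valid)
  n_inv_re <- sum(!rec$samples$right_valid)
  if (n_inv_le + n_inv_re > 0)
    hg_log("info", sprintf("%s: %d invalid LE and %d invalid RE samples of %d",
                           basename(path), n_inv_le, n_inv_re, nrow(rec$samples)))
  rec
}

#' Write a gaze recording in the canonical CSV dialect
#'
#' @param recording a [gaze_recording()]
#' @param path output CSV
#' @return `path`, invisibly
#' @export
write_gaze <- function(recording, path) {
  s <- recording$samples
  out <- data.frame(
    t_s = sprintf("%.6f", s$t_s),
    left_x_cm = ifelse(s$left_valid, sprintf("%.6f", s$left_x_cm), ""),
    left_y_cm = ifelse(s$left_valid, sprintf("%.6f", s$left_y_cm), ""),
    left_valid = as.integer(s$left_valid),
    right_x_cm = ifelse(s$right_valid, sprintf("%.6f", s$right_x_cm), ""),
    right_y_cm = ifelse(s$right_valid, sprintf("%.6f", s$right_y_cm), ""),
    right_valid = as.integer(s$right_valid)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Event annotations: the LE-test and RE-test intervals
#'
#' The recording is segmented into two examiner-marked events: first the
#' left-eye test, then the right-eye test. Intervals are `(start, end)` in
#' seconds and must not overlap.
#'
#' @param le,re numeric length-2 intervals (seconds)
#' @return object of class `event_annotations`
#' @export
event_annotations <- function(le, re) {
  chk <- function(iv, lab) {
    if (length(iv) != 2L || any(!is.finite(iv)) || iv[2] <= iv[1])
      hg_format_error(sprintf("event '%s' must be a non-empty (start, end) interval", lab))
  }
  chk(le, "LE"); chk(re, "RE")
  if (max(le[1], re[1]) < min(le[2], re[2]))
    hg_format_error("LE and RE event intervals overlap")
  structure(list(le = as.numeric(le), re = as.numeric(re)),
            class = "event_annotations")
}

#' Read / write event annotations (JSON)
#'
#' Canonical format: `{"LE": [t0, t1], "RE": [t0, t1]}` with times in seconds.
#'
#' @param path JSON file
#' @return an [event_annotations()] object
#' @export
read_events <- function(path) {
  if (!file.exists(path)) hg_io_error(sprintf("events file not found: %s", path))
  obj <- jsonlite::fromJSON(path)
  for (lab in c("LE", "RE")) {
    if (sum(names(obj) == lab) != 1L)
      hg_format_error(sprintf("events file must contain label '%s' exactly once", lab))
  }
  event_annotations(obj$LE, obj$RE)
}

#' @rdname read_events
#' @param annotations an [event_annotations()] object
#' @export
write_events <- function(annotations, path) {
  jsonlite::write_json(list(LE = annotations$le, RE = annotations$re), path,
                       digits = NA)
  invisible(path)
}

#' Read / write a subjective examiner template
#'
#' CSV columns `eye,target_id,dx_pd,dy_pd` (optional `subject_id`, `note`):
#' the examiner's per-eye, per-target deviation annotations in prism diopters,
#' typically on the 5 PD grid-square granularity.
#'
#' @param path CSV file
#' @param grid a `target_grid`; ids outside it are rejected
#' @return data.frame of class `subjective_template`
#' @export
read_subjective <- function(path, grid = build_target_grid()) {
  if (!file.exists(path)) hg_io_error(sprintf("subjective file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("eye", "target_id", "dx_pd", "dy_pd")
  missing <- setdiff(need, names(df))
  if (length(missing))
    hg_format_error(sprintf("subjective template missing column(s): %s",
                            paste(missing, collapse = ", ")))
  if (!"subject_id" %in% names(df)) df$subject_id <- "S1"
  bad_eye <- setdiff(unique(df$eye), c("LE", "RE"))
  if (length(bad_eye))
    hg_format_error(sprintf("unknown eye label(s): %s", paste(bad_eye, collapse = ", ")))
  bad_id <- setdiff(df$target_id, grid$id)
  if (length(bad_id))
    hg_format_error(sprintf("subjective template has target id(s) outside the grid: %s",
                            paste(bad_id, collapse = ", ")))
  if (any(!is.finite(df$dx_pd)) || any(!is.finite(df$dy_pd)))
    hg_format_error("subjective deviations must be finite numbers")
  keep <- intersect(c("subject_id", "eye", "target_id", "dx_pd", "dy_pd", "note"),
                    names(df))
  df <- df[, keep]
  class(df) <- c("subjective_template", "data.frame")
  df
}

#' @rdname read_subjective
#' @param template a `subjective_template` data.frame
#' @export
write_subjective <- function(template, path) {
  utils::write.csv(as.data.frame(template), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a deviation results table
#'
#' Results go to CSV with a stable column order plus a JSON sidecar
#' (`<path>.json`) holding provenance: package version and config hash.
#' Reading restores all fields; unknown extra columns are kept in the
#' `"extra"` attribute with a warning.
#'
#' @param records a `deviation_records` data.frame (see [build_records()])
#' @param path output CSV path
#' @param config optional config list recorded in provenance
#' @return `path`, invisibly
#' @export
write_results <- function(records, path, config = NULL) {
  cols <- c("subject_id", "tested_eye", "target_id", "dx_pd", "dy_pd",
            "n_valid_le", "n_valid_re", "quality")
  df <- as.data.frame(records)
  missing <- setdiff(cols, names(df))
  if (length(missing))
    hg_format_error(sprintf("results table missing column(s): %s",
                            paste(missing, collapse = ", ")))
  ok <- tryCatch({
    utils::write.csv(df[, cols], path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) hg_io_error(sprintf("cannot write results to %s: %s",
                                       path, conditionMessage(ok)))
  prov <- list(
    package = "hessgaze",
    version = as.character(utils::packageVersion("hessgaze")),
    config_hash = if (is.null(config)) NA_character_ else config_hash(config)
  )
  jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) hg_io_error(sprintf("results file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  cols <- c("subject_id", "tested_eye", "target_id", "dx_pd", "dy_pd",
            "n_valid_le", "n_valid_re", "quality")
  missing <- setdiff(cols, names(df))
  if (length(missing))
    hg_format_error(sprintf("results file missing column(s): %s",
                            paste(missing, collapse = ", ")))
  extra <- setdiff(names(df), cols)
  out <- df[, cols]
  if (length(extra)) {
    warning(sprintf("results file has unknown column(s) kept as attribute: %s",
                    paste(extra, collapse = ", ")))
    attr(out, "extra") <- df[, extra, drop = FALSE]
  }
  class(out) <- c("deviation_records", "data.frame")
  out
}
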
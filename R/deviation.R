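# Signed prismatic deviations from binocular fixation estimates, and
# Hess-chart assembly.
#
# Sign conventions (fixed throughout the package):
#   horizontal dx = 100 * (x_LE - x_RE) / D   esophoria (+), exophoria (-)
#   vertical   dy = 100 * (y_RE - y_LE) / D   RE hyperphoria (+), RE hypophoria (-)
# The horizontal axis reads the left eye relative to the right: the LE landing
# temporal-ward (subject's left) of the RE means divergence, hence exophoria,
# hence negative. The vertical axis is anchored to the right eye so that "RE
# higher" is positive regardless of which eye is under test.

#' Signed prismatic deviation at one target
#'
#' Converts a binocular fixation estimate into horizontal and vertical
#' deviations in prism diopters using the screen-plane landing-point
#' difference between the eyes (the operational definition of the dissociated
#' test; the ~6 cm inter-ocular offset contributes < 0.2 PD at 1 m and is
#' ignored).
#'
#' @param fix a [estimate_fixation()] result
#' @param geometry a [screen_geometry()]
#' @return list `(dx_pd, dy_pd, missing)`; when either eye's estimate is
#'   missing the deviations are `NA` and `missing` is `TRUE`
#' @examples
#' # LE landing 2 cm temporal-ward of RE at 1 m: 2 PD of exophoria
#' fix <- structure(list(target_id = 1, le_x = -2, le_y = 0, n_valid_le = 10,
#'                       re_x = 0, re_y = 0, n_valid_re = 10,
#'                       le_missing = FALSE, re_missing = FALSE),
#'                  class = "fixation_estimate")
#' compute_deviation(fix, screen_geometry())$dx_pd # -2
#' @export
compute_deviation <- function(fix, geometry = screen_geometry()) {
  if (isTRUE(fix$le_missing) || isTRUE(fix$re_missing)) {
    return(list(dx_pd = NA_real_, dy_pd = NA_real_, missing = TRUE))
  }
  D <- geometry$screen_distance_cm
  list(
    dx_pd = prism_from_offset(fix$le_x - fix$re_x, D),
    dy_pd = prism_from_offset(fix$re_y - fix$le_y, D),
    missing = FALSE
  )
}

#' Assemble per-target deviation records for one tested eye
#'
#' @param estimates list of [estimate_fixation()] results, one per detected
#'   target
#' @param tested_eye `"LE"` or `"RE"`
#' @param subject_id subject label
#' @param geometry a [screen_geometry()]
#' @param central_only keep only the nine central targets (ids 1-9 on the
#'   default grid); peripheral targets sit at the edge of tracker coverage
#' @param min_valid_floor records where either eye has fewer valid samples are
#'   downgraded to quality `"low_valid"`
#' @param grid grid used for the central-nine filter
#' @return data.frame of class `deviation_records` with columns `subject_id`,
#'   `tested_eye`, `target_id`, `dx_pd`, `dy_pd`, `n_valid_le`, `n_valid_re`,
#'   `quality` (`"ok"`, `"low_valid"` or `"missing"`)
#' @export
build_records <- function(estimates, tested_eye = c("LE", "RE"),
                          subject_id = "S1", geometry = screen_geometry(),
                          central_only = FALSE, min_valid_floor = 10,
                          grid = build_target_grid(geometry)) {
  tested_eye <- match.arg(tested_eye)
  rows <- lapply(estimates, function(fix) {
    dev <- compute_deviation(fix, geometry)
    quality <- if (dev$missing) "missing"
      else if (min(fix$n_valid_le, fix$n_valid_re) < min_valid_floor) "low_valid"
      else "ok"
    data.frame(
      subject_id = subject_id, tested_eye = tested_eye,
      target_id = fix$target_id, dx_pd = dev$dx_pd, dy_pd = dev$dy_pd,
      n_valid_le = fix$n_valid_le, n_valid_re = fix$n_valid_re,
      quality = quality, stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(0), tested_eye = character(0),
               target_id = integer(0), dx_pd = numeric(0), dy_pd = numeric(0),
               n_valid_le = integer(0), n_valid_re = integer(0),
               quality = character(0))
  if (central_only) out <- out[out$target_id %in% central_nine(grid), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("deviation_records", "data.frame")
  out
}

#' Hess chart data for plotting
#'
#' For each tested eye, the measured position at a target is the expected
#' (grid) position displaced by the tested eye's landing point relative to the
#' fixating eye, re-expressed in screen cm. With dx anchored to the left eye
#' and dy to the right eye, the LE chart shifts by `(+dx, -dy) * D/100` and
#' the RE chart by `(-dx, +dy) * D/100`: a uniform 4 PD exophoria (dx = -4)
#' displaces every LE point 4 cm left and every RE point 4 cm right at 1 m.
#' Inner- and outer-ring polygons connect the measured positions in circular
#' id order; missing targets leave a flagged gap.
#'
#' @param records a `deviation_records` data.frame for one subject (may hold
#'   both tested eyes)
#' @param grid a `target_grid`
#' @param geometry a [screen_geometry()]
#' @return object of class `hess_chart`: per tested eye a data.frame
#'   (`target_id`, `exp_x`, `exp_y`, `meas_x`, `meas_y`, `gap`) plus inner and
#'   outer polygon vertex tables with `NA` rows marking gaps
#' @export
assemble_chart <- function(records, grid = build_target_grid(),
                           geometry = screen_geometry()) {
  if (length(unique(records$subject_id)) > 1L)
    hg_format_error("assemble_chart expects records for a single subject")
  D <- geometry$screen_distance_cm
  rings <- list(
    inner = grid$id[grid$ring %in% c("inner_cardinal", "inner_diagonal")],
    outer = grid$id[grid$ring %in% c("outer_cardinal", "outer_diagonal")]
  )
  # circular order = clockwise from up: ids were built interleaved that way
  rings <- lapply(rings, sort)
  one_eye <- function(eye) {
    r <- records[records$tested_eye == eye & records$quality != "missing", ]
    if (!nrow(r)) return(NULL)
    sgn <- if (eye == "LE") c(1, -1) else c(-1, 1)
    m <- merge(grid, r[, c("target_id", "dx_pd", "dy_pd")],
               by.x = "id", by.y = "target_id", all.x = TRUE)
    m <- m[order(m$id), ]
    pts <- data.frame(
      target_id = m$id,
      exp_x = m$x_cm, exp_y = m$y_cm,
      meas_x = m$x_cm + sgn[1] * m$dx_pd * D / 100,
      meas_y = m$y_cm + sgn[2] * m$dy_pd * D / 100,
      gap = is.na(m$dx_pd)
    )
    poly <- function(ids) {
      p <- pts[match(ids, pts$target_id), c("target_id", "meas_x", "meas_y", "gap")]
      rownames(p) <- NULL
      p
    }
    list(points = pts, inner = poly(rings$inner), outer = poly(rings$outer))
  }
  structure(list(LE = one_eye("LE"), RE = one_eye("RE"),
                 subject_id = unique(records$subject_id)),
            class = "hess_chart")
}

#' Plot one eye's Hess chart
#'
#' Draws the grid, expected target positions (open circles) and measured
#' positions (filled points) with the inner and outer field polygons.
#'
#' @param chart an [assemble_chart()] result
#' @param eye `"LE"` or `"RE"`
#' @param geometry geometry for the square size
#' @param ... passed to [graphics::plot()]
#' @return `invisible(NULL)`
#' @export
plot_hess_chart <- function(chart, eye = c("LE", "RE"),
                            geometry = screen_geometry(), ...) {
  eye <- match.arg(eye)
  side <- chart[[eye]]
  if (is.null(side)) hg_format_error(sprintf("chart has no %s data", eye))
  sq <- geometry$square_cm
  lim <- c(-9, 9) * sq
  graphics::plot(NA, xlim = lim, ylim = lim, asp = 1,
                 xlab = "x (cm)", ylab = "y (cm)",
                 main = sprintf("Hess chart, %s tested (%s)", eye,
                                chart$subject_id), ...)
  graphics::abline(v = seq(lim[1], lim[2], by = sq),
                   h = seq(lim[1], lim[2], by = sq), col = "grey85")
  pts <- side$points
  graphics::points(pts$exp_x, pts$exp_y, pch = 1, col = "grey40")
  for (ring in list(side$inner, side$outer)) {
    ok <- !ring$gap & !is.na(ring$meas_x)
    xs <- ifelse(ok, ring$meas_x, NA)
    ys <- ifelse(ok, ring$meas_y, NA)
    graphics::lines(c(xs, xs[1]), c(ys, ys[1]), col = "red3")
  }
  graphics::points(pts$meas_x, pts$meas_y, pch = 16, col = "red3")
  invisible(NULL)
}

#' Classify a deviation into phoria labels
#'
#' @param dx_pd,dy_pd deviations in prism diopters (vectorized)
#' @param tol_pd deviations with absolute value at or below this are labelled
#'   neutral (default 0.5 PD; the objective method resolves deviations below
#'   1 PD that examiners cannot)
#' @return data.frame with columns `horizontal` (`"eso"`, `"exo"`, `"ortho"`)
#'   and `vertical` (`"RE_hyper"`, `"RE_hypo"`, `"none"`)
#' @export
classify_phoria <- function(dx_pd, dy_pd, tol_pd = 0.5) {
  if (any(!is.finite(dx_pd)) || any(!is.finite(dy_pd)))
    hg_domain_error("deviations must be finite")
  data.frame(
    horizontal = ifelse(abs(dx_pd) <= tol_pd, "ortho",
                        ifelse(dx_pd > 0, "eso", "exo")),
    vertical = ifelse(abs(dy_pd) <= tol_pd, "none",
                      ifelse(dy_pd > 0, "RE_hyper", "RE_hypo")),
    stringsAsFactors = FALSE
  )
}
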
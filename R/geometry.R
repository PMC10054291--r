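#' Screen, grid and tracker geometry for the Hess Lancaster screen test
#'
#' The test is administered on a wall grid of squares viewed from a fixed
#' distance, with a remote eye tracker between subject and screen. With the
#' default geometry (1 m viewing distance, 5 cm squares) one grid square of
#' deviation equals 5 prism diopters, since 1 prism diopter (PD) displaces the
#' image 1 cm at 1 m.
#'
#' @param screen_distance_cm subject-to-screen distance (cm, default 100)
#' @param square_cm side of one grid square (cm, default 5)
#' @param tracker_distance_cm subject-to-tracker distance (cm, default 60);
#'   must be smaller than `screen_distance_cm`
#' @param tracker_max_angle_deg largest gaze eccentricity the tracker can
#'   measure (degrees, default 35); landing points beyond it are flagged
#'   invalid by the simulator
#' @return an object of class `screen_geometry`
#' @examples
#' geom <- screen_geometry()
#' prism_from_offset(geom$square_cm, geom$screen_distance_cm) # one square = 5 PD
#' @export
screen_geometry <- function(screen_distance_cm = 100, square_cm = 5,
                            tracker_distance_cm = 60, tracker_max_angle_deg = 35) {
  num_ok <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v)
  if (!num_ok(screen_distance_cm) || screen_distance_cm <= 0)
    hg_config_error("screen_distance_cm must be a positive number")
  if (!num_ok(square_cm) || square_cm <= 0)
    hg_config_error("square_cm must be a positive number")
  if (!num_ok(tracker_distance_cm) || tracker_distance_cm <= 0)
    hg_config_error("tracker_distance_cm must be a positive number")
  if (tracker_distance_cm >= screen_distance_cm)
    hg_config_error("tracker_distance_cm must be smaller than screen_distance_cm")
  if (!num_ok(tracker_max_angle_deg) ||
      tracker_max_angle_deg <= 0 || tracker_max_angle_deg >= 90)
    hg_config_error("tracker_max_angle_deg must lie in (0, 90)")
  structure(
    list(
      screen_distance_cm = screen_distance_cm,
      square_cm = square_cm,
      tracker_distance_cm = tracker_distance_cm,
      tracker_max_angle_deg = tracker_max_angle_deg
    ),
    class = "screen_geometry"
  )
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf(
    "HLST geometry: screen %g cm, square %g cm (= %g PD), tracker %g cm (max %g deg)\n",
    x$screen_distance_cm, x$square_cm,
    prism_from_offset(x$square_cm, x$screen_distance_cm),
    x$tracker_distance_cm, x$tracker_max_angle_deg
  ))
  invisible(x)
}

# id -> direction assignment on the grid. Target 1 is the centre; the inner
# ring sits at 4 squares and the outer ring at 8 squares from the centre.
# Directions are unit steps in (x right, y up), clockwise from straight up.
.hg_ring_dirs <- function() {
  # up, up-right, right, down-right, down, down-left, left, up-left
  data.frame(
    ux = c(0, 1, 1, 1, 0, -1, -1, -1),
    uy = c(1, 1, 0, -1, -1, -1, 0, 1)
  )
}

.hg_classify_ring <- function(x, y, inner_cm = 20) {
  if (x == 0 && y == 0) return("center")
  diagonal <- (x != 0 && y != 0)
  outer <- max(abs(x), abs(y)) > inner_cm
  if (diagonal && outer) "outer_diagonal"
  else if (diagonal) "inner_diagonal"
  else if (outer) "outer_cardinal"
  else "inner_cardinal"
}

#' Build the 17-point Hess target grid
#'
#' Target 1 is the centre; ids 2-9 form the inner ring at 4 squares
#' (2,4,6,8 cardinal; 3,5,7,9 diagonal) and ids 10-17 the outer ring at
#' 8 squares (10,12,14,16 cardinal; 11,13,15,17 diagonal). Within each ring
#' ids run clockwise from straight up, as the chart is read. Coordinates are
#' screen cm, origin at target 1, x positive to the subject's right, y
#' positive up. The default traversal order is 1, 2, ..., 17.
#'
#' @param geometry a [screen_geometry()]
#' @param grid_file optional CSV (`id,x_cm,y_cm`) overriding the generated
#'   coordinates, for protocols whose id-to-direction assignment differs
#' @return a `target_grid`: a data.frame with columns `id`, `x_cm`, `y_cm`,
#'   `ring` and attribute `traversal_order`
#' @examples
#' grid <- build_target_grid(screen_geometry())
#' subset(grid, ring == "inner_cardinal")
#' @export
build_target_grid <- function(geometry = screen_geometry(), grid_file = NULL) {
  if (!inherits(geometry, "screen_geometry"))
    hg_config_error("geometry must be a screen_geometry object")
  if (!is.null(grid_file)) return(read_grid_csv(grid_file, geometry))
  sq <- geometry$square_cm
  dirs <- .hg_ring_dirs()
  inner <- dirs * 4 * sq
  outer <- dirs * 8 * sq
  xs <- c(0, inner$ux, outer$ux)
  ys <- c(0, inner$uy, outer$uy)
  grid <- data.frame(
    id = 1:17,
    x_cm = xs,
    y_cm = ys,
    ring = vapply(seq_along(xs),
                  function(i) .hg_classify_ring(xs[i], ys[i], inner_cm = 4 * sq), ""),
    stringsAsFactors = FALSE
  )
  .hg_as_grid(grid, traversal_order = 1:17)
}

.hg_as_grid <- function(grid, traversal_order) {
  if (anyDuplicated(grid$id)) hg_format_error("target ids must be unique")
  attr(grid, "traversal_order") <- traversal_order
  class(grid) <- c("target_grid", "data.frame")
  grid
}

#' Read a target grid override file
#'
#' @param path CSV with columns `id,x_cm,y_cm`
#' @param geometry geometry used to classify rings
#' @return a `target_grid`
#' @export
read_grid_csv <- function(path, geometry = screen_geometry()) {
  if (!file.exists(path)) hg_io_error(sprintf("grid file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "x_cm", "y_cm")
  missing <- setdiff(need, names(df))
  if (length(missing))
    hg_format_error(sprintf("grid file missing column(s): %s",
                            paste(missing, collapse = ", ")))
  df$ring <- vapply(seq_len(nrow(df)),
                    function(i) .hg_classify_ring(df$x_cm[i], df$y_cm[i],
                                                  inner_cm = 4 * geometry$square_cm), "")
  .hg_as_grid(df[, c("id", "x_cm", "y_cm", "ring")], traversal_order = df$id)
}

#' Ids of the nine central targets
#'
#' Peripheral targets (ids 10-17) sit near the edge of the tracker's angular
#' coverage and are excluded from quantitative analysis; only the centre and
#' the inner ring (ids 1-9) are retained.
#'
#' @param grid a `target_grid`
#' @return integer vector of ids
#' @export
central_nine <- function(grid) {
  grid$id[grid$ring %in% c("center", "inner_cardinal", "inner_diagonal")]
}

#' Eye rotation angle needed to fixate a screen point
#'
#' `atan(r / D)` where `r` is the point's distance from the screen centre and
#' `D` the viewing distance. With the default grid this reproduces the
#' canonical ring angles: 11.31 deg (inner cardinal), 15.79 deg (inner
#' diagonal), 21.80 deg (outer cardinal) and 29.50 deg (outer diagonal).
#'
#' @param x_cm,y_cm screen coordinates (cm); vectorized
#' @param geometry a [screen_geometry()]
#' @return angle in degrees, >= 0
#' @export
rotation_angle <- function(x_cm, y_cm, geometry = screen_geometry()) {
  if (!inherits(geometry, "screen_geometry"))
    hg_config_error("geometry must be a screen_geometry object")
  r <- sqrt(x_cm^2 + y_cm^2)
  atan(r / geometry$screen_distance_cm) * 180 / pi
}

#' Convert a lateral screen offset to prism diopters
#'
#' One prism diopter (PD) deviates a ray 1 cm per metre of travel, so an
#' offset of `o` cm seen at `d` cm is `100 * o / d` PD. The sign of the
#' offset is preserved. On the default grid one square (5 cm at 100 cm)
#' is exactly 5 PD.
#'
#' @param offset_cm signed offset on the screen (cm); vectorized
#' @param distance_cm viewing distance (cm), > 0
#' @return deviation in prism diopters
#' @export
prism_from_offset <- function(offset_cm, distance_cm) {
  if (!is.numeric(distance_cm) || any(!is.finite(distance_cm)) || any(distance_cm <= 0))
    hg_domain_error("distance_cm must be positive")
  100 * offset_cm / distance_cm
}

#' Angle / prism-diopter conversions
#'
#' `prism_from_angle()` implements the tangent definition `PD = 100 * tan(theta)`
#' (not centrads), the convention under which 4 squares of 5 cm at 1 m — an
#' 11.31 degree rotation — equal exactly 20 PD. `angle_from_prism()` is its
#' inverse; the pair round-trips to 1e-9.
#'
#' @param theta_deg angle in degrees, |theta| < 90; vectorized
#' @return prism diopters
#' @export
prism_from_angle <- function(theta_deg) {
  if (any(!is.finite(theta_deg)) || any(abs(theta_deg) >= 90))
    hg_domain_error("|theta_deg| must be < 90")
  100 * tan(theta_deg * pi / 180)
}

#' @rdname prism_from_angle
#' @param delta_pd deviation in prism diopters; vectorized
#' @export
angle_from_prism <- function(delta_pd) {
  if (any(!is.finite(delta_pd))) hg_domain_error("delta_pd must be finite")
  atan(delta_pd / 100) * 180 / pi
}

#' Intersect a gaze ray with the screen plane
#'
#' The screen is the plane z = 0 with +z pointing from the screen toward the
#' subject; a gaze ray therefore needs a negative z direction component to
#' land on it.
#'
#' @param origin_xyz numeric length-3, ray origin in cm (z > 0 in front of screen)
#' @param direction_xyz numeric length-3 direction (need not be unit length)
#' @return numeric length-2 `(x_cm, y_cm)` landing point
#' @export
intersect_screen <- function(origin_xyz, direction_xyz) {
  if (length(origin_xyz) != 3L || length(direction_xyz) != 3L)
    hg_domain_error("origin and direction must be length-3 vectors")
  dz <- direction_xyz[3]
  if (!is.finite(dz) || dz >= 0)
    hg_domain_error("gaze ray does not intersect the screen (direction z must be < 0)")
  t <- -origin_xyz[3] / dz
  if (t < 0)
    hg_domain_error("gaze ray points away from the screen")
  c(
    x_cm = unname(origin_xyz[1] + t * direction_xyz[1]),
    y_cm = unname(origin_xyz[2] + t * direction_xyz[2])
  )
}
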
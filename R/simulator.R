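# Synthetic binocular HLST gaze simulator.
#
# Emulates the acquisition protocol: a 250 Hz binocular stream of a subject
# traversing the 17 Hess-grid targets twice (LE test first, then RE test)
# under dissociated viewing, with a configurable comitant or incomitant
# phoria, isotropic Gaussian gaze noise, linear saccadic transitions,
# binocular blinks and per-eye tracking loss. Ground truth deviations and
# matching "examiner" subjective templates come along for free, which is what
# makes end-to-end parameter-recovery testing possible without hardware.

#' Simulation configuration
#'
#' @param phoria_h_pd comitant horizontal deviation in prism diopters
#'   (esophoria positive, exophoria negative)
#' @param phoria_v_pd comitant vertical deviation (RE hyperphoria positive)
#' @param incomitance_map optional data.frame `target_id, dh_pd, dv_pd` of
#'   per-target additions to the comitant deviation (gaze-direction-dependent
#'   deviation, as with a paretic muscle)
#' @param noise_deg_rms per-eye isotropic gaze noise, radial RMS in degrees
#'   (default 0.3); applied in angle and projected to screen cm so eccentric
#'   targets see realistic spatial noise
#' @param dwell_s time spent holding each target (default 2)
#' @param saccade_ms duration of the linear transition between targets
#'   (default 40)
#' @param blink_rate_hz rate of blink onsets (default 0.2); a blink marks both
#'   eyes invalid for `blink_ms`
#' @param blink_ms blink duration (default 150)
#' @param loss_prob per-sample, per-eye independent tracking-loss probability
#'   (default 0.005)
#' @param rate_hz sampling rate (default 250)
#' @param traversal target visiting order (default 1:17)
#' @param seed integer seed; identical seeds give identical recordings
#' @return a `simulation_config` list
#' @export
simulation_config <- function(phoria_h_pd = 0, phoria_v_pd = 0,
                              incomitance_map = NULL, noise_deg_rms = 0.3,
                              dwell_s = 2.0, saccade_ms = 40,
                              blink_rate_hz = 0.2, blink_ms = 150,
                              loss_prob = 0.005, rate_hz = 250,
                              traversal = 1:17, seed = NULL) {
  if (rate_hz <= 0) hg_config_error("rate_hz must be > 0")
  if (noise_deg_rms < 0) hg_config_error("noise_deg_rms must be >= 0")
  if (loss_prob < 0 || loss_prob > 1) hg_config_error("loss_prob must lie in [0, 1]")
  if (blink_rate_hz < 0) hg_config_error("blink_rate_hz must be >= 0")
  if (dwell_s <= 0 || saccade_ms < 0) hg_config_error("dwell_s > 0, saccade_ms >= 0 required")
  if (!is.null(incomitance_map)) {
    need <- c("target_id", "dh_pd", "dv_pd")
    if (!all(need %in% names(incomitance_map)))
      hg_config_error("incomitance_map needs columns target_id, dh_pd, dv_pd")
  }
  structure(list(
    phoria_h_pd = phoria_h_pd, phoria_v_pd = phoria_v_pd,
    incomitance_map = incomitance_map, noise_deg_rms = noise_deg_rms,
    dwell_s = dwell_s, saccade_ms = saccade_ms,
    blink_rate_hz = blink_rate_hz, blink_ms = blink_ms,
    loss_prob = loss_prob, rate_hz = rate_hz,
    traversal = traversal, seed = seed
  ), class = "simulation_config")
}

# True per-target deviation (comitant + incomitant part), PD
.hg_true_deviation <- function(config, target_id) {
  dh <- config$phoria_h_pd
  dv <- config$phoria_v_pd
  im <- config$incomitance_map
  if (!is.null(im)) {
    k <- match(target_id, im$target_id)
    if (!is.na(k)) {
      dh <- dh + im$dh_pd[k]
      dv <- dv + im$dv_pd[k]
    }
  }
  c(dh = dh, dv = dv)
}

# Nominal (noise-free) per-eye knot positions for one event.
# The fixating eye holds the examiner's light exactly on each target; the
# tested eye lands displaced by the deviation:
#   LE under test: x_LE = x_t + dh*D/100, y_LE = y_t - dv*D/100 (RE on target)
#   RE under test: x_RE = x_t - dh*D/100, y_RE = y_t + dv*D/100 (LE on target)
# so that the analysis-side definitions dx = 100*(x_LE - x_RE)/D and
# dy = 100*(y_RE - y_LE)/D recover (dh, dv) in either event.
.hg_event_track <- function(config, grid, geometry, tested_eye, t0) {
  D <- geometry$screen_distance_cm
  rate <- config$rate_hz
  dt <- 1 / rate
  sacc_s <- config$saccade_ms / 1000
  ids <- intersect(config$traversal, grid$id)

  knot_t <- numeric(0)
  knots <- list(LE = cbind(x = numeric(0), y = numeric(0)),
                RE = cbind(x = numeric(0), y = numeric(0)))
  dwell_iv <- data.frame(target_id = integer(0), t_start = numeric(0),
                         t_end = numeric(0))
  truth <- data.frame(target_id = integer(0), dx_pd = numeric(0),
                      dy_pd = numeric(0))
  tcur <- t0
  for (k in seq_along(ids)) {
    id <- ids[k]
    gx <- grid$x_cm[grid$id == id]
    gy <- grid$y_cm[grid$id == id]
    dev <- .hg_true_deviation(config, id)
    off_x <- dev[["dh"]] * D / 100
    off_y <- dev[["dv"]] * D / 100
    pos <- list(
      LE = if (tested_eye == "LE") c(gx + off_x, gy - off_y) else c(gx, gy),
      RE = if (tested_eye == "RE") c(gx - off_x, gy + off_y) else c(gx, gy)
    )
    if (k > 1L) tcur <- tcur + sacc_s # linear transition ends here
    # dwell plateau: knot at entry and at exit
    knot_t <- c(knot_t, tcur, tcur + config$dwell_s)
    for (eye in c("LE", "RE")) {
      knots[[eye]] <- rbind(knots[[eye]], pos[[eye]], pos[[eye]])
    }
    dwell_iv <- rbind(dwell_iv, data.frame(target_id = id, t_start = tcur,
                                           t_end = tcur + config$dwell_s))
    truth <- rbind(truth, data.frame(target_id = id, dx_pd = dev[["dh"]],
                                     dy_pd = dev[["dv"]]))
    tcur <- tcur + config$dwell_s
  }
  t_end <- tcur
  t_s <- seq(t0, t_end, by = dt)
  track <- lapply(c(LE = "LE", RE = "RE"), function(eye) {
    data.frame(
      x = stats::approx(knot_t, knots[[eye]][, 1], xout = t_s, rule = 2)$y,
      y = stats::approx(knot_t, knots[[eye]][, 2], xout = t_s, rule = 2)$y
    )
  })
  list(t_s = t_s, track = track, t_end = t_end, dwells = dwell_iv, truth = truth)
}

#' Simulate one subject's HLST recording
#'
#' Generates the full two-event recording (LE test then RE test, 1 s
#' inter-event gap), adds gaze noise, blinks and tracking loss, flags landing
#' points beyond the tracker's angular coverage invalid (with a warning,
#' mirroring peripheral tracking losses on real hardware), and returns the
#' matching ground truth.
#'
#' @param config a [simulation_config()]
#' @param grid a `target_grid`
#' @param geometry a [screen_geometry()]
#' @param subject_id subject label
#' @return list with elements `recording` ([gaze_recording()]), `annotations`
#'   ([event_annotations()]), and `truth` (class `ground_truth`: per-eye
#'   per-target true deviations, event intervals, per-target dwell intervals)
#' @export
simulate_subject <- function(config = simulation_config(),
                             grid = build_target_grid(),
                             geometry = screen_geometry(),
                             subject_id = "S1") {
  if (!is.null(config$seed)) set.seed(config$seed)
  D <- geometry$screen_distance_cm
  rate <- config$rate_hz
  gap_s <- 1.0

  le_ev <- .hg_event_track(config, grid, geometry, "LE", t0 = 0)
  re_ev <- .hg_event_track(config, grid, geometry, "RE",
                           t0 = le_ev$t_end + gap_s)

  t_s <- c(le_ev$t_s, re_ev$t_s)
  n <- length(t_s)
  eye_xy <- function(eye) rbind(le_ev$track[[eye]], re_ev$track[[eye]])
  le <- eye_xy("LE"); re <- eye_xy("RE")

  # isotropic angular noise projected to screen cm: radial RMS of
  # noise_deg_rms means per-axis sd = tan(noise)*D/sqrt(2)
  sd_cm <- tan(config$noise_deg_rms * pi / 180) * D / sqrt(2)
  if (sd_cm > 0) {
    le$x <- le$x + stats::rnorm(n, 0, sd_cm)
    le$y <- le$y + stats::rnorm(n, 0, sd_cm)
    re$x <- re$x + stats::rnorm(n, 0, sd_cm)
    re$y <- re$y + stats::rnorm(n, 0, sd_cm)
  }

  le_valid <- rep(TRUE, n)
  re_valid <- rep(TRUE, n)

  # blinks: Poisson-like onsets, both eyes dark for blink_ms
  if (config$blink_rate_hz > 0 && config$blink_ms > 0) {
    onsets <- which(stats::runif(n) < config$blink_rate_hz / rate)
    blink_len <- max(1L, round(config$blink_ms / 1000 * rate))
    for (o in onsets) {
      idx <- o:min(n, o + blink_len - 1L)
      le_valid[idx] <- FALSE
      re_valid[idx] <- FALSE
    }
  }
  # per-eye independent tracking loss
  if (config$loss_prob > 0) {
    le_valid <- le_valid & (stats::runif(n) >= config$loss_prob)
    re_valid <- re_valid & (stats::runif(n) >= config$loss_prob)
  }
  # tracker angular coverage
  max_ang <- geometry$tracker_max_angle_deg
  le_out <- rotation_angle(le$x, le$y, geometry) > max_ang
  re_out <- rotation_angle(re$x, re$y, geometry) > max_ang
  if (any(le_out | re_out)) {
    hg_warn_quality(sprintf(
      "%d samples land beyond the tracker's %g deg coverage and were flagged invalid",
      sum(le_out | re_out), max_ang))
    le_valid <- le_valid & !le_out
    re_valid <- re_valid & !re_out
  }

  samples <- data.frame(
    t_s = t_s,
    left_x_cm = le$x, left_y_cm = le$y, left_valid = le_valid,
    right_x_cm = re$x, right_y_cm = re$y, right_valid = re_valid
  )
  recording <- gaze_recording(samples, subject_id = subject_id, rate_hz = rate,
                              meta = list(simulated = TRUE))
  annotations <- event_annotations(le = c(0, le_ev$t_end),
                                   re = c(re_ev$t_s[1], re_ev$t_end))
  truth <- structure(list(
    deviations = rbind(
      cbind(tested_eye = "LE", le_ev$truth),
      cbind(tested_eye = "RE", re_ev$truth)
    ),
    events = annotations,
    dwells = rbind(
      cbind(tested_eye = "LE", le_ev$dwells),
      cbind(tested_eye = "RE", re_ev$dwells)
    ),
    config = config
  ), class = "ground_truth")
  list(recording = recording, annotations = annotations, truth = truth)
}

#' Simulate an examiner's subjective template from ground truth
#'
#' The manual test reads deviations off a grid whose squares are 5 PD, so the
#' examiner effectively quantizes: recorded value =
#' `round((true + jitter) / quant_pd) * quant_pd` with
#' `jitter ~ uniform(-jitter_pd, +jitter_pd)` modelling reading imprecision
#' and the subject's hand wobble.
#'
#' @param truth a `ground_truth` from [simulate_subject()]
#' @param quant_pd quantization step (default 5, one grid square)
#' @param jitter_pd half-width of the uniform pre-quantization jitter
#'   (default 2.5, half a square)
#' @param seed integer seed
#' @param subject_id label for the template's `subject_id` column
#' @return a `subjective_template` data.frame
#' @export
simulate_subjective <- function(truth, quant_pd = 5, jitter_pd = 2.5,
                                seed = NULL, subject_id = "S1") {
  if (!is.null(seed)) set.seed(seed)
  dev <- truth$deviations
  m <- nrow(dev)
  jx <- if (jitter_pd > 0) stats::runif(m, -jitter_pd, jitter_pd) else rep(0, m)
  jy <- if (jitter_pd > 0) stats::runif(m, -jitter_pd, jitter_pd) else rep(0, m)
  out <- data.frame(
    subject_id = subject_id,
    eye = dev$tested_eye,
    target_id = dev$target_id,
    dx_pd = round((dev$dx_pd + jx) / quant_pd) * quant_pd,
    dy_pd = round((dev$dy_pd + jy) / quant_pd) * quant_pd,
    stringsAsFactors = FALSE
  )
  class(out) <- c("subjective_template", "data.frame")
  out
}

#' Simulate a cohort of subjects
#'
#' Phorias are drawn per subject from uniform distributions (defaults:
#' horizontal U(-6, +6) PD, vertical U(-2, +2) PD — placeholders for an
#' unknown population, chosen to span clinically common small phorias), each
#' subject gets an independent derived seed, and the whole bundle is
#' reproducible from the master seed.
#'
#' @param n_subjects number of subjects (default 13)
#' @param phoria_h_range,phoria_v_range uniform ranges for the comitant
#'   phorias (PD)
#' @param base_config a [simulation_config()] supplying all non-phoria
#'   parameters
#' @param grid,geometry as in [simulate_subject()]
#' @param seed master seed
#' @return list of class `hlst_cohort`; each element has `subject_id`,
#'   `recording`, `annotations`, `truth`
#' @export
simulate_cohort <- function(n_subjects = 13, phoria_h_range = c(-6, 6),
                            phoria_v_range = c(-2, 2),
                            base_config = simulation_config(),
                            grid = build_target_grid(),
                            geometry = screen_geometry(), seed = 1) {
  if (n_subjects < 1) hg_config_error("n_subjects must be >= 1")
  set.seed(seed)
  h <- stats::runif(n_subjects, phoria_h_range[1], phoria_h_range[2])
  v <- stats::runif(n_subjects, phoria_v_range[1], phoria_v_range[2])
  seeds <- sample.int(2147483646L, n_subjects) # derived seeds stay 32-bit
  subjects <- lapply(seq_len(n_subjects), function(i) {
    cfg <- base_config
    cfg$phoria_h_pd <- h[i]
    cfg$phoria_v_pd <- v[i]
    cfg$seed <- seeds[i]
    sid <- sprintf("S%02d", i)
    sim <- simulate_subject(cfg, grid = grid, geometry = geometry,
                            subject_id = sid)
    c(list(subject_id = sid), sim)
  })
  structure(subjects, class = "hlst_cohort")
}
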
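test_that("slice_event restricts to the interval and records the eyes", {
  t <- seq(0, 120, by = 0.1)
  rec <- make_recording(t, rep(0, length(t)), rep(0, length(t)))
  ann <- event_annotations(le = c(0, 60), re = c(65, 120))
  le <- slice_event(rec, ann, "LE")
  expect_true(all(le$samples$t_s <= 60))
  expect_equal(le$meta$tested_eye, "LE")
  expect_equal(le$meta$fixating_eye, "RE")
  re <- slice_event(rec, ann, "RE")
  expect_true(all(re$samples$t_s >= 65))
  expect_equal(re$meta$fixating_eye, "LE")
  out_of_span <- event_annotations(le = c(0, 60), re = c(100, 130))
  expect_error(slice_event(rec, out_of_span, "RE"), class = "hg_segmentation_error")
})

test_that("slice_event recovers exactly the simulator's event samples", {
  cfg <- simulation_config(seed = 4, dwell_s = 0.4, traversal = 1:4,
                           blink_rate_hz = 0, loss_prob = 0)
  sim <- simulate_subject(cfg)
  le <- slice_event(sim$recording, sim$annotations, "LE")
  re <- slice_event(sim$recording, sim$annotations, "RE")
  expect_equal(nrow(le$samples) + nrow(re$samples), nrow(sim$recording$samples))
  expect_lt(max(le$samples$t_s), min(re$samples$t_s))
})

test_that("idt_fixations finds plateaus and rejects noise (constructed streams)", {
  rate <- 250
  t1 <- seq(0, 1, by = 1 / rate)
  const <- make_recording(t1, rep(3, length(t1)), rep(-2, length(t1)))
  fix <- idt_fixations(const, dispersion_max_cm = 1, min_duration_s = 0.3, eye = "LE")
  expect_equal(nrow(fix), 1L)
  expect_equal(fix$i_start, 1L)
  expect_equal(fix$i_end, length(t1))

  # two 0.5 s plateaus joined by a 40 ms ramp whose excursion breaks dispersion
  n_p <- 125L; n_r <- 10L
  x <- c(rep(0, n_p), seq(0, 30, length.out = n_r), rep(30, n_p))
  t2 <- seq(0, by = 1 / rate, length.out = length(x))
  two <- make_recording(t2, x, rep(0, length(x)))
  fix2 <- idt_fixations(two, dispersion_max_cm = 2, min_duration_s = 0.3, eye = "LE")
  expect_equal(nrow(fix2), 2L)
  expect_equal(fix2, oracle_idt(two, 2, 0.3, "LE"), tolerance = 1e-12)

  # dispersion far above threshold -> no fixations
  set.seed(8)
  noisy <- make_recording(t1, cumsum(rnorm(length(t1), 0, 3)),
                          cumsum(rnorm(length(t1), 0, 3)))
  expect_equal(nrow(idt_fixations(noisy, 1, 0.3, "LE")), 0L)
})

test_that("invalid samples break fixation windows", {
  rate <- 250
  t <- seq(0, 1, by = 1 / rate)
  v <- rep(TRUE, length(t))
  v[120:130] <- FALSE
  rec <- gaze_recording(make_samples(t, rep(0, length(t)), rep(0, length(t)),
                                     left_valid = v, right_valid = TRUE),
                        rate_hz = rate)
  fix <- idt_fixations(rec, 1, 0.3, "LE")
  expect_equal(nrow(fix), 2L)
  expect_true(all(fix$i_end < 120 | fix$i_start > 130))
  expect_equal(fix, oracle_idt(rec, 1, 0.3, "LE"), tolerance = 1e-12)
})

test_that("idt_fixations agrees with the exhaustive oracle (property)", {
  set.seed(123)
  for (rep in 1:60) {
    n <- sample(50:2000, 1)
    rec <- random_stream(n)
    disp <- runif(1, 0.5, 8)
    dur <- runif(1, 0.05, 0.5)
    eye <- sample(c("LE", "RE"), 1)
    got <- idt_fixations(rec, disp, dur, eye)
    want <- oracle_idt(rec, disp, dur, eye)
    expect_equal(got, want, tolerance = 1e-12,
                 info = sprintf("case %d (n=%d disp=%.2f dur=%.2f)", rep, n, disp, dur))
  }
})

test_that("detect_dwells recovers targets in order and flags omissions", {
  grid <- build_target_grid()
  cfg <- simulation_config(seed = 21, blink_rate_hz = 0, loss_prob = 0,
                           noise_deg_rms = 0.1, traversal = 1:9)
  sim <- simulate_subject(cfg)
  le <- slice_event(sim$recording, sim$annotations, "LE")
  dw <- detect_dwells(le, grid, order = 1:9)
  expect_equal(dw$target_id, 1:9)  # traversal order
  expect_true(all(diff(dw$t_start) > 0))
  expect_true(all(dw$t_end[-nrow(dw)] <= dw$t_start[-1])) # non-overlapping
  expect_true(all(dw$t_start >= min(le$samples$t_s) &
                    dw$t_end <= max(le$samples$t_s)))
  expect_equal(attr(dw, "missing_ids"), integer(0))

  # a stream that never enters target 5's radius: dwell list lacks id 5
  s <- le$samples
  g5 <- grid[grid$id == 5, ]
  near5 <- sqrt((s$right_x_cm - g5$x_cm)^2 + (s$right_y_cm - g5$y_cm)^2) <= 7.5
  s$right_valid[near5] <- FALSE
  le5 <- gaze_recording(s, rate_hz = le$rate_hz, meta = le$meta)
  expect_warning(dw5 <- detect_dwells(le5, grid, order = 1:9),
                 class = "hg_quality_warning")
  expect_false(5 %in% dw5$target_id)
  expect_equal(attr(dw5, "missing_ids"), 5L)

  # mostly-missing recording -> quality error advising re-recording
  s2 <- le$samples
  s2$right_valid[s2$t_s > 2] <- FALSE
  le_bad <- gaze_recording(s2, rate_hz = le$rate_hz, meta = le$meta)
  expect_error(suppressWarnings(detect_dwells(le_bad, grid, order = 1:9)),
               class = "hg_quality_error")
})

test_that("re-fixation picks the later visit; 'longest' picks the longer", {
  rate <- 250
  grid <- build_target_grid()
  # visit target 3 (20,20) twice: 0.5 s early, then elsewhere, then 0.4 s late
  seg <- function(x, y, dur) {
    n <- round(dur * rate)
    list(x = rep(x, n), y = rep(y, n))
  }
  parts <- list(seg(20, 20, 0.5), seg(0, -20, 0.6), seg(20, 20, 0.4))
  x <- unlist(lapply(parts, `[[`, "x"))
  y <- unlist(lapply(parts, `[[`, "y"))
  t <- seq(0, by = 1 / rate, length.out = length(x))
  rec <- make_recording(t, x, y)
  rec$meta$fixating_eye <- "RE"
  rec$meta$tested_eye <- "LE"
  dw_last <- suppressWarnings(detect_dwells(rec, grid, dwell_params(max_missing_frac = 1)))
  d3 <- dw_last[dw_last$target_id == 3, ]
  expect_gt(d3$t_start, 1.0) # the later visit
  dw_long <- suppressWarnings(detect_dwells(
    rec, grid, dwell_params(selection = "longest", max_missing_frac = 1)))
  d3l <- dw_long[dw_long$target_id == 3, ]
  expect_lt(d3l$t_start, 0.1) # the longer, earlier visit
})

test_that("estimate_fixation is a robust per-eye median over valid samples", {
  t <- seq(0, 1, by = 1 / 250)
  n <- length(t)
  s <- make_samples(t, rep(2, n), rep(-1, n))
  s$right_x_cm <- rep(4, n)
  s$right_y_cm <- rep(0.5, n)
  slice <- gaze_recording(s, rate_hz = 250)
  dwell <- list(i_start = 1L, i_end = n, target_id = 1L)
  est <- estimate_fixation(slice, dwell)
  expect_equal(c(est$le_x, est$le_y, est$re_x, est$re_y), c(2, -1, 4, 0.5))
  expect_equal(est$n_valid_le, n)

  # a 10 cm outlier in 100 samples leaves the median unchanged
  s2 <- s[1:100, ]
  s2$left_x_cm[50] <- 12
  slice2 <- gaze_recording(s2, rate_hz = 250)
  est2 <- estimate_fixation(slice2, list(i_start = 1L, i_end = 100L, target_id = 1L))
  expect_equal(est2$le_x, 2)

  # all-LE-invalid dwell -> LE estimate missing, flagged
  s3 <- s
  s3$left_valid <- FALSE
  slice3 <- gaze_recording(s3, rate_hz = 250)
  est3 <- estimate_fixation(slice3, dwell)
  expect_true(est3$le_missing)
  expect_equal(est3$n_valid_le, 0L)
  expect_true(is.na(est3$le_x))
  expect_false(est3$re_missing)
})

test_that("zero-noise dwell medians equal target coordinates exactly", {
  grid <- build_target_grid()
  cfg <- simulation_config(phoria_h_pd = -4, phoria_v_pd = 1.5,
                           noise_deg_rms = 0, blink_rate_hz = 0, loss_prob = 0,
                           seed = 17, traversal = 1:9)
  sim <- simulate_subject(cfg)
  for (eye in c("LE", "RE")) {
    slice <- slice_event(sim$recording, sim$annotations, eye)
    dw <- detect_dwells(slice, grid, order = 1:9)
    fix_eye <- slice$meta$fixating_eye
    for (i in seq_len(nrow(dw))) {
      est <- estimate_fixation(slice, dw[i, ])
      gx <- grid$x_cm[grid$id == dw$target_id[i]]
      gy <- grid$y_cm[grid$id == dw$target_id[i]]
      if (fix_eye == "LE") expect_identical(c(est$le_x, est$le_y), c(gx, gy))
      else expect_identical(c(est$re_x, est$re_y), c(gx, gy))
    }
  }
})
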
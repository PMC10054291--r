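test_that("simulation is deterministic per seed", {
  cfg <- simulation_config(phoria_h_pd = 2, phoria_v_pd = -1, seed = 101,
                           dwell_s = 0.5, traversal = 1:6)
  a <- simulate_subject(cfg)
  b <- simulate_subject(cfg)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$truth$deviations, b$truth$deviations)
  c2 <- simulate_subject(simulation_config(phoria_h_pd = 2, phoria_v_pd = -1,
                                           seed = 102, dwell_s = 0.5,
                                           traversal = 1:6))
  expect_false(identical(a$recording$samples, c2$recording$samples))
})

test_that("events are ordered LE then RE and cover the traversal", {
  cfg <- simulation_config(seed = 6, dwell_s = 0.4)
  sim <- simulate_subject(cfg)
  ann <- sim$annotations
  expect_lt(ann$le[2], ann$re[1])
  expect_equal(sim$truth$deviations$target_id,
               rep(1:17, 2))
  expect_equal(unique(sim$truth$deviations$tested_eye), c("LE", "RE"))
  # dwell intervals sit inside their events
  dw <- sim$truth$dwells
  le_dw <- dw[dw$tested_eye == "LE", ]
  expect_true(all(le_dw$t_start >= ann$le[1] & le_dw$t_end <= ann$le[2]))
})

test_that("tested-eye offsets implement the sign algebra exactly", {
  # zero noise: hand-check the landing points during each event
  cfg <- simulation_config(phoria_h_pd = 4, phoria_v_pd = 2, noise_deg_rms = 0,
                           blink_rate_hz = 0, loss_prob = 0, seed = 1,
                           dwell_s = 0.4, traversal = 1)
  sim <- simulate_subject(cfg)
  s <- sim$recording$samples
  ann <- sim$annotations
  le_test <- s[s$t_s <= ann$le[2], ]
  # LE under test at target (0,0): x_LE = +4*100/100 = 4, y_LE = -2; RE on target
  expect_equal(unique(le_test$left_x_cm), 4)
  expect_equal(unique(le_test$left_y_cm), -2)
  expect_equal(unique(le_test$right_x_cm), 0)
  expect_equal(unique(le_test$right_y_cm), 0)
  re_test <- s[s$t_s >= ann$re[1], ]
  # RE under test: x_RE = -4, y_RE = +2; LE on target
  expect_equal(unique(re_test$right_x_cm), -4)
  expect_equal(unique(re_test$right_y_cm), 2)
  expect_equal(unique(re_test$left_x_cm), 0)
})

test_that("incomitance map injects per-target deviations", {
  inc <- data.frame(target_id = 4L, dh_pd = 3, dv_pd = -1)
  cfg <- simulation_config(phoria_h_pd = 1, incomitance_map = inc,
                           noise_deg_rms = 0, blink_rate_hz = 0, loss_prob = 0,
                           seed = 2, dwell_s = 0.5, traversal = 1:9)
  sim <- simulate_subject(cfg)
  rec <- analyze_recording(sim$recording, sim$annotations, order = 1:9)
  expect_true(all(rec$dx_pd[rec$target_id == 4] == 4))
  expect_true(all(rec$dy_pd[rec$target_id == 4] == -1))
  expect_true(all(rec$dx_pd[rec$target_id != 4] == 1))
})

test_that("validity accounting matches the loss model (binomial 99% CI)", {
  # loss only (blinks off): per-eye invalid fraction ~ Binomial(n, loss_prob)
  cfg <- simulation_config(loss_prob = 0.01, blink_rate_hz = 0,
                           noise_deg_rms = 0.1, seed = 55)
  sim <- simulate_subject(cfg)
  s <- sim$recording$samples
  n <- nrow(s)
  ci <- qbinom(c(0.005, 0.995), n, 0.01)
  expect_gte(sum(!s$left_valid), ci[1])
  expect_lte(sum(!s$left_valid), ci[2])
  expect_gte(sum(!s$right_valid), ci[1])
  expect_lte(sum(!s$right_valid), ci[2])

  # blinks hit both eyes simultaneously
  cfgb <- simulation_config(loss_prob = 0, blink_rate_hz = 0.5,
                            noise_deg_rms = 0.1, seed = 56, dwell_s = 0.5)
  simb <- simulate_subject(cfgb)
  sb <- simb$recording$samples
  expect_true(any(!sb$left_valid))
  expect_identical(sb$left_valid, sb$right_valid)
  # expected blink coverage = rate * duration; allow a generous band
  frac <- mean(!sb$left_valid)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.20)
})

test_that("deviations beyond tracker coverage are flagged with a warning", {
  # a 60 PD exophoria at the (40,40) corner pushes the tested eye past 35 deg
  cfg <- simulation_config(phoria_h_pd = -60, noise_deg_rms = 0,
                           blink_rate_hz = 0, loss_prob = 0, seed = 3,
                           dwell_s = 0.3, traversal = c(1, 13))
  expect_warning(sim <- simulate_subject(cfg), class = "hg_quality_warning")
  s <- sim$recording$samples
  expect_true(any(!s$left_valid | !s$right_valid))
})

test_that("simulate_subjective quantizes truth like an examiner", {
  sim <- simulate_subject(simulation_config(phoria_h_pd = 0, noise_deg_rms = 0,
                                            blink_rate_hz = 0, loss_prob = 0,
                                            seed = 4, dwell_s = 0.3,
                                            traversal = 1:9))
  # truth 0, jitter 0 -> all zeros
  t0 <- simulate_subjective(sim$truth, jitter_pd = 0, seed = 1)
  expect_true(all(t0$dx_pd == 0 & t0$dy_pd == 0))
  # truth +4, jitter 0, quant 5 -> recorded +5
  sim4 <- simulate_subject(simulation_config(phoria_h_pd = 4, noise_deg_rms = 0,
                                             blink_rate_hz = 0, loss_prob = 0,
                                             seed = 5, dwell_s = 0.3,
                                             traversal = 1:9))
  t4 <- simulate_subjective(sim4$truth, jitter_pd = 0, seed = 1)
  expect_true(all(t4$dx_pd == 5))
  # jittered outputs remain multiples of the quantization step
  tj <- simulate_subjective(sim4$truth, jitter_pd = 2.5, seed = 2)
  expect_true(all(tj$dx_pd %% 5 == 0 & tj$dy_pd %% 5 == 0))
  # deterministic per seed
  expect_identical(tj, simulate_subjective(sim4$truth, jitter_pd = 2.5, seed = 2))
})

test_that("cohorts are reproducible and n = 1 zero-noise matches simulate_subject", {
  base <- simulation_config(noise_deg_rms = 0, blink_rate_hz = 0, loss_prob = 0,
                            dwell_s = 0.3, traversal = 1:5)
  co1 <- simulate_cohort(3, base_config = base, seed = 77)
  co2 <- simulate_cohort(3, base_config = base, seed = 77)
  expect_identical(lapply(co1, function(s) s$recording$samples),
                   lapply(co2, function(s) s$recording$samples))
  expect_equal(length(co1), 3L)
  # phorias drawn from the stated uniform ranges
  hs <- vapply(co1, function(s) s$truth$config$phoria_h_pd, 0)
  vs <- vapply(co1, function(s) s$truth$config$phoria_v_pd, 0)
  expect_true(all(abs(hs) <= 6) && all(abs(vs) <= 2))
  # single-subject bundle reduces to simulate_subject under the same seed
  cfg1 <- co1[[1]]$truth$config
  direct <- simulate_subject(cfg1, subject_id = co1[[1]]$subject_id)
  expect_identical(direct$recording$samples, co1[[1]]$recording$samples)
})

test_that("comitance: LE-event and RE-event deviations agree within noise", {
  cfg <- simulation_config(phoria_h_pd = -3, phoria_v_pd = 1, seed = 88)
  sim <- simulate_subject(cfg)
  rec <- analyze_recording(sim$recording, sim$annotations)
  w <- reshape(rec[, c("tested_eye", "target_id", "dx_pd", "dy_pd")],
               direction = "wide", idvar = "target_id", timevar = "tested_eye")
  # 2 x noise tolerance: recovered deviation RMSE is < 0.5 PD by design
  expect_true(all(abs(w$dx_pd.LE - w$dx_pd.RE) < 1, na.rm = TRUE))
  expect_true(all(abs(w$dy_pd.LE - w$dy_pd.RE) < 1, na.rm = TRUE))
})
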
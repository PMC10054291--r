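# Independent oracles and stream constructors shared across test files.

# Exhaustive window-scan I-DT oracle. Independent computation path: dispersion
# is recomputed per window with cummax/cummin from each candidate start, and
# invalid samples are handled by scanning runs found with which()/split().
# Semantics (shared with the implementation): earliest qualifying start,
# maximal extension (dispersion is monotone in window growth), non-overlapping.
oracle_idt <- function(recording, dispersion_max, min_duration, eye) {
  s <- recording$samples
  if (eye == "LE") {
    x <- s$left_x_cm; y <- s$left_y_cm; v <- s$left_valid
  } else {
    x <- s$right_x_cm; y <- s$right_y_cm; v <- s$right_valid
  }
  t <- s$t_s
  out <- NULL
  valid_idx <- which(v)
  runs <- split(valid_idx, cumsum(c(1L, diff(valid_idx) != 1L)))
  for (run in runs) {
    i <- 1L
    n <- length(run)
    while (i <= n) {
      seg <- run[i:n]
      disp <- (cummax(x[seg]) - cummin(x[seg])) + (cummax(y[seg]) - cummin(y[seg]))
      jrel <- max(which(disp <= dispersion_max)) # >= 1: single sample has 0 dispersion
      j <- i + jrel - 1L
      if (t[run[j]] - t[run[i]] >= min_duration) {
        out <- rbind(out, data.frame(t_start = t[run[i]], t_end = t[run[j]],
                                     i_start = run[i], i_end = run[j]))
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  if (is.null(out))
    out <- data.frame(t_start = numeric(0), t_end = numeric(0),
                      i_start = integer(0), i_end = integer(0))
  rownames(out) <- NULL
  out
}

# Exact permutation two-sided p for the Pearson correlation of tiny vectors.
oracle_perm_pearson_p <- function(a, b) {
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  r0 <- abs(cor(a, b))
  rs <- vapply(perms(b), function(p) abs(cor(a, p)), 0)
  mean(rs >= r0 - 1e-12)
}

# Minimal binocular sample frame where both eyes follow the same path.
make_samples <- function(t, x, y, left_valid = TRUE, right_valid = TRUE) {
  data.frame(t_s = t, left_x_cm = x, left_y_cm = y,
             left_valid = left_valid,
             right_x_cm = x, right_y_cm = y, right_valid = right_valid)
}

make_recording <- function(t, x, y, ...) {
  gaze_recording(make_samples(t, x, y, ...), subject_id = "T1", rate_hz = 250)
}

# Random gaze stream mixing plateaus, linear ramps and dropouts; used by the
# property tests that pit idt_fixations against oracle_idt.
random_stream <- function(n, rate = 250) {
  t <- seq(0, by = 1 / rate, length.out = n)
  x <- numeric(n)
  y <- numeric(n)
  i <- 1L
  px <- runif(1, -40, 40)
  py <- runif(1, -40, 40)
  while (i <= n) {
    len <- min(n - i + 1L, sample(5:200, 1))
    idx <- i:(i + len - 1L)
    if (runif(1) < 0.6) { # noisy plateau
      sd <- runif(1, 0, 1.5)
      x[idx] <- px + rnorm(len, 0, sd)
      y[idx] <- py + rnorm(len, 0, sd)
    } else { # ramp to a new location
      nx <- runif(1, -40, 40); ny <- runif(1, -40, 40)
      x[idx] <- seq(px, nx, length.out = len)
      y[idx] <- seq(py, ny, length.out = len)
      px <- nx; py <- ny
    }
    i <- i + len
  }
  valid <- runif(n) >= 0.03
  if (!any(valid)) valid[1] <- TRUE
  samples <- make_samples(t, x, y, left_valid = valid, right_valid = valid)
  gaze_recording(samples, subject_id = "rand", rate_hz = rate)
}

# Per-subject truth table of a simulated cohort, one row per (eye, target).
cohort_truth <- function(cohort) {
  do.call(rbind, lapply(cohort, function(s)
    cbind(subject_id = s$subject_id, s$truth$deviations)))
}

# Merge analyzed records with ground truth (complete records only).
merge_truth <- function(records, cohort) {
  m <- merge(records, cohort_truth(cohort),
             by = c("subject_id", "tested_eye", "target_id"),
             suffixes = c("", ".true"))
  m[m$quality != "missing", ]
}
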
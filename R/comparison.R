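# Subjective-vs-objective method comparison: paired t-tests, Pearson
# correlation and Kolmogorov-Smirnov normality checks, pooled across subjects
# and the nine central targets into one cell per (eye, axis).

#' Paired-sample t-test
#'
#' `t = mean(a - b) / (sd(a - b) / sqrt(n))` with the n-1 sd denominator and a
#' two-sided p from the t distribution on `n - 1` df. Incomplete pairs are
#' dropped (pairwise deletion) and counted.
#'
#' @param a,b paired numeric vectors of equal length
#' @return object of class `paired_comparison`: `n`, `n_dropped`, `mean_diff`,
#'   `t_stat`, `df`, `p`, `degenerate` (`TRUE` when the differences have zero
#'   variance)
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) hg_stats_error("paired_t needs equal-length vectors")
  ok <- is.finite(a) & is.finite(b)
  n_dropped <- sum(!ok)
  d <- a[ok] - b[ok]
  n <- length(d)
  if (n < 2L) hg_stats_error("paired_t needs at least 2 complete pairs")
  m <- mean(d)
  s <- stats::sd(d)
  degenerate <- s == 0
  if (degenerate) {
    t_stat <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
  } else {
    t_stat <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  }
  structure(list(n = n, n_dropped = n_dropped, mean_diff = m, t_stat = t_stat,
                 df = n - 1L, p = p, degenerate = degenerate),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("Paired t: n = %d, mean diff = %.4g, t(%d) = %.4g, p = %.4g%s\n",
              x$n, x$mean_diff, x$df, x$t_stat, x$p,
              if (x$degenerate) " [degenerate: zero-variance differences]" else ""))
  invisible(x)
}

#' Pearson correlation with t-based two-sided p
#'
#' @param a,b numeric vectors, pairwise-complete n >= 3, both with nonzero
#'   variance
#' @return object of class `correlation_result`: `n`, `r`, `p`
#' @export
pearson_cor <- function(a, b) {
  if (length(a) != length(b)) hg_stats_error("pearson_cor needs equal-length vectors")
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3L) hg_stats_error("pearson_cor needs at least 3 complete pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    hg_stats_error("correlation undefined: an input has zero variance")
  r <- stats::cor(a, b)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  structure(list(n = n, r = r, p = p), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson: n = %d, r = %.4g, p = %.4g\n", x$n, x$r, x$p))
  invisible(x)
}

# Lilliefors p-value approximation for the one-sample KS statistic against a
# normal with estimated mean and sd: Dallal & Wilkinson (1986) for p <= 0.1,
# Stephens (1974) polynomial inversion above.
.hg_lilliefors_p <- function(D, n) {
  if (n > 100) {
    Kd <- D * (n / 100)^0.49
    nd <- 100
  } else {
    Kd <- D
    nd <- n
  }
  p <- exp(-7.01256 * Kd^2 * (nd + 2.78019) +
             2.99587 * Kd * sqrt(nd + 2.78019) -
             0.122119 + 0.974598 / sqrt(nd) + 1.67997 / nd)
  if (p > 0.1) {
    KK <- (sqrt(n) - 0.01 + 0.85 / sqrt(n)) * D
    p <- if (KK <= 0.302) 1
      else if (KK <= 0.5)
        2.76773 - 19.828315 * KK + 80.709644 * KK^2 -
          138.55152 * KK^3 + 81.218052 * KK^4
      else if (KK <= 0.9)
        -4.901232 + 40.662806 * KK - 97.490286 * KK^2 +
          94.029866 * KK^3 - 32.355711 * KK^4
      else if (KK <= 1.31)
        6.198765 - 19.558097 * KK + 23.186922 * KK^2 -
          12.234627 * KK^3 + 2.423045 * KK^4
      else 0
  }
  min(max(p, 0), 1)
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS statistic of the data against a normal with the sample's own
#' mean and sd. Because the parameters are estimated, the default p-value uses
#' the Lilliefors approximation; `mode = "standard"` instead returns the
#' classical KS p (anti-conservative in this situation, provided for
#' comparability).
#'
#' @param values numeric vector, n >= 4, nonzero sd
#' @param mode `"lilliefors"` (default) or `"standard"`
#' @param label optional variable label carried into the result
#' @return object of class `normality_result`: `label`, `n`, `ks_stat`, `p`
#' @export
ks_normal <- function(values, mode = c("lilliefors", "standard"), label = "") {
  mode <- match.arg(mode)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 4L) hg_stats_error("ks_normal needs at least 4 values")
  s <- stats::sd(values)
  if (s == 0) hg_stats_error("ks_normal undefined for a constant vector")
  z <- sort((values - mean(values)) / s)
  Fz <- stats::pnorm(z)
  i <- seq_len(n)
  D <- max(i / n - Fz, Fz - (i - 1) / n)
  p <- if (mode == "lilliefors") .hg_lilliefors_p(D, n) else
    suppressWarnings(stats::ks.test(values, "pnorm",
                                    mean(values), s)$p.value)
  structure(list(label = label, n = n, ks_stat = D, p = p, mode = mode),
            class = "normality_result")
}

#' Compare objective and subjective deviations (method-agreement table)
#'
#' Pools (subject, target) pairs across the cohort and the nine central
#' targets into four cells — horizontal and vertical deviation for each tested
#' eye — and reports, per cell, the paired t-test between methods, the Pearson
#' correlation, and a normality check of the paired differences. Missing
#' objective points drop the pair (pairwise deletion, counted). Cells with
#' fewer than 3 pairs are reported as insufficient data. With 13 subjects and
#' 9 central points each cell holds n = 117 pairs.
#'
#' @param objective a `deviation_records` data.frame (possibly several
#'   subjects row-bound)
#' @param subjective a `subjective_template` data.frame with a `subject_id`
#'   column matching the objective records
#' @param grid a `target_grid`
#' @param central_only restrict to the nine central targets (default `TRUE`)
#' @param alpha significance threshold for the `significant` flags
#'   (default 0.05)
#' @param ks_mode passed to [ks_normal()]
#' @return data.frame of class `method_comparison`, one row per (eye, axis)
#'   cell with columns `eye`, `axis`, `n`, `n_dropped`, `mean_subj`,
#'   `mean_obj`, `mean_diff`, `t_stat`, `df`, `p_t`, `r`, `p_r`, `ks_stat`,
#'   `ks_p`, `t_significant`, `r_significant`, `note`
#' @export
compare_methods <- function(objective, subjective, grid = build_target_grid(),
                            central_only = TRUE, alpha = 0.05,
                            ks_mode = "lilliefors") {
  obj <- as.data.frame(objective)
  subj <- as.data.frame(subjective)
  if (!"subject_id" %in% names(subj)) subj$subject_id <- "S1"
  if (central_only) {
    keep <- central_nine(grid)
    obj <- obj[obj$target_id %in% keep, ]
    subj <- subj[subj$target_id %in% keep, ]
  }
  obj <- obj[obj$quality != "missing", ]
  merged <- merge(
    obj, subj,
    by.x = c("subject_id", "tested_eye", "target_id"),
    by.y = c("subject_id", "eye", "target_id"),
    suffixes = c("_obj", "_subj")
  )
  cells <- expand.grid(eye = c("LE", "RE"), axis = c("dx", "dy"),
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    eye <- cells$eye[i]; axis <- cells$axis[i]
    sub <- merged[merged$tested_eye == eye, ]
    o <- sub[[paste0(axis, "_pd_obj")]]
    s <- sub[[paste0(axis, "_pd_subj")]]
    base <- data.frame(eye = eye, axis = axis, n = NA_integer_,
                       n_dropped = NA_integer_, mean_subj = NA_real_,
                       mean_obj = NA_real_, mean_diff = NA_real_,
                       t_stat = NA_real_, df = NA_integer_, p_t = NA_real_,
                       r = NA_real_, p_r = NA_real_, ks_stat = NA_real_,
                       ks_p = NA_real_, t_significant = NA,
                       r_significant = NA, note = "", stringsAsFactors = FALSE)
    ok <- is.finite(o) & is.finite(s)
    if (sum(ok) < 3L) {
      base$note <- "insufficient data (< 3 pairs)"
      return(base)
    }
    tt <- paired_t(s, o)
    base$n <- tt$n
    base$n_dropped <- sum(!ok)
    base$mean_subj <- mean(s[ok]); base$mean_obj <- mean(o[ok])
    base$mean_diff <- tt$mean_diff; base$t_stat <- tt$t_stat
    base$df <- tt$df; base$p_t <- tt$p
    base$t_significant <- tt$p < alpha
    cr <- tryCatch(pearson_cor(s, o), hg_stats_error = function(e) e)
    if (inherits(cr, "condition")) {
      base$note <- conditionMessage(cr)
    } else {
      base$r <- cr$r; base$p_r <- cr$p
      base$r_significant <- cr$p < alpha
    }
    ks <- tryCatch(ks_normal(s[ok] - o[ok], mode = ks_mode,
                             label = paste(eye, axis, "diff")),
                   hg_stats_error = function(e) e)
    if (!inherits(ks, "condition")) {
      base$ks_stat <- ks$ks_stat; base$ks_p <- ks$p
    }
    base
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "n_merged") <- nrow(merged)
  class(out) <- c("method_comparison", "data.frame")
  out
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("Subjective vs objective deviations (pooled over subjects and central targets)\n")
  cat(sprintf("alpha = %g\n\n", attr(x, "alpha")))
  for (i in seq_len(nrow(x))) {
    lab <- sprintf("%s %s", x$eye[i], ifelse(x$axis[i] == "dx",
                                             "horizontal", "vertical"))
    if (!is.na(x$note[i]) && nzchar(x$note[i]) && is.na(x$r[i]) && is.na(x$t_stat[i])) {
      cat(sprintf("  %-14s %s\n", lab, x$note[i]))
      next
    }
    cat(sprintf(
      "  %-14s n = %3d  mean diff = %+6.2f PD  t(%d) = %6.2f (p = %.3g)  cc = %s (p = %s)\n",
      lab, x$n[i], x$mean_diff[i], x$df[i], x$t_stat[i], x$p_t[i],
      ifelse(is.na(x$r[i]), "NA", sprintf("%.3f", x$r[i])),
      ifelse(is.na(x$p_r[i]), "NA", sprintf("%.3g", x$p_r[i]))
    ))
    if (nzchar(x$note[i])) cat(sprintf("  %-14s (%s)\n", "", x$note[i]))
  }
  invisible(x)
}

#' Write a method comparison as CSV
#'
#' @param comparison a [compare_methods()] result
#' @param path output CSV
#' @return `path`, invisibly
#' @export
write_comparison <- function(comparison, path) {
  utils::write.csv(as.data.frame(comparison), path, row.names = FALSE)
  invisible(path)
}
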
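# Condition classes and logging shared across the package.
#
# Every user-facing failure is signalled as a classed condition so callers
# (and the CLI) can map error categories to exit codes:
#   hg_config_error, hg_format_error, hg_domain_error, hg_segmentation_error,
#   hg_quality_error, hg_io_error, hg_stats_error

hg_abort <- function(message, class, ...) {
  stop(structure(
    class = c(class, "hg_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

hg_config_error <- function(msg, ...) hg_abort(msg, "hg_config_error", ...)
hg_format_error <- function(msg, ...) hg_abort(msg, "hg_format_error", ...)
hg_domain_error <- function(msg, ...) hg_abort(msg, "hg_domain_error", ...)
hg_segmentation_error <- function(msg, ...) hg_abort(msg, "hg_segmentation_error", ...)
hg_quality_error <- function(msg, ...) hg_abort(msg, "hg_quality_error", ...)
hg_io_error <- function(msg, ...) hg_abort(msg, "hg_io_error", ...)
hg_stats_error <- function(msg, ...) hg_abort(msg, "hg_stats_error", ...)

#' Package logging
#'
#' Messages are emitted through [message()] at or above the level set by
#' `options(hessgaze.log_level = )` (`"debug"`, `"info"` (default), `"warn"`,
#' `"quiet"`). Quality warnings additionally honour the `hessgaze.strict`
#' option: when `TRUE`, [hg_warn_quality()] escalates to an error.
#'
#' @param level one of `"debug"`, `"info"`, `"warn"`
#' @param ... message parts, pasted with no separator
#' @return `invisible(NULL)`
#' @keywords internal
hg_log <- function(level = "info", ...) {
  levels <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)
  threshold <- levels[[getOption("hessgaze.log_level", "info")]]
  if (levels[[level]] >= threshold) {
    message(sprintf("[hessgaze %s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

# Quality warning that becomes an error under options(hessgaze.strict = TRUE)
hg_warn_quality <- function(msg) {
  if (isTRUE(getOption("hessgaze.strict", FALSE))) hg_quality_error(msg)
  warning(structure(
    class = c("hg_quality_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
  invisible(NULL)
}

# Polynomial rolling hash (mod 2^31 - 1) of a character scalar; used to
# fingerprint configs in results provenance. Stable short id, not cryptographic.
hg_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 17
  for (b in utf8ToInt(x)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
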
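# Run configuration.
#
# Configs are TOML files restricted to a documented subset: top-level tables
# (`[geometry]`, `[dwell]`, ...), scalar keys (numbers, double-quoted strings,
# true/false) and flat arrays of scalars. That covers every knob this pipeline
# exposes; nested tables-of-tables and dates are rejected.

.hg_toml_scalar <- function(tok, path, lineno) {
  tok <- trimws(tok)
  if (tok == "true") return(TRUE)
  if (tok == "false") return(FALSE)
  if (grepl('^".*"$', tok)) return(gsub('\\\\"', '"', substr(tok, 2, nchar(tok) - 1)))
  val <- suppressWarnings(as.numeric(tok))
  if (is.na(val))
    hg_format_error(sprintf("%s:%d: cannot parse TOML value '%s'", path, lineno, tok))
  val
}

#' Read a TOML configuration file (documented subset)
#'
#' @param path TOML file
#' @return nested named list: one element per table, plus any top-level keys
#' @export
read_toml <- function(path) {
  if (!file.exists(path)) hg_io_error(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  out <- list()
  section <- NULL
  for (i in seq_along(lines)) {
    line <- lines[i]
    # strip comments: first '#' not inside a double-quoted string
    chars <- strsplit(line, "")[[1]]
    in_str <- FALSE
    for (k in seq_along(chars)) {
      if (chars[k] == '"') in_str <- !in_str
      if (chars[k] == "#" && !in_str) {
        line <- substr(line, 1, k - 1)
        break
      }
    }
    line <- trimws(line)
    if (line == "") next
    if (grepl("^\\[.*\\]$", line)) {
      section <- trimws(gsub("^\\[|\\]$", "", line))
      if (grepl("[\\[\\.]", section))
        hg_format_error(sprintf("%s:%d: nested TOML tables are not supported", path, i))
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    if (!grepl("=", line, fixed = TRUE))
      hg_format_error(sprintf("%s:%d: expected 'key = value'", path, i))
    key <- trimws(sub("=.*$", "", line))
    val <- trimws(sub("^[^=]*=", "", line))
    parsed <- if (grepl("^\\[.*\\]$", val)) {
      inner <- trimws(gsub("^\\[|\\]$", "", val))
      if (inner == "") list() else {
        toks <- strsplit(inner, ",")[[1]]
        vals <- lapply(toks, .hg_toml_scalar, path = path, lineno = i)
        unlist(vals)
      }
    } else {
      .hg_toml_scalar(val, path, i)
    }
    if (is.null(section)) out[[key]] <- parsed else out[[section]][[key]] <- parsed
  }
  out
}

#' Default pipeline configuration
#'
#' All tunables of the analysis chain with their defaults, as a nested list
#' mirroring the TOML sections. See the methods vignette for the rationale
#' behind each default.
#'
#' @return nested named list with sections `geometry`, `dwell`, `deviation`,
#'   `stats`, `simulator`
#' @export
default_config <- function() {
  list(
    geometry = list(
      screen_distance_cm = 100,
      square_cm = 5,
      tracker_distance_cm = 60,
      tracker_max_angle_deg = 35
    ),
    dwell = list(
      radius_cm = 7.5,
      min_duration_s = 0.3,
      min_valid_frac = 0.8,
      dispersion_max_cm = 6.0,
      selection = "last",
      max_missing_frac = 0.5,
      center = "median"
    ),
    deviation = list(
      central_only = TRUE,
      tol_pd = 0.5,
      min_valid_floor = 10
    ),
    stats = list(
      alpha = 0.05,
      ks_mode = "lilliefors"
    ),
    simulator = list(
      n_subjects = 1,
      phoria_h_pd = 0,
      phoria_v_pd = 0,
      noise_deg_rms = 0.3,
      dwell_s = 2.0,
      saccade_ms = 40,
      blink_rate_hz = 0.2,
      blink_ms = 150,
      loss_prob = 0.005,
      rate_hz = 250,
      seed = 1
    )
  )
}

# Merge user values onto defaults, rejecting unknown sections/keys so typos
# fail loudly instead of being silently ignored.
.hg_merge_config <- function(user, defaults, where = "") {
  for (key in names(user)) {
    full <- if (where == "") key else paste0(where, ".", key)
    if (!key %in% names(defaults))
      hg_config_error(sprintf(
        "unknown config key '%s' (known: %s)", full,
        paste(names(defaults), collapse = ", ")
      ))
    if (is.list(defaults[[key]]) && !is.list(user[[key]]))
      hg_config_error(sprintf("config key '%s' must be a [%s] table", full, key))
    if (is.list(defaults[[key]])) {
      defaults[[key]] <- .hg_merge_config(user[[key]], defaults[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a TOML config and merges it onto [default_config()]. Unknown keys are
#' rejected with a message listing the accepted ones.
#'
#' @param path TOML file, or `NULL` for pure defaults
#' @return validated nested config list
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) cfg <- .hg_merge_config(read_toml(path), cfg)
  # construct-validate the geometry now so bad values fail at load time
  do.call(screen_geometry, cfg$geometry)
  dw <- cfg$dwell
  if (dw$radius_cm <= 0 || dw$min_duration_s <= 0 || dw$dispersion_max_cm <= 0)
    hg_config_error("dwell radius, duration and dispersion must be positive")
  if (dw$min_valid_frac <= 0 || dw$min_valid_frac > 1)
    hg_config_error("dwell.min_valid_frac must lie in (0, 1]")
  if (!dw$selection %in% c("last", "longest"))
    hg_config_error("dwell.selection must be 'last' or 'longest'")
  if (!dw$center %in% c("median", "mean"))
    hg_config_error("dwell.center must be 'median' or 'mean'")
  if (!cfg$stats$ks_mode %in% c("lilliefors", "standard"))
    hg_config_error("stats.ks_mode must be 'lilliefors' or 'standard'")
  cfg
}

# Geometry object from a config list
config_geometry <- function(cfg) do.call(screen_geometry, cfg$geometry)

# Stable fingerprint of a config, recorded in results provenance
config_hash <- function(cfg) {
  hg_hash(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA))
}
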
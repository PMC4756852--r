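#' Default pipeline configuration
#'
#' The packaged defaults: both built-in laser systems, water-like medium
#' constants, the literature damage thresholds, the measured recruitment
#' thresholds, and the quantification defaults (15/6 min windows,
#' detection level 0.1 sustained for 2 frames, strict >50% majority).
#'
#' @param seed integer base seed for simulation commands.
#' @return A list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1L) {
  systems <- list(mira900(), meta510())
  names(systems) <- vapply(systems, `[[`, "", "name")
  structure(list(
    systems = systems,
    medium = medium_constants(),
    damage_thresholds = damage_thresholds(),
    quantify = list(detection_level = 0.1, k = 2L,
                    window_53bp1_min = 15, window_trf2_min = 6,
                    majority_rule = 0.5),
    simulate = list(n_cells = 8L),
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file and merges it over [default_config()]; an empty or
#' absent document yields the full defaults. Laser systems are given
#' under a `systems` list with the fields of [laser_system()] plus a
#' `calibration` block (`mode`, `setting_unit`, and either
#' `throughput_coefficient` or `rows` as a list of
#' `[power_setting, energy_nJ]` pairs). Validation errors name the
#' offending key.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  if (is.null(raw)) return(cfg)

  if (!is.null(raw$systems)) {
    systems <- lapply(raw$systems, parse_system)
    names(systems) <- vapply(systems, `[[`, "", "name")
    if (anyDuplicated(names(systems))) {
      stop("configuration error in `systems`: system names must be unique",
           call. = FALSE)
    }
    cfg$systems <- systems
  }
  if (!is.null(raw$medium)) {
    cfg$medium <- with_key("medium", do.call(medium_constants, raw$medium))
  }
  if (!is.null(raw$damage_thresholds)) {
    cfg$damage_thresholds <-
      with_key("damage_thresholds", do.call(damage_thresholds, raw$damage_thresholds))
  }
  for (k in names(raw$quantify %||% list())) {
    if (!k %in% names(cfg$quantify)) {
      stop("configuration error: unknown key `quantify$", k, "`", call. = FALSE)
    }
    cfg$quantify[[k]] <- raw$quantify[[k]]
  }
  if (!is.null(raw$simulate$n_cells)) {
    cfg$simulate$n_cells <- as.integer(raw$simulate$n_cells)
  }
  if (!is.null(raw$seed)) cfg$seed <- as.integer(raw$seed)
  cfg
}

parse_system <- function(s) {
  cal <- s$calibration
  if (is.null(cal)) {
    stop("configuration error: system `", s$name %||% "?",
         "` is missing `calibration`", call. = FALSE)
  }
  rows <- NULL
  if (!is.null(cal$rows)) {
    m <- do.call(rbind, lapply(cal$rows, unlist))
    rows <- data.frame(power_setting = m[, 1], energy_nJ = m[, 2])
  }
  calibration <- with_key(
    paste0("systems/", s$name %||% "?", "/calibration"),
    power_calibration(mode = cal$mode %||% "linear_throughput",
                      setting_unit = cal$setting_unit %||% "mW",
                      throughput_coefficient = cal$throughput_coefficient,
                      rows = rows)
  )
  with_key(
    paste0("systems/", s$name %||% "?"),
    laser_system(
      name = s$name, wavelength_nm = s$wavelength_nm,
      pulse_width_fs = s$pulse_width_fs,
      repetition_rate_MHz = s$repetition_rate_MHz,
      objective_na = s$objective_na,
      objective_transmission = s$objective_transmission %||% 0.47,
      calibration = calibration,
      exposure = s$exposure %||% list(mode = "scanning", dwell_us = NA_real_)
    )
  )
}

# rethrow validation errors with the offending config key prefixed
with_key <- function(key, expr) {
  tryCatch(expr, error = function(e) {
    stop("configuration error in `", key, "`: ", conditionMessage(e),
         call. = FALSE)
  })
}
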
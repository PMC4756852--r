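#' Power calibration for a laser system
#'
#' Describes how an instrument power setting (the "input power" measured at
#' the microscope side port, or a software transmission percentage) maps to
#' the in-situ energy per pulse at the focal spot. Two modes are supported:
#'
#' * `"linear_throughput"`: energy is proportional to the setting, with a
#'   measured coefficient in nJ per setting unit. Appropriate when a
#'   polarizer-based attenuator gives a linear power ladder.
#' * `"lookup"`: a table of measured (setting, energy) pairs; energies at
#'   intermediate settings are linearly interpolated, and settings outside
#'   the tabulated range are refused (no extrapolation).
#'
#' @param mode `"linear_throughput"` or `"lookup"`.
#' @param setting_unit unit of the power setting, `"mW"` or `"percent"`.
#' @param throughput_coefficient nJ of in-situ energy per setting unit
#'   (linear mode only, > 0).
#' @param rows data frame with columns `power_setting` and `energy_nJ`
#'   (lookup mode only); both columns must be strictly increasing.
#' @return An object of class `power_calibration`.
#' @export
power_calibration <- function(mode = c("linear_throughput", "lookup"),
                              setting_unit = c("mW", "percent"),
                              throughput_coefficient = NULL,
                              rows = NULL) {
  mode <- match.arg(mode)
  setting_unit <- match.arg(setting_unit)
  if (mode == "linear_throughput") {
    if (is.null(throughput_coefficient) || !is.numeric(throughput_coefficient) ||
        length(throughput_coefficient) != 1L || throughput_coefficient <= 0) {
      stop("`throughput_coefficient` must be a single positive number for ",
           "linear_throughput mode", call. = FALSE)
    }
    rows <- NULL
  } else {
    rows <- tibble::as_tibble(rows)
    if (!all(c("power_setting", "energy_nJ") %in% names(rows)) ||
        nrow(rows) < 2L) {
      stop("lookup `rows` needs >= 2 rows with columns `power_setting` and ",
           "`energy_nJ`", call. = FALSE)
    }
    if (any(diff(rows$power_setting) <= 0) || any(diff(rows$energy_nJ) <= 0)) {
      stop("lookup rows must be strictly increasing in both `power_setting` ",
           "and `energy_nJ`", call. = FALSE)
    }
    throughput_coefficient <- NULL
  }
  structure(
    list(mode = mode, setting_unit = setting_unit,
         throughput_coefficient = throughput_coefficient, rows = rows),
    class = "power_calibration"
  )
}

#' Describe a laser microirradiation platform
#'
#' Bundles the optical parameters that determine dose (wavelength, pulse
#' width, repetition rate, objective NA and transmission) with a power
#' calibration and the macropulse delivery structure. Two ready-made
#' systems are provided: [mira900()] and [meta510()].
#'
#' @param name short label, e.g. `"Mira-900"`.
#' @param wavelength_nm laser wavelength in nm (> 0).
#' @param pulse_width_fs pulse duration in femtoseconds (> 0).
#' @param repetition_rate_MHz pulse repetition rate in MHz (> 0).
#' @param objective_na numerical aperture of the focusing objective,
#'   in (0, 1.7].
#' @param objective_transmission fraction of back-aperture power delivered
#'   to the focal spot, in (0, 1].
#' @param calibration a [power_calibration()].
#' @param exposure delivery structure: either
#'   `list(mode = "macropulse", exposure_ms =, gap_ms =)` for gated
#'   millisecond exposures separated by a cooling delay, or
#'   `list(mode = "scanning", dwell_us =)` for continuous raster scanning.
#'   Only the macropulse mode has an inter-pulse cooling interval to which
#'   the retained-heat estimate applies.
#' @return An object of class `laser_system`.
#' @seealso [dose_table()], [biophysics_report()]
#' @export
laser_system <- function(name, wavelength_nm, pulse_width_fs,
                         repetition_rate_MHz, objective_na,
                         objective_transmission, calibration,
                         exposure = list(mode = "scanning", dwell_us = NA_real_)) {
  stopifnot(is.character(name), length(name) == 1L)
  check_positive_scalar(wavelength_nm, "wavelength_nm")
  check_positive_scalar(pulse_width_fs, "pulse_width_fs")
  check_positive_scalar(repetition_rate_MHz, "repetition_rate_MHz")
  check_positive_scalar(objective_na, "objective_na")
  if (objective_na > 1.7) {
    stop("`objective_na` must be in (0, 1.7]", call. = FALSE)
  }
  check_positive_scalar(objective_transmission, "objective_transmission")
  if (objective_transmission > 1) {
    stop("`objective_transmission` must be in (0, 1]", call. = FALSE)
  }
  if (!inherits(calibration, "power_calibration")) {
    stop("`calibration` must be a power_calibration object", call. = FALSE)
  }
  if (!is.list(exposure) || !exposure$mode %in% c("macropulse", "scanning")) {
    stop("`exposure$mode` must be 'macropulse' or 'scanning'", call. = FALSE)
  }
  structure(
    list(name = name, wavelength_nm = wavelength_nm,
         pulse_width_fs = pulse_width_fs,
         repetition_rate_MHz = repetition_rate_MHz,
         objective_na = objective_na,
         objective_transmission = objective_transmission,
         calibration = calibration, exposure = exposure),
    class = "laser_system"
  )
}

#' @export
print.laser_system <- function(x, ...) {
  cat(sprintf("<laser_system> %s\n", x$name))
  cat(sprintf("  %g nm, %g fs, %g MHz, NA %g, objective transmission %g\n",
              x$wavelength_nm, x$pulse_width_fs, x$repetition_rate_MHz,
              x$objective_na, x$objective_transmission))
  cat(sprintf("  calibration: %s (%s), exposure: %s\n",
              x$calibration$mode, x$calibration$setting_unit, x$exposure$mode))
  invisible(x)
}

#' Built-in laser system descriptions
#'
#' `mira900()` is a Ti:Sapphire oscillator at 800 nm, 200 fs, 76 MHz focused
#' through a 63x/1.4 NA objective; its polarizer-controlled input-power
#' ladder is linear, with an in-situ throughput of 2.665e-3 nJ per mW of
#' input power, and exposures are delivered as 10 ms macropulses separated
#' by 100 ms cooling gaps. `meta510()` is a confocal-scanner-coupled
#' Ti:Sapphire at 780 nm, 140 fs, 80 MHz through a 100x/1.3 NA objective;
#' its software "power transmission" percentage is non-linear in delivered
#' energy, so the measured (percent, nJ) pairs are kept as a lookup table,
#' and delivery is continuous raster scanning at 12.8 us per pixel. Both
#' use the measured objective transmission of 47%.
#'
#' @return A `laser_system` object.
#' @export
mira900 <- function() {
  laser_system(
    name = "Mira-900",
    wavelength_nm = 800, pulse_width_fs = 200, repetition_rate_MHz = 76,
    objective_na = 1.4, objective_transmission = 0.47,
    calibration = power_calibration(
      mode = "linear_throughput", setting_unit = "mW",
      throughput_coefficient = 5.33e-2 / 20
    ),
    exposure = list(mode = "macropulse", exposure_ms = 10, gap_ms = 100)
  )
}

#' @rdname mira900
#' @export
meta510 <- function() {
  laser_system(
    name = "LSM-510-Meta",
    wavelength_nm = 780, pulse_width_fs = 140, repetition_rate_MHz = 80,
    objective_na = 1.3, objective_transmission = 0.47,
    calibration = power_calibration(
      mode = "lookup", setting_unit = "percent",
      rows = data.frame(power_setting = c(15, 20, 25),
                        energy_nJ = c(1.91e-2, 2.49e-2, 3.10e-2))
    ),
    exposure = list(mode = "scanning", dwell_us = 12.8)
  )
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be positive and finite", name), call. = FALSE)
  }
  invisible(x)
}
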
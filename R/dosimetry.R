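#' Diffraction-limited focal spot diameter
#'
#' Airy-disc diameter `1.22 * lambda / NA` of a diffraction-limited focus.
#' For the built-in systems this gives about 697 nm (800 nm, NA 1.4) and
#' 732 nm (780 nm, NA 1.3).
#'
#' @param wavelength_nm wavelength in nm (> 0); vectorised.
#' @param objective_na numerical aperture (> 0); vectorised.
#' @return Spot diameter in nm.
#' @export
focal_spot_diameter <- function(wavelength_nm, objective_na) {
  check_positive(wavelength_nm, "wavelength_nm")
  check_positive(objective_na, "objective_na")
  1.22 * wavelength_nm / objective_na
}

#' In-situ energy per pulse at a power setting
#'
#' Maps an instrument power setting to the energy of a single pulse at the
#' focal spot, using the system's power calibration. Linear-throughput
#' systems scale the setting by the measured coefficient; lookup systems
#' return tabulated energies exactly and interpolate linearly between
#' tabulated settings. Settings outside the lookup range are an error —
#' the calibration is a measurement, not a model, so no extrapolation.
#'
#' @param system a [laser_system()].
#' @param power_setting numeric vector of settings in the calibration's
#'   `setting_unit`.
#' @return Energy per pulse in nJ.
#' @export
energy_per_pulse <- function(system, power_setting) {
  stopifnot(inherits(system, "laser_system"))
  if (!is.numeric(power_setting) || any(!is.finite(power_setting))) {
    stop("`power_setting` must be finite numeric", call. = FALSE)
  }
  cal <- system$calibration
  if (cal$mode == "linear_throughput") {
    if (any(power_setting < 0)) {
      stop("`power_setting` must be >= 0", call. = FALSE)
    }
    cal$throughput_coefficient * power_setting
  } else {
    rng <- range(cal$rows$power_setting)
    if (any(power_setting < rng[1] | power_setting > rng[2])) {
      stop(sprintf(
        "power setting outside calibrated range [%g, %g] %s; extrapolation is not supported",
        rng[1], rng[2], cal$setting_unit), call. = FALSE)
    }
    stats::approx(cal$rows$power_setting, cal$rows$energy_nJ,
                  xout = power_setting, method = "linear")$y
  }
}

#' Focal-spot peak irradiance
#'
#' Peak irradiance `(E / t_p) / area` of a pulse of energy `E` and duration
#' `t_p` over a uniform disc of the given diameter, in W/cm2. Computation
#' is in SI internally; arguments are in the field's customary units.
#'
#' @param energy_nJ energy per pulse in nJ (> 0); vectorised.
#' @param pulse_width_fs pulse duration in fs (> 0).
#' @param spot_diameter_nm focal spot diameter in nm (> 0).
#' @return Peak irradiance in W/cm2.
#' @export
peak_irradiance <- function(energy_nJ, pulse_width_fs, spot_diameter_nm) {
  check_positive(energy_nJ, "energy_nJ")
  check_positive(pulse_width_fs, "pulse_width_fs")
  check_positive(spot_diameter_nm, "spot_diameter_nm")
  energy_J <- energy_nJ * 1e-9
  width_s <- pulse_width_fs * 1e-15
  radius_m <- spot_diameter_nm * 1e-9 / 2
  area_m2 <- pi * radius_m^2
  (energy_J / width_s) / (area_m2 * 1e4) # m2 -> cm2
}

#' Dose table for a ladder of power settings
#'
#' Composes [focal_spot_diameter()], [energy_per_pulse()] and
#' [peak_irradiance()] into one row per requested setting, reproducing the
#' in-situ dose ladder of a microirradiation titration experiment.
#'
#' @param system a [laser_system()].
#' @param settings numeric vector of power settings (may be empty).
#' @return A tibble with columns `system`, `setting`, `setting_unit`,
#'   `spot_diameter_nm`, `energy_nJ`, `peak_irradiance_W_cm2`, one row per
#'   setting in the order given.
#' @examples
#' dose_table(mira900(), c(20, 60, 100, 155))
#' @export
dose_table <- function(system, settings) {
  stopifnot(inherits(system, "laser_system"))
  if (length(settings) == 0L) {
    return(tibble::tibble(
      system = character(), setting = numeric(), setting_unit = character(),
      spot_diameter_nm = numeric(), energy_nJ = numeric(),
      peak_irradiance_W_cm2 = numeric()
    ))
  }
  d <- focal_spot_diameter(system$wavelength_nm, system$objective_na)
  e <- energy_per_pulse(system, settings)
  irr <- peak_irradiance(e, system$pulse_width_fs, d)
  unit <- system$calibration$setting_unit
  tibble::tibble(
    system = system$name,
    setting = as.numeric(settings),
    setting_unit = unit,
    spot_diameter_nm = d,
    energy_nJ = e,
    peak_irradiance_W_cm2 = irr
  )
}
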
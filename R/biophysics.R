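#' Thermal and acoustic constants of the medium
#'
#' Defaults describe an interphase chromosome treated as a 1 um slab in
#' water: thermal diffusivity 1.4e-7 m2/s, speed of sound 2600 m/s.
#'
#' @param thermal_diffusivity m2/s (> 0).
#' @param speed_of_sound m/s (> 0).
#' @param slab_thickness_um characteristic thickness of the heated
#'   structure, in um (> 0).
#' @return A list of class `medium_constants`.
#' @export
medium_constants <- function(thermal_diffusivity = 1.4e-7,
                             speed_of_sound = 2600,
                             slab_thickness_um = 1) {
  check_positive_scalar(thermal_diffusivity, "thermal_diffusivity")
  check_positive_scalar(speed_of_sound, "speed_of_sound")
  check_positive_scalar(slab_thickness_um, "slab_thickness_um")
  structure(list(thermal_diffusivity = thermal_diffusivity,
                 speed_of_sound = speed_of_sound,
                 slab_thickness_um = slab_thickness_um),
            class = "medium_constants")
}

#' Peak-irradiance damage thresholds for fs NIR pulses
#'
#' Literature threshold irradiances for the damage mechanisms relevant to
#' femtosecond near-infrared microirradiation: multiphoton photochemistry
#' (0.26e12 W/cm2), thermoelastic stress confinement (5e12 W/cm2) and
#' optical breakdown / plasma formation in transparent media (6e12 W/cm2).
#' Low-density plasmas capable of chemical damage can already form at
#' about 5% of the plasma-formation threshold.
#'
#' @param photochemical,thermoelastic_confinement,plasma_formation
#'   thresholds in W/cm2, strictly increasing in this order.
#' @param low_density_plasma_energy_fraction fraction of the
#'   plasma-formation threshold above which low-density plasma effects are
#'   considered possible, in (0, 1).
#' @return A list of class `damage_thresholds`.
#' @export
damage_thresholds <- function(photochemical = 0.26e12,
                              thermoelastic_confinement = 5e12,
                              plasma_formation = 6e12,
                              low_density_plasma_energy_fraction = 0.05) {
  check_positive_scalar(photochemical, "photochemical")
  check_positive_scalar(thermoelastic_confinement, "thermoelastic_confinement")
  check_positive_scalar(plasma_formation, "plasma_formation")
  check_positive_scalar(low_density_plasma_energy_fraction,
                        "low_density_plasma_energy_fraction")
  if (!(photochemical < thermoelastic_confinement &&
        thermoelastic_confinement < plasma_formation)) {
    stop("thresholds must be ordered photochemical < thermoelastic_confinement",
         " < plasma_formation", call. = FALSE)
  }
  if (low_density_plasma_energy_fraction >= 1) {
    stop("`low_density_plasma_energy_fraction` must be in (0, 1)", call. = FALSE)
  }
  structure(list(
    photochemical = photochemical,
    thermoelastic_confinement = thermoelastic_confinement,
    plasma_formation = plasma_formation,
    low_density_plasma_energy_fraction = low_density_plasma_energy_fraction
  ), class = "damage_thresholds")
}

#' Thermal diffusion time of the focal volume
#'
#' `T_d = 0.124 * lambda^2 / (k * NA^2)`, the time for heat to diffuse out
#' of a diffraction-limited focal volume. When `T_d` exceeds the pulse
#' duration, heat cannot escape between absorption and the end of the
#' pulse and photothermal confinement occurs.
#'
#' @param wavelength_nm wavelength in nm (> 0); vectorised.
#' @param objective_na numerical aperture (> 0).
#' @param thermal_diffusivity m2/s (> 0); default water, 1.4e-7.
#' @return Diffusion time in ns.
#' @examples
#' thermal_diffusion_time(800, 1.4) # ~289 ns
#' thermal_diffusion_time(780, 1.3) # ~319 ns
#' @export
thermal_diffusion_time <- function(wavelength_nm, objective_na,
                                   thermal_diffusivity = 1.4e-7) {
  check_positive(wavelength_nm, "wavelength_nm")
  check_positive(objective_na, "objective_na")
  check_positive(thermal_diffusivity, "thermal_diffusivity")
  lambda_m <- wavelength_nm * 1e-9
  0.124 * lambda_m^2 / (thermal_diffusivity * objective_na^2) * 1e9
}

#' Is the focal volume photothermally confined?
#'
#' TRUE when the thermal diffusion time exceeds the laser pulse duration.
#'
#' @param thermal_diffusion_time_ns diffusion time in ns (> 0).
#' @param pulse_width_fs pulse duration in fs (> 0).
#' @return Logical.
#' @export
is_thermally_confined <- function(thermal_diffusion_time_ns, pulse_width_fs) {
  check_positive(thermal_diffusion_time_ns, "thermal_diffusion_time_ns")
  check_positive(pulse_width_fs, "pulse_width_fs")
  thermal_diffusion_time_ns * 1e-9 > pulse_width_fs * 1e-15
}

#' Fraction of macropulse heat retained after a cooling delay
#'
#' Treats the heated chromatin as a uniformly heated thin slab of thickness
#' `d` and evaluates `1 - exp(-d^2 / (4 k t))`, the fractional temperature
#' remaining at the slab centre a time `t` after heating stops. For the
#' default 1 um slab in water and a 100 ms inter-macropulse delay this is
#' about 1.78e-5 (0.0018%): essentially all heat dissipates between
#' macropulses.
#'
#' @param slab_thickness_um slab thickness in um (> 0).
#' @param thermal_diffusivity m2/s (> 0).
#' @param delay_ms cooling delay in ms (>= 0); a zero delay returns the
#'   limit value 1 with a warning.
#' @return Retained-heat fraction in (0, 1].
#' @export
heat_retained_fraction <- function(slab_thickness_um = 1,
                                   thermal_diffusivity = 1.4e-7,
                                   delay_ms) {
  check_positive(slab_thickness_um, "slab_thickness_um")
  check_positive(thermal_diffusivity, "thermal_diffusivity")
  if (!is.numeric(delay_ms) || any(!is.finite(delay_ms)) || any(delay_ms < 0)) {
    stop("`delay_ms` must be finite and >= 0", call. = FALSE)
  }
  out <- numeric(length(delay_ms))
  zero <- delay_ms == 0
  if (any(zero)) {
    warning("delay of 0 returns the limiting retained fraction of 1",
            call. = FALSE)
    out[zero] <- 1
  }
  d_m <- slab_thickness_um * 1e-6
  t_s <- delay_ms[!zero] * 1e-3
  out[!zero] <- 1 - exp(-d_m^2 / (4 * thermal_diffusivity * t_s))
  out
}

#' Stress relaxation factor
#'
#' `tau_m = t_p * c_s / d`: the laser pulse duration relative to the time
#' an acoustic wave needs to cross the heated structure. Values below 1
#' mean the pulse ends before stresses can propagate out, i.e.
#' thermoelastic stress confinement.
#'
#' @param pulse_width_fs pulse duration in fs (> 0).
#' @param speed_of_sound m/s (> 0); default 2600.
#' @param slab_thickness_um structure thickness in um (> 0); default 1.
#' @return Dimensionless stress relaxation factor.
#' @export
stress_relaxation_factor <- function(pulse_width_fs, speed_of_sound = 2600,
                                     slab_thickness_um = 1) {
  check_positive(pulse_width_fs, "pulse_width_fs")
  check_positive(speed_of_sound, "speed_of_sound")
  check_positive(slab_thickness_um, "slab_thickness_um")
  (pulse_width_fs * 1e-15) * speed_of_sound / (slab_thickness_um * 1e-6)
}

#' Classify a peak irradiance against damage-mechanism thresholds
#'
#' Compares an irradiance against the photochemical, thermoelastic-stress
#' and plasma-formation thresholds (inclusive `>=` at the boundary) and
#' flags whether low-density plasma formation is possible (irradiance at or
#' above the configured fraction of the plasma threshold). Raising the
#' irradiance never clears a flag.
#'
#' @param peak_irradiance_W_cm2 irradiance in W/cm2 (> 0); vectorised.
#' @param thresholds a [damage_thresholds()].
#' @return A tibble with columns `peak_irradiance_W_cm2`,
#'   `above_photochemical`, `above_stress_threshold`, `above_plasma`,
#'   `low_density_plasma_possible`.
#' @export
classify_regime <- function(peak_irradiance_W_cm2,
                            thresholds = damage_thresholds()) {
  check_positive(peak_irradiance_W_cm2, "peak_irradiance_W_cm2")
  stopifnot(inherits(thresholds, "damage_thresholds"))
  i <- peak_irradiance_W_cm2
  tibble::tibble(
    peak_irradiance_W_cm2 = i,
    above_photochemical = i >= thresholds$photochemical,
    above_stress_threshold = i >= thresholds$thermoelastic_confinement,
    above_plasma = i >= thresholds$plasma_formation,
    low_density_plasma_possible =
      i >= thresholds$low_density_plasma_energy_fraction * thresholds$plasma_formation
  )
}

#' Biophysical damage-regime report for a dose
#'
#' Composes the confinement calculus for one system and power setting:
#' thermal diffusion time and photothermal confinement, the retained-heat
#' fraction over the inter-macropulse gap (only meaningful for macropulse
#' delivery; `NA` for continuously scanning systems, which have no cooling
#' interval), the stress relaxation factor, and the threshold
#' classification of the in-situ peak irradiance.
#'
#' @param system a [laser_system()].
#' @param power_setting a single power setting within the calibration
#'   domain.
#' @param medium a [medium_constants()].
#' @param thresholds a [damage_thresholds()].
#' @return A one-row tibble with the dose columns of [dose_table()]
#'   followed by `thermal_diffusion_time_ns`, `thermally_confined`,
#'   `heat_retained_fraction`, `stress_relaxation_factor`,
#'   `stress_confined`, and the [classify_regime()] flags.
#' @examples
#' biophysics_report(mira900(), 100)
#' @export
biophysics_report <- function(system, power_setting,
                              medium = medium_constants(),
                              thresholds = damage_thresholds()) {
  stopifnot(inherits(system, "laser_system"),
            inherits(medium, "medium_constants"))
  dose <- dose_table(system, power_setting)
  td <- thermal_diffusion_time(system$wavelength_nm, system$objective_na,
                               medium$thermal_diffusivity)
  retained <- if (identical(system$exposure$mode, "macropulse")) {
    heat_retained_fraction(medium$slab_thickness_um,
                           medium$thermal_diffusivity,
                           system$exposure$gap_ms)
  } else {
    NA_real_
  }
  tau_m <- stress_relaxation_factor(system$pulse_width_fs,
                                    medium$speed_of_sound,
                                    medium$slab_thickness_um)
  flags <- classify_regime(dose$peak_irradiance_W_cm2, thresholds)
  dplyr::bind_cols(
    dose,
    tibble::tibble(
      thermal_diffusion_time_ns = td,
      thermally_confined = is_thermally_confined(td, system$pulse_width_fs),
      heat_retained_fraction = retained,
      stress_relaxation_factor = tau_m,
      stress_confined = tau_m < 1
    ),
    flags[setdiff(names(flags), "peak_irradiance_W_cm2")]
  )
}
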
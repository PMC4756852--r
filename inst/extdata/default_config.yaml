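# Default laserddr pipeline configuration: the two characterised
# femtosecond NIR microirradiation platforms and the package defaults.
systems:
  - name: Mira-900
    wavelength_nm: 800
    pulse_width_fs: 200
    repetition_rate_MHz: 76
    objective_na: 1.4
    objective_transmission: 0.47
    calibration:
      mode: linear_throughput
      setting_unit: mW
      throughput_coefficient: 0.002665   # nJ per mW of input power
    exposure:
      mode: macropulse
      exposure_ms: 10
      gap_ms: 100
  - name: LSM-510-Meta
    wavelength_nm: 780
    pulse_width_fs: 140
    repetition_rate_MHz: 80
    objective_na: 1.3
    objective_transmission: 0.47
    calibration:
      mode: lookup
      setting_unit: percent
      rows:                              # [power transmission %, nJ per pulse]
        - [15, 0.0191]
        - [20, 0.0249]
        - [25, 0.0310]
    exposure:
      mode: scanning
      dwell_us: 12.8

medium:
  thermal_diffusivity: 1.4e-07            # m^2/s, water
  speed_of_sound: 2600                   # m/s
  slab_thickness_um: 1                   # interphase chromosome slab

damage_thresholds:
  photochemical: 2.6e+11                  # W/cm^2
  thermoelastic_confinement: 5.0e+12
  plasma_formation: 6.0e+12
  low_density_plasma_energy_fraction: 0.05

quantify:
  detection_level: 0.1                   # normalised units
  k: 2                                   # consecutive frames
  window_53bp1_min: 15
  window_trf2_min: 6
  majority_rule: 0.5                     # strict >

simulate:
  n_cells: 8

seed: 1
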
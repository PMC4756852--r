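# shared fixtures built in code

# printed dose-ladder values for the two built-in systems (energies in nJ,
# peak irradiances in W/cm2, 3 significant figures)
mira_table <- data.frame(
  setting = c(20, 25, 60, 85, 95, 100, 125, 155),
  energy_nJ = c(5.33e-2, 6.67e-2, 1.6e-1, 2.27e-1, 2.53e-1, 2.67e-1,
                3.33e-1, 4.13e-1),
  irradiance = c(6.99e10, 8.74e10, 2.1e11, 2.97e11, 3.31e11, 3.49e11,
                 4.36e11, 5.41e11)
)
meta_table <- data.frame(
  setting = c(15, 20, 25),
  energy_nJ = c(1.91e-2, 2.49e-2, 3.10e-2),
  irradiance = c(3.24e10, 4.23e10, 5.27e10)
)

# tiny noiseless stack: constant background `base`, stripe at
# base * (1 + contrast[t]); geometry fixed and small for speed
tiny_params <- function(kinetics = kinetics_preset("53BP1_low"),
                        frame_times = seq(-1, 15, by = 0.5),
                        noise = list(poisson_scale = 0, gaussian_sd = 0),
                        seed = 1L, ...) {
  simulation_params(
    image_shape = c(32, 32),
    nucleus = list(center = c(16, 16), semi_axes = c(13, 13)),
    stripe = roi_rect(8, 14, 24, 18),
    frame_times = frame_times,
    kinetics = kinetics, noise = noise, seed = seed, ...
  )
}

# independent brute-force oracle for threshold_power: scan powers in
# ascending order, return the first whose recruited fraction strictly
# exceeds the rule
brute_force_threshold <- function(calls, majority_rule = 0.5) {
  for (p in sort(unique(calls$power))) {
    rec <- calls$recruited[calls$power == p]
    if (sum(rec) / length(rec) > majority_rule) return(p)
  }
  NA_real_
}
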
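#' Noiseless kinetic recruitment profile
#'
#' Evaluates the normalised stripe contrast over time for one of the two
#' phenomenological models used throughout the package (see
#' [fit_kinetics()] for the functional forms). The profile is identically
#' zero before the onset delay.
#'
#' @param times frame times in minutes post-irradiation.
#' @param model `"saturating_rise"` or `"transient_pulse"`.
#' @param amplitude contrast amplitude `A` (>= 0).
#' @param tau_on rise time constant in minutes (> 0).
#' @param tau_off decay time constant in minutes (transient pulse only;
#'   must exceed `tau_on`).
#' @param delay onset delay in minutes (>= 0).
#' @return Numeric vector of contrasts, one per time.
#' @export
kinetic_profile <- function(times, model = c("saturating_rise", "transient_pulse"),
                            amplitude, tau_on, tau_off = NULL, delay = 0) {
  model <- match.arg(model)
  stopifnot(is.numeric(times), amplitude >= 0, delay >= 0)
  if (amplitude == 0) return(rep(0, length(times)))
  check_positive(tau_on, "tau_on")
  ts <- times - delay
  y <- numeric(length(times))
  on <- ts > 0
  if (model == "saturating_rise") {
    y[on] <- amplitude * (1 - exp(-ts[on] / tau_on))
  } else {
    check_positive(tau_off, "tau_off")
    if (tau_off <= tau_on) stop("`tau_off` must exceed `tau_on`", call. = FALSE)
    y[on] <- amplitude * (exp(-ts[on] / tau_off) - exp(-ts[on] / tau_on))
  }
  y
}

#' Kinetics presets emulating the measured recruitment classes
#'
#' Three presets anchor the generator to the observed recruitment timing:
#'
#' * `"53BP1_low"` — slow sustained accrual at a low-dose site: onset
#'   delay 5 min, rise time 8 min, amplitude 0.8, so the 0.1-contrast
#'   detection level is crossed between 5 and 7 min post-irradiation and
#'   the signal keeps rising through the 15 min window.
#' * `"53BP1_weak"` — the weak variant seen right at the low threshold:
#'   amplitude 0.3, same timing.
#' * `"TRF2_high"` — fast transient accrual at a high-dose site: delay
#'   0.5 min, rise 0.15 min, decay 1.5 min, amplitude 1.2, peaking
#'   within the first minute and substantially decayed by 5 min.
#' * `"none"` — amplitude 0 (no recruitment).
#'
#' @param name preset name.
#' @return A list of kinetics parameters accepted by
#'   [simulation_params()].
#' @export
kinetics_preset <- function(name = c("53BP1_low", "53BP1_weak", "TRF2_high",
                                     "none")) {
  name <- match.arg(name)
  switch(name,
    "53BP1_low" = list(model = "saturating_rise", amplitude = 0.8,
                       tau_on = 8, tau_off = NULL, delay = 5),
    "53BP1_weak" = list(model = "saturating_rise", amplitude = 0.3,
                        tau_on = 8, tau_off = NULL, delay = 5),
    "TRF2_high" = list(model = "transient_pulse", amplitude = 1.2,
                       tau_on = 0.15, tau_off = 1.5, delay = 0.5),
    "none" = list(model = "saturating_rise", amplitude = 0,
                  tau_on = 1, tau_off = NULL, delay = 0)
  )
}

#' Parameters for one synthetic stripe-irradiation movie
#'
#' Describes a single-nucleus time-lapse: an elliptical nucleus on a dark
#' background, a rectangular irradiated stripe inside it whose contrast
#' follows a kinetic profile, shot (Poisson) and read (Gaussian) noise,
#' and optional global photobleaching.
#'
#' @param image_shape `c(height, width)` in pixels.
#' @param nucleus `list(center = c(row, col), semi_axes = c(a_row, a_col))`
#'   ellipse, 0-based pixel centre coordinates.
#' @param stripe an [roi_rect()] fully inside the nucleus.
#' @param frame_times strictly increasing times in minutes; negative
#'   times are pre-damage frames.
#' @param baseline_intensity mean nucleus intensity in counts.
#' @param background_intensity mean intensity outside the nucleus.
#' @param kinetics a [kinetics_preset()] result or a list with the same
#'   fields.
#' @param noise `list(poisson_scale =, gaussian_sd =)`; `poisson_scale`
#'   multiplies a Poisson draw of mean `intensity / poisson_scale` (0
#'   disables shot noise), `gaussian_sd` is the read-noise SD in counts.
#' @param bleach_rate global photobleaching rate per minute (>= 0);
#'   applied as `exp(-bleach_rate * (t - t[1]))` to the whole frame.
#' @param seed integer RNG seed for the stack.
#' @return A list of class `simulation_params`.
#' @export
simulation_params <- function(image_shape = c(64, 64),
                              nucleus = list(center = c(32, 32),
                                             semi_axes = c(26, 26)),
                              stripe = roi_rect(16, 28, 48, 36),
                              frame_times = seq(-1, 15, by = 0.5),
                              baseline_intensity = 1000,
                              background_intensity = 100,
                              kinetics = kinetics_preset("53BP1_low"),
                              noise = list(poisson_scale = 1, gaussian_sd = 5),
                              bleach_rate = 0,
                              seed = 1L) {
  stopifnot(length(image_shape) == 2L, all(image_shape > 0),
            all(diff(frame_times) > 0),
            baseline_intensity > 0, background_intensity >= 0,
            noise$poisson_scale >= 0, noise$gaussian_sd >= 0,
            bleach_rate >= 0, kinetics$amplitude >= 0)
  nm <- ellipse_mask(image_shape, nucleus$center, nucleus$semi_axes)
  sm <- roi_mask(stripe, image_shape)
  if (!all(nm[sm])) stop("stripe must lie entirely inside the nucleus",
                         call. = FALSE)
  structure(list(
    image_shape = image_shape, nucleus = nucleus, stripe = stripe,
    frame_times = frame_times, baseline_intensity = baseline_intensity,
    background_intensity = background_intensity, kinetics = kinetics,
    noise = noise, bleach_rate = bleach_rate, seed = as.integer(seed)
  ), class = "simulation_params")
}

ellipse_mask <- function(dim_hw, center, semi_axes) {
  rows <- matrix(seq_len(dim_hw[1]) - 1, dim_hw[1], dim_hw[2])
  cols <- matrix(seq_len(dim_hw[2]) - 1, dim_hw[1], dim_hw[2], byrow = TRUE)
  ((rows - center[1]) / semi_axes[1])^2 +
    ((cols - center[2]) / semi_axes[2])^2 <= 1
}

#' Render a synthetic stripe-irradiation stack
#'
#' Builds the noiseless scene for every frame (background outside the
#' nucleus, baseline inside, `baseline * (1 + contrast(t))` inside the
#' stripe, all multiplied by the bleaching factor), then applies Poisson
#' and Gaussian noise in that order from one seeded stream. Identical
#' parameters and seed give identical stacks.
#'
#' @param params a [simulation_params()].
#' @return A list with elements `stack` (H x W x T array of counts),
#'   `truth` (ground truth: the parameters, nucleus and stripe masks, and
#'   the per-frame noiseless contrast) and `times`.
#' @export
render_stack <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  hw <- params$image_shape
  nm <- ellipse_mask(hw, params$nucleus$center, params$nucleus$semi_axes)
  sm <- roi_mask(params$stripe, hw)
  k <- params$kinetics
  contrast <- kinetic_profile(params$frame_times, k$model, k$amplitude,
                              k$tau_on, k$tau_off, k$delay)
  times <- params$frame_times
  bleach <- exp(-params$bleach_rate * (times - times[1]))
  n_frames <- length(times)
  stack <- array(0, dim = c(hw[1], hw[2], n_frames))
  base_frame <- matrix(params$background_intensity, hw[1], hw[2])
  base_frame[nm] <- params$baseline_intensity
  local_seeded(params$seed, {
    for (i in seq_len(n_frames)) {
      f <- base_frame
      f[sm] <- params$baseline_intensity * (1 + contrast[i])
      f <- f * bleach[i]
      ps <- params$noise$poisson_scale
      if (ps > 0) {
        f[] <- ps * stats::rpois(length(f), f / ps)
      }
      if (params$noise$gaussian_sd > 0) {
        f <- f + stats::rnorm(length(f), 0, params$noise$gaussian_sd)
      }
      stack[, , i] <- pmax(f, 0)
    }
  })
  list(
    stack = stack,
    truth = list(params = params, nucleus_mask = nm, stripe_mask = sm,
                 contrast = contrast),
    times = times
  )
}

#' Default quantification ROI for a synthetic stack
#'
#' Damage ROI equal to the stripe; background ROI the nucleus minus a
#' two-pixel guard band around the stripe.
#'
#' @param params a [simulation_params()].
#' @return An [roi_spec()].
#' @export
default_roi <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  hw <- params$image_shape
  nm <- ellipse_mask(hw, params$nucleus$center, params$nucleus$semi_axes)
  s <- params$stripe
  guard <- roi_mask(roi_rect(max(0, s$x0 - 2), max(0, s$y0 - 2),
                             min(hw[2], s$x1 + 2), min(hw[1], s$y1 + 2)), hw)
  roi_spec(
    damage = roi_mask(s, hw),
    background = nm & !guard,
    pre_damage_frames = sum(params$frame_times < 0)
  )
}

#' Simulate a cohort of cells
#'
#' Generates `n_cells` independent seeded movies. `sampler` maps a cell
#' index to a [simulation_params()] object (cell-to-cell variability goes
#' there); each cell's seed is derived as `seed + cell`, so the whole
#' cohort is reproducible from one base seed.
#'
#' @param n_cells number of cells (>= 1).
#' @param sampler function of the cell index returning a
#'   [simulation_params()] (its `seed` field is overwritten with the
#'   derived per-cell seed).
#' @param seed integer base seed.
#' @return A tibble with columns `cell`, `stack` (list), `truth` (list).
#' @export
simulate_cohort <- function(n_cells, sampler, seed = 1L) {
  stopifnot(n_cells >= 1, is.function(sampler))
  purrr::map_dfr(seq_len(n_cells), function(i) {
    p <- sampler(i)
    stopifnot(inherits(p, "simulation_params"))
    p$seed <- as.integer(seed + i)
    r <- render_stack(p)
    tibble::tibble(cell = i, stack = list(r$stack), truth = list(r$truth))
  })
}
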
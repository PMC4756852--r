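#' Fit a kinetic model to a recruitment trace
#'
#' Least-squares fit of one of two phenomenological recruitment models to
#' the normalised trace, on frames at or after the (known, fixed) onset
#' delay:
#'
#' * `saturating_rise`: `b + A * (1 - exp(-(t - delay) / tau_on))` — slow,
#'   sustained accrual (53BP1-like).
#' * `transient_pulse`:
#'   `b + A * (exp(-(t - delay) / tau_off) - exp(-(t - delay) / tau_on))`
#'   with `tau_off > tau_on` — fast, transient accrual (TRF2-like). Its
#'   peak occurs at the closed-form time
#'   `delay + tau_on * tau_off * log(tau_off / tau_on) / (tau_off - tau_on)`.
#'
#' Initialisation is deterministic: baseline from the earliest frames,
#' amplitude from the signal range, time constants from the time to
#' half-maximum. Optimisation uses Levenberg-Marquardt
#' ([minpack.lm::nlsLM()]) with positivity bounds on the time constants.
#'
#' @param trace a trace tibble from [extract_trace()].
#' @param model `"saturating_rise"` or `"transient_pulse"`.
#' @param delay fixed onset delay in minutes (default 0); frames before
#'   it are excluded from the fit.
#' @return An object of class `kinetics_fit` with [tidy()], [glance()],
#'   [predict()] and [autoplot()] methods.
#' @export
fit_kinetics <- function(trace, model = c("saturating_rise", "transient_pulse"),
                         delay = 0) {
  model <- match.arg(model)
  stopifnot(is.data.frame(trace),
            all(c("time_min", "normalized") %in% names(trace)))
  dat <- trace[trace$time_min >= delay, c("time_min", "normalized")]
  if (nrow(dat) < 5L) {
    stop("need >= 5 frames at or after `delay` to fit", call. = FALSE)
  }
  dat$ts <- dat$time_min - delay
  y <- dat$normalized
  rng <- max(y) - min(y)
  a0 <- max(rng, 1e-6)
  # deterministic initialisation: baseline from the signal floor, amplitude
  # from the range, time scales from time-to-half-range / time-of-peak
  half <- min(y) + rng / 2
  t_half <- max(dat$ts[which(y >= half)[1]], diff(range(dat$ts)) / 20, 1e-3)
  t_peak <- max(dat$ts[which.max(y)], diff(range(dat$ts)) / 20, 1e-2)

  fit <- switch(model,
    saturating_rise = minpack.lm::nlsLM(
      normalized ~ b + A * (1 - exp(-ts / tau_on)),
      data = dat,
      start = list(b = y[1], A = a0, tau_on = t_half / log(2)),
      lower = c(b = -Inf, A = 0, tau_on = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    transient_pulse = minpack.lm::nlsLM(
      normalized ~ b + A * (exp(-ts / tau_off) - exp(-ts / tau_on)),
      data = dat,
      start = list(b = min(y), A = 2 * a0, tau_on = t_peak / 3,
                   tau_off = 3 * t_peak),
      lower = c(b = -Inf, A = 0, tau_on = 1e-6, tau_off = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
  )
  est <- as.list(stats::coef(fit))
  if (model == "transient_pulse" && est$tau_off < est$tau_on) {
    # the difference-of-exponentials is symmetric under
    # (tau_on, tau_off, A) -> (tau_off, tau_on, -A); canonicalise
    est[c("tau_on", "tau_off")] <- est[c("tau_off", "tau_on")]
    est$A <- -est$A
  }
  structure(list(
    model = model, delay = delay, estimates = est,
    rss = sum(stats::residuals(fit)^2), n = nrow(dat),
    converged = fit$convInfo$isConv %||% TRUE,
    fit = fit, data = dat
  ), class = "kinetics_fit")
}

#' Closed-form peak time of the transient-pulse model
#'
#' @param tau_on,tau_off rise and decay time constants (`tau_off > tau_on`).
#' @param delay onset delay in minutes.
#' @return Peak time in minutes post-irradiation.
#' @export
pulse_peak_time <- function(tau_on, tau_off, delay = 0) {
  check_positive(tau_on, "tau_on")
  check_positive(tau_off, "tau_off")
  delay + tau_on * tau_off * log(tau_off / tau_on) / (tau_off - tau_on)
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("<kinetics_fit> %s (delay %g min, %d frames)\n",
              x$model, x$delay, x$n))
  print(tidy(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a kinetics fit
#'
#' @param x a `kinetics_fit`.
#' @param ... unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @method tidy kinetics_fit
#' @export
tidy.kinetics_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimates),
                 estimate = unlist(x$estimates, use.names = FALSE))
}

#' One-row model summary of a kinetics fit
#'
#' @param x a `kinetics_fit`.
#' @param ... unused.
#' @return A tibble with columns `model`, `rss`, `n`, `converged` and,
#'   for the transient pulse, the closed-form `peak_min`.
#' @method glance kinetics_fit
#' @export
glance.kinetics_fit <- function(x, ...) {
  out <- tibble::tibble(model = x$model, rss = x$rss, n = x$n,
                        converged = x$converged)
  if (x$model == "transient_pulse") {
    out$peak_min <- pulse_peak_time(x$estimates$tau_on, x$estimates$tau_off,
                                    x$delay)
  }
  out
}

#' @export
predict.kinetics_fit <- function(object, times = NULL, ...) {
  times <- times %||% object$data$time_min
  ts <- pmax(times - object$delay, 0)
  e <- object$estimates
  y <- switch(object$model,
    saturating_rise = e$b + e$A * (1 - exp(-ts / e$tau_on)),
    transient_pulse = e$b + e$A * (exp(-ts / e$tau_off) - exp(-ts / e$tau_on))
  )
  y[times < object$delay] <- e$b
  y
}

#' Plot a kinetics fit over its trace
#'
#' @param object a `kinetics_fit`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot kinetics_fit
#' @export
autoplot.kinetics_fit <- function(object, ...) {
  dat <- tibble::tibble(time_min = object$data$time_min,
                        normalized = object$data$normalized)
  grid <- tibble::tibble(
    time_min = seq(min(dat$time_min), max(dat$time_min), length.out = 200)
  )
  grid$fitted <- predict(object, grid$time_min)
  ggplot2::ggplot(dat, ggplot2::aes(.data$time_min, .data$normalized)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(.data$time_min, .data$fitted),
                       colour = "firebrick") +
    ggplot2::labs(x = "time post-irradiation (min)",
                  y = "normalised damage-site signal",
                  title = sprintf("%s fit", object$model)) +
    ggplot2::theme_minimal()
}

#' Plot one or more recruitment traces
#'
#' @param traces a trace tibble (optionally with a `cell` column) from
#'   [extract_trace()] or a row-bound set of such tibbles.
#' @param window_min optional detection window to mark.
#' @param detection_level optional detection level to mark.
#' @return A ggplot.
#' @export
plot_traces <- function(traces, window_min = NULL, detection_level = NULL) {
  stopifnot(is.data.frame(traces))
  p <- ggplot2::ggplot(traces,
                       ggplot2::aes(.data$time_min, .data$normalized))
  if ("cell" %in% names(traces)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(group = .data$cell),
                                alpha = 0.5)
  } else {
    p <- p + ggplot2::geom_line()
  }
  if (!is.null(detection_level)) {
    p <- p + ggplot2::geom_hline(yintercept = detection_level,
                                 linetype = "dashed")
  }
  if (!is.null(window_min)) {
    p <- p + ggplot2::geom_vline(xintercept = window_min,
                                 linetype = "dotted")
  }
  p + ggplot2::labs(x = "time post-irradiation (min)",
                    y = "normalised damage-site signal") +
    ggplot2::theme_minimal()
}
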
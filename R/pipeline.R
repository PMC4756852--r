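#' End-to-end self-consistency experiment
#'
#' Simulates per-power cohorts of 53BP1-like and TRF2-like movies whose
#' responder status follows the configured dose bands, quantifies every
#' movie with the package's own trace extraction and recruitment calling,
#' and recovers the detection-threshold powers under the strict majority
#' rule. With the default presets the recovered thresholds equal the
#' configured band edges (25 mW for 53BP1, 85 mW for TRF2 on the
#' input-power ladder).
#'
#' Responder presets per band: 53BP1 movies use the weak-responder preset
#' at the low band edge, the full low-dose preset elsewhere in the low
#' band, and no recruitment in the sub-threshold and high bands (high-dose
#' damage suppresses early 53BP1); TRF2 movies respond only in the high
#' band, with the fast transient preset.
#'
#' @param config a [default_config()] or [load_config()] result.
#' @param powers settings to titrate (default the five characterised
#'   input powers 20, 25, 60, 85, 100 mW).
#' @param system which configured system the settings belong to.
#' @param n_cells cells per power per marker.
#' @param seed integer base seed.
#' @return A list with `calls` (per-cell tibble: marker, power, cell,
#'   recruited), `thresholds` (tibble: marker, recovered, expected,
#'   consistent), and `summary` (per power recruited fractions).
#' @export
end_to_end <- function(config = default_config(),
                       powers = c(20, 25, 60, 85, 100),
                       system = "Mira-900",
                       n_cells = config$simulate$n_cells,
                       seed = config$seed) {
  stopifnot(inherits(config, "pipeline_config"))
  sys <- config$systems[[system]]
  if (is.null(sys)) stop("unknown system: ", system, call. = FALSE)
  thr <- recruitment_thresholds(sys)
  q <- config$quantify

  marker_preset <- function(marker, band, power) {
    if (marker == "53BP1") {
      if (band == "low") {
        if (power == thr$p53bp1_low) kinetics_preset("53BP1_weak")
        else kinetics_preset("53BP1_low")
      } else kinetics_preset("none")
    } else {
      if (band == "high") kinetics_preset("TRF2_high") else kinetics_preset("none")
    }
  }
  frame_times <- list(
    "53BP1" = seq(-1, q$window_53bp1_min, by = 0.5),
    "TRF2" = seq(-0.5, q$window_trf2_min, by = 0.25)
  )
  windows <- c("53BP1" = q$window_53bp1_min, "TRF2" = q$window_trf2_min)

  grid <- tidyr::expand_grid(marker = c("53BP1", "TRF2"), power = powers)
  calls <- purrr::pmap_dfr(grid, function(marker, power) {
    band <- dose_band(sys, power, thr)
    preset <- marker_preset(marker, band, power)
    sampler <- function(i) {
      simulation_params(kinetics = preset,
                        frame_times = frame_times[[marker]])
    }
    cohort_seed <- seed + 1000 * match(marker, c("53BP1", "TRF2")) +
      10 * match(power, powers)
    cohort <- simulate_cohort(n_cells, sampler, seed = cohort_seed)
    cohort |>
      dplyr::mutate(
        call = purrr::map2(.data$stack, .data$truth, function(st, tr) {
          trace <- extract_trace(st, default_roi(tr$params),
                                 tr$params$frame_times)
          call_recruitment(trace, windows[[marker]],
                           q$detection_level, q$k)
        })
      ) |>
      tidyr::unnest("call") |>
      dplyr::transmute(marker = marker, power = power, cell = .data$cell,
                       recruited = .data$recruited,
                       onset_min = .data$onset_min)
  })

  thresholds <- calls |>
    dplyr::group_by(.data$marker) |>
    dplyr::group_modify(~ tibble::tibble(
      recovered = threshold_power(.x, q$majority_rule))) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      expected = dplyr::if_else(.data$marker == "53BP1",
                                thr$p53bp1_low, thr$trf2_low),
      consistent = .data$recovered == .data$expected
    )

  summary <- calls |>
    dplyr::group_by(.data$marker, .data$power) |>
    dplyr::summarise(n = dplyr::n(),
                     recruited_fraction = mean(.data$recruited),
                     .groups = "drop")

  list(calls = calls, thresholds = thresholds, summary = summary)
}

#' Run a pipeline command and write its artifacts
#'
#' A single programmatic entry point over the analysis stages. Commands:
#'
#' * `"dose-table"`: `args = list(system =, settings =)`; writes
#'   `dose_table.csv`.
#' * `"biophysics-report"`: `args = list(system =, setting =)`; writes
#'   `biophysics_report.csv`.
#' * `"predict"`: `args = list(system =, setting =, inhibitors =,
#'   knockdowns =, hoechst =)`; writes `prediction.json`.
#' * `"simulate"`: `args = list(preset =, n_cells =)`; writes
#'   `cell_###.tif` stacks, `ground_truth.json` and `frame_times.csv`.
#' * `"quantify"`: `args = list(stack =, roi =, times =, window_min =,
#'   model =)` with file paths; writes `trace.csv`, `call.csv` and
#'   `fit.csv`.
#' * `"end-to-end"`: runs [end_to_end()]; writes `calls.csv`,
#'   `thresholds.csv` and `summary.csv`.
#'
#' Every run writes `run_log.json` with the command, a configuration
#' hash and the seed, so identical config + seed reruns are byte
#' reproducible.
#'
#' @param config a `pipeline_config`.
#' @param command one of the subcommands above.
#' @param args named list of command arguments.
#' @param outdir output directory (created if needed).
#' @return Invisibly, a character vector of the files written.
#' @export
run_pipeline <- function(config = default_config(), command, args = list(),
                         outdir = ".") {
  stopifnot(inherits(config, "pipeline_config"))
  commands <- c("dose-table", "biophysics-report", "predict", "simulate",
                "quantify", "end-to-end")
  if (!command %in% commands) {
    stop("unknown command `", command, "`; available: ",
         paste(commands, collapse = ", "), call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(outdir, f)
  get_system <- function() {
    sys <- config$systems[[args$system %||% names(config$systems)[1]]]
    if (is.null(sys)) stop("unknown system: ", args$system, call. = FALSE)
    sys
  }
  written <- character()

  if (command == "dose-table") {
    tab <- dose_table(get_system(), args$settings)
    write_table_csv(tab, out("dose_table.csv"))
    written <- "dose_table.csv"
  } else if (command == "biophysics-report") {
    rep <- biophysics_report(get_system(), args$setting, config$medium,
                             config$damage_thresholds)
    write_table_csv(rep, out("biophysics_report.csv"))
    written <- "biophysics_report.csv"
  } else if (command == "predict") {
    sys <- get_system()
    cond <- treatment(inhibitors = args$inhibitors %||% character(),
                      knockdowns = args$knockdowns %||% character(),
                      hoechst = args$hoechst %||% FALSE)
    pred <- ddr_predict(sys, args$setting, cond)
    jsonlite::write_json(
      list(system = sys$name, setting = args$setting,
           band = attr(pred, "band"),
           endogenous_trf2_detectable = attr(pred, "endogenous_trf2_detectable"),
           markers = pred),
      out("prediction.json"), auto_unbox = TRUE, pretty = TRUE, na = "null")
    written <- "prediction.json"
  } else if (command == "simulate") {
    preset <- kinetics_preset(args$preset %||% "53BP1_low")
    n <- args$n_cells %||% config$simulate$n_cells
    sampler <- function(i) simulation_params(kinetics = preset)
    cohort <- simulate_cohort(n, sampler, seed = config$seed)
    truths <- list()
    for (i in seq_len(n)) {
      f <- sprintf("cell_%03d.tif", i)
      write_stack(cohort$stack[[i]], out(f))
      written <- c(written, f)
      tr <- cohort$truth[[i]]
      truths[[i]] <- list(cell = i, kinetics = tr$params$kinetics,
                          seed = tr$params$seed, contrast = tr$contrast)
    }
    jsonlite::write_json(truths, out("ground_truth.json"),
                         auto_unbox = TRUE, pretty = TRUE, na = "null")
    write_table_csv(
      data.frame(frame = seq_along(cohort$truth[[1]]$params$frame_times),
                 time_min = cohort$truth[[1]]$params$frame_times),
      out("frame_times.csv"))
    written <- c(written, "ground_truth.json", "frame_times.csv")
  } else if (command == "quantify") {
    stack <- read_stack(args$stack)
    roi <- read_roi(args$roi)
    times <- if (!is.null(args$times)) read_frame_times(args$times) else NULL
    trace <- extract_trace(stack, roi, times)
    write_table_csv(trace, out("trace.csv"))
    call <- call_recruitment(trace,
                             args$window_min %||% config$quantify$window_53bp1_min,
                             config$quantify$detection_level,
                             config$quantify$k)
    write_table_csv(call, out("call.csv"))
    written <- c("trace.csv", "call.csv")
    if (!is.null(args$model)) {
      fit <- fit_kinetics(trace, args$model, delay = args$delay %||% 0)
      write_table_csv(dplyr::bind_cols(glance(fit),
                                       tidyr::pivot_wider(tidy(fit),
                                                          names_from = "term",
                                                          values_from = "estimate")),
                      out("fit.csv"))
      written <- c(written, "fit.csv")
    }
  } else if (command == "end-to-end") {
    res <- end_to_end(config,
                      powers = args$powers %||% c(20, 25, 60, 85, 100),
                      system = args$system %||% names(config$systems)[1])
    write_table_csv(res$calls, out("calls.csv"))
    write_table_csv(res$thresholds, out("thresholds.csv"))
    write_table_csv(res$summary, out("summary.csv"))
    written <- c("calls.csv", "thresholds.csv", "summary.csv")
  }

  jsonlite::write_json(
    list(command = command, seed = config$seed,
         config_hash = rlang::hash(config),
         files = written),
    out("run_log.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(file.path(outdir, c(written, "run_log.json")))
}
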
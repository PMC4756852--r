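#' Measured recruitment thresholds for a system
#'
#' Operational dose bands for DDR factor recruitment, in instrument power
#' settings. For the input-power (mW) ladder: 53BP1 recruitment first
#' becomes detectable in a majority of cells at 25 mW (the low threshold)
#' and is lost again at 85 mW (the high threshold), which is also where
#' TRF2 recruitment first appears. For the percent-transmission scanner
#' the corresponding band edges are 15% and 25%. Bands are system-relative
#' operational definitions, not irradiance-equivalent across systems.
#'
#' @param system a [laser_system()]; the defaults are chosen by the
#'   calibration's setting unit (mW: 25/85; percent: 15/25).
#' @param p53bp1_low,p53bp1_high band edges for 53BP1 (low <= setting <
#'   high is the "low" band; >= high is "high").
#' @param trf2_low lowest setting at which TRF2 recruitment is detected in
#'   a majority of cells (equal to `p53bp1_high` in both measured systems).
#' @param window_53bp1_min,window_trf2_min detection windows in minutes
#'   post-irradiation (15 and 6).
#' @param majority_rule fraction of cells that must show recruitment for a
#'   power to count as above threshold; the rule is strict (`>`).
#' @return A list of class `recruitment_thresholds`.
#' @export
recruitment_thresholds <- function(system = mira900(),
                                   p53bp1_low = NULL, p53bp1_high = NULL,
                                   trf2_low = NULL,
                                   window_53bp1_min = 15,
                                   window_trf2_min = 6,
                                   majority_rule = 0.5) {
  unit <- system$calibration$setting_unit
  defaults <- if (unit == "mW") c(low = 25, high = 85) else c(low = 15, high = 25)
  p53bp1_low <- p53bp1_low %||% defaults[["low"]]
  p53bp1_high <- p53bp1_high %||% defaults[["high"]]
  trf2_low <- trf2_low %||% p53bp1_high
  if (!(p53bp1_low < p53bp1_high)) {
    stop("`p53bp1_low` must be < `p53bp1_high`", call. = FALSE)
  }
  if (trf2_low < p53bp1_low) {
    stop("`trf2_low` must be >= `p53bp1_low`", call. = FALSE)
  }
  if (majority_rule <= 0 || majority_rule >= 1) {
    stop("`majority_rule` must be in (0, 1)", call. = FALSE)
  }
  structure(list(
    setting_unit = unit,
    p53bp1_low = p53bp1_low, p53bp1_high = p53bp1_high, trf2_low = trf2_low,
    window_53bp1_min = window_53bp1_min, window_trf2_min = window_trf2_min,
    majority_rule = majority_rule
  ), class = "recruitment_thresholds")
}

#' Treatment condition for a prediction
#'
#' @param inhibitors character subset of `c("Pi", "Ai", "Di", "PARGi")`
#'   (PARP, ATM, DNA-PK and PARG inhibitors).
#' @param knockdowns character subset of
#'   `c("PARP1_siRNA", "TRF2_siRNA")`.
#' @param hoechst logical; Hoechst 33258 photosensitisation present.
#' @return A list of class `treatment_condition`.
#' @export
treatment <- function(inhibitors = character(), knockdowns = character(),
                      hoechst = FALSE) {
  ok_inh <- c("Pi", "Ai", "Di", "PARGi")
  ok_kd <- c("PARP1_siRNA", "TRF2_siRNA")
  if (!all(inhibitors %in% ok_inh)) {
    stop("unknown inhibitor token(s): ",
         paste(setdiff(inhibitors, ok_inh), collapse = ", "),
         " (allowed: ", paste(ok_inh, collapse = ", "), ")", call. = FALSE)
  }
  if (!all(knockdowns %in% ok_kd)) {
    stop("unknown knockdown token(s): ",
         paste(setdiff(knockdowns, ok_kd), collapse = ", "), call. = FALSE)
  }
  stopifnot(is.logical(hoechst), length(hoechst) == 1L)
  structure(list(inhibitors = unique(inhibitors),
                 knockdowns = unique(knockdowns), hoechst = hoechst),
            class = "treatment_condition")
}

# ordinal scale for abundance-type marker levels; pattern markers use
# their own label sets and are set, not shifted
.level_scale <- c("none", "weak", "robust", "enhanced")
.gH2AX_scale <- c("none", "local", "pan_nuclear")

shift_level <- function(level, by, scale = .level_scale) {
  i <- match(level, scale)
  if (is.na(i)) return(level) # labels outside the scale are left alone
  scale[max(1L, min(length(scale), i + by))]
}

ddr_markers <- c("53BP1_early", "53BP1_late", "TRF2", "PAR",
                 "gammaH2AX_pattern", "MDC1_at_site", "Ub", "CPD",
                 "base_damage_NTH1", "XPA", "pChk1_pattern", "pChk2_pattern")

baseline_prediction <- function(band) {
  lv <- switch(band,
    sub_threshold = list(
      "53BP1_early" = "none", "53BP1_late" = "none", TRF2 = "none",
      PAR = "none", gammaH2AX_pattern = "none", MDC1_at_site = "none",
      Ub = "none", CPD = "none", base_damage_NTH1 = "none", XPA = "none",
      pChk1_pattern = "none", pChk2_pattern = "none"),
    low = list(
      "53BP1_early" = "robust", "53BP1_late" = "robust", TRF2 = "none",
      PAR = "weak", gammaH2AX_pattern = "local", MDC1_at_site = "at_site",
      Ub = "robust", CPD = "none", base_damage_NTH1 = "none", XPA = "none",
      pChk1_pattern = "none", pChk2_pattern = "none"),
    high = list(
      "53BP1_early" = "none", "53BP1_late" = "weak", TRF2 = "robust",
      PAR = "robust", gammaH2AX_pattern = "pan_nuclear",
      MDC1_at_site = "dispersed", Ub = "weak", CPD = "robust",
      base_damage_NTH1 = "robust", XPA = "occasional",
      pChk1_pattern = "at_site", pChk2_pattern = "pan_nuclear"),
    stop("unknown band: ", band, call. = FALSE)
  )
  timing <- switch(band,
    low = list("53BP1_early" = "detectable 5-7 min p.i., sustained",
               "53BP1_late" = "peaks 3-4 h p.i., retained >24 h"),
    high = list(TRF2 = "within 1 min, transient <=5 min",
                "53BP1_late" = "delayed, >=4 h p.i."),
    list()
  )
  list(levels = lv, timing = timing)
}

#' Dose band of a power setting
#'
#' Assigns a setting to the operational recruitment bands: below the 53BP1
#' low threshold (`sub_threshold`), between the low and high thresholds
#' (`low`: efficient 53BP1 recruitment, simple strand breaks), or at and
#' above the high threshold (`high`: complex damage, TRF2/PARP response,
#' 53BP1 suppressed). Boundaries are inclusive on the upper band.
#'
#' @param system a [laser_system()].
#' @param power_setting numeric vector of settings within the calibration
#'   domain.
#' @param thresholds a [recruitment_thresholds()]; defaults to the
#'   system's measured thresholds.
#' @return Character vector: `"sub_threshold"`, `"low"` or `"high"`.
#' @export
dose_band <- function(system, power_setting,
                      thresholds = recruitment_thresholds(system)) {
  stopifnot(inherits(system, "laser_system"),
            inherits(thresholds, "recruitment_thresholds"))
  energy_per_pulse(system, power_setting) # domain check
  dplyr::case_when(
    power_setting >= thresholds$p53bp1_high ~ "high",
    power_setting >= thresholds$p53bp1_low ~ "low",
    TRUE ~ "sub_threshold"
  )
}

#' Predict DDR marker outcomes for a dose and treatment
#'
#' Deterministic rule-based predictor of the qualitative damage-site
#' outcome for each DDR marker, given the dose band and a treatment
#' condition. The baseline rule table encodes the two damage regimes: at
#' low dose 53BP1 is recruited efficiently while PARP activation is weak
#' and TRF2 absent; at high dose complex damage (crosslinks, base damage)
#' drives robust PARP activation and rapid transient TRF2 recruitment
#' while 53BP1 recruitment is suppressed, gamma-H2AX spreads pan-nuclear
#' and MDC1 is dispersed. Treatment modifiers encode the measured
#' epistasis:
#'
#' * `Pi` (PARP inhibitor): abolishes PAR and TRF2 recruitment; 53BP1
#'   early recruitment is upgraded one level (partial restoration at high
#'   dose, enhancement at low dose).
#' * `Ai` + `Di` together: reverts gamma-H2AX spreading and MDC1
#'   dispersion, suppresses pChk2, upgrades 53BP1 at high dose; TRF2 is
#'   unaffected. Singleton `Ai` or `Di` is left without effect — the
#'   measurements only characterise the combination, and at low dose the
#'   singletons had minimal effect; treating them as no-ops is an
#'   extrapolation.
#' * `Ai` + `Di` + `Pi`: near-complete restoration — 53BP1 early
#'   recruitment robust in both bands.
#' * `PARGi`: stabilises PAR (upgraded one level) and suppresses early
#'   53BP1 at low dose (downgraded one level).
#' * `PARP1_siRNA`: abolishes TRF2 recruitment; `TRF2_siRNA` changes no
#'   marker (PARP1 localisation is TRF2-independent).
#' * `hoechst`: photosensitisation upgrades the gamma-H2AX pattern one
#'   step and makes endogenous TRF2 detectable (recorded as the
#'   `endogenous_trf2_detectable` attribute).
#'
#' Modifiers are a function of the condition set, so the prediction does
#' not depend on any token order.
#'
#' @param system a [laser_system()].
#' @param power_setting a single setting within the calibration domain.
#' @param condition a [treatment()].
#' @param thresholds a [recruitment_thresholds()].
#' @return A tibble with columns `marker`, `level`, `timing` and
#'   attributes `band`, `condition`, `endogenous_trf2_detectable`.
#' @examples
#' ddr_predict(mira900(), 100, treatment(inhibitors = "Pi"))
#' @export
ddr_predict <- function(system, power_setting, condition = treatment(),
                        thresholds = recruitment_thresholds(system)) {
  stopifnot(inherits(condition, "treatment_condition"))
  band <- dose_band(system, power_setting, thresholds)
  base <- baseline_prediction(band)
  lv <- base$levels
  timing <- base$timing
  inh <- condition$inhibitors
  has <- function(x) x %in% inh

  if (has("Pi")) {
    lv$TRF2 <- "none"
    lv$PAR <- "none"
    timing$TRF2 <- "abolished by PARP inhibition"
    lv[["53BP1_early"]] <- shift_level(lv[["53BP1_early"]], +1L)
    timing[["53BP1_early"]] <- if (band == "low") {
      "PARP inhibition enhances the immediate early phase (~first 20 min)"
    } else if (band == "high") "partial restoration" else NULL
  }
  if (has("Ai") && has("Di")) {
    if (band == "high") {
      lv$gammaH2AX_pattern <- "local"
      lv$MDC1_at_site <- "at_site"
      lv$pChk2_pattern <- "none"
      lv[["53BP1_early"]] <- shift_level(lv[["53BP1_early"]], +1L)
    }
  }
  if (has("Ai") && has("Di") && has("Pi")) {
    lv[["53BP1_early"]] <- "robust"
  }
  if (has("PARGi")) {
    lv$PAR <- shift_level(lv$PAR, +1L)
    if (band == "low") {
      lv[["53BP1_early"]] <- shift_level(lv[["53BP1_early"]], -1L)
    }
  }
  if ("PARP1_siRNA" %in% condition$knockdowns) {
    lv$TRF2 <- "none"
    timing$TRF2 <- "abolished by PARP1 knockdown"
  }
  if (condition$hoechst) {
    lv$gammaH2AX_pattern <- shift_level(lv$gammaH2AX_pattern, +1L, .gH2AX_scale)
  }

  out <- tibble::tibble(
    marker = ddr_markers,
    level = unlist(lv[ddr_markers], use.names = FALSE),
    timing = purrr::map_chr(ddr_markers, ~ timing[[.x]] %||% NA_character_)
  )
  attr(out, "band") <- band
  attr(out, "condition") <- condition
  attr(out, "endogenous_trf2_detectable") <- condition$hoechst
  out
}

#' Trans-inhibition between co-irradiated sites in one nucleus
#'
#' When a high-dose site is present in the same nucleus, early 53BP1
#' recruitment at low-dose sites is inhibited in trans (via pan-nuclear
#' gamma-H2AX/MDC1 dispersion and PARP signalling). The inhibition is
#' relieved by PARP inhibition or by joint ATM+DNA-PK inhibition, each of
#' which is already reflected in the per-site predictions; in their
#' absence this adjustment downgrades `53BP1_early` to `"none"` at every
#' low-band site. No other marker is touched.
#'
#' @param site_predictions a non-empty list of [ddr_predict()] outputs for
#'   sites sharing one nucleus and one treatment condition.
#' @return The list with `53BP1_early` adjusted at low-band sites.
#' @export
trans_inhibition <- function(site_predictions) {
  if (!is.list(site_predictions) || length(site_predictions) == 0L ||
      !all(purrr::map_lgl(site_predictions, is.data.frame))) {
    stop("`site_predictions` must be a non-empty list of ddr_predict() results",
         call. = FALSE)
  }
  bands <- purrr::map_chr(site_predictions, ~ attr(.x, "band"))
  condition <- attr(site_predictions[[1]], "condition") %||% treatment()
  inh <- condition$inhibitors
  relieved <- ("Pi" %in% inh) || (all(c("Ai", "Di") %in% inh))
  if (any(bands == "high") && !relieved) {
    site_predictions <- purrr::map2(site_predictions, bands, function(p, b) {
      if (b == "low") {
        p$level[p$marker == "53BP1_early"] <- "none"
        p$timing[p$marker == "53BP1_early"] <- "inhibited in trans by high-dose site"
      }
      p
    })
  }
  site_predictions
}
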
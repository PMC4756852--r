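level_of <- function(pred, marker) pred$level[pred$marker == marker]

test_that("dose bands flip exactly at the measured thresholds", {
  sys <- mira900()
  expect_equal(dose_band(sys, 20), "sub_threshold")
  expect_equal(dose_band(sys, 25), "low")
  expect_equal(dose_band(sys, 60), "low")
  expect_equal(dose_band(sys, 84.999), "low")
  expect_equal(dose_band(sys, 85), "high")
  expect_equal(dose_band(sys, 100), "high")
  meta <- meta510()
  expect_equal(dose_band(meta, 15), "low")
  expect_equal(dose_band(meta, 24), "low")
  expect_equal(dose_band(meta, 25), "high")
  expect_error(dose_band(meta, 40), "range")
})

test_that("baseline predictions encode the two damage regimes", {
  low <- ddr_predict(mira900(), 60)
  expect_equal(level_of(low, "53BP1_early"), "robust")
  expect_equal(level_of(low, "TRF2"), "none")
  expect_equal(level_of(low, "PAR"), "weak")
  expect_equal(level_of(low, "gammaH2AX_pattern"), "local")
  expect_equal(level_of(low, "MDC1_at_site"), "at_site")
  expect_equal(level_of(low, "CPD"), "none")

  high <- ddr_predict(mira900(), 100)
  expect_equal(level_of(high, "53BP1_early"), "none")
  expect_equal(level_of(high, "TRF2"), "robust")
  expect_equal(level_of(high, "PAR"), "robust")
  expect_equal(level_of(high, "gammaH2AX_pattern"), "pan_nuclear")
  expect_equal(level_of(high, "MDC1_at_site"), "dispersed")
  expect_equal(level_of(high, "CPD"), "robust")
  expect_equal(level_of(high, "base_damage_NTH1"), "robust")
  expect_equal(level_of(high, "XPA"), "occasional")
  expect_equal(level_of(high, "pChk2_pattern"), "pan_nuclear")
  expect_match(high$timing[high$marker == "TRF2"], "within 1 min")

  sub <- ddr_predict(mira900(), 20)
  expect_true(all(sub$level == "none"))

  # within a band, the setting does not change the baseline
  expect_equal(ddr_predict(mira900(), 30)$level, ddr_predict(mira900(), 80)$level)
  expect_equal(ddr_predict(mira900(), 85)$level, ddr_predict(mira900(), 155)$level)
})

test_that("inhibitor modifiers reproduce the measured epistasis", {
  sys <- mira900()
  # PARP inhibition abolishes TRF2 recruitment and PAR at high dose
  pi_high <- ddr_predict(sys, 100, treatment(inhibitors = "Pi"))
  expect_equal(level_of(pi_high, "TRF2"), "none")
  expect_equal(level_of(pi_high, "PAR"), "none")
  expect_equal(level_of(pi_high, "53BP1_early"), "weak") # partial restore
  # triple inhibition restores 53BP1 in both bands
  triple <- treatment(inhibitors = c("Ai", "Di", "Pi"))
  expect_equal(level_of(ddr_predict(sys, 100, triple), "53BP1_early"), "robust")
  expect_equal(level_of(ddr_predict(sys, 60, triple), "53BP1_early"), "robust")
  expect_equal(level_of(ddr_predict(meta510(), 25, triple), "53BP1_early"),
               "robust")
  # PARG inhibition suppresses early 53BP1 at low dose, boosts PAR
  pargi <- ddr_predict(sys, 60, treatment(inhibitors = "PARGi"))
  expect_equal(level_of(pargi, "53BP1_early"), "weak")
  expect_equal(level_of(pargi, "PAR"), "robust")
  # Ai+Di reverts the spreading phenotypes at high dose, leaves TRF2
  aidi <- ddr_predict(sys, 100, treatment(inhibitors = c("Ai", "Di")))
  expect_equal(level_of(aidi, "gammaH2AX_pattern"), "local")
  expect_equal(level_of(aidi, "MDC1_at_site"), "at_site")
  expect_equal(level_of(aidi, "pChk2_pattern"), "none")
  expect_equal(level_of(aidi, "TRF2"), "robust")
  # Ai+Di has minimal effect at low dose
  expect_equal(ddr_predict(sys, 60, treatment(inhibitors = c("Ai", "Di")))$level,
               ddr_predict(sys, 60)$level)
  # PARP1 knockdown abolishes TRF2; TRF2 knockdown changes nothing
  expect_equal(level_of(ddr_predict(sys, 100,
                                    treatment(knockdowns = "PARP1_siRNA")),
                        "TRF2"), "none")
  expect_equal(ddr_predict(sys, 100, treatment(knockdowns = "TRF2_siRNA"))$level,
               ddr_predict(sys, 100)$level)
  # Hoechst photosensitisation upgrades gamma-H2AX and flags endogenous TRF2
  ho <- ddr_predict(sys, 60, treatment(hoechst = TRUE))
  expect_equal(level_of(ho, "gammaH2AX_pattern"), "pan_nuclear")
  expect_true(attr(ho, "endogenous_trf2_detectable"))
  expect_error(treatment(inhibitors = "XYZ"), "unknown inhibitor")
})

test_that("predictions are pure and modifier application is set-based", {
  sys <- mira900()
  subsets <- unlist(lapply(0:4, function(k)
    combn(c("Pi", "Ai", "Di", "PARGi"), k, simplify = FALSE)),
    recursive = FALSE)
  for (inh in subsets) {
    for (setting in c(60, 100)) {
      a <- ddr_predict(sys, setting, treatment(inhibitors = inh))
      b <- ddr_predict(sys, setting, treatment(inhibitors = rev(inh)))
      expect_identical(a$level, b$level)
      expect_identical(a$level,
                       ddr_predict(sys, setting,
                                   treatment(inhibitors = inh))$level)
      expect_equal(nrow(a), 12L)
      expect_false(any(duplicated(a$marker)))
    }
  }
})

test_that("trans-inhibition downgrades 53BP1 at low sites when a high site is present", {
  meta <- meta510()
  lone <- trans_inhibition(list(ddr_predict(meta, 15)))
  expect_equal(level_of(lone[[1]], "53BP1_early"), "robust")

  both <- trans_inhibition(list(ddr_predict(meta, 15), ddr_predict(meta, 25)))
  expect_equal(level_of(both[[1]], "53BP1_early"), "none")

  # joint ATM/DNA-PK/PARP inhibition restores both sites
  triple <- treatment(inhibitors = c("Ai", "Di", "Pi"))
  rescued <- trans_inhibition(list(ddr_predict(meta, 15, triple),
                                   ddr_predict(meta, 25, triple)))
  expect_equal(level_of(rescued[[1]], "53BP1_early"), "robust")
  expect_equal(level_of(rescued[[2]], "53BP1_early"), "robust")

  # non-53BP1 markers are never altered
  before <- list(ddr_predict(meta, 15), ddr_predict(meta, 25))
  after <- trans_inhibition(before)
  for (i in 1:2) {
    keep <- before[[i]]$marker != "53BP1_early"
    expect_identical(after[[i]]$level[keep], before[[i]]$level[keep])
  }
  expect_error(trans_inhibition(list()), "non-empty")
})
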
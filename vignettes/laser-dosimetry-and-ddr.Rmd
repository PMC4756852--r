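---
title: "Methods: fs NIR microirradiation dosimetry and DDR recruitment analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fs NIR microirradiation dosimetry and DDR recruitment analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laserddr)
```

`laserddr` treats a laser-microirradiation DDR experiment as four
connected computations: instrument settings to physical dose; dose to
candidate damage mechanisms; dose and treatment to expected qualitative
marker outcomes; and time-lapse stacks to quantified recruitment
kinetics. This vignette records the models behind each stage, the
parameters that matter, and the choices made where the design was
genuinely open.

## Dosimetry

The focal spot is modelled as a uniform disc of Airy diameter
`d = 1.22 λ / NA`. This is the standard diffraction-limited estimate;
for the two built-in systems (800 nm / NA 1.4 and 780 nm / NA 1.3) it
gives 697 nm and 732 nm. No beam-profile or aberration modelling is
attempted: the uniform-disc area `π (d/2)²` is what enters the
irradiance, so all irradiances are *peak* values in the sense of
energy averaged over the nominal spot.

Power calibrations come in two modes, because attenuators behave
differently:

* **Linear throughput** (Mira-900): a Glan–Thompson polarizer attenuates
  the beam smoothly, and the measured in-situ energies are proportional
  to the side-port input power to well within the 3-significant-figure
  rounding of the measurements. The coefficient (2.665 × 10⁻³ nJ/mW) is
  anchored at the 20 mW calibration point; all other measured rungs of
  the ladder agree within rounding, which is the evidence for linearity.
* **Lookup** (LSM-510-Meta): the software "power transmission"
  percentage is demonstrably non-linear in delivered energy
  (15% → 0.0191 nJ but 25% → 0.0310 nJ), so the measured
  (setting, energy) pairs are kept verbatim. Intermediate settings are
  linearly interpolated in energy; settings outside the measured range
  are refused rather than extrapolated, since the calibration is a
  measurement, not a model.

All internal computation is in SI; nJ, fs, nm, mW and W/cm² appear only
at the interface. Peak irradiance is `(E / t_p) / area`, and
`dose_table()` composes the three steps into one row per setting.

The objective transmission (47% at these wavelengths) is carried on the
system description as a constant from the three-objective measurement
method; the optics chain between the side port and the back aperture is
not modelled — it is folded into the measured calibration.

## Damage-regime biophysics

Three closed-form quantities, all with water-like medium defaults
(`thermal_diffusivity` 1.4 × 10⁻⁷ m²/s, `speed_of_sound` 2600 m/s,
`slab_thickness_um` 1 µm for an interphase chromosome):

* **Thermal diffusion time** `T_d = 0.124 λ²/(k NA²)` — about 289 ns
  and 319 ns for the two systems, more than ten orders of magnitude
  above the 200/140 fs pulse widths, so photothermal confinement holds
  for any plausible configuration of these instruments.
* **Retained-heat fraction** `1 − exp(−d²/(4kt))` for a uniformly
  heated thin slab after a cooling delay `t`. For the macropulse-gated
  system (10 ms exposures, 100 ms gaps) the 100 ms delay leaves
  ~1.8 × 10⁻⁵ of the temperature rise — macropulse-to-macropulse heat
  accumulation is negligible. The formula is implemented exactly in
  this printed form, deliberately: it is the form whose published
  numerical consequences the package reproduces, and substituting a
  different slab-cooling kernel would silently change them. The
  quantity is only reported for macropulse delivery; a continuously
  scanning system has no cooling interval for it to describe, and the
  report carries `NA` there.
* **Stress relaxation factor** `τ_m = t_p c_s / d` — of order 10⁻⁴ for
  both systems, so thermoelastic stress confinement also holds. Note a
  documented oddity: evaluating the formula gives 5.2 × 10⁻⁴ for the
  200 fs system and 3.64 × 10⁻⁴ for the 140 fs system; published
  discussion of these two instruments pairs the two numbers the other
  way around. The package follows the formula.

Threshold classification compares the peak irradiance against
literature constants (`photochemical` 0.26 × 10¹² W/cm²,
`thermoelastic_confinement` 5 × 10¹², `plasma_formation` 6 × 10¹²
W/cm², and `low_density_plasma_energy_fraction` 0.05 of the plasma
threshold). Comparisons are inclusive (`≥`): the sources only
characterise strictly-above and strictly-below cases, so the boundary
convention is free; inclusive was chosen so that classification is
monotone and a dose exactly at threshold is flagged. No plasma or
free-electron dynamics are simulated — thresholds are compared, never
derived.

## The recruitment rule table

Dose bands are operational and system-relative, expressed in the
instrument's own setting unit: on the mW ladder, `sub_threshold`
(< 25 mW), `low` (25–85 mW) and `high` (≥ 85 mW); on the percent
scanner, 15% and 25% play the corresponding roles. The dosimetry module
can express the bands in W/cm² for cross-system comparison, but the
bands themselves are not transferred by irradiance — the percent
scanner's "high" irradiance is below the mW ladder's "high" — mirroring
how the thresholds were measured.

Baseline outcomes per band and the treatment modifiers (PARP inhibitor,
ATM+DNA-PK inhibitors, the triple combination, PARG inhibitor, siRNA
knockdowns, Hoechst photosensitisation, and in-trans inhibition between
co-irradiated sites) are encoded as a pure function of the condition
*set*, so no token ordering can change a prediction. Qualitative levels
sit on a four-point ordinal scale `none < weak < robust < enhanced` on
which "upgrade/downgrade one level" is defined; pattern-type markers
(γH2AX local/pan-nuclear, MDC1 at-site/dispersed, pChk1/pChk2) carry
their own label sets and are set directly rather than shifted.
Two encodings are worth flagging:

* ATM or DNA-PK inhibition *alone* is encoded as no change. Only the
  combination was characterised (and at low dose the singletons had
  minimal effect); treating singletons as no-ops is the only
  "half-rule" consistent with every characterised case, and it is an
  extrapolation.
* Intermediate high-band settings are treated uniformly: the band model
  does not distinguish 85 from 155 on the mW ladder, although the
  underlying biology is only partially characterised between those
  rungs.

## Quantification

The normalisation is the ratio of the damage-site ROI mean to a
user-supplied nucleoplasmic background ROI mean, minus one. Mean (not
median) ROI intensity is used — the reference measurement does not
specify, and means keep the estimator linear so that the ratio exactly
cancels global multiplicative effects (gain, uniform photobleaching),
which is tested as an invariant. Background ROIs are user-supplied;
auto-segmentation is out of scope.

"Detectable" recruitment needs a concrete rule: the default is
normalised signal > 0.1 sustained for k = 2 consecutive frames within
the detection window (15 min for 53BP1-class factors, 6 min for
TRF2-class), all configurable. On well-separated synthetic cohorts the
recovered threshold power is insensitive to this choice, which is the
property that matters for the threshold definition: the threshold is
the lowest power with recruitment in strictly more than 50% of cells
(exactly half does not qualify).

Kinetic models are phenomenological, chosen to match the observed curve
shapes rather than any mechanistic claim: a saturating exponential
rise `b + A(1 − e^(−(t−delay)/τ_on))` for slow sustained accrual, and a
difference of exponentials
`b + A(e^(−(t−delay)/τ_off) − e^(−(t−delay)/τ_on))` for fast transient
accrual, whose peak time has the closed form
`delay + τ_on τ_off ln(τ_off/τ_on)/(τ_off − τ_on)` used as an internal
consistency check. The onset delay is a fixed, known offset (estimable
separately from the recruitment call), not a free parameter.
Initialisation is deterministic — baseline from the signal floor,
amplitude from the range, time constants from time-to-half-range or
time-of-peak — and optimisation is Levenberg–Marquardt with positivity
bounds on the time constants; there are no random restarts, so fits are
reproducible by construction. The difference-of-exponentials is
symmetric under exchanging the two time constants (with a sign flip of
the amplitude), so fits are canonicalised to `τ_off > τ_on`.

Group comparisons use a two-sided permutation test on the difference of
means (default 10⁴ relabellings, seeded, add-one p-value estimator): no
specific parametric test is implied by the data-generating process, and
the permutation test is exact under the null up to Monte-Carlo error.

## The synthetic generator

`render_stack()` draws an elliptical nucleus at a baseline intensity
(default 1000 counts) on a dark background (100 counts), a rectangular
irradiated stripe inside it whose contrast follows a kinetic preset,
optional global exponential photobleaching, then Poisson shot noise and
Gaussian read noise in that order from a single seeded stream — so a
uniform pixel's variance is `poisson_scale · mean + gaussian_sd²`,
which is verified against the empirical variance in the tests. Output
is 16-bit counts. Identical parameters and seed give bit-identical
stacks; cohort members derive their seeds from one base seed.

The presets anchor the generator to the observed recruitment timing:
the 53BP1-like preset (delay 5 min, τ_on 8 min, amplitude 0.8) crosses
the 0.1 detection contrast between 5 and 7 min and keeps rising through
the 15 min window; a weak variant (amplitude 0.3) represents cells at
the low threshold; the TRF2-like preset (delay 0.5 min, τ_on 0.15 min,
τ_off 1.5 min, amplitude 1.2) peaks within the first minute and has
decayed below detection by 5 min. Absolute amplitudes are chosen for
testability — no published intensity scale exists for them, and no
curve was digitised.

What the generator does **not** emulate: optics (no PSF, the stripe has
hard edges), cell motion and focus drift, 3-D acquisition,
multi-channel imaging, spatially varying background, and
biology-induced cell-to-cell kinetic correlation. Passing tests
therefore demonstrate that the quantification pipeline is correct on
its own model class and noise levels, not that it is robust to every
artefact of real microscopy.

Problem sizes used in the validation suite are deliberately modest —
32–64 px frames, 30–60 frame movies, cohorts of eight cells per power
(matching the scale of the characterised per-power cohorts), 50
replicates for parameter-recovery studies, movies of 30 min for
kinetic fits (the length of the reference time courses) — chosen so
the whole suite documents the method at desk scale.

## Configuration and reproducibility

`load_config()` merges a YAML file over the packaged defaults and
validates every field, naming the offending key on failure; an empty
file yields the full defaults, which reproduce the built-in systems
exactly. Every `run_pipeline()` invocation writes a run log with the
command, a configuration hash and the seed; numeric CSV output is
written at 6 significant digits with locale-independent formatting, so
identical config + seed reruns produce byte-identical artifacts.

## Known limitations

* The dose calculus assumes the calibration measurements transfer to
  the day of the experiment; drift in objective transmission or
  alignment is not modelled.
* Dose bands are step functions; real dose-response is graded, and
  behaviour near band edges (e.g. between 85 and 155 on the mW ladder)
  is summarised, not resolved.
* The rule table is qualitative and deterministic: cell-to-cell
  variability lives exclusively in the synthetic cohort sampler, not in
  the predictor.
* The kinetics models are two fixed shapes; multi-phasic recruitment
  (e.g. fast PAR-dependent plus slow chromatin-dependent phases
  superimposed) must be windowed or fit piecewise.
* Whether pChk2 participates in trans-inhibition is unresolved in the
  underlying measurements and is not modelled.
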
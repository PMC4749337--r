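---
title: "Modelling individual colorimetric observers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling individual colorimetric observers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indivobs)
```

## The model

Colour-normal observers differ substantially in their colour matching
functions (CMFs).  `indivobs` models an individual observer's cone
fundamentals by perturbing an age- and field-size-parameterised average
observer with eight physiological deviation parameters:

```
lms = f(a, v, d_lens, d_macula, d_L, d_M, d_S, s_L, s_M, s_S)
```

* `a` — age in years; drives the ocular-media (lens) density.
* `v` — field size in degrees; drives the macular pigment peak density and
  the photopigment peak densities (self-screening).
* `d_lens`, `d_macula` — percentage deviations of the lens and macular
  pigment densities from the average.
* `d_L`, `d_M`, `d_S` — percentage deviations of the photopigment peak
  optical densities.
* `s_L`, `s_M`, `s_S` — translations (nm) of the photopigment absorbance
  spectra along the wavelength axis.

The computation mirrors the standard physiological-observer recipe.  The
average ocular-media density is `docul1 * (1 + 0.02 (a - 32)) + docul2` up
to age 60 and `docul1 * (1.56 + 0.0667 (a - 60)) + docul2` above it (the two
branches agree exactly at 60); the individual density multiplies the whole
average by `(1 + d_lens/100)`.  The same linear relation is used below age
20 — a documented extrapolation, since the underlying fit was made for ages
20–60.  The macular peak density is `0.485 exp(-v / 6.132) (1 +
d_macula/100)` times the peak-normalised relative density spectrum.  Cone
absorptances are `1 - 10^(-D_max,j A_j(lambda - s_j))` with `D_max,L/M =
(0.38 + 0.54 exp(-v/1.333))(1 + d_j/100)` and `D_max,S = (0.30 + 0.45
exp(-v/1.333))(1 + d_S/100)`; the lambda-max shift is realised by
natural-spline evaluation of the absorbance table at `lambda - s_j`.
Quanta-based fundamentals multiply the absorptances by
`10^(-D_macula - D_ocul)`, are converted to energy by multiplying by
wavelength, and each function is finally normalised to unit peak.  With all
eight deviations at zero the output is exactly the average observer for
`(a, v)`:

```{r reduction}
cf <- cone_fundamentals(observer_spec(age = 32, field_size = 2))
round(apply(cf$lms, 2, max), 6)
```

## Basis tables are synthetic stand-ins

The five fixed reference tables the model consumes (the two ocular-media
components, the relative macular density, and the three low-density
photopigment absorbances) are tabulated reference data in the original
physiological-observer publication and the CVRL archive.  This package ships
*synthetic stand-ins* generated by `synthetic_basis_tables()`: the
absorbances use the Govardovskii A1 visual-pigment nomogram (alpha plus beta
band, peaks at 558, 530 and 421 nm), the ocular-media components are
exponential decays tuned to typical human ocular-media curves, and the
macular density is a three-Gaussian mixture peaking at 460 nm.  The standard
XYZ-type observer used for CIELAB evaluation is likewise synthetic: a fixed
trichromatic recombination of the baseline 10-degree fundamentals.  All
files carry a `_synthetic` suffix, and `load_basis_tables()` accepts a
directory of replacement CSVs, so users holding the archival tables can drop
them in and work with the reference data unchanged.

Consequences: every structural property of the model (reduction to the
average observer, deviation algebra, metamerism, dispersion predictions) is
exact, but absolute spectral values differ from the archival tabulation, so
quantities that depend on the precise curve shapes (e.g. predicted
population SDs) are internally consistent rather than numerically tied to
published validation tables.

## Parameter variability: pooling and the two-scalar fit

The standard deviations of the eight parameters are derived in two stages.

**Stage 1** pools per-study SDs from a literature survey (shipped as
`extdata/studies/study_sds.csv`): SDs are converted to variances, averaged
with equal weights, and the square root taken — `pool_sds()` is exactly
`sqrt(mean(sd^2))`.  For lens density, where age dominates, per-study SDs
are first computed inside ±5-year age windows (`lens_windowed_sds()`):
every integer age centre with at least two subjects contributes
`100 * sd / mean` of the windowed densities, and the study SD is the mean
over centres (sample SDs use the n−1 convention throughout).

```{r step1}
print(derive_step1())
```

**Stage 2** rescales the pooled SDs because stage-1 estimates accumulate
intra-observer and instrumental uncertainty on top of true inter-observer
variability.  Two scalars in [0, 1] are fitted: one multiplying the
prereceptoral SDs (lens, macula), one multiplying the photopigment SDs
(`apply_scalars()`).  The fit (`optimize_scalars()`) minimises the
city-block distance (Euclidean offered as an option) between per-match
target SDs and SDs predicted by a forward Monte Carlo simulation of the
five-match protocol at a 6.5-degree field.  The adopted stage-2 row
(18.7, 36.5, 9.0, 9.0, 7.4, 2.0, 1.5, 1.3) is available as
`sd_table("step2")` and is the package default.

Numerical choices in the fit, made here because the procedure leaves them
open:

* **Common random numbers.**  At finite Monte Carlo size the objective is
  otherwise stochastic and its argmin ill-defined.  The age draw and a
  fixed queue of standard normals per (observer, parameter) are frozen from
  the seed; rejection of deviations below −100% walks along the queue
  instead of redrawing, keeping the objective a deterministic function of
  the scalars.
* **Search strategy.**  A coarse grid over [0, 1]² followed by a
  Nelder–Mead polish (derivative-free; the objective is piecewise smooth).
* **Target SDs.**  One number per match: the mean of the a\* and b\* SDs,
  matching the use of a single per-match SD in the objective.

The measured matching data behind the published fit are unpublished, so
`synthetic_target()` stands in: it forward-simulates a finite cohort
(default 75 observers) and optionally adds intra-observer noise (default SD
1.4 CIELAB units, the reported average intra-observer match variability).
The test suite validates the fit by parameter recovery: a target generated
at planted scalars under the same seed policy is recovered to well within
±0.05.

## Monte Carlo populations

`sample_observers()` draws each deviation independently from a zero-mean
normal with the chosen SD — per-parameter normals with no covariance
structure.  Draws at or below −100% (physically impossible negative
densities) are rejected and redrawn, so the effective law is a left-truncated
normal; at the stage-2 SDs the bound sits at 2.7 standard deviations for the
macular parameter (truncating its SD by about 1.3%) and beyond 4 sigma for
all others.  The sampler-recovery test centres its chi-square band on the
truncated-normal SD for exactly this reason.  Ages come from an explicit
list (used verbatim when the requested size equals the list length,
resampled with replacement otherwise) or a uniform range.  One master seed
derives independent substreams for ages and each parameter, so extending the
model cannot reshuffle existing streams.

## Colour-match simulation

For a match with reference spectrum `S_ref` and maximum-energy primaries
`S_max` (stimulus grid 380–780 nm at 1 nm, 401 samples), the observer's
3×401 CMF matrix `C` gives primary intensities `R = (C S_max)^(-1) C S_ref`
— an exact, unconstrained 3×3 solve; negative intensities are legitimate
(out-of-gamut references) and retained.  The matched spectrum `S_max R` is
evaluated in CIELAB using the *standard* observer (not the matching
observer) so all observers' matches live in one colour space; tristimulus
values use the 683 lm/W factor, and the reference white is the reference
spectrum's own shape for neutral references or the equal-energy spectrum for
saturated ones, scaled so the reference stimulus has L\* = 50.

Grid handling: the model-native grid is 390–830 nm at 5 nm; fundamentals
and the standard observer are resampled to the 1 nm stimulus grid by natural
cubic splines with zero fill outside the model span (extrapolating steep
lens-filtered tails would be unsafe).  Because natural-spline interpolation
is linear in the ordinates, the 5 nm → 1 nm resampling is precomputed once
as a 401×89 matrix, which keeps 10^4-observer simulations in dense matrix
algebra (a five-match simulation of 2,000 observers runs in a fraction of a
second).

Rayleigh matches treat the anomaloscope primaries (defaults: red 700 nm,
green 550 nm, yellow 589 nm) as ideal monochromatic lights evaluated by
spline off the grid — exact and grid-independent — and solve the 2×2 system
in the L and M excitations; the result is reported as the red fraction
`w_R / (w_R + w_G)` in [0, 1], with an optional affine map to instrument
units (no published mapping to anomaloscope scale units is adopted here).

## Dispersion prediction and testing

`predict_population_sd()` emulates three kinds of variability measurement:
CMF dispersion in a primary-normalised rgb space (each observer's
fundamentals transformed so the rgb functions take unit values at 645.2,
526.3 and 444.4 nm, evaluated at 35 wavelengths equally spaced in
wavenumber over 392.2–714.3 nm), CIELAB a\*/b\* dispersion over a set of
matches, and Rayleigh red-fraction dispersion.  Each prediction averages a
configurable number of independent Monte Carlo repeats (default 100).
`variance_ratio_test()` (a thin wrapper over `stats::var.test`) provides the
two-tailed F test used to compare measured against simulated dispersions
variable by variable.

The packaged five-match stimuli (`generate_fixture_stimuli()`) are
themselves synthetic: Gaussian display-like primaries at 612, 543 and
452 nm, three broadband neutral references, a saturated cyan (dominant
wavelength near 490 nm) and a saturated orange.  They reproduce the
*structure* of the matching protocol, not its measured spectra; predicted
match SDs therefore exercise the machinery but are not comparable to
published CIELAB dispersion values, which depend on the actual instrument
spectra.

## Problem sizes and limitations

The shipped tests use 10,000 observers for sampler recovery, 2,000
observers per objective evaluation for scalar recovery, and 100 repeats
for Monte Carlo stability — sizes chosen so the full suite runs in well
under a minute of simulation time while leaving sampling error far below
the tested tolerances.  Known limitations: the basis tables and match
stimuli are synthetic stand-ins (above); qualitative covariates (genetics,
gender, ethnicity, smoking, diet, pupil entry) are not modelled — they are
not quantified well enough to parameterise; field sizes above 10 degrees
are rejected as outside the tabulated domain; and the deviation parameters
are sampled independently, so any real covariance between physiological
factors is not represented.
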
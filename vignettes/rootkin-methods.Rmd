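---
title: "Methods: kinematics, water relations and multi-omic calling in rootkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinematics, water relations and multi-omic calling in rootkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootkin)
```

`rootkin` implements the quantitative backbone of a root growth-zone
water-deficit study: kinematic analysis of the growing apex, the
water-relations arithmetic of osmotic adjustment, differential calling
for metabolite and transcript abundances, topology-aware pathway
enrichment, and a transcript–metabolite concordance classifier. This
vignette explains the models, their assumptions, the defaults, and the
numerical choices, in that order.

## The kinematic model

The growing root is treated as a one-dimensional material continuum in
steady state. Positions `x` are measured in mm from the root-cap
junction. A tissue element at `x` moves basally with displacement
velocity `v(x)` (mm h⁻¹); in the mature zone `v` plateaus at the overall
elongation rate `E`. The local relative elongation rate (REL, h⁻¹) is
`dv/dx`.

Three assumptions carry the whole analysis:

1. **Steady state.** The spatial pattern of growth does not change over
   the observation window, so a single profile characterises the organ.
2. **Flux constancy.** Cells move through the growth zone in files
   without division beyond the meristem, so the cell flux
   `F = v(x) / l(x)` is constant along a file, where `l(x)` is the
   cortical cell-length profile. This inverts to the velocity
   reconstruction `v(x) = F · l(x)` with `F = E / l_final`, the form
   used by `velocity_profile()`. The same constancy means `F` equals
   the meristematic cell-production rate.
3. **Circular cross-sections.** Root volume per unit length is taken
   equal to the cross-sectional area `A(x) = π d(x)² / 4` from the
   diameter profile (the study's volume-per-length data are not
   available separately).

Velocities are summarised by the four-parameter logistic

`v(x) = a2 + (a1 − a2) / (1 + (x / x0)^p)`

(`a1` tip velocity, `a2` plateau = `E`, `x0` midpoint, `p` steepness).
Its derivative is evaluated analytically by `rel_profile()`; the
goodness of fit `R` is reported as the Pearson correlation between
observed and fitted velocities (whether such reported `R` values are
Pearson r or the square root of R² is rarely stated in the field; the
two are numerically indistinguishable at the fit qualities involved,
R > 0.98).

Cross-sectional growth is the logarithmic derivative form
`radtan(x) = v(x) · d ln A / dx` (h⁻¹), the standard reading of the
radial-plus-tangential expansion rate. The relative volumetric
expansion rate is `relvol = rel + radtan`, and the volumetric expansion
rate is `volrate = relvol · A` (mm³ mm⁻¹ h⁻¹). Both identities are
asserted, not merely documented, every time `volumetric_profiles()`
builds a profile set. Because `relvol · A = d(vA)/dx`, the integral of
`volrate` over the growth zone telescopes to a boundary flux
difference, which the test suite verifies numerically.

### Numerical choices

* Profile algebra requires a shared grid; the package standard is
  0.1 mm spacing with linear resampling (`region_summaries()` uses it
  for its trapezoidal integrals and means). Parameter-recovery checks
  use the same density.
* `d ln A/dx` and the deposition derivative use central finite
  differences with one-sided end stencils; an optional smoothing spline
  (`smooth = TRUE`, `spar = 0.5`) is available because diameter data
  are noisy and a log-derivative amplifies that noise.
* `fit_logistic()` uses bounded Levenberg–Marquardt iteration
  (`minpack.lm::nlsLM`) started from the data shape (`a1 = min v`,
  `a2 = max v`, `x0` at the half-range crossing, `p = 4`) with a fixed
  five-step restart schedule perturbing `x0` and `p`; `a1 ≥ 0`,
  `x0, p > 0` are enforced as bounds, and a fit with `a2 ≤ a1` is
  rejected as degenerate.
* `growth_zone_extent()` defines cessation as the first position beyond
  the REL peak where the rate falls below 5% of its peak (linearly
  interpolated). A 5% floor rather than an absolute rate makes the
  definition scale-free across treatments.
* Beyond the mature plateau the reconstructed velocity is constant by
  construction, so logistic fits should use the pre-plateau points; the
  pipeline does. The fitted REL is analytic and can be evaluated past
  the measured grid when the cessation point lies outside it.

## Water relations and solute deposition

Turgor is `Ψ_P = Ψ_W − Ψ_S` (MPa). `osmotic_adjustment()` compares a
well-watered and a water-deficit tissue status and calls the adjustment
*complete* when turgor is maintained within a tolerance, default
0.05 MPa — a package choice reflecting typical psychrometric
repeatability; there is no field-standard cutoff.

`deposition_rate()` implements the steady-state continuity statement
that the net local rate of solute addition to the osmotic pool is the
spatial derivative of the solute flux, `D(x) = d(c·A·v)/dx`. It is a
framework for decomposing osmotic adjustment into solute-deposition
versus water-deposition contributions on model fields — the package
does not estimate deposition from measured concentrations.
Concentration units are treated as opaque but consistent. The discrete
fundamental theorem (midpoint-rule integral of the interior central
differences equals a flux difference exactly) is asserted on every
call.

## Differential omics

The metabolomics chain is order-locked: per-feature **minimum
imputation** of missing values, then **median scaling** (each feature
divided by its observed median, so the post-scaling median is 1), then
a **natural-log transform** for testing. Imputation precedes scaling
because scaling a feature whose missing cells will later receive its
minimum must not change that minimum's relative position; the order is
locked and any other order raises a warning, since it silently changes
q-values. Fold changes are WD/WW ratios of arithmetic means on the
scaled, imputed, pre-log data (a geometric-mean option exists).

Significance requires all three gates: Welch two-sample p < 0.05,
Benjamini–Hochberg q < 0.10 within each region, and a two-sided fold
change (≥ 1.5 or ≤ 1/1.5). The "two-way" label sometimes attached to
Welch's test in this context is read as the ordinary two-sample,
two-sided unequal-variance test. Note that the fold-change gate acts on
the *estimated* ratio: a feature whose true fold change sits exactly at
1.5 passes only about half the time at triplicate sample sizes, which
is why the power checks in the test suite use effects comfortably above
the gate (true FC ≥ 1.8) rather than at the boundary.

Transcript differential tables are consumed, not produced: upstream
normalisation and quantification are out of scope. `count_dats()`
counts features beyond the |log2FC| ≥ 2 and ≥ 1 tiers (nested by
construction); `tf_filter()` keeps features with a maximum mean count
≥ 5 in at least one region-by-treatment combination and |log2FC| ≥ 1.2
— two-sided by default, with `two_sided = FALSE` for the
increasing-only reading, since the direction convention is often left
implicit in published threshold statements.

## Pathway impact

Enrichment of a hit list within pathway member sets uses the upper-tail
hypergeometric probability, with BH adjustment across pathways. Impact
is topological: betweenness centrality of each member on the pathway
graph, normalised to sum to 1 per pathway, summed over the hit members.
Members absent from the edge list are isolated nodes and receive the
uniform floor weight `1/|members|` before normalisation; a graph where
no node lies between two others (a single edge, or an isolated single
node) falls back to uniform weights. A pathway is *dominant* when
−log10 p > 2, impact > 0.1 and FDR < 0.1 simultaneously; the raw
p < 0.01 screening gate used by some tools is the same order of
magnitude but not identical — both are available, the dominance gates
are the default.

## Concordance classification

For each significant metabolite, the mapped enzymatic steps (a TSV with
`metabolite`, `step`, `role`, `transcript`) are checked against the
transcript table at a configurable threshold (default |log2FC| ≥ 1, the
relaxed tier). For an accumulating metabolite, consistent evidence is a
synthesis step up, a degradation step down, or a competing
(flux-diverting) step down; mirrored for a depleting metabolite. Any
consistent passing transcript ⇒ `transcriptionally_coordinated`; no
passing transcript ⇒ `metabolic_control`; passing but all inconsistent
⇒ `discordant`; no map entry ⇒ `unmapped`. Encoding the
synthesis/degradation/competing orientation as data keeps pathway logic
(e.g. a competing shunt that diverts carbon away from an osmolyte) out
of the code.

## What the synthetic generators emulate

The packaged scenarios are calibrated to the study conditions:

* **WW**: elongation 3.08 cm day⁻¹ (1.2833 mm h⁻¹), mature cell length
  156.9 µm (so the cell flux is 8.18 cells h⁻¹), logistic truth
  `a1 = 0.05`, `a2 = 1.2833`, `x0 = 3.3006`, `p = 2.7469` — `x0` and
  `p` jointly solve a REL peak at 2.5 mm and 5%-of-peak cessation at
  10 mm; diameter taper 0.85 → 1.05 mm with a 2 mm decay length;
  cohorts of 9 plants with 1.0 cm Gaussian length SD.
* **WD**: elongation 3.13 cm day⁻¹, mature cell length 169.8 µm (flux
  7.68 cells h⁻¹), slightly wider taper 0.86 → 1.15 mm, and a
  volumetric-expansion peak 1.5 mm basal of the WW peak. A diameter
  difference alone can move that peak only ~0.2 mm, so the shift is
  realised by displacing the velocity midpoint; the offset is solved
  numerically at construction so the configured knob is the observable
  displacement itself. The cost is that the simulated WD growth zone is
  longer (~16 mm) than a maintained ~10 mm zone — the generator
  reproduces the volumetric geometry at the expense of growth-zone
  length fidelity, and downstream code must not assume the two
  treatments share an extent.
* **Metabolome**: three replicates per treatment-by-region cell,
  multiplicative lognormal noise with CV 0.10, true WD/WW fold changes
  from the packaged 21-metabolite effect table, missing cells
  missing-at-random (default rate 0; the demo uses 0.05). Lognormal
  noise and Gaussian length noise are choices, not estimates — the
  source designs report no replicate-level variances — chosen because
  abundances and lengths are strictly positive.
* **Transcriptome**: 45,764 features per region with multinomial tier
  assignment matching the configured expected counts at the
  |log2FC| ≥ 2 and ≥ 1 thresholds; magnitudes are drawn as 2 + an
  exponential tail (tier 2), uniform on [1, 2) (tier-1-only) and
  uniform inside (−1, 1) (background). Planted `anchors` rows with
  known fold changes support the concordance demonstration.

What the generators do **not** emulate: spatial correlation of
measurement errors along a profile, batch structure or
feature–feature correlation in the omics matrices, censored (limit of
detection) missingness, and any non-steady growth dynamics. Passing
tests therefore demonstrate that the algorithms are correct and
well-calibrated under the stated noise models, not that they are robust
to every pathology of real data.

## Problem sizes

The packaged analyses are sized for interactive use: cohorts of 9
(study scale) or 1000 (recovery checks) plants, profiles of ~120
points, triplicate metabolomes of 21 features × 3 regions, transcript
tables of 3 × 45,764 rows, and null calibrations of 1000 features. The
full test suite runs in seconds on one core.

## Known limitations

* The steady-state inversion cannot see time-dependent growth; marker
  tracking or repeated imaging is required for that.
* `R` from `fit_logistic()` is a correlation, not a residual-based
  uncertainty; use the embedded `nls` object for standard errors.
* The deposition framework requires smooth, co-registered `c`, `A`, `v`
  fields; it is a model-exploration tool, not an estimator with error
  propagation.
* Pathway impact depends entirely on the supplied graphs; with a small
  universe (the packaged 21-metabolite demo) the hypergeometric test is
  underpowered and dominance rarely triggers — realistic use needs a
  compound universe of hundreds.
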
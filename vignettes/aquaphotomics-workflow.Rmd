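---
title: "Methods: NIR aquaphotomics chemometrics for sprouting bean extracts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NIR aquaphotomics chemometrics for sprouting bean extracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sproutspec)
```

## The problem

Mung bean sprouting quality is conventionally tracked with destructive
laboratory measurements: oven-drying for water content, pH and
conductivity of a bean extract, and iodometric titration for ascorbic
acid. Near-infrared (NIR) spectroscopy of the bean sprout extract offers
a reagent-free alternative. This package implements the full chemometric
workflow for that setting: spectral pretreatment, classification of
germination time, quantitative prediction of water content and ascorbic
acid, and aquaphotomic analysis of the water spectral pattern — together
with the wet-lab calculators and univariate statistics needed to anchor
the models to reference chemistry.

Because the original instrument dataset is not publicly deposited, the
package carries a seeded synthetic generator that emulates the study
design, so that every stage of the pipeline is exercised end-to-end by
code alone.

## Spectral model and pretreatment

Spectra are absorbance rows on a shared 900–1700 nm grid (2 nm default).
The pretreatment chain is fixed as *truncate → Savitzky–Golay → SNV*:

* **Truncation** to 950–1630 nm for wide-window work, or 1300–1600 nm
  (the first O–H overtone) for all aquaphotomics-related analyses. Bounds
  are inclusive with a 1e-9 nm comparison tolerance.
* **Savitzky–Golay smoothing**, 15 points, second-order polynomial,
  derivative 0. Edge points are handled by least-squares fits on the
  truncated one-sided neighbourhood rather than reflection padding; this
  keeps the filter exact on polynomials of degree ≤ 2 at every point,
  which the test suite asserts directly. Non-uniform grids are treated as
  index-spaced (a documented caveat; derivatives scale by the median
  step).
* **SNV** (standard normal variate): each spectrum is centred and scaled
  by its sample (n−1) standard deviation — the divisor convention is
  stated because implementations differ. SNV removes per-spectrum offsets
  and multiplicative scatter, so all downstream results are invariant
  under per-row affine maps with positive scale.

The chain is deliberately not idempotent (SNV renormalises smoothed
rows); the provenance attribute on the output records exactly what was
applied.

## Classification: PCA-score LDA with replicate folds

PCA is computed by SVD on mean-centred absorbance, without column
autoscaling — SNV already row-normalises, and autoscaling would inflate
quiet spectral regions. Loadings carry the sign convention that each
loading's largest-magnitude element is positive.

LDA operates on the first 10 PC scores. Canonical axes come from the
eigen-decomposition of pooled-within⁻¹ × between scatter, scaled to unit
pooled within-class variance, so nearest-centroid assignment in root
space equals Mahalanobis LDA with equal priors. An ill-conditioned
pooled scatter receives a ridge of `1e-8 · trace/dim` with a warning;
nearest-centroid ties break to the lowest class label.

Validation mirrors the acquisition design: each of the three measurement
replicates is held out once (*replicate three-fold*). PCA and LDA are
refit inside every fold on calibration rows only. An alternative reading
of the source method — PCA computed once on all data, folds applied only
to LDA — would leak validation information into the loadings; the
non-leaky per-fold refit was chosen and the leakage guard is tested (a
null-response data set must not yield cross-validated R² above 0.1, and
copying a validation row into calibration must change its held-out
prediction).

## Regression: PLS1 with grouped CV and parsimonious LV choice

PLSR is univariate NIPALS with X-deflation; the regression vector
`W (PᵀW)⁻¹ q` is verified against the deflation path. Cross-validation
groups all spectra of one germination time into the same fold
(*leave-time-out*), with the 21 time points dealt round-robin into 6
folds after a seeded shuffle — this reconciles a 6-fold design with the
requirement that no time point straddles calibration and validation.

The source states that RMSECV guided the latent-variable count but gives
no rule. The package uses a parsimony rule: the smallest count whose
RMSECV is within 2 % of the global minimum. On the synthetic extract
data this selects 2 latent variables for water-content prediction, which
matches the reported "two variables". (That phrase could alternatively
mean two predictor wavelengths; both readings are runnable — restrict
the predictor matrix to two selected wavelengths to get the other — but
latent variables are the default interpretation.)

Important wavelengths are extracted from PC1/PC2 loading curves as local
extrema with |loading| ≥ 0.5 of the per-PC maximum, deduplicated within
10 nm keeping the larger magnitude. The 0.5/10 nm defaults were
calibrated once on the synthetic fixture and are configuration, not
fact. Note that SNV and band overlap shift apparent peak positions by up
to ~15 nm from the generating band centres; the tests therefore assert
that a majority of selected peaks fall near generator bands rather than
all of them.

## Aquagrams

The twelve water matrix coordinates (C1–C12) of the first O–H overtone
are shipped as a configurable table; the exact nm ranges the source
authors used are not printed, so the defaults follow the conventional
aquaphotomics coordinates and are flagged as configuration. The aquagram
standardizes absorbance at each display wavelength across *all* samples
of the analysed set (`z = (A − μ)/σ`, sample sd) and averages within
groups — the classical aquagram; no extra radial min–max scaling is
applied. Band values are read at the single nearest grid point to the
display wavelength, not averaged over the WAMAC range, matching the
single-nm peak language of published aquagram figures; display
wavelengths can be overridden (e.g. 1462/1477/1489/1513 nm) for plotting
parity.

## Wet-lab calculators

The titration chain implements the printed equations literally:
thiosulfate normality = V(iodate) × N(iodate) × 0.1; iodine normality =
V(thio) × N(thio) × 0.1; ascorbic mass (mg) = N × (V_sample − V_blank) ×
88.065, where 88.065 = 176.13/2 is the two-electron equivalent weight of
ascorbic acid against iodine. The 0.1 factor is the 1/(10 mL) titrated
aliquot hard-coded as printed; a general N₁V₁ = N₂V₂ helper
(`titrant_normality()`) covers other aliquots. Whether the final
equation's normality label denotes the thiosulfate or the iodine
solution is ambiguous in the source; the calculator takes a single
`titrant_normality` argument so either reading works. The mg → mg/100 g
conversion assumes the nominal 200 mL water : 100 g bean recipe and
ignores the bean's own water contribution to extract volume.

## Univariate statistics

One-way ANOVA is reconstructed from (mean, sd, n) summaries — the
primary entry point, because only summary tables are available — and is
algebraically identical to raw-data ANOVA (property-tested to 1e-10).
Duncan's multiple range test computes critical ranges from
studentized-range quantiles at the protection level
`α_p = 1 − (1 − α)^(p−1)` (via `stats::qtukey`) rather than embedded
lookup tables, so it works at any df and is directly testable. Letters
are assigned by the standard maximal non-significant-run sweep, with the
monotone "protection" closure that an enclosing non-significant span
shields its sub-pairs.

A known limitation inherited from the source tables: the published water
content letters imply all 21 adjacent time points differ, but at n = 3
several adjacent pairs (e.g. 64.50 ± 0.31 vs 64.76 ± 0.28) are not
separable by any standard range test from the printed summaries. Letter
recovery is therefore asserted only for the six-group ascorbic titration
column (a, b, b, c, d, e), which does reproduce exactly.

The Durbin–Watson statistic is exposed both on raw residual sequences
and on residuals of a least-squares straight-line trend fit, the screen
applied to the quality trends before plotting.

## What the synthetic generator emulates — and what it does not

The generator states a fixed world chosen once:

* design: 21 classes × 3 replicates × 5 scans (extract), 6 levels × 3 ×
  3 (ascorbic standards, 0–500 mg/L in 100 mg/L steps);
* water bands (centre nm, width nm, base amplitude AU, slope AU/h):
  shoulder (1380, 12, 0.25, −0.0004), free water (1412, 18, 0.60,
  −0.0012), solvation (1452, 14, 0.45, +0.0004), bound water (1512, 16,
  0.30, +0.0018) — encoding the free→bound shift with germination;
* analyte bands at 1414/1477/1503 nm (width 10 nm) with 2×10⁻⁴ AU per
  mg/L, a response magnitude that puts the 500 mg/L standard at ~0.1 AU,
  comfortably above the noise floor but far below the water bands, as in
  real extract spectra;
* ascorbic trajectory anchored to the reference titration means
  (interpolated over the 6 h grid, converted to mg/L by the ×5
  extract-recipe factor); water-content truth anchored to the reference
  means with per-replicate gravimetric noise at the printed sds;
* noise: 1 % multiplicative lognormal scatter, 0.005 AU baseline offset
  sd, 0.002 AU white noise — levels typical of a miniature DLP
  spectrometer after averaging;
* two fixed background bands (970, 1190 nm) give the spectra a realistic
  envelope below the first overtone; they carry no class information and
  sit outside every analysis window.

Band shapes are Gaussian in wavelength — adequate for overtone envelopes
at 2 nm resolution, but not a physical water model: no
temperature dependence, no band-shape asymmetry, no wavelength-dependent
pathlength or detector effects, and class information enters only
through linear amplitude drifts plus the analyte trajectory. A green
classification or regression test therefore establishes that the
*pipeline* behaves correctly on data with the stated structure; it
cannot certify performance on real instrument data, and the
replicate-level comparison of predicted versus titrated ascorbic acid
(R² ≈ 0.85 in the source) is out of reach without the raw data.

## Numerical choices and degenerate inputs

Wavelength window bounds are inclusive (tolerance 1e-9 nm). Constant
spectra are rejected by SNV with the offending sample named; zero
variance at an aquagram band raises a degenerate-band error naming the
wavelength; zero-variance responses are rejected in PLSR and R². SG
windows must be odd, wider than the polynomial order and no wider than
the spectrum. `max_lv` is silently capped at the rank available in the
smallest calibration fold (with a logged note). Unequal group sizes in
DMRT fall back to the harmonic mean n with a warning. All generators
accept a seed, restore the caller's RNG stream, and are byte-identical
under a fixed seed.

## Known limitations

* The replicate-granularity question (the source models used N = 90
  extract spectra although 315 scans were acquired; the reduction rule
  is unstated) is left to the caller: `aggregate_scans()` provides scan-
  and replicate-level means, and the default analyses run on all scans.
* No MSC, detrending, SIMPLS, kernel PLS, QDA, VIP selection, or
  extended (temperature-perturbation) aquagrams.
* The CLI consumes JSON run configurations rather than YAML (no YAML
  parser among the package's dependencies).
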
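---
title: "PSMA-PET tumor volumetry and outcome analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PSMA-PET tumor volumetry and outcome analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmavol)
```

## What the package computes

`psmavol` quantifies whole-body tumor burden on PSMA-PET in patients with
metastatic castration-resistant prostate cancer under radioligand therapy,
and analyses how changes in that burden between a pre-therapeutic
(baseline) and a first-restaging (interim) scan relate to overall
survival. The pipeline has four stages:

1. **Segmentation.** All foci with SUVmax above a liver-referenced
   threshold are detected, physiological uptake (liver, spleen, kidneys)
   is removed, and each remaining metastasis is delineated by the
   50%-of-local-SUVmax isocontour.
2. **Metrics.** Per lesion: volume (ml), SUVmax, SUVmean and the lesion
   quotient TLQ = volume / SUVmean. Per scan: PSMA-TV (summed volume),
   summed TLQ, and meanSUVmax (unweighted mean of lesion SUVmax, a proxy
   for average PSMA expression).
3. **Response.** Volumetric response is a PSMA-TV decline strictly
   greater than 30%; biochemical response a best-PSA decline strictly
   greater than 50%; low PSMA expression a baseline meanSUVmax of at
   most 14.3.
4. **Survival analysis.** Log-transformed uni- and multivariable Cox
   regression, Kaplan–Meier comparisons with median or
   maximally-selected-rank-statistic binarization, Martingale residual
   diagnostics, and Spearman/Wilcoxon comparisons of volumetric versus
   biochemical response.

Because clinical scans cannot ship with a package, every stage is
exercised against synthetic data: digital PET phantoms with known lesion
supports, and simulated cohorts with a known hazard structure.

## The segmentation model

The adaptive threshold is
$$ t \;=\; \frac{4.3}{\mathrm{SUVmean}_{liver}}\,
   \left(\mathrm{SUVmean}_{liver} + \mathrm{SUVsd}_{liver}\right), $$
so a noise-free liver yields exactly the reference constant 4.3 SUV and
the threshold grows with liver noise. Foci are the 26-connected
components of the *strict* supra-threshold set $\{v : \mathrm{SUV}(v) >
t\}$; each focus is then refined to the 26-connected component of
$\{v : \mathrm{SUV}(v) \ge 0.5 \cdot \mathrm{SUVmax}_{focus}\}$ that
contains the focus' hottest voxel. The refinement may grow beyond the
original focus.

Conventions that the method statement leaves open are fixed as follows
and are part of the package contract:

* **Connectivity** is 26-neighbour in 3-D at both stages — the standard
  choice for PET hot-spot labeling — so the test oracles are exact.
* **Boundary handling** is strict (`>`) at detection and inclusive
  (`≥`) at the 50% refinement.
* **Liver statistics** use the whole supplied liver mask and the
  population (divide-by-*n*) standard deviation. The reference-region
  definition is genuinely a configuration choice: the mask is an explicit
  input, `sphericalRoi()` places a spherical VOI of configurable radius
  instead, and the sample-sd convention is selectable.
* **Organ exclusion** removes a focus when more than half of its voxels
  (`overlapFrac = 0.5`) lie inside an organ mask, so metastases merely
  abutting an organ survive. Physician review is replaced by explicit
  lists: `excludeFoci` drops foci, `includeRegions` re-seeds lesions
  inside organ masks (the liver-metastasis path). A re-inserted seed
  anchors the 50% rule at the seed voxel's SUV, so seeds should be placed
  on the lesion's hottest voxel.
* **Deduplication**: refinements of distinct foci whose isocontours
  merge are collapsed (identical sets) or unioned (overlapping sets), so
  PSMA-TV never double-counts a voxel. Lesions are ordered by descending
  volume with a stable tie-break on the originating focus index.
* Volumes are voxel count × voxel volume (mm³) / 1000; SUV values are
  assumed decay- and weight-corrected upstream.

## The phantom generator

`generatePhantom()` builds: uniform background (default 0.8 SUV),
ellipsoidal organs with per-voxel Gaussian uptake (liver 5 ± 0.3, spleen
1.8 ± 0.2, kidneys 12 ± 1), spherical lesions at a uniform peak SUV,
then a separable Gaussian PSF of configurable FWHM and additive Gaussian
noise clipped at zero. Ground truth is the **pre-blur** lesion support
under voxel-center-in-sphere inclusion; coordinates are voxel-center,
0-based, world units via the spacing only (no oblique affine). The
default grid is 64 × 64 × 96 at 2 mm isotropic spacing with a 4 mm
(2-voxel) PSF and 0.05 SUV noise.

Defaults for lesion size (7–10 mm radius) and uptake (peak SUV 12–20)
are assumptions: no lesion-level size or uptake distributions are
printed for the clinical cohort, so values were chosen once to straddle
a typical PSMA-PET scan and are not revisited. Noise is additive
Gaussian rather than Poisson-scaled — the noise level is a free
parameter in SUV units, which keeps the generator simple and the tests
interpretable. The phantom deliberately omits scatter, attenuation,
reconstruction artifacts and anatomical texture; passing its tests shows
the *geometry and logic* of segmentation are right, not that the method
is robust to every property of real scanner data.

Expected accuracy: with no blur and no noise, uniform-intensity lesions
are recovered voxel-exactly. Under a 2-voxel PSF, the half-maximum
isocontour of a blurred uniform sphere sits close to the true boundary
as long as the diameter is large against the FWHM, so volumes of lesions
≥ 2 ml are recovered within 20%; smaller lesions lose peak signal to
partial-volume averaging and carry no accuracy guarantee.

## The cohort simulator

`simulateCohort()` draws, per patient:

* baseline PSMA-TV log-normal with median 138 ml and IQR 230 ml
  (`sdlog` ≈ 1.13 via the sinh relation between IQR/median and `sdlog`);
* an interim/baseline volume ratio: true responders from a truncated
  log-normal below 0.7 (median decline ≈ 55%), non-responders above 0.7;
* baseline meanSUVmax above 14.3 (high expression, log-normal around 25)
  or uniform on [6, 14.3] for the low-expression fraction (default
  6/33 ≈ 18%);
* overall survival exponential around a 15-month median with log-hazard
  `betaLogTv`·(log TV − log 138) + `betaResponse`·I(true responder),
  centred so the marginal median stays at 15 months (a constant shift of
  the linear predictor leaves every hazard ratio unchanged);
* uniform administrative censoring with the horizon solved numerically
  so the expected censoring fraction matches `censoringRate` (default
  0.4, matching a 60% event rate);
* a best-PSA ratio correlated with the volume ratio on the log scale
  (Gaussian-copula-style construction, Pearson 0.687 on logs, targeting
  a Spearman ρ near 0.67).

Default log-hazards are log(1.618) per unit log baseline TV and
log(0.378) for true response — the scale of the univariable estimates
the method is designed to detect.

**The confounding mechanism.** Low-expression patients are where volume
response and survival decouple: their observed decline is drawn
*independently* of their hazard. Half of them (default) show a spurious
"response" whose median apparent decline is 85% — dedifferentiating
tumors lose tracer uptake, so segmented volume collapses while disease
progresses. Low expression itself carries an extra log-hazard of log(3),
and spurious responders a further log(3) on top. The magnitudes were
fixed at design time so that spurious responders die within the
follow-up window rather than instantly (deaths that occur immediately
leave all risk sets and stop influencing a Cox fit) and act as
high-leverage points on the continuous log-ratio response model. The
qualitative consequence — the response HR is null-like in the full
cohort and clearly protective once low-expression patients are excluded
— is a structural property of this mechanism, reproduced across seeds,
not a number tuned to any particular replicate.

## Survival-analysis conventions

* Natural logarithms everywhere a covariate is log-transformed; Efron
  tie handling in `coxFit()` (the ecosystem default); complete-case per
  model with the used *n* reported.
* Response enters Cox models as the ratio baseline/interim, log
  transformed; the binary >30% flag is kept alongside for Kaplan–Meier
  displays.
* Kaplan–Meier medians are the earliest time at which the survival
  estimate drops to 0.5 or below; median splits send ties to the low
  group (a fixed convention so runs are reproducible); degenerate
  all-equal covariates raise an error rather than returning an arbitrary
  split.
* `logrankStatistic()` computes the two-sample log-rank z directly from
  risk sets with the hypergeometric variance. On tie-free data it equals
  the Cox partial-likelihood score test at β = 0 to numerical precision
  (with tied times the hypergeometric correction and the Cox score
  variance differ slightly; the package keeps the classical log-rank
  form).
* `maxstatCutoff()` searches midpoints between consecutive distinct
  covariate values whose groups both hold ≥ 10% of patients (default
  `minProp`), using the linear log-rank-scores statistic with
  conditional (permutation) standardization — the formulation of the
  maximally-selected-rank-statistics literature. The smallest cutoff
  wins ties. The adjusted p-value for the maximum, when requested, comes
  from a permutation of the scores (default 10 000 draws) rather than an
  analytic approximation; the point estimate is the primary output, as
  the cutoffs are used for visualization-style stratification.
* Martingale residuals are event − cumulative hazard (Nelson–Aalen under
  the null model, Breslow baseline times risk score under a fit); they
  sum to zero by construction, which the tests assert to 1e-8.
* Whether the expression median used to stratify the responder subgroup
  should come from that subgroup or the whole cohort is not determined
  by the method statement; the package uses the subgroup's own median
  (the default of `medianBinarize` applied to the subset) and exposes
  the choice through ordinary subsetting.

## Numerical and degenerate-input choices

Response boundaries are evaluated as `100·(b − i)/b > 30` (and the PSA
analogue at 50): algebraically identical to `100·(1 − i/b)` but exact in
floating point at the printed boundaries, so a decline of exactly 30% is
never a response and a meanSUVmax of exactly 14.3 is always low
expression. A vanished interim volume counts as response with an
undefined (missing) ratio; a zero baseline leaves response undefined;
scans with no lesions have PSMA-TV 0 and missing meanSUVmax.

## What the test suite runs

Unit and property tests run on small grids (≤ 32³ oracle-equivalence
volumes, 24³–64×64×96 phantoms) and moderate simulations chosen to keep
the default suite fast while leaving the estimators in their asymptotic
regime where that is what is being tested: 200 replicates at n = 500 for
hazard-ratio recovery and CI coverage, 100 replicates at n = 132 for the
low-expression contrast, 200 null replicates at n = 40 for the log-rank
type-I check, 100 fixtures for the maxstat oracle. `scripts/acceptance.R`
re-runs the same computations from scratch at comparable sizes.

## Known limitations

* The phantom is geometric; no scatter/attenuation/reconstruction
  physics, no respiratory motion, no heterogeneous lesion texture.
* Whether a refined isocontour may drop below the global threshold is
  not specified by the method statement; the package's rule (the
  component containing the focus peak, inclusive at half-max) is one
  defensible reading and is documented rather than hidden.
* The cohort simulator injects a binary true-response effect; fitting
  the continuous log-ratio therefore estimates a working coefficient,
  not the generative parameter, which is why parameter-recovery tests
  target the baseline-volume coefficient.
* Real-data mode expects SUV-calibrated NIfTI volumes and organ label
  masks produced upstream; the package does not segment organs from CT
  and does not register PET to CT.
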
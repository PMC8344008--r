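# psmavol

Whole-body tumor volumetry on PSMA-PET and its relation to overall
survival under ¹⁷⁷Lu-PSMA radioligand therapy.

Patients with metastatic castration-resistant prostate cancer (mCRPC)
receiving Lu-PSMA therapy are restaged with a PSMA-PET after two cycles.
An early drop in PSMA-PET-derived total tumor volume looks like
response — but tumors that *dedifferentiate* lose PSMA expression, so
their segmented volume can collapse while the disease progresses. This
package implements the quantification pipeline needed to study that
problem, end to end and fully testable without patient data:

* **Segmentation** of all metastases on an SUV-calibrated PET volume:
  liver-referenced adaptive threshold, 26-connected focus detection,
  automatic removal of physiological liver/spleen/kidney uptake (with
  explicit include/exclude review lists), and refinement of each focus
  by its 50%-of-local-SUVmax isocontour.
* **Metrics**: per-lesion volume, SUVmax, SUVmean, TLQ (volume/SUVmean);
  per-scan PSMA-TV (total tumor volume), summed TLQ, meanSUVmax.
* **Response classification**: volumetric (PSMA-TV decline > 30%),
  biochemical (best PSA decline > 50%), and PSMA-expression status
  (low expression: baseline meanSUVmax ≤ 14.3).
* **Survival analysis**: log-transformed uni-/multivariable Cox models,
  Kaplan–Meier with median and maximally-selected-rank-statistic
  binarization, log-rank tests, Martingale residuals, Spearman/Wilcoxon
  response comparisons — including the key contrast of the volumetric
  response model with and without low-expression patients.
* **Synthetic data**: digital PET phantoms with ground-truth lesion
  masks, and simulated cohorts whose hazard depends on log baseline
  tumor volume and true response, with a low-expression subgroup whose
  apparent volume decline is decoupled from survival.

The segmentation threshold is
`t = (4.3 / SUVmean_liver) × (SUVmean_liver + SUVsd_liver)`,
and a lesion's final extent is the 26-connected component of
`{SUV ≥ 0.5 · SUVmax_focus}` containing the focus peak.

## Worked example

Segment a synthetic whole-body phantom (three spherical metastases over
liver/spleen/kidney uptake, 4 mm PSF, noise) and aggregate the scan:

```r
library(psmavol)

ph  <- generatePhantom(defaultPhantomSpec(seed = 7))
seg <- segmentScan(ph@volume, ph@organMasks)
seg$referenceStats
#> ReferenceStats: liver SUVmean 4.711, SUVsd 0.5387 -> threshold 4.792
lesionTable(seg$lesions, scanId = "demo")
#>   scan_id timepoint lesion_id n_voxels suv_max suv_mean volume_ml tlq_lesion
#> 1    demo  baseline         1      485   20.14   16.581     3.880     0.2340
#> 2    demo  baseline         2      251   15.09   11.629     2.008     0.1727
#> 3    demo  baseline         3      171   12.00    9.042     1.368     0.1513
aggregateScan(seg$lesions, scanId = "demo")
#> ScanMetrics 'demo' (baseline): 3 lesions, PSMA-TV 7.256 ml,
#>   TLQ 0.55796, meanSUVmax 15.74
```

The liver noise pushes the threshold above the 4.3 reference constant;
the three recovered volumes sit within a few percent of the 4.12, 2.06
and 1.43 ml ground truth (`ph@truthTable`), the residual error being
partial-volume blur. Simulate a 33-patient cohort and run the analysis
plan:

```r
co  <- simulateCohort(cohortSimSpec(seed = 42))
rep <- runOutcomeAnalysis(co)
rep
#> Outcome analysis on 33 patients ( 8 low expression )
#>
#> Volumetric-response hazard ratios (log baseline/interim ratio):
#>             cohort    hr ci_lower ci_upper       p
#>               full 0.605   0.3032    1.208 0.15452
#>  no_low_expression 0.148   0.0351    0.622 0.00909
#>
#> Spearman rho (TV vs PSA decline): 0.656
```

This is the package's central contrast: in the full simulated cohort the
volume-response hazard ratio is not significant, because low-expression
patients contribute deep but spurious volume declines together with poor
survival; excluding them unmasks a clearly protective response effect.
`rep$coxTable` holds every fitted model, `rep$km` the Kaplan–Meier
comparisons, and `runOutcomeAnalysis(co, outDir = "report")` writes CSV
tables, `report.json` and KM plots.

An end-to-end run (simulate → segment → metrics → response → analysis,
with a manifest) is one call:

```r
runPipeline(pipelineConfig(cohortSim = cohortSimSpec(seed = 1),
                           outDir = "out"))
```

or from a shell via the thin CLI wrapper
`Rscript inst/cli/psmavol.R run --seed 1 --out-dir out` (subcommands:
`simulate`, `segment`, `metrics`, `analyze`, `run`).

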
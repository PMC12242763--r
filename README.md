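# lastrain

Regional 3D left atrial strain, fibrosis quantification, and a classifier
harness for testing whether regional mechanics predict regional fibrosis.

## The problem

In atrial cardiomyopathy the left atrium (LA) dilates, loses contractile
function and fibroses. Fibrosis is imaged with late gadolinium enhancement
(LGE) MRI and scored regionally; atrial mechanics are measured as 3D
surface strain from tracked anatomy. Whether *regional* strain is a usable
surrogate for *regional* fibrosis — as opposed to global measures of
remodelling such as chamber volume (LAV) and emptying fraction (LAEF) —
is the question this package operationalizes: it provides every stage of
the analysis as tested, reusable R functions, plus a fully seeded
synthetic cohort generator so the complete pipeline can be exercised and
validated without patient data.

## What it computes

On a labelled triangulated LA surface (body, four pulmonary veins, left
atrial appendage, mitral rim):

* **Harmonic surface coordinates** `alpha` (lateral→septal) and `beta`
  (posterior→anterior) from a cotangent-Laplacian Dirichlet solve, and the
  six-region parcellation — left/right PV antra (all body vertices within
  10 mm geodesic of the PV junction rings), posterior, septal, anterior
  and lateral walls.
* **Fibrosis**: the image intensity ratio IIR = intensity / blood-pool
  mean; a surface region's enhancement is the percent area of triangles
  whose mean vertex IIR exceeds 1.2, staged 1 (<10%), 2 (10–20%),
  3 (20–30%), 4 (>30%, *severe*).
* **Strain**: per-element area strain
  `100·(A_e(t) − A_e(0))/A_e(0)` with the LVED frame as reference;
  regional curves as ratio-of-sums; reservoir strain RS = max − min of the
  curve; peak strain rate; fibre strain (engineering stretch of an
  atlas-mapped fibre direction).
* **Volumes**: divergence-theorem LAV(t) with the appendage and veins
  excluded and openings capped, and
  `LAEF = 100·(LAV_max − LAV_min)/LAV_max`.
* **Classification**: subject-grouped stratified 5-fold cross-validation
  (random forest by default) of severe regional fibrosis from regional
  features (region, RS, strain rate, strain-curve principal components,
  healthy-cohort Z-scores `z = (x − μ_healthy)/σ_healthy`) and global
  features (global RS, LAV, LAEF); block-permutation p-values; external
  cohort evaluation; single/pair/triple feature sweeps.

## Worked example

Generate a small synthetic AF cohort, run the measurement pipeline, and
ask whether regional strain or global anatomy classifies severe regional
fibrosis:

```r
library(lastrain)

spec <- cohort_spec(12, "AF", seed = 7, mesh_subdiv = 3)
ch <- generate_cohort(spec)
ch
#> <la_cohort> AF, n = 12 subjects (72 region rows)
#>   pooled RS 20.1 +/- 13 %; severe regions 62.5%

an <- analyze_cohort(ch)          # strain curves, volumes, fibrosis maps
ft <- build_feature_table(an)     # one row per (subject, region)

crossval_classify(ft, c("region", "lav", "laef"), "rf", k = 4, seed = 2)
#> <cv_report> [region + lav + laef] rf, 4-fold
#>   accuracy 75.0 +/- 10.6 %, AUC 0.849 +/- 0.095

crossval_classify(ft, "rs", "rf", k = 4, seed = 2)
#> <cv_report> [rs] rf, 4-fold
#>   accuracy 63.9 +/- 7.2 %, AUC 0.568 +/- 0.074

round(regional_prevalence(ft), 1)
#>      LPVA      RPVA posterior    septal  anterior   lateral
#>      33.3      58.3      66.7      66.7      58.3      91.7
```

The pattern to read: the model combining region with the global measures
(LAV + LAEF) discriminates severe fibrosis well (AUC ≈ 0.85), regional
reservoir strain alone is near chance (AUC ≈ 0.57), and severe fibrosis
concentrates in the lateral and posterior walls — the statistical
structure the generator encodes as ground truth.

The pooled reservoir strain (20.1 ± 13% here) tracks the AF preset
(19.5 ± 15.7%); the healthy preset is 48.0 ± 33.2%. Per-region burden
means in the AF preset are lateral 44.4, posterior 40.9, septal 32.7,
anterior 31.4, LPVA 26.0 (%).

A batch interface with YAML configuration is included
(`inst/cli/lastrain-pipeline.R generate/analyze/report`); stage outputs
are plain VTK/NIfTI/CSV/JSON files so any stage can be run on
user-supplied data in those formats. See the methods vignette
(`vignettes/lastrain-methods.Rmd`) for the models, calibration procedures
and their assumptions.

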
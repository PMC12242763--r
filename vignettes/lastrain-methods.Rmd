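---
title: "Regional left atrial strain and fibrosis: models and methods"
author: "lastrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional left atrial strain and fibrosis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lastrain)
```

## Scope

`lastrain` implements a surface-mesh pipeline for studying whether regional
left atrial (LA) mechanics predict regional fibrosis. Its stages are:

1. **Geometry and parameterization** — a labelled triangulated LA surface
   (body, four pulmonary-vein (PV) stubs, appendage (LAA), mitral rim), two
   harmonic surface coordinates, a six-region parcellation (left/right PV
   antra, posterior, septal, anterior, lateral walls), geodesic antral
   delimitation, and divergence-theorem chamber volumes.
2. **Fibrosis quantification** — image-intensity-ratio (IIR) thresholding
   of a late-gadolinium-enhancement-like (LGE) intensity field at 1.2 times
   the blood-pool mean, percent-area staging (1: <10%, 2: 10--20%,
   3: 20--30%, 4: >30% = severe).
3. **Strain kinematics** — per-element area strain relative to the
   ventricular end-diastolic (LVED) frame, regional/global reservoir
   strain (RS, the curve amplitude), peak strain rate, fibre strain, LA
   volume (LAV) and emptying fraction (LAEF), plus a simplified surface
   tracker for uncorresponded frame sequences.
4. **Classification harness** — subject-grouped, stratified 5-fold
   cross-validated classifiers of severe regional fibrosis over regional
   and global feature sets, with block-permutation significance and
   external-cohort evaluation.
5. **Synthetic cohort generator** — fully seeded anatomies, cyclic motion,
   and intensity fields with a known statistical link between severe
   fibrosis and LAV/LAEF/region, so every downstream stage is testable
   end to end without patient data.

## Harmonic surface coordinates and parcellation

Two discrete-harmonic fields are solved on the full surface with a
cotangent-weight Laplacian and Dirichlet data on landmark vertex sets:
`alpha` (0 on a lateral anchor patch, 1 on a septal patch) and `beta`
(0 posterior, 1 anterior). Edges whose cotangent weight is negative (poor
triangles) fall back to a uniform graph weight of 1, which preserves the
discrete maximum principle; exact-zero weights (right angles) are kept, and
on a flat sheet the solution reproduces the linear coordinate to machine
precision. The solve is a sparse Cholesky via `Matrix`.

The PV antra are all body vertices whose edge-graph geodesic distance
(Dijkstra with Euclidean edge lengths, via `igraph`) to the corresponding
PV--LA junction ring is *strictly less* than `antra_radius` (default
10 mm); the junction ring itself belongs to the antrum. The remaining body
is split on coordinate thirds: `beta < 1/3` posterior, `beta > 2/3`
anterior, otherwise `alpha < 1/3` lateral and `alpha > 2/3` septal, with
the central roof band resolved at `beta >= 0.5` into anterior versus
posterior. These thresholds are configuration, not inference: they are
chosen to reproduce the qualitative six-region layout, and the package
exposes them (`alpha_thresholds`, `beta_thresholds`) because no printed
standard exists. Whether antral distance should be geodesic or Euclidean
is equally open; geodesic is the default because it is insensitive to PV
stub folding.

A triangle belongs to the majority region of its vertices. Regional
quantities are therefore area-weighted over whole triangles, and a
conservation identity holds exactly: the whole-surface enhancement equals
the area-weighted mean of the regional values.

## Volumes

`enclosed_volume()` removes every triangle touching an excluded label
(LAA and the four PVs by default), caps each boundary loop (mitral rim and
the exclusion holes) with a flat fan at the loop centroid, verifies that
the capped surface is closed and consistently oriented, and evaluates the
divergence-theorem volume. LAEF is `100 * (LAV_max - LAV_min) / LAV_max`
over the frame sequence. On an icosphere the volume converges to the
closed form well within 0.5% at subdivision 4.

## Strain

Area strain of element *e* at frame *t* is
`100 * (A_e(t) - A_e(0)) / A_e(0)`, with frame 0 the LVED (minimum volume)
configuration, so all curves start at zero. The regional curve is the
strain of the *summed* regional area (ratio of sums), which is robust to
small-element noise; the per-element mean variant is available through
`method = "mean_of_elements"`. Reservoir strain is the curve amplitude
`max - min`; the peak strain rate is the maximum absolute
central-difference derivative, periodic across the cycle ends by default
(a `periodic = FALSE` switch uses one-sided ends, under which a pure ramp
returns exactly its slope). Curves from different frame counts are aligned
by periodic linear resampling onto a common 30-frame grid, preserving the
phase-0 value exactly.

Fibre strain is the engineering stretch (`lambda - 1`, not
Green--Lagrange) of a unit tangent fibre under the in-plane deformation
gradient built from the triangle edge vectors; the choice is recorded here
because both conventions appear in practice and the difference is
first-order at atrial strain magnitudes. Atlas fibre fields are
transferred between meshes by matching `(alpha, beta)` triangle
barycentres and re-expressing the fibre in each triangle's local frame
aligned to the in-plane gradient of `alpha`, which makes the transfer
exactly equivariant under rigid motions.

## The simplified surface tracker

The image-registration motion tracking used with real cine data is out of
scope; `track_surfaces()` is a deliberately simple stand-in for tracking
smooth chamber deformations: iterative closest-point correspondence to
each target surface, with the displacement increment smoothed over the
vertex 1-ring (`regularization = 0.4`, 5 passes) and the result propagated
frame to frame. Its acceptance surface is strain recovery on synthetic
truth -- on moderate-amplitude synthetic motion with shuffled, jittered
target vertices it recovers regional RS within 10% relative -- not
registration fidelity on images.

## Fibrosis quantification

IIR is the per-vertex intensity divided by the blood-pool mean; vertices
project from images by taking the maximum trilinear sample along the
outward normal over ±3 mm (bright-rim capture; the depth is
configurable). A triangle is enhanced when the mean of its three vertex
IIRs exceeds the threshold (default rule; a fractional per-vertex
area-share rule is available), and regional enhancement is the enhanced
area fraction. Stages use half-open intervals `[0,10) [10,20) [20,30)`,
and severe fibrosis requires *strictly* more than 30% — exactly 30.0 is
stage 3. The boundary conventions are not derivable from any printed
source; they are fixed here and tested exactly.

## The synthetic cohort generator

The generator encodes, as ground truth, the hypothesis structure the
classifier harness is meant to detect: severe regional fibrosis driven by
chamber size (LAV), function (LAEF) and region, with regional strain
*decoupled* unless the `strain_fibrosis_coupling` knob is turned on.

**Anatomy.** An ellipsoidal body (semi-axes 27/23/33 mm with ±5% subject
jitter) built from a subdivision-4 icosphere, with an open mitral orifice,
four extruded PV stubs and an LAA stub at fixed anatomical directions,
junction rings and anchor patches recorded as landmarks, and the whole
shape rescaled so the body volume matches the subject's target minimum
volume exactly.

**Strain targets.** Per-(subject, region) reservoir strains are drawn as
`cohort mean + region offset + subject effect + residual`, floor-censored
at 1%. The censoring shift is solved analytically so the *pooled* mean
matches the cohort preset (healthy 48.0%, AF 19.5%, DCM 35%). Region
offsets fix the septal wall highest and the PV antra lowest; their values
are chosen so that the cross-region covariance between the strain and
fibrosis-burden patterns is negligible, which the decoupling contract
requires.

**Motion.** Each vertex moves radially about the body centroid with a
region-specific amplitude following a biphasic reservoir/conduit/booster
shape (raised-cosine rise to the reservoir peak at 45% of the cycle,
conduit plateau at 35%, booster return to zero). Amplitudes are calibrated
by a fixed point on the measured regional area ratios at the cycle peak.
Two practical details matter. First, amplitudes are clamped to expansion
(scale ≥ 1): narrow regions squeezed between much stronger neighbours
would otherwise be driven below baseline, at which point the *amplitude*
measures the negative excursion and the fixed point runs away. Second,
because vertex-based amplitudes mix across region boundaries, a region at
the floor bordered by strong neighbours can stay above its target even at
the clamp; a final global amplitude factor therefore restores each
subject's mean reservoir strain, keeping the pooled cohort mean calibrated
(to within ~1 percentage point at test scale) at the cost of a bounded
per-region residual in extreme-contrast draws.

**Emptying fraction is emergent.** For a closed surface the peak volume is
bounded by the volume of the sphere with the peak area
(`LAEF <= 100 * (1 - (1 + RS/100)^(-3/2))` for uniform strain), so once
the strain level is set LAEF is not a free dial: clinically typical
LAEF values cannot coexist with clinically typical area-strain levels
under any surface-only deformation. The generator accepts this: LAEF is
measured from the generated motion (healthy ≈ 34 ± 11%, AF ≈ 19 ± 7%,
DCM ≈ 27 ± 9%), preserving the clinical *ordering* across cohorts, and
all downstream use is through standardized values, so only ordering and
dispersion matter. An axial-squash alternative that targets LAEF directly
was tried and rejected: with radial growth and axial compression sharing
the cycle shape, the chamber volume peaks mid-cycle and the squash barely
moves the cycle maximum.

**Fibrosis.** Severe status per region is Bernoulli with log-odds
`intercept_r + 2.0 * z(LAV) - 0.5 * z(LAEF)` (defaults; plus the optional
strain coupling). LAV enters as the *drawn* anatomical size, which is
independent of strain by construction; LAEF is the emergent value, whose
correlation with subject strain is why its coefficient is kept small --
together these hold the pooled correlation between regional RS and
enhancement within ±0.1 of zero while region and LAV carry the
discrimination. Intercepts are solved exactly from the target marginal
prevalences (lateral 0.851, posterior 0.66, septal 0.60,
anterior/RPVA 0.55, LPVA 0.45 in the AF preset) by integrating the
logistic-normal mean, and cohort generation standardizes LAV/LAEF against
the realized cohort so the marginals do not drift with truncation or
sampling. Burden fractions are drawn from per-region truncated normals
(AF means: lateral 44.4, posterior 40.9, septal 32.7, anterior 31.4,
LPVA 26.0, RPVA 28.7 -- the RPVA value is a declared default between its
neighbours, not an observed one), truncated to the severe or non-severe
side of the 30% boundary with a safety margin.

**Painting.** Enhancement is painted as contiguous vertex patches grown by
breadth-first search until the enhanced area fraction (triangle rule: at
least 2 of 3 vertices enhanced) matches the target; enhanced vertices draw
intensity ratios in (1.45, 1.70) and quiescent ones in (0.75, 0.94), ranges
chosen so the 2-of-3 rule and the triangle-mean-IIR > 1.2 rule agree
exactly in the noise-free field. Patches spill across region boundaries
through shared triangles, so a reconciliation phase re-evaluates every
region against the global field and nudges it back onto its side of the
staging boundary. Additive Gaussian intensity noise (2% of blood pool) and
small vertex jitter (0.02 mm) are applied on top; the stored truth is the
noise-free field's achieved fraction, which the quantification path
recovers exactly.

**What the generator does not emulate.** MR physics (bias fields,
banding, partial volume beyond the voxelizer's nearest-vertex wall band),
wall thickness and transmurality, dense-versus-patchy fibrosis texture,
fibre-mediated mechanics, ventricular coupling, and realistic PV/LAA
geometry. Passing tests therefore show the *analysis* is correct and the
*statistical* structure is recoverable; they do not validate the imaging
chain on real data.

## Classifier harness

Folds are grouped by subject (all six regions share a fold) so global
features cannot leak across the split, and stratified on the subjects'
severe-region counts. PCA bases for curve-shape features are refit on the
training rows of every fold; Z-score normalization uses the healthy
cohort, which is external to the split. The default model is a random
forest (`ranger`, 200 trees, single-threaded for reproducibility);
logistic and gradient-boosting variants are selectable, and a custom
`list(fit, predict)` spec plugs in anything else.

Permutation significance permutes the severe labels at the subject-block
level -- each subject's six-region label vector is reassigned to another
subject -- preserving within-subject dependence and the regional label
structure, and recomputes the cross-validated metric; p-values use the
add-one formula `(1 + #(permuted >= observed)) / (n_perm + 1)`, which
cannot return zero. Under null features the p-values are calibrated
(rejection at 5% within [0.02, 0.09] over 200 simulations). Reported
accuracies and AUCs are mean ± SD *across folds*, not across repeated
runs. An 80/20 split with 5-fold cross-validation inside the 80% is
available through the pipeline configuration; the package-level reports
cross-validate the full table by default.

## Numerical choices, in one place

* Cotangent Laplacian; negative edge weights replaced by unit weights;
  zero weights kept.
* Geodesics are edge-graph shortest paths, not exact polyhedral
  geodesics; the error is second-order at the 10 mm antral scale on these
  mesh resolutions.
* Antral membership is strictly-less-than the radius; ties between left
  and right antra resolve to the left (distance comparison `dl <= dr`).
* Excluded openings are capped with flat centroid fans; orientation is
  verified before integrating.
* Stage intervals half-open; severe strictly above 30%.
* Engineering fibre stretch; LVED phase convention; curves in percent with
  baseline 0.
* Floor-censored strain draws with an analytic mean-restoring shift;
  expansion-only amplitude clamp `[1, 2.5]`; secant global amplitude
  correction targeting the subject mean to 0.1 points.
* Logistic-normal intercepts by adaptive quadrature + root finding;
  cohort-empirical covariate standardization from 8 subjects upward.
* Add-one permutation p-values; permutations that produce a single-class
  fold are retried under a small set of alternative fold seeds.
* Units: mm, mm², mL, percent; conversions only at I/O boundaries.

## Problem sizes

Defaults are study scale: subdivision-4 meshes (2562 vertices), 30 frames
per cycle, cohorts of 47 (AF), 41 (healthy) and 25 (external). The test
suite exercises the identical code paths at subdivision 3 (642 vertices)
and uses 200-subject cohorts for the Monte-Carlo calibration checks, 47
for the classifier checks, and 99 permutations per test for the
permutation sweeps (logistic models for single-feature significance --
the more efficient test for a monotone link -- and the raw-score
classifier for the calibration study); these sizes are the package's
chosen test scale
and are stated here so their sampling error (for example ±1 point on a
pooled strain mean over 1200 region samples) can be judged against the
tolerances in the tests.

## Known limitations

* The tracker is a correspondence heuristic; it is not a substitute for
  registration-based feature tracking on images and will drift on
  deformations with large tangential sliding.
* Regional boundaries are configuration; conclusions that depend on the
  exact parcellation thresholds should sweep them.
* The emergent-LAEF compromise means absolute LAEF values are below
  clinical ranges; use standardized or within-cohort comparisons.
* Painting granularity is one vertex (~0.5--2% of a region's area
  depending on resolution), which bounds how precisely a burden target can
  be realized.
* The generator's per-region strain calibration carries a bounded residual
  for floor-level targets adjacent to high-strain regions (boundary
  mixing); the pooled mean is restored globally.
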
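---
title: "Cord morphometry at C2: methods, calibration, and validation design"
author: "cordmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cord morphometry at C2: methods, calibration, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cordmorph)
```

## The measurement problem

After traumatic spinal cord injury (SCI) the cervical cord atrophies
rostral to the lesion, and the degree of atrophy carries clinical
information — including, in paraplegic patients, an association with
below-level neuropathic pain. The standard semi-automated measurement takes
a T1-weighted volume at roughly 1 mm isotropic resolution, asks an expert
to mark one anatomic landmark (the C2 vertebral level and the cord centre
on that axial slice), and from there proceeds automatically: the cord
cross-section is segmented on each slice, an ellipse is fitted to the
segmented boundary, and the cross-sectional area (SCA, mm²),
anterior-posterior width (APW, mm) and left-right width (LRW, mm) are
extracted per slice and averaged over 15 consecutive slices — 1.5 cm of
rostro-caudal coverage. The averages enter group statistics.

This package implements that measurement chain, a phantom and cohort
simulator with analytic ground truth to validate it, and the cohort-level
statistical battery (Kruskal-Wallis, Bonferroni-corrected pairwise
Mann-Whitney-U, covariate-adjusted regression, Spearman correlations,
percent-difference summaries).

## Segmentation: seeded best-first region growing

`growRegion()` operationalizes "grow from the seed until the signal drops
25% below the region mean" as follows:

* **Criterion.** A candidate voxel is admitted iff its own intensity is at
  least `frac = 0.75` times the *current* region mean. The mean is running,
  not seed-fixed: "the mean of the region" is read literally, and the mean
  is updated incrementally with each admitted voxel.
* **Initialization.** The region mean starts from the 3×3 in-plane
  neighbourhood of the seed (contributing with count 1), which makes the
  starting threshold robust to noise in the single seed voxel. A seed whose
  own intensity already fails the criterion against this neighbourhood mean
  yields a single-voxel region flagged by QC, rather than an error.
* **Order.** Growth is best-first: among the 4-connected frontier the
  *brightest* voxel is examined next, and growth stops the first time the
  best candidate fails. This makes the procedure order-deterministic — with
  plain queue-order growth the final region depends on the arbitrary order
  in which equal-priority voxels are popped, because each admission moves
  the running mean. Under best-first order, when the best frontier voxel
  fails every other frontier voxel fails too, so "stop at the first
  failure" and "stop when no candidate passes" coincide.
* **Connectivity and dimensionality.** 4-connectivity, strictly 2D per
  axial slice. Slices are processed caudal to rostral; each superior slice
  is seeded at the previous slice's fitted ellipse centre (re-seeded to the
  brightest voxel of the surrounding 3×3 patch if that centre voxel fails
  the criterion on the new slice).

Because the criterion is relative, the segmentation is exactly invariant
under global intensity scaling; the test suite asserts bit-identical
results after multiplying a volume by constants spanning five orders of
magnitude.

## From region to measures

The boundary of the grown region (members with a non-member 4-neighbour)
is represented for fitting by the **midpoints of exposed voxel faces**.
Voxel centres of the outermost layer sit systematically *inside* the true
tissue interface (by up to one voxel, half a voxel on average), so fitting
through centres would shrink every cord by a nearly constant offset;
face midpoints straddle the interface without directional bias and sample
the outline at sub-voxel spacing.

`fitEllipse()` is a direct least-squares conic fit constrained to an
ellipse (the numerically stable block-partition formulation of the
constrained eigenproblem), converted to centre, semi-axes, orientation;
area is π·a·b. If the constrained solve degenerates (e.g. near-collinear
boundary), a least-squares circle is substituted and QC flags the slice.
The reported RMS residual uses the first-order point-to-conic distance
|Q(p)|/|∇Q(p)|.

**Width assignment.** Cord cross-sections at C2 are wider left-right than
anterior-posterior in healthy cords and in every patient group, so "APW =
long axis, LRW = short axis" and "widths measured along the anatomical AP
and LR image axes" are contradictory conventions — the long axis almost
always runs left-right. `assignWidths()` defaults to the **projection**
rule: APW and LRW are the support-function widths of the fitted ellipse
measured along the image AP and LR axes,
w(φ) = 2·sqrt(a²cos²(φ−θ) + b²sin²(φ−θ)). For an axis-aligned ellipse
these are the corresponding diameters. The literal long/short labelling
remains available as `mode = "axis-label"` for comparability.

**Averaging window.** The window is the landmark slice plus its 14
superior neighbours: 15 slices at 1 mm = 1.5 cm, anchored so the C2
landmark is included. The per-subject summary is the arithmetic mean of
the 15 per-slice values.

**QC.** `qcCheck()` automates the visual inspection step with four
per-slice flags — field-of-view border contact, RMS residual > 0.75 mm,
adjacent-slice area change > 20%, region smaller than 20 voxels — plus
degenerate growth and circle fallback. A run passes iff no flag is raised.
All thresholds are configurable (`qcThresholds()`); the defaults are set
at the scale of the expected measurement (sub-millimetre residuals for a
well-fit cross-section; a 20% slice-to-slice area jump is anatomically
implausible over 1 mm).

**Coordinates.** Voxel indices are 1-based, as everywhere in R; the world
coordinate of voxel *i* is (i−1)·voxelSize at the voxel centre, axes
ordered (LR, AP, IS) with superior = increasing third index. Volumes
carrying permuted axis labels are reoriented on entry.

## The phantom generator

`generateCordPhantom()` builds the simplest object that exercises every
part of the algorithm with exactly known answers: per-slice true ellipses
rasterized by the voxel-centre rule at a bright cord intensity, a CSF
annulus of fixed radial thickness at lower intensity, background, then an
in-plane Gaussian point-spread blur and additive noise. `PhantomTruth`
stores π·a·b and the closed-form axis widths — never an estimate.

Defaults (units in parentheses):

| parameter | default | why |
|---|---|---|
| grid, slices | 48×48×24 voxels (1 mm iso) | smallest volume holding cord + annulus with margin; full cohort runs in seconds |
| cord / CSF / background intensity | 100 / 50 / 10 (a.u.) | T1w-like contrast; CSF at 50% of cord puts the half-maximum boundary exactly at the 75% criterion, so the noiseless threshold contour is the true interface |
| semi-axes | 4.35 (AP) × 4.9 (LR) mm | healthy-cord widths of 8.7 / 9.8 mm |
| CSF annulus thickness | 3 mm | typical subarachnoid gap at C2 |
| PSF sigma | 0.6 mm | effective in-plane resolution of a 1 mm acquisition |
| noise SD | 4 (a.u.) | cord SNR 25, T1w-like; Gaussian by default, Rician optional |
| landmark slice | 5 | leaves the required 14 superior slices in a 24-slice volume |

What the phantom deliberately omits: vertebral bone, gray/white cord
substructure, motion, bias fields, through-slice blur. Passing tests on
phantoms therefore validate the *measurement chain* — criterion, growth
order, fitting, propagation, averaging — not robustness to artefacts real
scans can contain.

## The cohort simulator and its calibration

`generateCohort()` draws one subject at a time with a pre-drawn
per-subject seed (so output is independent of processing order and
bit-reproducible). Defaults encode the reference study's printed group
summaries, bundled with the package (`referenceTables()`):

* **Groups.** 31 healthy controls (true SCA 79.2 ± 9.1 mm²), 14
  tetraplegics (56.0 ± 10.2), 14 paraplegics (pooled 65.1 ± 5.1); 8 of the
  paraplegics and 5 of the tetraplegics carry below-level neuropathic pain
  (NP).
* **Shape.** A subject's true area A is drawn from its group distribution;
  semi-axes follow the group's LRW/APW ratio (controls 9.8/8.7 ≈ 1.13,
  paraplegics 10.2/6.2 ≈ 1.65, tetraplegics 9.4/5.4 ≈ 1.74 — the AP axis
  shrinks preferentially after injury). The printed group mean widths and
  mean areas are mutually inconsistent under an exact-ellipse model
  (π·(APW/2)·(LRW/2) ≠ mean SCA in every group), so the simulator honours
  the *area* distribution and the width *ratio*, not both absolutes.
* **Pain contrast.** Among paraplegics the NP subgroup's true mean is
  `painMultiplier = 0.884` times the pain-free subgroup's — an exact
  −11.6% contrast — with the two subgroup means solved so the pooled
  paraplegic mean stays 65.1 mm². Subgroup SDs keep the printed group SD.
* **M1/pain dependence.** In NP subjects, the M1 gray-matter-volume
  covariate and the continuous 0–10 pain intensity are linked by a
  Gaussian copula. The default correlation parameter is **calibrated at
  finite n**: `calibrateDependence(0.637, 13)` inverts the exact
  bivariate-normal expectation
  E[r_S] = 6/(π(n+1))·[asin ρ + (n−2)·asin(ρ/2)], giving ρ ≈ 0.695, so
  that the *expected sample* Spearman coefficient in cohorts of n = 13
  equals 0.637. Inverting the population relation ρ = 2·sin(π·ρ_S/6)
  instead would undershoot the mean sample correlation by ≈ 0.04 at this
  n. Pain intensity is kept continuous (a strictly monotone Beta-quantile
  transform of the copula normal) precisely so rank ties cannot attenuate
  this calibration; at dependence 0 the two covariates are independent by
  construction.
* **Sub-voxel placement jitter.** Each subject's cord centre is offset
  uniformly within ±0.5 voxel. Rasterizing every phantom at one fixed
  grid alignment is not a property of real acquisitions, and it aliases:
  at a fixed alignment the voxel-centre count of an ellipse oscillates
  around π·a·b by several percent as the radii grow, which turns into a
  spurious, area-dependent measurement bias and distorts between-subgroup
  contrasts. With arbitrary per-subject alignment the rasterization error
  averages to ≈ 0 uniformly in area, as in real cohorts.
* **Covariates.** Age, sex, lesion level (ordinal, C1=1…S5=30; group
  ranges C2–C8 and Th1–L3), time since injury (moment-matched gamma),
  ISNCSCI motor/sensory scores, thermal thresholds, and independent S1 /
  ACC / thalamus ROI volumes complete the record; they reproduce the
  *structure* of the clinical table, not any individual patient.

Because tetraplegics (smaller SCA) occupy rostral lesion levels and
paraplegics caudal ones, the positive association between lesion level
and SCA across SCI subjects emerges from the group structure rather than
being imposed.

## Statistics

`kruskalWallis()`, `pairwiseMannWhitney()`, `spearmanCor()` and
`adjustedRegression()` wrap the standard R implementations
(`kruskal.test`, `wilcox.test` with exact small-sample p-values,
`cor.test`, `lm`) behind the package's tidy result types; the test suite
verifies each against independent brute-force rank oracles (full
enumeration of arrangements or permutations at small n). H and U are
reported under their own names; `cohortReport()` additionally reports a
one-way ANOVA F per measure for side-by-side comparability with reports
that print F values for rank tests, without attempting to reproduce any
real-data F value. Bonferroni families are: the 3 pairwise group
comparisons per measure, and the correlation battery over the number of
correlations actually run. Missing data are handled complete-case per
analysis, with counts carried in the results.

`percentDifference(a, b)` is 100·(a−b)/b, reported to one decimal in
reports; the tetraplegic-vs-paraplegic worked example from the printed
group means is 100·(56.0−65.1)/65.1 = −14.0%.

## Validation design and problem sizes

The package validates itself at four levels, chosen so the full suite
runs in minutes on one CPU:

1. **Exact oracles.** On noiseless, blur-free phantoms with CSF at 50% of
   cord intensity, the grown region must equal the analytic
   voxel-centre-inside-ellipse mask on every slice, exhaustively.
2. **Closed-form recovery.** Ellipse fits on exactly sampled points must
   recover parameters to 1e-6; widths must follow the rotated-width
   closed form, cross-checked against dense support-function evaluation.
3. **Noisy recovery.** Over 100 phantoms with geometry drawn from the
   control distribution at default SNR, the aggregate recovered SCA must
   sit within 5% of truth with systematic bias below 2%. Orientation
   invariance of recovered area is asserted after averaging over
   sub-voxel placements, because a single fixed alignment aliases the
   rasterized area by several percent (see above) — an inherent property
   of the discrete mask, not of the algorithm.
4. **Cohort calibration.** Simulated cohorts pushed through the full
   pipeline must reproduce the configured group means (150 subjects per
   group in the tests) and the −11.6% paraplegic NP contrast (40
   replicate cohorts in the tests; 200 in `scripts/acceptance.R`), and
   1000 replicate n = 13 NP cohorts must average a Spearman correlation
   of 0.637 between M1 volume and pain intensity.

## Known limitations

* The measurement floor is set by 1 mm voxels on a ~9 mm structure:
  per-subject SCA has a quantization-driven SD of 2–4%, and fitted widths
  on near-axis-aligned cross-sections carry an eccentricity exaggeration
  of a few tenths of a millimetre. Group contrasts are unaffected (the
  error averages out), but single-subject widths should be read with
  half-voxel caution.
* The stopping criterion presumes bright cord over darker CSF with CSF
  below 75% of cord intensity; the generator's validity check enforces
  this, and inverted-contrast (T2-like) volumes are out of scope.
* Propagation assumes the cord stays near the previous slice's centre;
  pathology that displaces the cord by more than the 3×3 re-seeding
  neighbourhood between adjacent slices would require a new landmark.
* The simulator reproduces summary-level structure (means, SDs, ratios,
  subgroup contrasts, one rank dependence). It does not model
  subject-level couplings it has no calibration for — e.g. age-atrophy
  interactions — and findings about such couplings cannot be validated
  against it.
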
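# cordmorph

Semi-automated spinal cord cross-sectional morphometry at the C2
vertebral level, for researchers quantifying cord atrophy after spinal
cord injury (SCI) and relating it to clinical status — including
below-level neuropathic pain.

Given a T1-weighted-like volume (≈1 mm isotropic) and a single
user-supplied landmark (the C2 axial slice and the in-plane cord centre),
the package measures, per subject:

* **SCA** — cross-sectional cord area (mm²),
* **APW / LRW** — anterior-posterior and left-right cord widths (mm),

each per axial slice and averaged over a 15-slice (1.5 cm) window, with
automated quality control. Because no scan data are distributed with the
measurement protocol, the package also ships a phantom/cohort simulator
with analytic ground truth, calibrated to the published group summary
statistics it bundles, plus the cohort-level statistical battery.

## Method

1. **Seeded region growing.** From the landmark seed, the cord region is
   grown by best-first admission of 4-neighbour frontier voxels: the
   brightest candidate is admitted while its intensity is at least 75% of
   the running region mean (a 25% relative signal drop marks the
   cord–CSF boundary). The criterion is relative, so segmentation is
   invariant to global intensity scaling.
2. **Ellipse fit.** The region outline (midpoints of exposed voxel faces)
   is fitted with a direct least-squares conic constrained to an ellipse;
   area = π·a·b, and APW/LRW are the widths of the fitted ellipse along
   the anatomical image axes, w(φ) = 2√(a²cos²(φ−θ) + b²sin²(φ−θ)).
3. **Propagation and averaging.** Each superior slice is re-seeded at the
   previous slice's fitted centre; 15 slices are measured and
   arithmetically averaged. QC flags border contact, poor fits, area
   discontinuities and degenerate regions.
4. **Statistics.** Kruskal-Wallis across groups, Bonferroni-corrected
   pairwise Mann-Whitney-U, Spearman correlations with clinical scores,
   and regression of behavioural measures on SCA/APW/LRW adjusted for
   age, sex and lesion level.

## Worked example

```r
library(cordmorph)

# a 48x48x24 voxel phantom: healthy-cord ellipse (4.35 x 4.9 mm semi-axes),
# CSF annulus at 50% of cord intensity, 0.6 mm PSF, noise SD 4
ph <- generateCordPhantom(phantomSpec(), seed = 7)

m <- segmentCord(ph$volume, cordLandmark(slice = 5, center = c(24, 24)))
m
#> CordMorphometry over 15 axial slices
#>   mean SCA 68.34 mm^2, APW 8.44 mm, LRW 10.31 mm
#>   QC: pass

head(sliceTable(m), 3)
#>   slice     area      apw      lrw rmsResidual nVoxels voxelArea
#> 1     5 68.18091 8.438077 10.28796   0.1421443      68        68
#> 2     6 68.18091 8.438077 10.28796   0.1421443      68        68
#> 3     7 68.18091 8.438077 10.28796   0.1421443      68        68

sca(ph$truth)   # analytic truth for this phantom: 66.96 mm^2
```

The measured 68.3 mm² sits ~2% from the analytic 66.96 mm² — the
quantization floor of 1 mm voxels on a ~9 mm structure at one fixed grid
alignment; across a simulated cohort (random sub-voxel placement) the
bias averages below 1%. The worked ellipse example from the bundled
group-summary table:

```r
round(percentDifference(56.0, 65.1), 1)  # tetraplegic vs paraplegic SCA
#> [1] -14
```

A full synthetic study — simulate 59 subjects, segment every volume, run
the statistics — is one call:

```r
res <- runPipeline(runConfig("out_demo", seed = 1))
res$report$painContrasts   # NP vs pain-free cord area within each group
```

A command-line driver with `simulate`, `segment`, `stats` and `run`
subcommands is installed at `inst/scripts/cordmorph`; cohort
specification overrides are given as JSON (see `?cohortSpecFromList`).

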
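#' @import methods
NULL

#' 3D scalar image volume with anatomical axis labels
#'
#' A minimal container for a T1-weighted-like image grid: the voxel data, the
#' voxel dimensions in mm, and a label per array axis saying which anatomical
#' direction it runs along (`"LR"` left-right, `"AP"` anterior-posterior,
#' `"IS"` inferior-superior, i.e. rostro-caudal). Axial slices are taken
#' perpendicular to the `"IS"` axis; increasing index along it is superior.
#'
#' @slot data 3D numeric array of intensities (arbitrary units).
#' @slot voxelSize numeric(3), voxel edge length in mm per array axis.
#' @slot axes character(3), a permutation of `c("LR", "AP", "IS")`.
#'
#' @export
setClass("CordVolume",
  representation(data = "array", voxelSize = "numeric", axes = "character"),
  prototype(voxelSize = c(1, 1, 1), axes = c("LR", "AP", "IS"))
)

setValidity("CordVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive numbers (mm)")
  if (length(object@axes) != 3L || !setequal(object@axes, c("LR", "AP", "IS")))
    msg <- c(msg, "axes must be a permutation of LR, AP, IS")
  if (length(msg)) msg else TRUE
})

#' Phantom specification: geometry, contrast and degradation model
#'
#' Describes a synthetic cervical-cord volume: per-axial-slice true ellipse
#' (the cord cross-section), a surrounding CSF annulus, background, an
#' in-plane Gaussian point-spread blur and additive noise, plus the C2-like
#' landmark (seed slice and in-plane centre) used to start segmentation.
#'
#' The contrast model is T1-weighted: cord bright, CSF darker. The CSF
#' intensity must stay below 75% of the cord intensity so that the
#' relative-intensity stopping criterion of [growRegion()] is well posed in
#' the noiseless limit.
#'
#' @slot nSlices integer, number of axial slices.
#' @slot shape integer(2), in-plane grid size in voxels (LR, AP).
#' @slot voxelSize numeric(3), mm per axis (LR, AP, IS); default 1 mm isotropic.
#' @slot ellipses data.frame with one row per slice: `slice`, `cx`, `cy`
#'   (centre, mm), `semiAP`, `semiLR` (semi-axes, mm), `theta` (in-plane
#'   rotation of the AP semi-axis away from the image AP axis, rad).
#' @slot intensityCord,intensityCsf,intensityBackground numeric, arbitrary units.
#' @slot csfThickness numeric, radial thickness of the CSF annulus in mm.
#' @slot psfSigma numeric, in-plane Gaussian PSF sigma in mm (0 = none).
#' @slot noiseSd numeric, additive noise SD in intensity units (0 = none).
#' @slot noiseModel `"gaussian"` (default) or `"rician"`.
#' @slot landmark list with `slice` (1-based axial index) and `center`
#'   (in-plane voxel coordinates, 1-based).
#'
#' @export
setClass("PhantomSpec",
  representation(
    nSlices = "integer", shape = "integer", voxelSize = "numeric",
    ellipses = "data.frame",
    intensityCord = "numeric", intensityCsf = "numeric",
    intensityBackground = "numeric", csfThickness = "numeric",
    psfSigma = "numeric", noiseSd = "numeric", noiseModel = "character",
    landmark = "list"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  e <- object@ellipses
  need <- c("slice", "cx", "cy", "semiAP", "semiLR", "theta")
  if (!all(need %in% names(e)))
    return(paste("ellipses must have columns:", paste(need, collapse = ", ")))
  if (nrow(e) != object@nSlices)
    msg <- c(msg, "ellipses must have one row per slice")
  if (any(e$semiAP <= 0) || any(e$semiLR <= 0))
    msg <- c(msg, "semi-axes must be strictly positive")
  if (object@intensityCsf >= 0.75 * object@intensityCord)
    msg <- c(msg, "CSF intensity must be below 75% of cord intensity")
  if (any(object@shape < 4L) || object@nSlices < 1L)
    msg <- c(msg, "non-positive or degenerate grid dimensions")
  if (any(object@voxelSize <= 0))
    msg <- c(msg, "voxel sizes must be positive")
  ## outer CSF ellipse must stay >= 2 voxels inside the field of view
  fovLR <- object@shape[1] * object@voxelSize[1]
  fovAP <- object@shape[2] * object@voxelSize[2]
  marg <- 2 * object@voxelSize[1:2]
  rmax <- pmax(e$semiAP, e$semiLR) + object@csfThickness
  if (any(e$cx - rmax < marg[1]) || any(e$cx + rmax > fovLR - marg[1]) ||
      any(e$cy - rmax < marg[2]) || any(e$cy + rmax > fovAP - marg[2]))
    msg <- c(msg, "ellipse (plus CSF annulus) leaves the in-plane field of view (need >= 2 voxels margin)")
  lm <- object@landmark
  if (!all(c("slice", "center") %in% names(lm)))
    msg <- c(msg, "landmark must have elements 'slice' and 'center'")
  else {
    if (lm$slice < 1L || lm$slice > object@nSlices)
      msg <- c(msg, "landmark slice outside volume")
    if (object@nSlices < lm$slice + 14L)
      msg <- c(msg, "need at least 14 slices superior to the landmark slice")
  }
  if (!object@noiseModel %in% c("gaussian", "rician"))
    msg <- c(msg, "noiseModel must be 'gaussian' or 'rician'")
  if (length(msg)) msg else TRUE
})

#' Analytic ground truth for a phantom
#'
#' Exact per-slice cord geometry implied by a [PhantomSpec]: area
#' \eqn{\pi a b}, and the full widths of the (possibly rotated) true ellipse
#' measured along the image AP and LR axes, plus their means over the
#' 15-slice analysis window anchored at the landmark slice.
#'
#' @slot perSlice data.frame: `slice`, `area` (mm^2), `apw`, `lrw` (mm).
#' @slot meanArea,meanApw,meanLrw numeric, means over the analysis window.
#' @slot window integer vector of slice indices forming the analysis window.
#'
#' @export
setClass("PhantomTruth",
  representation(perSlice = "data.frame", meanArea = "numeric",
                 meanApw = "numeric", meanLrw = "numeric", window = "integer")
)

#' Grown cord region on one axial slice
#'
#' Result of seeded best-first region growing on a single slice: the member
#' voxels, the boundary voxels (members with at least one non-member
#' 4-neighbour), sub-voxel boundary points used for ellipse fitting, the
#' final region mean, and a log showing that every accepted voxel met the
#' relative-intensity criterion at the moment of acceptance.
#'
#' @slot sliceIndex integer.
#' @slot region integer matrix (n x 2), member voxel indices (LR, AP), 1-based.
#' @slot boundary integer matrix, subset of `region`.
#' @slot boundaryPoints numeric matrix (m x 2), mm coordinates of the
#'   midpoints of exposed voxel faces (sub-voxel outline samples).
#' @slot regionMean numeric, final mean intensity of the region.
#' @slot acceptLog data.frame: `intensity` and `threshold` at acceptance,
#'   one row per admitted voxel in admission order.
#' @slot touchesBorder logical, region reached the slice border.
#' @slot degenerate logical, growth collapsed to the seed voxel.
#'
#' @export
setClass("SliceSegmentation",
  representation(sliceIndex = "integer", region = "matrix",
                 boundary = "matrix", boundaryPoints = "matrix",
                 regionMean = "numeric", acceptLog = "data.frame",
                 touchesBorder = "logical", degenerate = "logical")
)

setValidity("SliceSegmentation", function(object) {
  msg <- character()
  if (ncol(object@region) != 2L) msg <- c(msg, "region must be n x 2")
  if (nrow(object@boundary) > nrow(object@region))
    msg <- c(msg, "boundary cannot exceed region")
  if (length(msg)) msg else TRUE
})

#' Fitted ellipse and derived cord measures
#'
#' A conic fitted to boundary points by direct least squares, constrained to
#' an ellipse, with the morphometric quantities derived from it: area
#' \eqn{\pi a b}, and the anterior-posterior / left-right widths (full
#' support-function widths of the rotated ellipse along the image axes).
#'
#' @slot center numeric(2), mm.
#' @slot semiMajor,semiMinor numeric, mm; `semiMajor >= semiMinor > 0`.
#' @slot orientation numeric, angle of the major axis from the image LR
#'   axis, rad, in (-pi/2, pi/2].
#' @slot area numeric, `pi * semiMajor * semiMinor`, mm^2.
#' @slot apw,lrw numeric, widths in mm (see [assignWidths()]).
#' @slot rmsResidual numeric, RMS point-to-ellipse distance, mm.
#' @slot method `"ellipse"` for the constrained conic fit, `"circle"` for the
#'   least-squares circle fallback used when the conic degenerates.
#'
#' @export
setClass("EllipseFit",
  representation(center = "numeric", semiMajor = "numeric",
                 semiMinor = "numeric", orientation = "numeric",
                 area = "numeric", apw = "numeric", lrw = "numeric",
                 rmsResidual = "numeric", method = "character")
)

setValidity("EllipseFit", function(object) {
  msg <- character()
  if (!(object@semiMajor >= object@semiMinor && object@semiMinor > 0))
    msg <- c(msg, "need semiMajor >= semiMinor > 0")
  if (object@area <= 0) msg <- c(msg, "area must be positive")
  if (length(msg)) msg else TRUE
})

#' Per-slice quality-control flags for a morphometry run
#'
#' Automates the visual inspection step: flags any slice whose region touches
#' the field-of-view border, whose ellipse fit has a large RMS residual,
#' whose area jumps relative to the adjacent slice, whose region is
#' implausibly small, whose growth degenerated to the seed, or whose conic
#' fit fell back to a circle. The run fails QC iff any flag is raised.
#'
#' @slot flags data.frame, one row per slice, logical flag columns.
#' @slot pass logical.
#' @slot thresholds list of the thresholds used.
#'
#' @export
setClass("QCReport",
  representation(flags = "data.frame", pass = "logical", thresholds = "list")
)

setValidity("QCReport", function(object) {
  flagCols <- vapply(object@flags, is.logical, logical(1))
  anyFlag <- nrow(object@flags) > 0 && any(unlist(object@flags[flagCols]))
  if (identical(object@pass, !anyFlag)) TRUE
  else "pass must be TRUE iff no flag is raised"
})

#' Cord morphometry for one subject
#'
#' Per-slice segmentations and ellipse fits over the 15-slice (1.5 cm at
#' 1 mm) analysis window, together with the window-averaged cord area, APW
#' and LRW used for statistics, and the QC report.
#'
#' @slot fits list of [EllipseFit] objects, one per slice, caudal to rostral.
#' @slot segmentations list of [SliceSegmentation] objects.
#' @slot sliceTable data.frame: `slice`, `area`, `apw`, `lrw`, `rmsResidual`,
#'   `nVoxels`, `voxelArea` (region voxel count x in-plane voxel area, a QC
#'   cross-check never used for statistics).
#' @slot meanSca,meanApw,meanLrw numeric, arithmetic means over the window.
#' @slot qc [QCReport].
#' @slot landmark list, the landmark the run was seeded from.
#' @slot voxelSize numeric(3).
#'
#' @export
setClass("CordMorphometry",
  representation(fits = "list", segmentations = "list",
                 sliceTable = "data.frame",
                 meanSca = "numeric", meanApw = "numeric", meanLrw = "numeric",
                 qc = "QCReport", landmark = "list", voxelSize = "numeric")
)

setValidity("CordMorphometry", function(object) {
  msg <- character()
  st <- object@sliceTable
  if (nrow(st) != length(object@fits))
    msg <- c(msg, "sliceTable must have one row per fit")
  if (nrow(st) > 0) {
    if (abs(object@meanSca - mean(st$area)) > 1e-8)
      msg <- c(msg, "meanSca must equal the mean of per-slice areas")
    if (abs(object@meanApw - mean(st$apw)) > 1e-8 ||
        abs(object@meanLrw - mean(st$lrw)) > 1e-8)
      msg <- c(msg, "mean widths must equal the per-slice means")
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort specification
#'
#' Parameters of the simulated study population: per-group sample sizes and
#' true cord-area distributions, per-group LRW/APW width ratios, the
#' neuropathic-pain (NP) subgroup structure among paraplegics, demographic
#' and clinical covariate distributions, and the Gaussian-copula dependence
#' between the M1 gray-matter-volume covariate and ongoing pain intensity in
#' NP subjects.
#'
#' Groups are `HC` (healthy controls), `pSCI` (paraplegia) and `tSCI`
#' (tetraplegia). Each element of `groups` is a list with `n`, `scaMean`,
#' `scaSd` (mm^2), `widthRatio` (LRW/APW), `ageMean`, `ageSd`, `maleProp`,
#' `lesionLevels` (ordinal range, C1=1 ... S5=30; NULL for HC), `nNP`
#' (below-level NP count), `warmMean`, `warmSd`, `painThrMean`, `painThrSd`
#' (degrees C).
#'
#' @slot groups named list (`HC`, `pSCI`, `tSCI`) of per-group parameter lists.
#' @slot painMultiplier numeric in (0, 1]: ratio of the paraplegic NP
#'   subgroup's true-mean SCA to the pain-free subgroup's; the two subgroup
#'   means are solved so the pooled paraplegic mean equals `scaMean`.
#' @slot m1PainDependence numeric in [-1, 1]: Gaussian-copula correlation
#'   between M1 volume and pain intensity for NP subjects; 0 means generated
#'   independently. The default is calibrated with [calibrateDependence()].
#' @slot m1Mean,m1Sd numeric, M1 ROI volume covariate (arbitrary units).
#' @slot painShape numeric(2), Beta shape parameters of pain intensity / 10.
#' @slot phantom list of phantom degradation settings shared by all subjects:
#'   `shape`, `nSlices`, `voxelSize`, `intensityCord`, `intensityCsf`,
#'   `intensityBackground`, `csfThickness`, `psfSigma`, `noiseSd`.
#'
#' @export
setClass("CohortSpec",
  representation(groups = "list", painMultiplier = "numeric",
                 m1PainDependence = "numeric",
                 m1Mean = "numeric", m1Sd = "numeric", painShape = "numeric",
                 phantom = "list")
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  for (g in names(object@groups)) {
    p <- object@groups[[g]]
    if (p$n < 1) msg <- c(msg, paste0(g, ": sample size must be >= 1"))
    if (p$scaMean <= 0 || p$scaSd <= 0)
      msg <- c(msg, paste0(g, ": SCA mean and SD must be strictly positive"))
  }
  if (object@painMultiplier <= 0 || object@painMultiplier > 1)
    msg <- c(msg, "painMultiplier must lie in (0, 1]")
  if (abs(object@m1PainDependence) > 1)
    msg <- c(msg, "m1PainDependence must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})
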
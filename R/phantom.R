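## Synthetic cervical-cord phantoms with analytic ground truth.
##
## World coordinates: voxel i (1-based) is centred at (i - 1) * voxelSize mm,
## axes ordered (LR, AP, IS). The true cord cross-section on each axial slice
## is an ellipse whose AP semi-axis is rotated by theta from the image AP
## axis; a CSF annulus of fixed radial thickness surrounds it.

#' Construct a phantom specification
#'
#' Builds a [PhantomSpec] describing a synthetic cervical cord volume.
#' Geometry arguments (`semiAP`, `semiLR`, `theta`, `center`) may be scalars
#' (a uniform cylindrical cord) or vectors of length `nSlices` (e.g. a
#' tapered cord).
#'
#' Defaults emulate a 1 mm isotropic T1-weighted acquisition of a healthy
#' cervical cord at C2: semi-axes 4.35 mm (AP) x 4.9 mm (LR), i.e. widths of
#' 8.7 and 9.8 mm; bright cord over darker CSF at 50% of cord intensity, so
#' the 75% relative-intensity boundary criterion falls exactly halfway
#' between the two tissue plateaus; a 0.6 mm in-plane PSF and additive
#' Gaussian noise at SD 4 (cord SNR 25).
#'
#' @param nSlices number of axial slices (default 24).
#' @param shape in-plane grid (LR, AP) in voxels.
#' @param voxelSize numeric(3), mm.
#' @param semiAP,semiLR true semi-axes in mm (scalar or per-slice).
#' @param theta in-plane rotation of the AP semi-axis away from the image AP
#'   axis, radians (scalar or per-slice).
#' @param center in-plane ellipse centre in mm; default the grid centre.
#' @param intensityCord,intensityCsf,intensityBackground tissue intensities.
#' @param csfThickness radial thickness of the CSF annulus, mm.
#' @param psfSigma in-plane Gaussian PSF sigma, mm.
#' @param noiseSd additive noise SD.
#' @param noiseModel `"gaussian"` or `"rician"`.
#' @param landmarkSlice 1-based axial index of the C2-like landmark; at least
#'   14 more-superior slices must exist.
#' @return A validated [PhantomSpec].
#' @examples
#' spec <- phantomSpec()
#' truthTable(phantomTruth(spec))[1, ]
#' @export
phantomSpec <- function(nSlices = 24L, shape = c(48L, 48L),
                        voxelSize = c(1, 1, 1),
                        semiAP = 4.35, semiLR = 4.9, theta = 0,
                        center = NULL,
                        intensityCord = 100, intensityCsf = 50,
                        intensityBackground = 10,
                        csfThickness = 3, psfSigma = 0.6, noiseSd = 4,
                        noiseModel = c("gaussian", "rician"),
                        landmarkSlice = 5L) {
  nSlices <- as.integer(nSlices)
  shape <- as.integer(shape)
  if (is.null(center))
    center <- (shape[1:2] - 1) / 2 * voxelSize[1:2]
  ell <- data.frame(
    slice = seq_len(nSlices),
    cx = rep_len(center[1], nSlices), cy = rep_len(center[2], nSlices),
    semiAP = rep_len(semiAP, nSlices), semiLR = rep_len(semiLR, nSlices),
    theta = rep_len(theta, nSlices))
  lmCenter <- round(c(ell$cx[landmarkSlice] / voxelSize[1],
                      ell$cy[landmarkSlice] / voxelSize[2])) + 1L
  new("PhantomSpec", nSlices = nSlices, shape = shape,
      voxelSize = as.numeric(voxelSize), ellipses = ell,
      intensityCord = intensityCord, intensityCsf = intensityCsf,
      intensityBackground = intensityBackground,
      csfThickness = csfThickness, psfSigma = psfSigma, noiseSd = noiseSd,
      noiseModel = match.arg(noiseModel),
      landmark = list(slice = as.integer(landmarkSlice),
                      center = as.integer(lmCenter)))
}

## full widths of the rotated true ellipse along the image AP and LR axes
ellipseAxisWidths <- function(semiAP, semiLR, theta) {
  list(apw = 2 * sqrt(semiAP^2 * cos(theta)^2 + semiLR^2 * sin(theta)^2),
       lrw = 2 * sqrt(semiAP^2 * sin(theta)^2 + semiLR^2 * cos(theta)^2))
}

#' Analytic ground truth of a phantom specification
#'
#' Computes the exact per-slice cord area (\eqn{\pi a b}) and the widths of
#' the true ellipse along the image AP and LR axes, plus their means over the
#' 15-slice analysis window starting at the landmark slice. Truth is closed
#' form; no estimate is ever stored here.
#'
#' @param spec a [PhantomSpec].
#' @param window integer slice indices of the analysis window; default the
#'   landmark slice plus its 14 superior neighbours.
#' @return A [PhantomTruth].
#' @export
phantomTruth <- function(spec, window = NULL) {
  stopifnot(is(spec, "PhantomSpec"))
  e <- spec@ellipses
  w <- ellipseAxisWidths(e$semiAP, e$semiLR, e$theta)
  per <- data.frame(slice = e$slice, area = pi * e$semiAP * e$semiLR,
                    apw = w$apw, lrw = w$lrw)
  if (is.null(window))
    window <- seq(spec@landmark$slice, length.out = 15L)
  window <- as.integer(window)
  if (any(window < 1L) || any(window > spec@nSlices))
    stop("analysis window outside the volume")
  sel <- per[match(window, per$slice), ]
  new("PhantomTruth", perSlice = per, meanArea = mean(sel$area),
      meanApw = mean(sel$apw), meanLrw = mean(sel$lrw), window = window)
}

## rasterize one slice: cord ellipse inside a CSF annulus inside background.
## A voxel belongs to a compartment iff its centre does.
rasterizeSlice <- function(spec, k) {
  e <- spec@ellipses[k, ]
  nx <- spec@shape[1]; ny <- spec@shape[2]
  vx <- spec@voxelSize[1]; vy <- spec@voxelSize[2]
  x <- (seq_len(nx) - 1) * vx - e$cx
  y <- (seq_len(ny) - 1) * vy - e$cy
  X <- matrix(x, nx, ny); Y <- matrix(y, nx, ny, byrow = TRUE)
  ## components along the ellipse's AP and LR principal directions
  tAP <- -X * sin(e$theta) + Y * cos(e$theta)
  tLR <- X * cos(e$theta) + Y * sin(e$theta)
  inCord <- (tAP / e$semiAP)^2 + (tLR / e$semiLR)^2 <= 1
  inOuter <- (tAP / (e$semiAP + spec@csfThickness))^2 +
             (tLR / (e$semiLR + spec@csfThickness))^2 <= 1
  img <- matrix(spec@intensityBackground, nx, ny)
  img[inOuter] <- spec@intensityCsf
  img[inCord] <- spec@intensityCord
  img
}

## analytic cord-membership mask (voxel-centre rule) for oracle tests
#' True cord membership mask for one phantom slice
#'
#' Returns the exact set of voxels whose centres fall inside the true cord
#' ellipse of slice `k` — the analytic oracle against which grown regions are
#' checked on noiseless phantoms.
#'
#' @param spec a [PhantomSpec].
#' @param k slice index.
#' @return Logical matrix of the in-plane grid.
#' @export
cordMask <- function(spec, k) {
  e <- spec@ellipses[k, ]
  nx <- spec@shape[1]; ny <- spec@shape[2]
  x <- (seq_len(nx) - 1) * spec@voxelSize[1] - e$cx
  y <- (seq_len(ny) - 1) * spec@voxelSize[2] - e$cy
  X <- matrix(x, nx, ny); Y <- matrix(y, nx, ny, byrow = TRUE)
  tAP <- -X * sin(e$theta) + Y * cos(e$theta)
  tLR <- X * cos(e$theta) + Y * sin(e$theta)
  (tAP / e$semiAP)^2 + (tLR / e$semiLR)^2 <= 1
}

#' Generate a cord phantom volume with analytic ground truth
#'
#' Rasterizes the per-slice true ellipses of `spec` (bright cord, darker CSF
#' annulus, background), applies an in-plane Gaussian point-spread blur, adds
#' noise, and returns the volume together with its exact [PhantomTruth].
#' Identical `(spec, seed)` pairs reproduce the volume bit-exactly.
#'
#' @param spec a [PhantomSpec].
#' @param seed integer seed for the noise.
#' @return `list(volume = CordVolume, truth = PhantomTruth)`.
#' @examples
#' ph <- generateCordPhantom(phantomSpec(), seed = 1)
#' ph$volume
#' sca(ph$truth)
#' @export
generateCordPhantom <- function(spec, seed = 1L) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  vol <- array(0, dim = c(spec@shape, spec@nSlices))
  for (k in seq_len(spec@nSlices)) vol[, , k] <- rasterizeSlice(spec, k)
  if (spec@psfSigma > 0) {
    if (abs(spec@voxelSize[1] - spec@voxelSize[2]) > 1e-9)
      stop("PSF blur assumes isotropic in-plane voxels")
    vol <- EBImage::gblur(vol, sigma = spec@psfSigma / spec@voxelSize[1])
  }
  if (spec@noiseSd > 0) {
    set.seed(as.integer(seed))
    if (spec@noiseModel == "gaussian") {
      vol <- vol + array(stats::rnorm(length(vol), 0, spec@noiseSd), dim(vol))
    } else {
      n1 <- array(stats::rnorm(length(vol), 0, spec@noiseSd), dim(vol))
      n2 <- array(stats::rnorm(length(vol), 0, spec@noiseSd), dim(vol))
      vol <- sqrt((vol + n1)^2 + n2^2)
    }
  }
  volume <- new("CordVolume", data = vol, voxelSize = spec@voxelSize,
                axes = c("LR", "AP", "IS"))
  list(volume = volume, truth = phantomTruth(spec))
}

#' Write / read a cord volume as NIfTI-1 with an axis sidecar
#'
#' `writeVolume()` writes `.nii`/`.nii.gz` with correct voxel-size header
#' fields plus a JSON sidecar recording the anatomical axis labels;
#' `readVolume()` reads both back. Without a sidecar the axes default to
#' `(LR, AP, IS)`.
#'
#' @param volume a [CordVolume].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `writeVolume()` returns `path` invisibly; `readVolume()` a
#'   [CordVolume].
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "CordVolume"))
  img <- RNifti::asNifti(volume@data, pixdim = volume@voxelSize)
  RNifti::writeNifti(img, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(axes = volume@axes,
                            voxelSizeMM = volume@voxelSize),
                       sidecar, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  axes <- c("LR", "AP", "IS")
  if (file.exists(sidecar))
    axes <- unlist(jsonlite::read_json(sidecar)$axes)
  new("CordVolume", data = array(as.numeric(img), dim = dim(img)),
      voxelSize = RNifti::pixdim(img)[1:3], axes = axes)
}
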
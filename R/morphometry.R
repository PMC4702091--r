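## Semi-automated cord morphometry: seeded best-first region growing at a
## C2-like landmark, ellipse fitting of the region outline, superior slice
## propagation over a 1.5 cm window, averaging and QC.

## reorder a volume so its axes are (LR, AP, IS)
asCanonical <- function(volume) {
  stopifnot(is(volume, "CordVolume"))
  perm <- match(c("LR", "AP", "IS"), volume@axes)
  if (identical(perm, 1:3)) return(volume)
  new("CordVolume", data = aperm(volume@data, perm),
      voxelSize = volume@voxelSize[perm], axes = c("LR", "AP", "IS"))
}

#' Construct a segmentation landmark
#'
#' The C2-level landmark the analysis is seeded from: the axial slice index
#' containing the anatomic landmark and the in-plane centre of the cord on
#' that slice (1-based voxel coordinates). The slice must have at least 14
#' more-superior slices available.
#'
#' @param slice 1-based axial slice index.
#' @param center integer(2), in-plane voxel coordinates (LR, AP).
#' @return A list of class `"cordLandmark"`.
#' @export
cordLandmark <- function(slice, center) {
  slice <- as.integer(slice)
  center <- as.integer(round(center))
  if (length(center) != 2L || slice < 1L)
    stop("landmark needs a positive slice index and an in-plane centre pair")
  structure(list(slice = slice, center = center), class = "cordLandmark")
}

#' Seeded best-first region growing on one axial slice
#'
#' Grows the cord region from a seed voxel by repeatedly admitting the
#' highest-intensity 4-neighbour frontier voxel while its intensity is at
#' least `frac` (default 0.75, i.e. within a 25% drop) of the current region
#' mean. The mean is initialized from the 3x3 neighbourhood of the seed and
#' updated incrementally; growth stops the first time the best frontier
#' candidate fails, which under best-first order means every candidate
#' fails. The stopping criterion is relative, so the segmentation is
#' invariant to global intensity scaling.
#'
#' Boundary voxels are region members with at least one non-member
#' 4-neighbour; for ellipse fitting the region outline is sampled at the
#' midpoints of exposed voxel faces, which localizes the tissue interface
#' with sub-voxel precision and without inward bias (voxel centres of the
#' outermost layer sit systematically inside the true boundary).
#'
#' @param volume a [CordVolume].
#' @param sliceIndex 1-based axial slice index.
#' @param seed integer(2), in-plane seed voxel (LR, AP), 1-based; must not
#'   lie on the slice border and must have positive intensity.
#' @param frac criterion fraction (default 0.75).
#' @return A [SliceSegmentation]. A seed whose own intensity fails the
#'   criterion against its neighbourhood mean yields a single-voxel region
#'   marked `degenerate` (flagged by QC) rather than an error.
#' @export
growRegion <- function(volume, sliceIndex, seed, frac = 0.75) {
  volume <- asCanonical(volume)
  d <- dim(volume@data)
  sliceIndex <- as.integer(sliceIndex)
  if (sliceIndex < 1L || sliceIndex > d[3]) stop("slice index outside volume")
  img <- volume@data[, , sliceIndex]
  res <- .growRegionCpp(img, as.integer(seed[1]), as.integer(seed[2]), frac)
  reg <- res$region
  nx <- d[1]; ny <- d[2]
  P <- matrix(FALSE, nx + 2, ny + 2)
  P[cbind(reg[, 1] + 1L, reg[, 2] + 1L)] <- TRUE
  vx <- volume@voxelSize[1]; vy <- volume@voxelSize[2]
  bpts <- list(); isBoundary <- rep(FALSE, nrow(reg))
  dirs <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  for (dd in dirs) {
    exposed <- !P[cbind(reg[, 1] + 1L + dd[1], reg[, 2] + 1L + dd[2])]
    isBoundary <- isBoundary | exposed
    if (any(exposed))
      bpts[[length(bpts) + 1L]] <- cbind(
        (reg[exposed, 1] - 1 + 0.5 * dd[1]) * vx,
        (reg[exposed, 2] - 1 + 0.5 * dd[2]) * vy)
  }
  new("SliceSegmentation", sliceIndex = sliceIndex, region = reg,
      boundary = reg[isBoundary, , drop = FALSE],
      boundaryPoints = do.call(rbind, bpts),
      regionMean = res$regionMean,
      acceptLog = data.frame(intensity = res$acceptIntensity,
                             threshold = res$acceptThreshold),
      touchesBorder = res$touchesBorder, degenerate = res$degenerate)
}

#' Default quality-control thresholds
#'
#' @param rmsResidual maximum acceptable RMS point-to-ellipse residual, mm.
#' @param areaJump maximum relative area change between adjacent slices.
#' @param minVoxels minimum plausible region size in voxels.
#' @return Named list of thresholds.
#' @export
qcThresholds <- function(rmsResidual = 0.75, areaJump = 0.20,
                         minVoxels = 20L) {
  list(rmsResidual = rmsResidual, areaJump = areaJump,
       minVoxels = as.integer(minVoxels))
}

computeQC <- function(sliceTable, segmentations, fits, thresholds) {
  n <- nrow(sliceTable)
  areas <- sliceTable$area
  jump <- c(FALSE, abs(diff(areas)) / areas[-n] > thresholds$areaJump)
  flags <- data.frame(
    slice = sliceTable$slice,
    borderTouch = vapply(segmentations, function(s) s@touchesBorder,
                         logical(1)),
    highResidual = sliceTable$rmsResidual > thresholds$rmsResidual,
    areaJump = jump,
    smallRegion = sliceTable$nVoxels < thresholds$minVoxels,
    degenerate = vapply(segmentations, function(s) s@degenerate, logical(1)),
    circleFallback = vapply(fits, function(f) f@method == "circle",
                            logical(1)))
  flagCols <- names(flags)[vapply(flags, is.logical, logical(1))]
  new("QCReport", flags = flags,
      pass = !any(unlist(flags[flagCols])), thresholds = thresholds)
}

#' Quality control of a morphometry run
#'
#' Recomputes the per-slice QC flags of a [CordMorphometry] from its stored
#' per-slice results under the given thresholds: field-of-view border
#' contact, ellipse RMS residual above threshold, adjacent-slice area jump
#' above threshold, implausibly small region, degenerate growth, and circle
#' fallback of the conic fit. A pure function of its inputs; the run passes
#' iff no flag is raised. This automates the visual fit inspection of the
#' original semi-automated protocol.
#'
#' @param morph a [CordMorphometry].
#' @param thresholds see [qcThresholds()].
#' @return A [QCReport].
#' @export
qcCheck <- function(morph, thresholds = qcThresholds()) {
  stopifnot(is(morph, "CordMorphometry"))
  computeQC(morph@sliceTable, morph@segmentations, morph@fits, thresholds)
}

propagationError <- function(message, partial) {
  structure(class = c("cordmorphPropagationError", "error", "condition"),
            list(message = message, call = sys.call(-1), partial = partial))
}

#' Segment the cord over the 15-slice analysis window
#'
#' Runs the full per-subject morphometry: grows the cord region on the
#' landmark slice from the user-supplied seed, then propagates superiorly,
#' seeding each adjacent slice at the previous slice's fitted ellipse centre
#' (rounded to the nearest voxel, re-seeded to the brightest voxel of the
#' surrounding 3x3 patch if that voxel fails the intensity criterion). Each
#' slice's region outline is fitted with an ellipse; cord area, APW and LRW
#' are extracted per slice and averaged arithmetically over the window
#' (default 15 slices, i.e. 1.5 cm of rostro-caudal coverage at 1 mm slice
#' thickness). QC flags are computed with [qcCheck()].
#'
#' If growth collapses to a single voxel on any slice (the propagation lost
#' the cord), an error of class `"cordmorphPropagationError"` is signalled
#' whose `partial` field carries the slices completed so far.
#'
#' @param volume a [CordVolume].
#' @param landmark a [cordLandmark()] (or list with `slice`, `center`).
#' @param nSlices number of slices in the window, default 15.
#' @param frac region-growing criterion fraction, default 0.75.
#' @param thresholds QC thresholds, see [qcThresholds()].
#' @param widthMode width-assignment convention, see [assignWidths()].
#' @return A [CordMorphometry].
#' @examples
#' ph <- generateCordPhantom(phantomSpec(), seed = 7)
#' m <- segmentCord(ph$volume, cordLandmark(5, c(24, 24)))
#' c(sca(m), apw(m), lrw(m), qcPass(m))
#' @export
segmentCord <- function(volume, landmark, nSlices = 15L, frac = 0.75,
                        thresholds = qcThresholds(),
                        widthMode = c("projection", "axis-label")) {
  widthMode <- match.arg(widthMode)
  volume <- asCanonical(volume)
  d <- dim(volume@data)
  nSlices <- as.integer(nSlices)
  window <- seq(landmark$slice, length.out = nSlices)
  if (landmark$slice < 1L || max(window) > d[3])
    stop(sprintf(
      "fewer than %d slices available at/superior to landmark slice %d",
      nSlices, landmark$slice))
  vx <- volume@voxelSize[1]; vy <- volume@voxelSize[2]
  seed <- as.integer(landmark$center)

  fits <- vector("list", nSlices)
  segs <- vector("list", nSlices)
  rows <- vector("list", nSlices)
  for (ii in seq_along(window)) {
    k <- window[ii]
    seg <- growRegion(volume, k, seed, frac = frac)
    if (nrow(seg@region) == 1L) {
      partial <- list(fits = fits[seq_len(ii - 1L)],
                      sliceTable = do.call(rbind, rows[seq_len(ii - 1L)]))
      stop(propagationError(sprintf(
        "propagation lost the cord on slice %d (single-voxel region)", k),
        partial))
    }
    fit <- assignWidths(fitEllipse(seg@boundaryPoints),
                        orientationLabels = c("LR", "AP"), mode = widthMode)
    fits[[ii]] <- fit
    segs[[ii]] <- seg
    rows[[ii]] <- data.frame(
      slice = k, area = fit@area, apw = fit@apw, lrw = fit@lrw,
      rmsResidual = fit@rmsResidual, nVoxels = nrow(seg@region),
      voxelArea = nrow(seg@region) * vx * vy)
    ## seed for the adjacent superior slice: fitted centre, re-seeded to the
    ## brightest 3x3 neighbour if the centre voxel fails the criterion
    if (ii < nSlices) {
      ctr <- as.integer(round(fit@center / c(vx, vy))) + 1L
      ctr <- pmin(pmax(ctr, 2L), d[1:2] - 1L)
      nxt <- volume@data[, , window[ii + 1L]]
      patch <- nxt[(ctr[1] - 1):(ctr[1] + 1), (ctr[2] - 1):(ctr[2] + 1)]
      if (nxt[ctr[1], ctr[2]] < frac * mean(patch)) {
        w <- which(patch == max(patch), arr.ind = TRUE)[1, ]
        ctr <- ctr + as.integer(w) - 2L
      }
      seed <- ctr
    }
  }
  st <- do.call(rbind, rows)
  qc <- computeQC(st, segs, fits, thresholds)
  new("CordMorphometry", fits = fits, segmentations = segs, sliceTable = st,
      meanSca = mean(st$area), meanApw = mean(st$apw),
      meanLrw = mean(st$lrw), qc = qc,
      landmark = list(slice = landmark$slice, center = landmark$center),
      voxelSize = volume@voxelSize)
}

#' Label mask of the grown regions
#'
#' Returns a volume of the same geometry as `volume` holding 1 inside the
#' grown cord regions and 0 elsewhere, for visual inspection of the
#' segmentation (e.g. written next to the input with [writeVolume()]).
#'
#' @param morph a [CordMorphometry].
#' @param volume the [CordVolume] the morphometry was computed from.
#' @return A [CordVolume] with binary data.
#' @export
regionMask <- function(morph, volume) {
  volume <- asCanonical(volume)
  m <- array(0, dim(volume@data))
  for (seg in morph@segmentations)
    m[cbind(seg@region, seg@sliceIndex)] <- 1
  new("CordVolume", data = m, voxelSize = volume@voxelSize,
      axes = volume@axes)
}
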
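#' @rdname accessors
#' @export
setGeneric("sca", function(x) standardGeneric("sca"))

#' @rdname accessors
#' @export
setGeneric("apw", function(x) standardGeneric("apw"))

#' @rdname accessors
#' @export
setGeneric("lrw", function(x) standardGeneric("lrw"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("sliceTable", function(x) standardGeneric("sliceTable"))

#' @rdname accessors
#' @export
setGeneric("qcReport", function(x) standardGeneric("qcReport"))

#' @rdname accessors
#' @export
setGeneric("qcPass", function(x) standardGeneric("qcPass"))

#' @rdname accessors
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

## ---- accessors -------------------------------------------------------------

#' Accessors for cordmorph objects
#'
#' `sca()`, `apw()`, `lrw()` return the window-averaged cord area (mm^2) and
#' widths (mm) of a [CordMorphometry], or the analytic means of a
#' [PhantomTruth]. `voxelSize()` returns voxel dimensions in mm.
#' `sliceTable()` returns the per-slice measurement table, `truthTable()` the
#' analytic per-slice truth. `qcReport()` and `qcPass()` expose quality
#' control.
#'
#' @param x a cordmorph S4 object.
#' @return Numeric scalars/vectors, a data.frame, or a [QCReport].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("sca", "CordMorphometry", function(x) x@meanSca)
#' @rdname accessors
#' @export
setMethod("apw", "CordMorphometry", function(x) x@meanApw)
#' @rdname accessors
#' @export
setMethod("lrw", "CordMorphometry", function(x) x@meanLrw)
#' @rdname accessors
#' @export
setMethod("sca", "PhantomTruth", function(x) x@meanArea)
#' @rdname accessors
#' @export
setMethod("apw", "PhantomTruth", function(x) x@meanApw)
#' @rdname accessors
#' @export
setMethod("lrw", "PhantomTruth", function(x) x@meanLrw)
#' @rdname accessors
#' @export
setMethod("apw", "EllipseFit", function(x) x@apw)
#' @rdname accessors
#' @export
setMethod("lrw", "EllipseFit", function(x) x@lrw)
#' @rdname accessors
#' @export
setMethod("sca", "EllipseFit", function(x) x@area)
#' @rdname accessors
#' @export
setMethod("voxelSize", "CordVolume", function(x) x@voxelSize)
#' @rdname accessors
#' @export
setMethod("voxelSize", "CordMorphometry", function(x) x@voxelSize)
#' @rdname accessors
#' @export
setMethod("sliceTable", "CordMorphometry", function(x) x@sliceTable)
#' @rdname accessors
#' @export
setMethod("truthTable", "PhantomTruth", function(x) x@perSlice)
#' @rdname accessors
#' @export
setMethod("qcReport", "CordMorphometry", function(x) x@qc)
#' @rdname accessors
#' @export
setMethod("qcPass", "CordMorphometry", function(x) x@qc@pass)
#' @rdname accessors
#' @export
setMethod("qcPass", "QCReport", function(x) x@pass)

#' @rdname accessors
#' @export
setMethod("dim", "CordVolume", function(x) dim(x@data))

## ---- show methods ----------------------------------------------------------

setMethod("show", "CordVolume", function(object) {
  d <- dim(object@data)
  cat("CordVolume:", paste(d, collapse = " x "), "voxels\n")
  cat("  voxel size (mm):", paste(format(object@voxelSize), collapse = " x "),
      " axes:", paste(object@axes, collapse = ","), "\n")
  cat("  intensity range:", paste(format(range(object@data), digits = 4),
                                  collapse = " .. "), "\n")
})

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:", object@nSlices, "slices of",
      paste(object@shape, collapse = " x "), "voxels\n")
  cat("  cord/CSF/background intensity:", object@intensityCord, "/",
      object@intensityCsf, "/", object@intensityBackground, "\n")
  cat("  PSF sigma:", object@psfSigma, "mm  noise SD:", object@noiseSd,
      paste0("(", object@noiseModel, ")"), "\n")
  cat("  landmark: slice", object@landmark$slice, "centre (",
      paste(object@landmark$center, collapse = ", "), ")\n")
})

setMethod("show", "PhantomTruth", function(object) {
  cat("PhantomTruth over", length(object@window), "analysis slices\n")
  cat("  mean area:", format(object@meanArea, digits = 5), "mm^2  APW:",
      format(object@meanApw, digits = 4), "mm  LRW:",
      format(object@meanLrw, digits = 4), "mm\n")
})

setMethod("show", "SliceSegmentation", function(object) {
  cat("SliceSegmentation: slice", object@sliceIndex, "-",
      nrow(object@region), "voxels,", nrow(object@boundary),
      "boundary voxels, region mean",
      format(object@regionMean, digits = 4), "\n")
  if (object@degenerate) cat("  [degenerate: collapsed to seed]\n")
  if (object@touchesBorder) cat("  [touches field-of-view border]\n")
})

setMethod("show", "EllipseFit", function(object) {
  cat(sprintf(
    "EllipseFit (%s): area %.2f mm^2, APW %.2f mm, LRW %.2f mm\n",
    object@method, object@area, object@apw, object@lrw))
  cat(sprintf("  semi-axes %.3f / %.3f mm, orientation %.1f deg, rms %.3f mm\n",
              object@semiMajor, object@semiMinor,
              object@orientation * 180 / pi, object@rmsResidual))
})

setMethod("show", "QCReport", function(object) {
  cat("QCReport:", if (object@pass) "PASS" else "FAIL", "\n")
  if (!object@pass) {
    fl <- object@flags
    flagCols <- names(fl)[vapply(fl, is.logical, logical(1))]
    for (cn in flagCols) {
      bad <- fl$slice[fl[[cn]]]
      if (length(bad))
        cat("  ", cn, "on slice(s):", paste(bad, collapse = ", "), "\n")
    }
  }
})

setMethod("show", "CordMorphometry", function(object) {
  cat("CordMorphometry over", nrow(object@sliceTable), "axial slices\n")
  cat(sprintf("  mean SCA %.2f mm^2, APW %.2f mm, LRW %.2f mm\n",
              object@meanSca, object@meanApw, object@meanLrw))
  cat("  QC:", if (object@qc@pass) "pass" else "FAIL", "\n")
})

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:\n")
  for (g in names(object@groups)) {
    p <- object@groups[[g]]
    cat(sprintf("  %-4s n = %2d, SCA %.1f +/- %.1f mm^2, LRW/APW %.3f, NP %d\n",
                g, p$n, p$scaMean, p$scaSd, p$widthRatio, p$nNP))
  }
  cat(sprintf("  paraplegic NP multiplier %.3f, M1/pain dependence %.3f\n",
              object@painMultiplier, object@m1PainDependence))
})
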
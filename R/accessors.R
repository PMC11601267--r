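# Accessors and show methods. Slots are implementation detail; use these.

#' @rdname GradientTable-class
#' @param x,object a GradientTable or DWIVolume
#' @export
setGeneric("bvals", function(x) standardGeneric("bvals"))
#' @rdname GradientTable-class
#' @export
setGeneric("bvecs", function(x) standardGeneric("bvecs"))
#' @rdname GradientTable-class
#' @export
setGeneric("shellIds", function(x) standardGeneric("shellIds"))
#' @rdname GradientTable-class
#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))

#' @rdname GradientTable-class
#' @export
setMethod("bvals", "GradientTable", function(x) x@bvals)
#' @rdname GradientTable-class
#' @export
setMethod("bvecs", "GradientTable", function(x) x@bvecs)
#' @rdname GradientTable-class
#' @export
setMethod("shellIds", "GradientTable", function(x) x@shellIds)
#' @rdname GradientTable-class
#' @export
setMethod("nVolumes", "GradientTable", function(x) length(x@bvals))

#' @rdname DWIVolume-class
#' @param x a DWIVolume
#' @export
setGeneric("gradients", function(x) standardGeneric("gradients"))
#' @rdname DWIVolume-class
#' @export
setGeneric("dwiSignal", function(x) standardGeneric("dwiSignal"))
#' @rdname DWIVolume-class
#' @export
setMethod("gradients", "DWIVolume", function(x) x@gtab)
#' @rdname DWIVolume-class
#' @export
setMethod("dwiSignal", "DWIVolume", function(x) x@signal)
#' @rdname DWIVolume-class
#' @export
setMethod("bvals", "DWIVolume", function(x) x@gtab@bvals)
#' @rdname DWIVolume-class
#' @export
setMethod("bvecs", "DWIVolume", function(x) x@gtab@bvecs)
#' @rdname DWIVolume-class
#' @export
setMethod("nVolumes", "DWIVolume", function(x) length(x@gtab@bvals))

#' @rdname FreeWaterFit-class
#' @param x a FreeWaterFit
#' @export
setGeneric("freeWaterFraction", function(x) standardGeneric("freeWaterFraction"))
#' @rdname FreeWaterFit-class
#' @export
setMethod("freeWaterFraction", "FreeWaterFit", function(x) x@f)

#' @rdname Bundle-class
#' @param x a Bundle
#' @export
setGeneric("streamlines", function(x) standardGeneric("streamlines"))
#' @rdname Bundle-class
#' @export
setMethod("streamlines", "Bundle", function(x) x@streamlines)
#' @rdname Bundle-class
#' @export
setGeneric("nStreamlines", function(x) standardGeneric("nStreamlines"))
#' @rdname Bundle-class
#' @export
setMethod("nStreamlines", "Bundle", function(x) length(x@streamlines))

#' @rdname TractProfile-class
#' @param x a TractProfile
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))
#' @rdname TractProfile-class
#' @export
setMethod("profileValues", "TractProfile", function(x) x@values)

setMethod("show", "GradientTable", function(object) {
  sh <- table(object@shellIds)
  nominal <- vapply(names(sh), function(s) {
    round(mean(object@bvals[object@shellIds == as.integer(s)]))
  }, numeric(1))
  cat("GradientTable with", length(object@bvals), "volumes\n")
  cat("  shells (b ~ n):", paste(sprintf("%g x %d", nominal, as.integer(sh)),
                                 collapse = ", "), "\n")
})

setMethod("show", "DWIVolume", function(object) {
  d <- dim(object@signal)
  cat(sprintf("DWIVolume %d x %d x %d, %d volumes\n", d[1], d[2], d[3], d[4]))
  cat("  masks:", if (is.null(object@brainMask)) "none" else "brain",
      if (is.null(object@wmMask)) "" else "+ wm", "\n")
  show(object@gtab)
})

setMethod("show", "SplitHalfPair", function(object) {
  cat(sprintf("SplitHalfPair (seed %d, parent '%s'): %d + %d volumes\n",
              object@seed, object@parentId,
              length(object@indicesA), length(object@indicesB)))
})

setMethod("show", "FreeWaterFit", function(object) {
  fin <- object@f[object@mask]
  cat(sprintf("FreeWaterFit on %d voxels; f median %.3f [%.3f, %.3f]; %.0f%% converged\n",
              sum(object@mask), median(fin), min(fin), max(fin),
              100 * mean(object@converged[object@mask])))
})

setMethod("show", "SHField", function(object) {
  cat(sprintf("SHField lmax %d (%d coefficients) on %d voxels\n",
              object@lmax, dim(object@coef)[4], sum(object@mask)))
})

setMethod("show", "DiscretizedODFField", function(object) {
  cat(sprintf("DiscretizedODFField: 362-vertex sphere on %d voxels\n",
              sum(object@mask)))
})

setMethod("show", "Bundle", function(object) {
  cat(sprintf("Bundle '%s': %d streamlines (%d removed by cleaning)\n",
              object@name, length(object@streamlines), object@removed))
})

setMethod("show", "TractProfile", function(object) {
  cat(sprintf("TractProfile %s / %s: %d nodes, mean %.4g\n",
              object@tract, object@metric, length(object@values),
              mean(object@values, na.rm = TRUE)))
})

setMethod("show", "ReliabilityReport", function(object) {
  cat("ReliabilityReport:\n")
  cat("  voxel rows:", nrow(object@voxel), " dice rows:", nrow(object@dice),
      " icc rows:", nrow(object@icc), "\n")
  if (nrow(object@summary)) {
    cat("  summary:\n")
    print(object@summary, row.names = FALSE)
  }
})

setMethod("show", "PredictionReport", function(object) {
  cat(sprintf("PredictionReport: MAE %.3f, R^2 %.3f over %d predictions\n",
              object@mae, object@r2, nrow(object@predictions)))
  if (nrow(object@auc)) print(object@auc, row.names = FALSE)
})
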
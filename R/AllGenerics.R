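#' @describeIn RibeyeSegmentation-class binary rib eye mask accessor
#' @param object a \linkS4class{RibeyeSegmentation}
#' @export
setGeneric("ribeyeMask", function(object) standardGeneric("ribeyeMask"))
setMethod("ribeyeMask", "RibeyeSegmentation", function(object) object@mask)

#' @describeIn RibeyeSegmentation-class interior pixel count accessor
#' @export
setGeneric("ribeyeArea", function(object) standardGeneric("ribeyeArea"))
setMethod("ribeyeArea", "RibeyeSegmentation", function(object) object@areaPx)

#' @describeIn RibeyeSegmentation-class per-stage iteration counts
#' @export
setGeneric("stageIterations",
           function(object) standardGeneric("stageIterations"))
setMethod("stageIterations", "RibeyeSegmentation",
          function(object) object@stageIterations)

setMethod("show", "RibeyeSegmentation", function(object) {
  cat("RibeyeSegmentation:", paste(dim(object@mask), collapse = " x "),
      "mask,", object@areaPx, "px interior\n")
  cat("  stage iterations:",
      paste(names(object@stageIterations), object@stageIterations,
            sep = "=", collapse = ", "), "\n")
})

#' @describeIn ThicknessProfile-class profile samples as a data.frame with
#'   columns arc_position and thickness_px
#' @param object a \linkS4class{ThicknessProfile}
#' @export
setGeneric("profileSamples", function(object) standardGeneric("profileSamples"))
setMethod("profileSamples", "ThicknessProfile", function(object)
  data.frame(arc_position = object@arcPosition,
             thickness_px = object@thicknessPx))

#' @describeIn ThicknessProfile-class the 1/2 and 3/4 axis thickness marks (px)
#' @export
setGeneric("backfatMarks", function(object) standardGeneric("backfatMarks"))
setMethod("backfatMarks", "ThicknessProfile", function(object)
  c(half = object@markHalf, threequarter = object@markThreeQuarter))

setMethod("show", "ThicknessProfile", function(object) {
  cat("ThicknessProfile:", length(object@thicknessPx), "samples,",
      sprintf("marks 1/2 = %.1f px, 3/4 = %.1f px\n",
              object@markHalf, object@markThreeQuarter))
})

#' @describeIn USROI-class ROI bounds as c(x, y, side)
#' @param object a \linkS4class{USROI}
#' @export
setGeneric("roiBounds", function(object) standardGeneric("roiBounds"))
setMethod("roiBounds", "USROI", function(object)
  c(x = object@x, y = object@y, side = object@side))

#' @describeIn USROI-class detected rib centers, 2x2 matrix (x, y) rows
#' @export
setGeneric("ribPositions", function(object) standardGeneric("ribPositions"))
setMethod("ribPositions", "USROI", function(object) object@ribPositions)

setMethod("show", "USROI", function(object) {
  cat(sprintf("USROI: %dx%d at (x=%d, y=%d); ribs at x = %s; fat rows %d-%d\n",
              object@side, object@side, object@x, object@y,
              paste(round(object@ribPositions[, 1]), collapse = ", "),
              object@fatRows[1], object@fatRows[2]))
})

#' @describeIn PCAModel-class loading matrix accessor
#' @param object a \linkS4class{PCAModel}
#' @export
setGeneric("pcaLoadings", function(object) standardGeneric("pcaLoadings"))
setMethod("pcaLoadings", "PCAModel", function(object) object@loadings)

#' @describeIn PCAModel-class explained-variance ratios accessor
#' @export
setGeneric("explainedVariance",
           function(object) standardGeneric("explainedVariance"))
setMethod("explainedVariance", "PCAModel",
          function(object) object@explainedVarianceRatio)

setMethod("show", "PCAModel", function(object) {
  cat(sprintf("PCAModel: %d -> %d components, %.1f%% variance retained\n",
              nrow(object@loadings), ncol(object@loadings),
              100 * sum(object@explainedVarianceRatio)))
})

setMethod("show", "IMFModel", function(object) {
  if (is.na(object@constant))
    cat(sprintf(
      "IMFModel: RBF SVR on %d PCA components (gamma = %.4g, tol = %.1e)\n",
      ncol(object@pca@loadings), object@gamma, object@tolerance))
  else
    cat(sprintf("IMFModel: constant predictor (%.3f)\n", object@constant))
})

#' @describeIn SteakPhantom-class rendered image accessor
#' @param object a phantom object
#' @export
setGeneric("phantomImage", function(object) standardGeneric("phantomImage"))
setMethod("phantomImage", "SteakPhantom", function(object) object@image)
#' @describeIn USPhantom-class rendered frame accessor
#' @export
setMethod("phantomImage", "USPhantom", function(object) object@image)

#' @describeIn SteakPhantom-class ground-truth list accessor
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
setMethod("groundTruth", "SteakPhantom", function(object) object@truth)
#' @describeIn USPhantom-class ground-truth list accessor
#' @export
setMethod("groundTruth", "USPhantom", function(object) object@truth)

setMethod("show", "SteakPhantom", function(object) {
  d <- dim(object@image)
  cat(sprintf("SteakPhantom: %dx%d, rib eye area %d px (seed %s)\n",
              d[1], d[2], object@truth$areaPx,
              as.character(object@spec$seed)))
})

setMethod("show", "USPhantom", function(object) {
  d <- dim(object@image)
  cat(sprintf("USPhantom: %dx%d, imf scalar %.2f (seed %s)\n",
              d[1], d[2], object@spec$imfScalar,
              as.character(object@spec$seed)))
})
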
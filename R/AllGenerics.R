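#' @rdname MorphImage-class
#' @param object,x a `MorphImage`.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname MorphImage-class
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))

#' @rdname MorphImage-class
#' @export
setGeneric("pixelSizeUm", function(x) standardGeneric("pixelSizeUm"))

#' @rdname QuantizedROI-class
#' @param x a `QuantizedROI`.
#' @export
setGeneric("grayLevels", function(x) standardGeneric("grayLevels"))

#' @rdname QuantizedROI-class
#' @export
setGeneric("nGrayLevels", function(x) standardGeneric("nGrayLevels"))

#' @rdname QuantizedROI-class
#' @export
setGeneric("roiMask", function(x) standardGeneric("roiMask"))

#' @rdname FeatureSelection-class
#' @param x a `FeatureSelection`.
#' @export
setGeneric("retainedFeatures", function(x) standardGeneric("retainedFeatures"))

#' @rdname FeatureSelection-class
#' @export
setGeneric("featureRanking", function(x) standardGeneric("featureRanking"))

#' @export
#' @rdname EvalReport-class
#' @param x an `EvalReport`.
setGeneric("cvAccuracy", function(x) standardGeneric("cvAccuracy"))

#' @export
#' @rdname EvalReport-class
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))

#' @export
#' @rdname EvalReport-class
setGeneric("perClassMetrics", function(x) standardGeneric("perClassMetrics"))

#' @export
#' @rdname EvalReport-class
setGeneric("aucTable", function(x) standardGeneric("aucTable"))

# ---- accessor methods ----

#' @rdname MorphImage-class
#' @export
setMethod("pixels", "MorphImage", function(x) x@pixels)

#' @rdname MorphImage-class
#' @export
setMethod("bitDepth", "MorphImage", function(x) x@bitDepth)

#' @rdname MorphImage-class
#' @export
setMethod("pixelSizeUm", "MorphImage", function(x) x@pixelSizeUm)

#' @rdname MorphImage-class
#' @export
setMethod("dim", "MorphImage", function(x) dim(x@pixels))

#' @rdname QuantizedROI-class
#' @export
setMethod("grayLevels", "QuantizedROI", function(x) x@levels)

#' @rdname QuantizedROI-class
#' @export
setMethod("nGrayLevels", "QuantizedROI", function(x) x@ng)

#' @rdname QuantizedROI-class
#' @export
setMethod("roiMask", "QuantizedROI", function(x) x@mask)

#' @rdname FeatureSelection-class
#' @export
setMethod("retainedFeatures", "FeatureSelection", function(x) x@retained)

#' @rdname FeatureSelection-class
#' @export
setMethod("featureRanking", "FeatureSelection", function(x) x@ranking)

#' @rdname EvalReport-class
#' @export
setMethod("cvAccuracy", "EvalReport", function(x) x@accuracy)

#' @rdname EvalReport-class
#' @export
setMethod("confusionMatrix", "EvalReport", function(x) x@confusion)

#' @rdname EvalReport-class
#' @export
setMethod("perClassMetrics", "EvalReport", function(x) x@perClass)

#' @rdname EvalReport-class
#' @export
setMethod("aucTable", "EvalReport", function(x) x@auc)

# ---- show methods ----

setMethod("show", "MorphImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf(
    "MorphImage %dx%d, %d-bit, pixel size %s um\n", d[1], d[2],
    object@bitDepth,
    if (is.na(object@pixelSizeUm)) "unknown" else format(object@pixelSizeUm)
  ))
  cat(sprintf(
    "  intensity range [%g, %g]\n",
    min(object@pixels), max(object@pixels)
  ))
})

setMethod("show", "QuantizedROI", function(object) {
  cat(sprintf(
    "QuantizedROI %dx%d, Ng = %d, %d masked-in pixels\n",
    nrow(object@levels), ncol(object@levels), object@ng, sum(object@mask)
  ))
})

setMethod("show", "FeatureSelection", function(object) {
  cat(sprintf(
    "FeatureSelection: %d of %d features retained\n",
    length(object@retained), nrow(object@ranking)
  ))
  cat("  top:", paste(utils::head(object@retained, 5L), collapse = ", "),
      "...\n")
})

setMethod("show", "TrainedModel", function(object) {
  cat(sprintf(
    "TrainedModel <%s>: %d classes (%s), %d features\n",
    object@kind, length(object@classes),
    paste(object@classes, collapse = "/"), length(object@features)
  ))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf(
    "EvalReport: accuracy %.3f +/- %.3f over %d folds\n",
    object@accuracy[["mean"]], object@accuracy[["sd"]],
    length(object@foldAccuracy)
  ))
  if (nrow(object@auc)) {
    m <- object@auc[object@auc$class == "macro", , drop = FALSE]
    if (nrow(m)) cat(sprintf("  macro AUC %.3f\n", m$auc[1]))
  }
})
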
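#' @import methods
#' @importFrom stats median predict quantile sd var
NULL

#' MorphImage: a 2D grayscale microscopy raster
#'
#' Container for a single-channel 2D image. Intensities are stored as a
#' numeric matrix; the declared bit depth fixes the dynamic range
#' \eqn{[0, 2^{bits}-1]} used by the contrast operations. Pre-processing
#' stages keep fractional (floating point) intensities within that range;
#' integer quantization happens only when a chain ends or the image is
#' written to disk.
#'
#' @slot pixels numeric matrix of intensities, all within
#'   \eqn{[0, 2^{bitDepth}-1]}.
#' @slot bitDepth integer, 8 or 16.
#' @slot pixelSizeUm numeric(1), physical pixel edge length in micrometers,
#'   or `NA` when unknown. High-resolution confocal data in this domain is
#'   commonly sampled at 0.035 um/px.
#'
#' @examples
#' img <- MorphImage(matrix(0:255, 16, 16), bitDepth = 8L)
#' dim(pixels(img))
#' @export
setClass("MorphImage",
  representation(
    pixels = "matrix",
    bitDepth = "integer",
    pixelSizeUm = "numeric"
  ),
  prototype(bitDepth = 8L, pixelSizeUm = NA_real_)
)

setValidity("MorphImage", function(object) {
  msg <- character()
  p <- object@pixels
  if (!is.numeric(p)) msg <- c(msg, "pixels must be a numeric matrix")
  if (nrow(p) < 1L || ncol(p) < 1L) msg <- c(msg, "image must be at least 1x1")
  if (!(object@bitDepth %in% c(8L, 16L))) {
    msg <- c(msg, "bitDepth must be 8 or 16")
  }
  if (is.numeric(p) && length(p)) {
    if (anyNA(p)) msg <- c(msg, "pixels must be finite")
    else {
      hi <- 2^object@bitDepth - 1
      if (min(p) < 0 || max(p) > hi) {
        msg <- c(msg, sprintf("intensities must lie in [0, %d]", hi))
      }
    }
  }
  if (length(object@pixelSizeUm) != 1L ||
      (!is.na(object@pixelSizeUm) && object@pixelSizeUm <= 0)) {
    msg <- c(msg, "pixelSizeUm must be a single positive value or NA")
  }
  if (length(msg)) msg else TRUE
})

#' @param pixels numeric matrix of intensities.
#' @param bitDepth 8 or 16.
#' @param pixelSizeUm physical pixel size in micrometers (optional).
#' @rdname MorphImage-class
#' @export
MorphImage <- function(pixels, bitDepth = 8L, pixelSizeUm = NA_real_) {
  new("MorphImage",
    pixels = as.matrix(pixels),
    bitDepth = as.integer(bitDepth),
    pixelSizeUm = as.numeric(pixelSizeUm)
  )
}

#' QuantizedROI: gray-level discretized region of interest
#'
#' Integer gray levels `1..Ng` shared by all texture-matrix computations,
#' together with the pixel mask they were computed under. Pixels outside
#' the mask carry `NA` and never participate in pairs, runs, zones or
#' neighborhoods.
#'
#' @slot levels integer matrix; `NA` outside the mask, values in `1..ng`
#'   inside.
#' @slot ng integer, number of gray levels covered.
#' @slot mask logical matrix, same shape as `levels`.
#' @slot binWidth numeric, the intensity width of one gray level
#'   (`NA` for fixed-bin-count quantization).
#' @export
setClass("QuantizedROI",
  representation(
    levels = "matrix",
    ng = "integer",
    mask = "matrix",
    binWidth = "numeric"
  )
)

setValidity("QuantizedROI", function(object) {
  msg <- character()
  lv <- object@levels
  mk <- object@mask
  if (!identical(dim(lv), dim(mk))) msg <- c(msg, "levels/mask shape mismatch")
  if (!is.logical(mk)) msg <- c(msg, "mask must be logical")
  inside <- lv[mk]
  if (length(inside)) {
    if (anyNA(inside)) msg <- c(msg, "masked-in levels must be defined")
    else {
      if (min(inside) < 1L) msg <- c(msg, "gray levels start at 1")
      if (max(inside) > object@ng) msg <- c(msg, "levels exceed ng")
    }
  } else {
    msg <- c(msg, "mask is empty")
  }
  if (object@ng < 1L) msg <- c(msg, "ng must be >= 1")
  if (length(msg)) msg else TRUE
})

#' FeatureSelection: result of recursive feature elimination
#'
#' @slot ranking data.frame with columns `feature`, `rank` (1 = most
#'   important), `retained`.
#' @slot retained character vector of the retained feature names, in rank
#'   order.
#' @slot accuracyCurve data.frame with columns `n_features`, `cv_accuracy`
#'   (empty when the accuracy curve was not requested).
#' @export
setClass("FeatureSelection",
  representation(
    ranking = "data.frame",
    retained = "character",
    accuracyCurve = "data.frame"
  )
)

setValidity("FeatureSelection", function(object) {
  msg <- character()
  if (!all(c("feature", "rank", "retained") %in% names(object@ranking))) {
    msg <- c(msg, "ranking must have feature/rank/retained columns")
  }
  if (!all(object@retained %in% object@ranking$feature)) {
    msg <- c(msg, "retained features must appear in the ranking")
  }
  if (anyDuplicated(object@retained)) msg <- c(msg, "duplicated retained feature")
  if (length(msg)) msg else TRUE
})

#' TrainedModel: a fitted morphology classifier
#'
#' Wraps a fitted decision tree or one-vs-rest SVM together with everything
#' needed to score new feature tables: the class label order (which also
#' fixes tie-breaking), the standardization learned on the training data,
#' and the retained feature set.
#'
#' @slot kind `"dt"` or `"ovr-svm"`.
#' @slot fit the underlying fit (an `rpart` tree, or a named list of binary
#'   `e1071::svm` fits, one per class).
#' @slot classes character, class labels in fixed order; prediction ties go
#'   to the earlier label.
#' @slot scaler per-feature `center`/`scale` list, or empty list when no
#'   standardization is applied (decision trees).
#' @slot features character, feature names in the order the model consumes.
#' @slot threshold numeric, decision threshold for the two-class decision
#'   tree mode (default 0.5).
#' @slot params list of hyperparameters recorded at fit time.
#' @export
setClass("TrainedModel",
  representation(
    kind = "character",
    fit = "ANY",
    classes = "character",
    scaler = "list",
    features = "character",
    threshold = "numeric",
    params = "list"
  ),
  prototype(threshold = 0.5, params = list())
)

setValidity("TrainedModel", function(object) {
  msg <- character()
  if (!(object@kind %in% c("dt", "ovr-svm"))) {
    msg <- c(msg, "kind must be 'dt' or 'ovr-svm'")
  }
  if (length(object@classes) < 2L) msg <- c(msg, "need >= 2 classes")
  if (anyDuplicated(object@features)) msg <- c(msg, "duplicated feature name")
  if (length(msg)) msg else TRUE
})

#' EvalReport: cross-validated classification performance
#'
#' @slot accuracy named numeric: `mean` and `sd` of accuracy across
#'   folds/repeats.
#' @slot foldAccuracy numeric vector, one accuracy per evaluated fold.
#' @slot confusion integer matrix of pooled test-fold counts
#'   (rows = true class, columns = predicted class).
#' @slot perClass data.frame: `class`, `precision`, `recall`, `f1`,
#'   `support`, `undefined` flag for zero-division conventions.
#' @slot auc data.frame: per-class one-vs-rest AUC with bootstrap CI bounds,
#'   plus a `macro` row (empty if ROC analysis was not run).
#' @slot details list: scores, labels and settings kept for downstream ROC
#'   plotting.
#' @export
setClass("EvalReport",
  representation(
    accuracy = "numeric",
    foldAccuracy = "numeric",
    confusion = "matrix",
    perClass = "data.frame",
    auc = "data.frame",
    details = "list"
  ),
  prototype(details = list())
)

setValidity("EvalReport", function(object) {
  msg <- character()
  cm <- object@confusion
  if (length(cm) && nrow(cm) != ncol(cm)) msg <- c(msg, "confusion must be square")
  pc <- object@perClass
  if (nrow(pc)) {
    vals <- unlist(pc[c("precision", "recall", "f1")])
    if (any(vals < -1e-12 | vals > 1 + 1e-12)) {
      msg <- c(msg, "precision/recall/f1 must lie in [0,1]")
    }
  }
  if (length(msg)) msg else TRUE
})
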
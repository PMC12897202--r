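# Assembly of the full 93-feature descriptor: 18 first-order + 24 GLCM +
# 14 GLDM + 16 GLRLM + 16 GLSZM + 5 NGTDM features per ROI, computed from
# one shared quantization. Feature columns are named <family>_<Feature>,
# families in fixed order (firstorder, glcm, gldm, glrlm, glszm, ngtdm) and
# alphabetical within each family, so tables diff cleanly across runs.

#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
NULL

.FEATURE_FAMILIES <- c("firstorder", "glcm", "gldm", "glrlm", "glszm",
                       "ngtdm")

#' Canonical names of the 93 features
#'
#' @return character vector of length 93 in the canonical column order.
#' @export
featureNames93 <- function() {
  c(
    paste0("firstorder_", .FIRSTORDER_NAMES),
    paste0("glcm_", .GLCM_NAMES),
    paste0("gldm_", .GLDM_NAMES),
    paste0("glrlm_", .GLRLM_NAMES),
    paste0("glszm_", .GLSZM_NAMES),
    paste0("ngtdm_", .NGTDM_NAMES)
  )
}

#' Feature-extraction configuration
#'
#' @param binWidth gray-level bin width for the fixed-bin-width dialect.
#' @param dialect `"fixedBinWidth"` (default) or `"fixedBinCount"`.
#' @param nBins bin count for the fixed-bin-count dialect.
#' @param distance GLCM pixel distance.
#' @param alpha GLDM dependence tolerance.
#' @return named list of validated settings.
#' @export
featureConfig <- function(binWidth = 25, dialect = c("fixedBinWidth",
                                                     "fixedBinCount"),
                          nBins = 32L, distance = 1L, alpha = 0) {
  dialect <- match.arg(dialect)
  stopifnot(binWidth > 0, nBins >= 2L, distance >= 1L, alpha >= 0)
  list(
    binWidth = binWidth, dialect = dialect, nBins = as.integer(nBins),
    distance = as.integer(distance), alpha = alpha
  )
}

#' Extract the full 93-feature vector from one ROI
#'
#' Quantization is performed once and shared by all five texture-matrix
#' families; first-order features are computed on the raw intensities
#' (with the same discretization for the histogram-shape features).
#'
#' @param roi a [MorphImage] or numeric matrix.
#' @param config a [featureConfig()] list.
#' @param mask optional logical matrix.
#' @return named numeric vector of exactly 93 features.
#' @export
extractAllFeatures <- function(roi, config = featureConfig(), mask = NULL) {
  q <- if (config$dialect == "fixedBinWidth") {
    quantizeFixedBinWidth(roi, config$binWidth, mask)
  } else {
    quantizeFixedBinCount(roi, config$nBins, mask)
  }
  out <- c(
    firstorderFeatures(roi, mask, binWidth = config$binWidth),
    glcmFeatures(q, config$distance),
    gldmFeatures(q, config$alpha),
    glrlmFeatures(q),
    glszmFeatures(q),
    ngtdmFeatures(q)
  )
  names(out) <- featureNames93()
  out
}

#' Build a feature table from a list of ROIs
#'
#' @param rois list of [MorphImage] (or numeric matrix) ROIs.
#' @param classLabels character vector of class labels, one per ROI.
#' @param roiIds optional character IDs (default `roi_0001`, ...).
#' @param config a [featureConfig()] list, recorded in the metadata.
#' @param preprocess optional [preprocessConfig()]; when given, each ROI is
#'   run through [preprocessImage()] before extraction and the settings are
#'   recorded in the metadata.
#' @param seed optional integer recorded in the metadata (provenance only;
#'   extraction itself is deterministic).
#' @return a [SummarizedExperiment::SummarizedExperiment] with one assay
#'   `"features"` (93 rows, one column per ROI) and `colData` columns
#'   `roi_id` and `class_label`.
#' @export
extractFeatureTable <- function(rois, classLabels, roiIds = NULL,
                                config = featureConfig(),
                                preprocess = NULL, seed = NULL) {
  n <- length(rois)
  stopifnot(n >= 1L, length(classLabels) == n)
  if (is.null(roiIds)) roiIds <- sprintf("roi_%04d", seq_len(n))
  stopifnot(!anyDuplicated(roiIds))
  mat <- matrix(NA_real_, length(featureNames93()), n,
                dimnames = list(featureNames93(), roiIds))
  for (k in seq_len(n)) {
    roi <- rois[[k]]
    if (!is.null(preprocess)) roi <- preprocessImage(roi, preprocess)
    mat[, k] <- tryCatch(
      extractAllFeatures(roi, config),
      error = function(e) {
        stop("feature extraction failed for ROI '", roiIds[k], "': ",
             conditionMessage(e))
      }
    )
  }
  SummarizedExperiment(
    assays = list(features = mat),
    colData = DataFrame(
      roi_id = roiIds,
      class_label = as.character(classLabels),
      row.names = roiIds
    ),
    metadata = list(
      quantization = config,
      preprocess = preprocess,
      seed = seed
    )
  )
}

#' Feature matrix in samples-by-features orientation
#'
#' @param se a feature table from [extractFeatureTable()].
#' @return numeric matrix, one row per ROI, one column per feature.
#' @export
featureMatrix <- function(se) {
  t(assay(se, "features"))
}

#' Class labels of a feature table
#' @param se a feature table.
#' @return character vector of labels.
#' @export
classLabels <- function(se) {
  as.character(colData(se)$class_label)
}

#' Write a feature table to CSV (plus a JSON metadata sidecar)
#'
#' The CSV has columns `roi_id`, `class_label`, then the 93 features in
#' canonical order. Extraction settings are written to `<path>.meta.json`.
#'
#' @param se a feature table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(se, path) {
  df <- data.frame(
    roi_id = colData(se)$roi_id,
    class_label = colData(se)$class_label,
    featureMatrix(se),
    check.names = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  meta <- metadata(se)
  jsonlite::write_json(
    meta[!vapply(meta, is.null, logical(1))],
    paste0(path, ".meta.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a feature table written by [writeFeatureTable()]
#'
#' @param path CSV path.
#' @return a [SummarizedExperiment::SummarizedExperiment]; the metadata
#'   sidecar is restored when present.
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  stopifnot(all(c("roi_id", "class_label") %in% names(df)))
  featCols <- setdiff(names(df), c("roi_id", "class_label"))
  mat <- t(as.matrix(df[, featCols, drop = FALSE]))
  colnames(mat) <- df$roi_id
  metaPath <- paste0(path, ".meta.json")
  meta <- if (file.exists(metaPath)) {
    jsonlite::read_json(metaPath, simplifyVector = TRUE)
  } else {
    list()
  }
  SummarizedExperiment(
    assays = list(features = mat),
    colData = DataFrame(
      roi_id = df$roi_id,
      class_label = as.character(df$class_label),
      row.names = df$roi_id
    ),
    metadata = meta
  )
}
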
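# First-order (histogram) statistics of the raw ROI intensities. The two
# histogram-shape features (Entropy, Uniformity) are computed on the same
# fixed-bin-width discretization used by the texture matrices. Moments are
# population (biased) moments; kurtosis is non-excess (normal => 3); both
# fall back to 0 for a zero-variance ROI.

.FIRSTORDER_NAMES <- c(
  "10Percentile", "90Percentile", "Energy", "Entropy", "InterquartileRange",
  "Kurtosis", "Maximum", "Mean", "MeanAbsoluteDeviation", "Median",
  "Minimum", "Range", "RobustMeanAbsoluteDeviation", "RootMeanSquared",
  "Skewness", "TotalEnergy", "Uniformity", "Variance"
)

#' First-order intensity statistics (18 features)
#'
#' @param roi a [MorphImage] or numeric matrix.
#' @param mask optional logical matrix; defaults to all pixels.
#' @param binWidth intensity bin width for the discretized-histogram
#'   features (Entropy, Uniformity); default 25.
#' @param pixelAreaUm2 physical pixel area used by TotalEnergy; defaults to
#'   `pixelSizeUm^2` when the image records a pixel size, else 1.
#' @return named numeric vector of the 18 first-order features.
#' @export
firstorderFeatures <- function(roi, mask = NULL, binWidth = 25,
                               pixelAreaUm2 = NULL) {
  x <- .asPixelMatrix(roi)
  if (is.null(pixelAreaUm2)) {
    ps <- if (is(roi, "MorphImage")) roi@pixelSizeUm else NA_real_
    pixelAreaUm2 <- if (is.na(ps)) 1 else ps^2
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(x), ncol(x))
  v <- x[mask]
  if (!length(v)) stop("empty mask")

  # discretized histogram for Entropy / Uniformity
  lv <- floor(v / binWidth) - floor(min(v) / binWidth) + 1
  p <- tabulate(lv, max(lv))
  p <- p[p > 0] / length(v)

  mu <- mean(v)
  qs <- .q(v, c(0.10, 0.25, 0.50, 0.75, 0.90))
  inRobust <- v >= qs[1] & v <= qs[5]
  sk <- .popSkewKurt(v)
  energy <- sum(v^2)

  out <- c(
    qs[1], qs[5], energy, -sum(p * .log2e(p)), qs[4] - qs[2],
    sk[["kurtosis"]], max(v), mu, mean(abs(v - mu)), qs[3],
    min(v), max(v) - min(v),
    mean(abs(v[inRobust] - mean(v[inRobust]))), sqrt(mean(v^2)),
    sk[["skewness"]], energy * pixelAreaUm2, sum(p^2),
    mean((v - mu)^2)
  )
  names(out) <- .FIRSTORDER_NAMES
  out
}
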
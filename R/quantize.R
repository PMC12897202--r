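# Gray-level discretization shared by all texture-matrix computations.
# The default dialect is fixed bin width (absolute intensity units), which
# keeps the level <-> intensity correspondence comparable across ROIs;
# fixed bin count (relative, per-ROI range) is offered as an alternative.

.asPixelMatrix <- function(x) {
  if (is(x, "MorphImage")) x@pixels else as.matrix(x)
}

#' Quantize an ROI with a fixed intensity bin width
#'
#' Gray level of a pixel with intensity `x` is
#' `floor(x / binWidth) - floor(min / binWidth) + 1`, where `min` is the
#' smallest masked-in intensity, so levels start at 1 and adding any whole
#' number of bin widths to the image leaves the levels unchanged.
#'
#' @param roi a [MorphImage] or numeric matrix.
#' @param binWidth positive intensity width of one gray level (default 25,
#'   the conventional radiomics default for 8-bit fluorescence data).
#' @param mask optional logical matrix; defaults to all pixels.
#' @return a [QuantizedROI].
#' @export
quantizeFixedBinWidth <- function(roi, binWidth = 25, mask = NULL) {
  stopifnot(binWidth > 0)
  x <- .asPixelMatrix(roi)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(x), ncol(x))
  stopifnot(identical(dim(mask), dim(x)))
  if (!any(mask)) stop("empty mask")
  base <- floor(min(x[mask]) / binWidth)
  lv <- matrix(NA_integer_, nrow(x), ncol(x))
  lv[mask] <- as.integer(floor(x[mask] / binWidth) - base + 1)
  new("QuantizedROI",
    levels = lv, ng = max(lv[mask]), mask = mask,
    binWidth = as.numeric(binWidth)
  )
}

#' Quantize an ROI into a fixed number of equal-width bins
#'
#' Equal-width bins span the masked intensity range; the top edge is
#' inclusive. A constant ROI cannot be split and yields a single level
#' with a warning.
#'
#' @param roi a [MorphImage] or numeric matrix.
#' @param nBins number of gray levels (>= 2).
#' @param mask optional logical matrix; defaults to all pixels.
#' @return a [QuantizedROI] with `binWidth = NA` semantics replaced by the
#'   realized bin width `(max - min) / nBins`.
#' @export
quantizeFixedBinCount <- function(roi, nBins = 32L, mask = NULL) {
  stopifnot(nBins >= 2L)
  x <- .asPixelMatrix(roi)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(x), ncol(x))
  stopifnot(identical(dim(mask), dim(x)))
  if (!any(mask)) stop("empty mask")
  v <- x[mask]
  rng <- range(v)
  lv <- matrix(NA_integer_, nrow(x), ncol(x))
  if (rng[1] == rng[2]) {
    warning("constant ROI: all pixels assigned level 1")
    lv[mask] <- 1L
    return(new("QuantizedROI",
      levels = lv, ng = 1L, mask = mask, binWidth = NA_real_
    ))
  }
  w <- (rng[2] - rng[1]) / nBins
  lv[mask] <- pmin(as.integer(floor((v - rng[1]) / w)) + 1L, as.integer(nBins))
  new("QuantizedROI",
    levels = lv, ng = as.integer(nBins), mask = mask, binWidth = w
  )
}
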
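# Gray-level run-length matrix features. A run is a maximal collinear
# sequence of equal-level pixels along one of four directions (horizontal,
# vertical, both diagonals); masked-out pixels break runs. One run-length
# matrix per direction; the 16 features are computed per direction and
# averaged.

.GLRLM_NAMES <- c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelRunEmphasis",
  "LongRunEmphasis", "LongRunHighGrayLevelEmphasis",
  "LongRunLowGrayLevelEmphasis", "LowGrayLevelRunEmphasis",
  "RunEntropy", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage",
  "RunVariance", "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
  "ShortRunLowGrayLevelEmphasis"
)

# scan lines of a matrix along a direction: list of integer vectors
# (NA where masked out)
.scanLines <- function(lv, direction) {
  nr <- nrow(lv)
  nc <- ncol(lv)
  switch(direction,
    horizontal = lapply(seq_len(nr), function(r) lv[r, ]),
    vertical = lapply(seq_len(nc), function(cc) lv[, cc]),
    # diagonal: constant (col - row); runs go down-right
    diag = {
      d <- col(lv) - row(lv)
      lapply(split(seq_along(lv)[order(d, row(lv))], sort(as.vector(d))),
             function(ix) lv[ix])
    },
    # antidiagonal: constant (col + row); runs go down-left
    antidiag = {
      d <- col(lv) + row(lv)
      lapply(split(seq_along(lv)[order(d, row(lv))], sort(as.vector(d))),
             function(ix) lv[ix])
    }
  )
}

# run-length count matrix (ng x maxRunLen) for one direction
.glrlmCount <- function(q, direction) {
  lv <- q@levels
  ng <- q@ng
  maxLen <- max(dim(lv))
  M <- matrix(0, ng, maxLen)
  for (line in .scanLines(lv, direction)) {
    r <- rle(as.vector(line))
    keep <- !is.na(r$values)
    if (!any(keep)) next
    idx <- cbind(r$values[keep], r$lengths[keep])
    for (k in seq_len(nrow(idx))) {
      M[idx[k, 1], idx[k, 2]] <- M[idx[k, 1], idx[k, 2]] + 1
    }
  }
  M
}

# the 16 features of one run-length count matrix
.glrlmFeaturesOne <- function(M, np) {
  nr <- sum(M)
  if (nr == 0) stop("no runs")
  i <- row(M)
  j <- col(M)
  p <- M / nr
  pg <- rowSums(p)
  pr <- colSums(p)
  mug <- sum(seq_along(pg) * pg)
  mur <- sum(seq_along(pr) * pr)
  out <- c(
    GrayLevelNonUniformity = sum(rowSums(M)^2) / nr,
    GrayLevelNonUniformityNormalized = sum(rowSums(M)^2) / nr^2,
    GrayLevelVariance = sum((seq_along(pg) - mug)^2 * pg),
    HighGrayLevelRunEmphasis = sum(M * i^2) / nr,
    LongRunEmphasis = sum(M * j^2) / nr,
    LongRunHighGrayLevelEmphasis = sum(M * i^2 * j^2) / nr,
    LongRunLowGrayLevelEmphasis = sum(M * j^2 / i^2) / nr,
    LowGrayLevelRunEmphasis = sum(M / i^2) / nr,
    RunEntropy = -sum(p * .log2e(p) * (p > 0)),
    RunLengthNonUniformity = sum(colSums(M)^2) / nr,
    RunLengthNonUniformityNormalized = sum(colSums(M)^2) / nr^2,
    RunPercentage = nr / np,
    RunVariance = sum((seq_along(pr) - mur)^2 * pr),
    ShortRunEmphasis = sum(M / j^2) / nr,
    ShortRunHighGrayLevelEmphasis = sum(M * i^2 / j^2) / nr,
    ShortRunLowGrayLevelEmphasis = sum(M / (i^2 * j^2)) / nr
  )
  out[.GLRLM_NAMES]
}

#' GLRLM texture features (16 features)
#'
#' Run-length matrices are built over four directions and the features
#' averaged across directions. `RunPercentage` uses the masked pixel count
#' as the denominator.
#'
#' @param q a [QuantizedROI].
#' @return named numeric vector of 16 features.
#' @export
glrlmFeatures <- function(q) {
  stopifnot(is(q, "QuantizedROI"))
  np <- sum(q@mask)
  per <- vapply(
    c("horizontal", "vertical", "diag", "antidiag"),
    function(d) .glrlmFeaturesOne(.glrlmCount(q, d), np),
    numeric(length(.GLRLM_NAMES))
  )
  rowMeans(per)
}
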
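# Gray-level dependence matrix features. A neighbor (8-connectivity,
# distance 1) is "dependent" on the center pixel when the absolute level
# difference is at most alpha; the dependence size of a pixel is
# j = 1 + (number of dependent neighbors), i.e. the center pixel counts
# itself. P(i, j) counts pixels of level i with dependence size j, so row
# sums equal per-level pixel counts.

.GLDM_NAMES <- c(
  "DependenceEntropy", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "DependenceVariance",
  "GrayLevelNonUniformity", "GrayLevelVariance", "HighGrayLevelEmphasis",
  "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
  "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
  "SmallDependenceLowGrayLevelEmphasis"
)

#' Gray-level dependence matrix
#'
#' @param q a [QuantizedROI].
#' @param alpha gray-level tolerance for dependence (default 0: neighbors
#'   must have exactly the center's level).
#' @return Ng x 9 count matrix (dependence sizes 1..9 in 2D).
#' @export
gldmMatrix <- function(q, alpha = 0) {
  stopifnot(is(q, "QuantizedROI"), alpha >= 0)
  lv <- q@levels
  ng <- q@ng
  nr <- nrow(lv)
  nc <- ncol(lv)
  dep <- matrix(0L, nr, nc)
  for (dr in -1L:1L) {
    for (dc in -1L:1L) {
      if (dr == 0L && dc == 0L) next
      r0 <- max(1L, 1L - dr); r1 <- min(nr, nr - dr)
      c0 <- max(1L, 1L - dc); c1 <- min(nc, nc - dc)
      if (r0 > r1 || c0 > c1) next
      a <- lv[r0:r1, c0:c1, drop = FALSE]
      b <- lv[(r0 + dr):(r1 + dr), (c0 + dc):(c1 + dc), drop = FALSE]
      hit <- !is.na(a) & !is.na(b) & abs(a - b) <= alpha
      dep[r0:r1, c0:c1] <- dep[r0:r1, c0:c1] + hit
    }
  }
  ok <- !is.na(lv)
  j <- dep[ok] + 1L
  i <- lv[ok]
  M <- matrix(tabulate((j - 1L) * ng + i, ng * 9L), ng, 9L)
  M
}

#' GLDM texture features (14 features)
#'
#' @param q a [QuantizedROI].
#' @param alpha dependence tolerance (default 0).
#' @return named numeric vector of 14 features.
#' @export
gldmFeatures <- function(q, alpha = 0) {
  M <- gldmMatrix(q, alpha)
  nz <- sum(M)
  i <- row(M)
  j <- col(M)
  p <- M / nz
  pg <- rowSums(p)
  pd <- colSums(p)
  mug <- sum(seq_along(pg) * pg)
  mud <- sum(seq_along(pd) * pd)
  out <- c(
    DependenceEntropy = -sum(p * .log2e(p) * (p > 0)),
    DependenceNonUniformity = sum(colSums(M)^2) / nz,
    DependenceNonUniformityNormalized = sum(colSums(M)^2) / nz^2,
    DependenceVariance = sum((seq_along(pd) - mud)^2 * pd),
    GrayLevelNonUniformity = sum(rowSums(M)^2) / nz,
    GrayLevelVariance = sum((seq_along(pg) - mug)^2 * pg),
    HighGrayLevelEmphasis = sum(M * i^2) / nz,
    LargeDependenceEmphasis = sum(M * j^2) / nz,
    LargeDependenceHighGrayLevelEmphasis = sum(M * i^2 * j^2) / nz,
    LargeDependenceLowGrayLevelEmphasis = sum(M * j^2 / i^2) / nz,
    LowGrayLevelEmphasis = sum(M / i^2) / nz,
    SmallDependenceEmphasis = sum(M / j^2) / nz,
    SmallDependenceHighGrayLevelEmphasis = sum(M * i^2 / j^2) / nz,
    SmallDependenceLowGrayLevelEmphasis = sum(M / (i^2 * j^2)) / nz
  )
  out[.GLDM_NAMES]
}
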
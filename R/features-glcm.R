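# Gray-level co-occurrence matrix features. Four 2D angles at a fixed
# pixel distance, symmetric matrices (count + transpose), features computed
# per angle and averaged. Entropies are base-2 with an epsilon guard inside
# the logarithm. Degenerate conventions: Correlation = 1 when a marginal
# variance vanishes; MCC = 1 when fewer than two occupied levels.

.GLCM_NAMES <- c(
  "Autocorrelation", "ClusterProminence", "ClusterShade", "ClusterTendency",
  "Contrast", "Correlation", "DifferenceAverage", "DifferenceEntropy",
  "DifferenceVariance", "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2",
  "InverseVariance", "JointAverage", "JointEnergy", "JointEntropy",
  "MCC", "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares"
)

# offsets (drow, dcol) for angles 0, 45, 90, 135 degrees
.GLCM_OFFSETS <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))

# Count co-occurrences of quantized levels for one offset; returns the
# symmetrized Ng x Ng count matrix. Pairs with either pixel outside the
# mask are skipped.
.glcmCount <- function(q, dr, dc) {
  lv <- q@levels
  ng <- q@ng
  nr <- nrow(lv)
  nc <- ncol(lv)
  r0 <- max(1L, 1L - dr); r1 <- min(nr, nr - dr)
  c0 <- max(1L, 1L - dc); c1 <- min(nc, nc - dc)
  if (r0 > r1 || c0 > c1) return(matrix(0, ng, ng))
  a <- lv[r0:r1, c0:c1, drop = FALSE]
  b <- lv[(r0 + dr):(r1 + dr), (c0 + dc):(c1 + dc), drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(matrix(0, ng, ng))
  idx <- (b[ok] - 1L) * ng + a[ok]
  cnt <- matrix(tabulate(idx, ng * ng), ng, ng)
  cnt + t(cnt)
}

#' Gray-level co-occurrence matrices
#'
#' One symmetrized, normalized co-occurrence matrix per angle at the given
#' pixel distance (offsets (0,1), (1,1), (1,0), (1,-1) scaled by
#' `distance`).
#'
#' @param q a [QuantizedROI].
#' @param distance pixel offset distance (default 1).
#' @return list of Ng x Ng probability matrices, one per angle; angles with
#'   no valid pixel pair are dropped. An error is raised if no angle has a
#'   valid pair.
#' @export
glcmMatrix <- function(q, distance = 1L) {
  stopifnot(is(q, "QuantizedROI"), distance >= 1L)
  mats <- lapply(.GLCM_OFFSETS, function(o) {
    .glcmCount(q, o[1] * as.integer(distance), o[2] * as.integer(distance))
  })
  mats <- Filter(function(m) sum(m) > 0, mats)
  if (!length(mats)) stop("no valid pixel pairs for any angle")
  lapply(mats, function(m) m / sum(m))
}

# All 24 features of one normalized symmetric GLCM.
.glcmFeaturesOne <- function(P) {
  ng <- nrow(P)
  i <- row(P)
  j <- col(P)
  px <- rowSums(P) # == colSums by symmetry
  py <- colSums(P)
  mux <- sum(seq_len(ng) * px)
  muy <- sum(seq_len(ng) * py)
  sx2 <- sum((seq_len(ng) - mux)^2 * px)
  sy2 <- sum((seq_len(ng) - muy)^2 * py)

  # diagonal (difference) and cross-diagonal (sum) distributions
  k_d <- 0:(ng - 1)
  pxmy <- vapply(k_d, function(k) sum(P[abs(i - j) == k]), numeric(1))
  k_s <- 2:(2 * ng)
  pxpy <- vapply(k_s, function(k) sum(P[(i + j) == k]), numeric(1))

  da <- sum(k_d * pxmy)
  sa <- sum(k_s * pxpy)

  hxy <- -sum(P * .log2e(P))
  hx <- -sum(px * .log2e(px))
  hy <- -sum(py * .log2e(py))
  pxpyOuter <- outer(px, py)
  hxy1 <- -sum(P * .log2e(pxpyOuter))
  hxy2 <- -sum(pxpyOuter * .log2e(pxpyOuter))

  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))

  corr <- if (sx2 > 0 && sy2 > 0) {
    (sum(i * j * P) - mux * muy) / sqrt(sx2 * sy2)
  } else 1

  # maximal correlation coefficient: sqrt of the second largest eigenvalue
  # of Q(i,j) = sum_k P(i,k) P(j,k) / (px(i) py(k)), over occupied levels
  occ <- which(px > 0)
  mcc <- if (length(occ) < 2L) 1 else {
    Ps <- P[occ, occ, drop = FALSE]
    Q <- matrix(0, length(occ), length(occ))
    for (a in seq_along(occ)) {
      for (b in seq_along(occ)) {
        Q[a, b] <- sum(Ps[a, ] * Ps[b, ] / (px[occ][a] * py[occ]))
      }
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(pmax(ev[2], 0))
  }

  out <- c(
    Autocorrelation = sum(i * j * P),
    ClusterProminence = sum((i + j - mux - muy)^4 * P),
    ClusterShade = sum((i + j - mux - muy)^3 * P),
    ClusterTendency = sum((i + j - mux - muy)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pxmy * .log2e(pxmy)),
    DifferenceVariance = sum((k_d - da)^2 * pxmy),
    Id = sum(P / (1 + abs(i - j))),
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + ((i - j) / ng)^2)),
    Idn = sum(P / (1 + abs(i - j) / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(P[i != j] / (i[i != j] - j[i != j])^2),
    JointAverage = mux,
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(P),
    SumAverage = sa,
    SumEntropy = -sum(pxpy * .log2e(pxpy)),
    SumSquares = sum((i - mux)^2 * P)
  )
  out[.GLCM_NAMES]
}

#' GLCM texture features (24 features)
#'
#' Computes the 24 co-occurrence features per angle and averages over
#' angles.
#'
#' @param q a [QuantizedROI], or a list of normalized GLCMs from
#'   [glcmMatrix()].
#' @param distance pixel distance when `q` is a [QuantizedROI].
#' @return named numeric vector of 24 features.
#' @export
glcmFeatures <- function(q, distance = 1L) {
  mats <- if (is(q, "QuantizedROI")) glcmMatrix(q, distance) else q
  per <- vapply(mats, .glcmFeaturesOne, numeric(length(.GLCM_NAMES)))
  rowMeans(per)
}
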
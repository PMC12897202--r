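# Gray-level size-zone matrix features. A zone is an 8-connected component
# of equal gray level; unlike run-length analysis there is no direction, so
# a single matrix describes the ROI. Connected components are found with
# igraph on the equal-level pixel adjacency graph.

.GLSZM_NAMES <- c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelZoneEmphasis",
  "LargeAreaEmphasis", "LargeAreaHighGrayLevelEmphasis",
  "LargeAreaLowGrayLevelEmphasis", "LowGrayLevelZoneEmphasis",
  "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
  "SmallAreaEmphasis", "SmallAreaHighGrayLevelEmphasis",
  "SmallAreaLowGrayLevelEmphasis", "ZoneEntropy", "ZonePercentage",
  "ZoneVariance"
)

# 8-connectivity neighbor offsets covering each undirected pair once
.HALF_NEIGHBORS <- list(c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))

# data.frame(level, size) of all equal-level 8-connected zones
.zoneList <- function(q) {
  lv <- q@levels
  nr <- nrow(lv)
  nc <- ncol(lv)
  n <- nr * nc
  valid <- which(!is.na(lv))
  edges <- integer(0)
  for (o in .HALF_NEIGHBORS) {
    dr <- o[1]; dc <- o[2]
    r0 <- max(1L, 1L - dr); r1 <- min(nr, nr - dr)
    c0 <- max(1L, 1L - dc); c1 <- min(nc, nc - dc)
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1
    cc <- c0:c1
    a <- as.vector(outer(rr, (cc - 1L) * nr, "+"))
    b <- a + dr + dc * nr
    ok <- !is.na(lv[a]) & !is.na(lv[b]) & lv[a] == lv[b]
    if (any(ok)) edges <- c(edges, rbind(a[ok], b[ok]))
  }
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  comp <- igraph::components(g)
  memb <- comp$membership[valid]
  zid <- match(memb, unique(memb))
  data.frame(
    level = as.integer(tapply(lv[valid], zid, function(z) z[1])),
    size = as.integer(tabulate(zid))
  )
}

#' GLSZM texture features (16 features)
#'
#' Zones are 8-connected components of equal gray level; the size-zone
#' matrix counts zones by (gray level, zone size). `ZonePercentage` is the
#' zone count over the masked pixel count.
#'
#' @param q a [QuantizedROI].
#' @return named numeric vector of 16 features.
#' @export
glszmFeatures <- function(q) {
  stopifnot(is(q, "QuantizedROI"))
  zones <- .zoneList(q)
  np <- sum(q@mask)
  nz <- nrow(zones)
  i <- zones$level
  j <- zones$size
  p <- rep(1 / nz, nz) # each zone contributes one count
  # marginals over levels and sizes
  glCounts <- tapply(rep(1, nz), i, sum)
  szCounts <- tapply(rep(1, nz), j, sum)
  pg <- as.vector(glCounts) / nz
  gl <- as.numeric(names(glCounts))
  ps <- as.vector(szCounts) / nz
  sz <- as.numeric(names(szCounts))
  mug <- sum(gl * pg)
  muz <- sum(sz * ps)
  # joint probabilities for entropy: group zones by (level, size)
  key <- paste(i, j)
  pj <- as.vector(table(key)) / nz

  out <- c(
    GrayLevelNonUniformity = sum(as.vector(glCounts)^2) / nz,
    GrayLevelNonUniformityNormalized = sum(as.vector(glCounts)^2) / nz^2,
    GrayLevelVariance = sum((gl - mug)^2 * pg),
    HighGrayLevelZoneEmphasis = sum(i^2) / nz,
    LargeAreaEmphasis = sum(as.numeric(j)^2) / nz,
    LargeAreaHighGrayLevelEmphasis = sum(as.numeric(i)^2 * as.numeric(j)^2) / nz,
    LargeAreaLowGrayLevelEmphasis = sum(as.numeric(j)^2 / as.numeric(i)^2) / nz,
    LowGrayLevelZoneEmphasis = sum(1 / i^2) / nz,
    SizeZoneNonUniformity = sum(as.vector(szCounts)^2) / nz,
    SizeZoneNonUniformityNormalized = sum(as.vector(szCounts)^2) / nz^2,
    SmallAreaEmphasis = sum(1 / as.numeric(j)^2) / nz,
    SmallAreaHighGrayLevelEmphasis = sum(as.numeric(i)^2 / as.numeric(j)^2) / nz,
    SmallAreaLowGrayLevelEmphasis = sum(1 / (as.numeric(i)^2 * as.numeric(j)^2)) / nz,
    ZoneEntropy = -sum(pj * .log2e(pj)),
    ZonePercentage = nz / np,
    ZoneVariance = sum((sz - muz)^2 * ps)
  )
  out[.GLSZM_NAMES]
}
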
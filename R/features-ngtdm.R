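# Neighboring gray tone difference matrix features. For each masked pixel
# with at least one valid 8-neighbor, the absolute difference between its
# level and the mean level of its valid neighbors is accumulated per gray
# level (s_i), together with the per-level pixel count n_i and probability
# p_i. Degenerate-denominator conventions: Coarseness capped at 1e6,
# Busyness/Strength 0 when their denominators vanish, Contrast 0 with a
# single occupied level.

.NGTDM_NAMES <- c("Busyness", "Coarseness", "Complexity", "Contrast",
                  "Strength")

.NGTDM_COARSENESS_CAP <- 1e6

# per-level (n_i, p_i, s_i) table
.ngtdmTable <- function(q) {
  lv <- q@levels
  ng <- q@ng
  nr <- nrow(lv)
  nc <- ncol(lv)
  lvNA0 <- ifelse(is.na(lv), 0, lv)
  present <- !is.na(lv)
  m <- 1L
  # mirror-free zero padding: sum and count of valid neighbors via shifts
  sumN <- matrix(0, nr, nc)
  cntN <- matrix(0, nr, nc)
  for (dr in -1L:1L) {
    for (dc in -1L:1L) {
      if (dr == 0L && dc == 0L) next
      r0 <- max(1L, 1L - dr); r1 <- min(nr, nr - dr)
      c0 <- max(1L, 1L - dc); c1 <- min(nc, nc - dc)
      if (r0 > r1 || c0 > c1) next
      tgtR <- r0:r1
      tgtC <- c0:c1
      srcR <- (r0 + dr):(r1 + dr)
      srcC <- (c0 + dc):(c1 + dc)
      sumN[tgtR, tgtC] <- sumN[tgtR, tgtC] + lvNA0[srcR, srcC]
      cntN[tgtR, tgtC] <- cntN[tgtR, tgtC] + present[srcR, srcC]
    }
  }
  use <- present & cntN > 0
  if (!any(use)) stop("no pixel has a valid neighbor")
  dev <- abs(lv[use] - sumN[use] / cntN[use])
  li <- lv[use]
  n_i <- tabulate(li, ng)
  s_i <- vapply(seq_len(ng), function(g) sum(dev[li == g]), numeric(1))
  nvp <- sum(n_i)
  data.frame(level = seq_len(ng), n = n_i, p = n_i / nvp, s = s_i)
}

#' NGTDM texture features (5 features)
#'
#' @param q a [QuantizedROI].
#' @return named numeric vector: Busyness, Coarseness, Complexity,
#'   Contrast, Strength.
#' @export
ngtdmFeatures <- function(q) {
  stopifnot(is(q, "QuantizedROI"))
  tb <- .ngtdmTable(q)
  occ <- tb[tb$p > 0, ]
  i <- occ$level
  p <- occ$p
  s <- occ$s
  ngp <- nrow(occ)
  nvp <- sum(occ$n)

  coarse <- if (sum(p * s) > 0) {
    min(1 / sum(p * s), .NGTDM_COARSENESS_CAP)
  } else .NGTDM_COARSENESS_CAP

  contrast <- if (ngp > 1) {
    pij <- outer(p, p)
    dij2 <- outer(i, i, "-")^2
    sum(pij * dij2) / (ngp * (ngp - 1)) * sum(s) / nvp
  } else 0

  ip <- i * p
  busyDen <- sum(abs(outer(ip, ip, "-")))
  busy <- if (busyDen > 0) sum(p * s) / busyDen else 0

  cplx <- {
    pi_ <- matrix(p, ngp, ngp)
    pj_ <- t(pi_)
    si_ <- matrix(s, ngp, ngp)
    sj_ <- t(si_)
    sum(abs(outer(i, i, "-")) * (pi_ * si_ + pj_ * sj_) / (pi_ + pj_)) / nvp
  }

  strength <- if (sum(s) > 0) {
    pi_ <- matrix(p, ngp, ngp)
    sum((pi_ + t(pi_)) * outer(i, i, "-")^2) / sum(s)
  } else 0

  out <- c(
    Busyness = busy, Coarseness = coarse, Complexity = cplx,
    Contrast = contrast, Strength = strength
  )
  out[.NGTDM_NAMES]
}
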
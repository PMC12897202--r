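# Independent brute-force oracles for the 93-feature suite, written as
# naive scalar loops over pairs / runs / zones / neighborhoods. These are
# deliberately implemented from the definitions, separately from the
# package's vectorized code, and serve as the reference in the
# oracle-equivalence tests.

oEPS <- 2^-52
olog2 <- function(p) log2(p + oEPS)

# type-7 (linear interpolation) quantile, by hand
oQuantile <- function(v, p) {
  s <- sort(v)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

oracleQuantize <- function(x, bw) {
  base <- floor(min(x) / bw)
  matrix(as.integer(floor(x / bw) - base + 1), nrow(x), ncol(x))
}

oracleFirstorder <- function(x, bw = 25, area = 1) {
  v <- as.vector(x)
  n <- length(v)
  lv <- floor(v / bw) - floor(min(v) / bw) + 1
  p <- as.vector(table(lv)) / n
  mu <- sum(v) / n
  m2 <- sum((v - mu)^2) / n
  m3 <- sum((v - mu)^3) / n
  m4 <- sum((v - mu)^4) / n
  p10 <- oQuantile(v, 0.10)
  p90 <- oQuantile(v, 0.90)
  rob <- v[v >= p10 & v <= p90]
  c(
    `10Percentile` = p10,
    `90Percentile` = p90,
    Energy = sum(v^2),
    Entropy = -sum(p * olog2(p)),
    InterquartileRange = oQuantile(v, 0.75) - oQuantile(v, 0.25),
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Maximum = max(v),
    Mean = mu,
    MeanAbsoluteDeviation = sum(abs(v - mu)) / n,
    Median = oQuantile(v, 0.5),
    Minimum = min(v),
    Range = max(v) - min(v),
    RobustMeanAbsoluteDeviation = sum(abs(rob - mean(rob))) / length(rob),
    RootMeanSquared = sqrt(sum(v^2) / n),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    TotalEnergy = sum(v^2) * area,
    Uniformity = sum(p^2),
    Variance = m2
  )
}

# ---- GLCM ----

oracleGlcmCounts <- function(lv, ng, dr, dc) {
  nr <- nrow(lv)
  nc <- ncol(lv)
  C <- matrix(0, ng, ng)
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      r2 <- r + dr
      c2 <- cc + dc
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        C[lv[r, cc], lv[r2, c2]] <- C[lv[r, cc], lv[r2, c2]] + 1
      }
    }
  }
  C + t(C)
}

oracleGlcmFeaturesOne <- function(P) {
  ng <- nrow(P)
  px <- numeric(ng)
  py <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    px[i] <- px[i] + P[i, j]
    py[j] <- py[j] + P[i, j]
  }
  mux <- sum((1:ng) * px)
  muy <- sum((1:ng) * py)
  sx2 <- sum(((1:ng) - mux)^2 * px)
  sy2 <- sum(((1:ng) - muy)^2 * py)
  pd <- numeric(ng)        # |i-j| in 0..ng-1 at index k+1
  ps <- numeric(2 * ng - 1) # i+j in 2..2ng at index i+j-1
  for (i in 1:ng) for (j in 1:ng) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + P[i, j]
    ps[i + j - 1] <- ps[i + j - 1] + P[i, j]
  }
  kd <- 0:(ng - 1)
  ks <- 2:(2 * ng)
  da <- sum(kd * pd)
  hxy <- 0; hx <- 0; hy <- 0; hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) {
    hx <- hx - px[i] * olog2(px[i])
    hy <- hy - py[i] * olog2(py[i])
    for (j in 1:ng) {
      hxy <- hxy - P[i, j] * olog2(P[i, j])
      hxy1 <- hxy1 - P[i, j] * olog2(px[i] * py[j])
      hxy2 <- hxy2 - px[i] * py[j] * olog2(px[i] * py[j])
    }
  }
  acor <- 0; cpro <- 0; csha <- 0; cten <- 0; contr <- 0; id <- 0
  idm <- 0; idmn <- 0; idn <- 0; iv <- 0; je <- 0; ss <- 0; ija <- 0
  for (i in 1:ng) for (j in 1:ng) {
    acor <- acor + i * j * P[i, j]
    cpro <- cpro + (i + j - mux - muy)^4 * P[i, j]
    csha <- csha + (i + j - mux - muy)^3 * P[i, j]
    cten <- cten + (i + j - mux - muy)^2 * P[i, j]
    contr <- contr + (i - j)^2 * P[i, j]
    id <- id + P[i, j] / (1 + abs(i - j))
    idm <- idm + P[i, j] / (1 + (i - j)^2)
    idmn <- idmn + P[i, j] / (1 + ((i - j) / ng)^2)
    idn <- idn + P[i, j] / (1 + abs(i - j) / ng)
    if (i != j) iv <- iv + P[i, j] / (i - j)^2
    je <- je + P[i, j]^2
    ss <- ss + (i - mux)^2 * P[i, j]
    ija <- ija + i * j * P[i, j]
  }
  occ <- which(px > 0)
  mcc <- if (length(occ) < 2) 1 else {
    m <- length(occ)
    Q <- matrix(0, m, m)
    for (a in 1:m) for (b in 1:m) {
      for (kk in 1:m) {
        Q[a, b] <- Q[a, b] +
          P[occ[a], occ[kk]] * P[occ[b], occ[kk]] /
            (px[occ[a]] * py[occ[kk]])
      }
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(ev[2], 0))
  }
  c(
    Autocorrelation = acor,
    ClusterProminence = cpro,
    ClusterShade = csha,
    ClusterTendency = cten,
    Contrast = contr,
    Correlation = if (sx2 > 0 && sy2 > 0) (ija - mux * muy) / sqrt(sx2 * sy2) else 1,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pd * olog2(pd)),
    DifferenceVariance = sum((kd - da)^2 * pd),
    Id = id, Idm = idm, Idmn = idmn, Idn = idn,
    Imc1 = if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0,
    Imc2 = sqrt(max(1 - exp(-2 * (hxy2 - hxy)), 0)),
    InverseVariance = iv,
    JointAverage = mux,
    JointEnergy = je,
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(P),
    SumAverage = sum(ks * ps),
    SumEntropy = -sum(ps * olog2(ps)),
    SumSquares = ss
  )
}

oracleGlcm <- function(lv, ng, distance = 1) {
  offs <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  per <- NULL
  for (o in offs) {
    C <- oracleGlcmCounts(lv, ng, o[1] * distance, o[2] * distance)
    if (sum(C) == 0) next
    per <- cbind(per, oracleGlcmFeaturesOne(C / sum(C)))
  }
  rowMeans(per)
}

# ---- GLRLM ----

oracleRuns <- function(lv, dr, dc) {
  nr <- nrow(lv)
  nc <- ncol(lv)
  runs <- NULL
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      pr <- r - dr
      pc <- cc - dc
      isStart <- pr < 1 || pr > nr || pc < 1 || pc > nc ||
        lv[pr, pc] != lv[r, cc]
      if (!isStart) next
      len <- 1
      r2 <- r + dr
      c2 <- cc + dc
      while (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
             lv[r2, c2] == lv[r, cc]) {
        len <- len + 1
        r2 <- r2 + dr
        c2 <- c2 + dc
      }
      runs <- rbind(runs, c(lv[r, cc], len))
    }
  }
  runs
}

oracleGlrlmFeaturesOne <- function(runs, ng, np) {
  maxj <- max(runs[, 2])
  M <- matrix(0, ng, maxj)
  for (k in seq_len(nrow(runs))) {
    M[runs[k, 1], runs[k, 2]] <- M[runs[k, 1], runs[k, 2]] + 1
  }
  nr <- sum(M)
  sre <- 0; lre <- 0; hgl <- 0; lgl <- 0; srl <- 0; srh <- 0
  lrl <- 0; lrh <- 0; re <- 0
  for (i in 1:ng) for (j in 1:maxj) {
    m <- M[i, j]
    sre <- sre + m / j^2; lre <- lre + m * j^2
    hgl <- hgl + m * i^2; lgl <- lgl + m / i^2
    srl <- srl + m / (i^2 * j^2); srh <- srh + m * i^2 / j^2
    lrl <- lrl + m * j^2 / i^2; lrh <- lrh + m * i^2 * j^2
    p <- m / nr
    re <- re - p * olog2(p) * (p > 0)
  }
  ri <- rowSums(M)
  cj <- colSums(M)
  pg <- ri / nr
  pr <- cj / nr
  mug <- sum((1:ng) * pg)
  mur <- sum((1:maxj) * pr)
  c(
    GrayLevelNonUniformity = sum(ri^2) / nr,
    GrayLevelNonUniformityNormalized = sum(ri^2) / nr^2,
    GrayLevelVariance = sum(((1:ng) - mug)^2 * pg),
    HighGrayLevelRunEmphasis = hgl / nr,
    LongRunEmphasis = lre / nr,
    LongRunHighGrayLevelEmphasis = lrh / nr,
    LongRunLowGrayLevelEmphasis = lrl / nr,
    LowGrayLevelRunEmphasis = lgl / nr,
    RunEntropy = re,
    RunLengthNonUniformity = sum(cj^2) / nr,
    RunLengthNonUniformityNormalized = sum(cj^2) / nr^2,
    RunPercentage = nr / np,
    RunVariance = sum(((1:maxj) - mur)^2 * pr),
    ShortRunEmphasis = sre / nr,
    ShortRunHighGrayLevelEmphasis = srh / nr,
    ShortRunLowGrayLevelEmphasis = srl / nr
  )
}

oracleGlrlm <- function(lv, ng) {
  np <- length(lv)
  per <- NULL
  for (o in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    runs <- oracleRuns(lv, o[1], o[2])
    per <- cbind(per, oracleGlrlmFeaturesOne(runs, ng, np))
  }
  rowMeans(per)
}

# ---- GLSZM ----

oracleZones <- function(lv) {
  nr <- nrow(lv)
  nc <- ncol(lv)
  seen <- matrix(FALSE, nr, nc)
  zones <- NULL
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      if (seen[r, cc]) next
      # BFS over 8-connected equal-level pixels
      stack <- list(c(r, cc))
      seen[r, cc] <- TRUE
      size <- 0
      while (length(stack)) {
        p <- stack[[1]]
        stack <- stack[-1]
        size <- size + 1
        for (dr in -1:1) for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          r2 <- p[1] + dr
          c2 <- p[2] + dc
          if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
              !seen[r2, c2] && lv[r2, c2] == lv[r, cc]) {
            seen[r2, c2] <- TRUE
            stack <- c(stack, list(c(r2, c2)))
          }
        }
      }
      zones <- rbind(zones, c(lv[r, cc], size))
    }
  }
  zones
}

oracleGlszm <- function(lv, ng) {
  zones <- oracleZones(lv)
  np <- length(lv)
  nz <- nrow(zones)
  i <- zones[, 1]
  j <- zones[, 2]
  glc <- sapply(1:ng, function(g) sum(i == g))
  sizes <- sort(unique(j))
  szc <- sapply(sizes, function(s) sum(j == s))
  pg <- glc / nz
  ps <- szc / nz
  mug <- sum((1:ng) * pg)
  muz <- sum(sizes * ps)
  keys <- paste(i, j)
  pj <- as.vector(table(keys)) / nz
  c(
    GrayLevelNonUniformity = sum(glc^2) / nz,
    GrayLevelNonUniformityNormalized = sum(glc^2) / nz^2,
    GrayLevelVariance = sum(((1:ng) - mug)^2 * pg),
    HighGrayLevelZoneEmphasis = sum(i^2) / nz,
    LargeAreaEmphasis = sum(j^2) / nz,
    LargeAreaHighGrayLevelEmphasis = sum(i^2 * j^2) / nz,
    LargeAreaLowGrayLevelEmphasis = sum(j^2 / i^2) / nz,
    LowGrayLevelZoneEmphasis = sum(1 / i^2) / nz,
    SizeZoneNonUniformity = sum(szc^2) / nz,
    SizeZoneNonUniformityNormalized = sum(szc^2) / nz^2,
    SmallAreaEmphasis = sum(1 / j^2) / nz,
    SmallAreaHighGrayLevelEmphasis = sum(i^2 / j^2) / nz,
    SmallAreaLowGrayLevelEmphasis = sum(1 / (i^2 * j^2)) / nz,
    ZoneEntropy = -sum(pj * olog2(pj)),
    ZonePercentage = nz / np,
    ZoneVariance = sum((sizes - muz)^2 * ps)
  )
}

# ---- NGTDM ----

oracleNgtdm <- function(lv, ng) {
  nr <- nrow(lv)
  nc <- ncol(lv)
  n_i <- numeric(ng)
  s_i <- numeric(ng)
  nvp <- 0
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      nb <- c()
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- r + dr
        c2 <- cc + dc
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
          nb <- c(nb, lv[r2, c2])
        }
      }
      if (!length(nb)) next
      nvp <- nvp + 1
      g <- lv[r, cc]
      n_i[g] <- n_i[g] + 1
      s_i[g] <- s_i[g] + abs(g - mean(nb))
    }
  }
  p_i <- n_i / nvp
  occ <- which(p_i > 0)
  ngp <- length(occ)
  cps <- sum(p_i[occ] * s_i[occ])
  coarse <- if (cps > 0) min(1 / cps, 1e6) else 1e6
  contr <- 0
  if (ngp > 1) {
    acc <- 0
    for (i in occ) for (j in occ) acc <- acc + p_i[i] * p_i[j] * (i - j)^2
    contr <- acc / (ngp * (ngp - 1)) * sum(s_i) / nvp
  }
  bden <- 0
  for (i in occ) for (j in occ) bden <- bden + abs(i * p_i[i] - j * p_i[j])
  busy <- if (bden > 0) cps / bden else 0
  cplx <- 0
  for (i in occ) for (j in occ) {
    cplx <- cplx + abs(i - j) *
      (p_i[i] * s_i[i] + p_i[j] * s_i[j]) / (p_i[i] + p_i[j])
  }
  cplx <- cplx / nvp
  stren <- 0
  if (sum(s_i) > 0) {
    for (i in occ) for (j in occ) {
      stren <- stren + (p_i[i] + p_i[j]) * (i - j)^2
    }
    stren <- stren / sum(s_i)
  }
  c(Busyness = busy, Coarseness = coarse, Complexity = cplx,
    Contrast = contr, Strength = stren)
}

# ---- GLDM ----

oracleGldm <- function(lv, ng, alpha = 0) {
  nr <- nrow(lv)
  nc <- ncol(lv)
  M <- matrix(0, ng, 9)
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      d <- 0
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- r + dr
        c2 <- cc + dc
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            abs(lv[r2, c2] - lv[r, cc]) <= alpha) {
          d <- d + 1
        }
      }
      M[lv[r, cc], d + 1] <- M[lv[r, cc], d + 1] + 1
    }
  }
  nz <- sum(M)
  sde <- 0; lde <- 0; hgl <- 0; lgl <- 0; sdl <- 0; sdh <- 0
  ldl <- 0; ldh <- 0; de <- 0
  for (i in 1:ng) for (j in 1:9) {
    m <- M[i, j]
    sde <- sde + m / j^2; lde <- lde + m * j^2
    hgl <- hgl + m * i^2; lgl <- lgl + m / i^2
    sdl <- sdl + m / (i^2 * j^2); sdh <- sdh + m * i^2 / j^2
    ldl <- ldl + m * j^2 / i^2; ldh <- ldh + m * i^2 * j^2
    p <- m / nz
    de <- de - p * olog2(p) * (p > 0)
  }
  ri <- rowSums(M)
  cj <- colSums(M)
  pg <- ri / nz
  pd <- cj / nz
  mug <- sum((1:ng) * pg)
  mud <- sum((1:9) * pd)
  c(
    DependenceEntropy = de,
    DependenceNonUniformity = sum(cj^2) / nz,
    DependenceNonUniformityNormalized = sum(cj^2) / nz^2,
    DependenceVariance = sum(((1:9) - mud)^2 * pd),
    GrayLevelNonUniformity = sum(ri^2) / nz,
    GrayLevelVariance = sum(((1:ng) - mug)^2 * pg),
    HighGrayLevelEmphasis = hgl / nz,
    LargeDependenceEmphasis = lde / nz,
    LargeDependenceHighGrayLevelEmphasis = ldh / nz,
    LargeDependenceLowGrayLevelEmphasis = ldl / nz,
    LowGrayLevelEmphasis = lgl / nz,
    SmallDependenceEmphasis = sde / nz,
    SmallDependenceHighGrayLevelEmphasis = sdh / nz,
    SmallDependenceLowGrayLevelEmphasis = sdl / nz
  )
}

# ---- full 93-vector oracle ----

oracleAll93 <- function(x, bw = 25, area = 1, alpha = 0) {
  lv <- oracleQuantize(x, bw)
  ng <- max(lv)
  fam <- list(
    firstorder = oracleFirstorder(x, bw, area),
    glcm = oracleGlcm(lv, ng),
    gldm = oracleGldm(lv, ng, alpha),
    glrlm = oracleGlrlm(lv, ng),
    glszm = oracleGlszm(lv, ng),
    ngtdm = oracleNgtdm(lv, ng)
  )
  unlist(lapply(names(fam), function(f) {
    setNames(fam[[f]], paste0(f, "_", names(fam[[f]])))
  }))
}
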
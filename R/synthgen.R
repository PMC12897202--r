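# Synthetic mitochondrial-morphology image generator. Emulates the three
# morphology classes seen in confocal images of mitochondria -- fibers
# (interconnected curvilinear tubular networks), puncta (small disconnected
# circular spots) and rods (short unbranched tubular segments) -- plus a
# two-condition mode in which a "treated" population is a
# fragmentation-shifted mixture of the morphologies. The noise model is
# Poisson shot noise on the signal plus additive Gaussian read noise, the
# standard confocal approximation. Everything is deterministic under the
# configured seed.

#' Synthetic image configuration
#'
#' Defaults are chosen to mimic moderately noisy confocal ROIs: tubular
#' structures ~3 px wide on a dim background, shot noise at ~80 photons at
#' full scale, and 5% read noise. Class overlap is deliberate -- fibers and
#' rods share tubular texture and are the hard pair, while puncta are
#' well separated.
#'
#' @param imageSize edge length in pixels (>= 32; default 69 to match the
#'   ROI convention).
#' @param noiseSd Gaussian read-noise standard deviation as a fraction of
#'   the dynamic range.
#' @param backgroundLevel background intensity as a fraction of full scale.
#' @param photonScale photons at full scale for the Poisson shot noise
#'   (larger = cleaner).
#' @param seed RNG seed for a single generated image.
#' @return named list.
#' @export
synthConfig <- function(imageSize = 69L, noiseSd = 0.05,
                        backgroundLevel = 0.08, photonScale = 80,
                        seed = NULL) {
  stopifnot(imageSize >= 32L, noiseSd >= 0, backgroundLevel >= 0,
            backgroundLevel < 1, photonScale > 0)
  list(
    imageSize = as.integer(imageSize), noiseSd = noiseSd,
    backgroundLevel = backgroundLevel, photonScale = photonScale,
    seed = seed
  )
}

# stamp a soft disc of radius ~r at (row, col) into canvas (max-compose)
.stampDisc <- function(canvas, r0, c0, r = 1.5, amp = 1) {
  n <- nrow(canvas)
  ir <- round(r0)
  ic <- round(c0)
  w <- ceiling(r) + 1L
  rr <- max(1L, ir - w):min(n, ir + w)
  cc <- max(1L, ic - w):min(n, ic + w)
  if (!length(rr) || !length(cc)) return(canvas)
  d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
  patch <- amp * exp(-d2 / (2 * (r / 1.6)^2))
  canvas[rr, cc] <- pmax(canvas[rr, cc], patch)
  canvas
}

# Poisson shot noise + Gaussian read noise, quantized to 8 bit
.renderNoisy <- function(clean, cfg) {
  n <- length(clean)
  noisy <- stats::rpois(n, pmax(clean, 0) * cfg$photonScale) / cfg$photonScale
  if (cfg$noiseSd > 0) noisy <- noisy + stats::rnorm(n, 0, cfg$noiseSd)
  m <- matrix(.clip(noisy, 0, 1), nrow(clean), ncol(clean))
  MorphImage(round(m * 255), bitDepth = 8L, pixelSizeUm = 0.035)
}

# clean signal painters (no noise); each returns list(clean, params)
.cleanPuncta <- function(cfg) {
  n <- cfg$imageSize
  canvas <- matrix(0, n, n)
  nSpots <- sample(8:20, 1L)
  margin <- 5
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(centers) < nSpots && tries < 500L) {
    tries <- tries + 1L
    cand <- stats::runif(2, margin, n - margin)
    if (!nrow(centers) || min((centers[, 1] - cand[1])^2 +
                              (centers[, 2] - cand[2])^2) > 8^2) {
      centers <- rbind(centers, cand)
    }
  }
  nSpots <- nrow(centers)
  sig <- stats::runif(nSpots, 1.5, 3)
  amp <- stats::runif(nSpots, 0.55, 1)
  for (s in seq_len(nSpots)) {
    canvas <- .stampDisc(canvas, centers[s, 1], centers[s, 2],
                         r = sig[s], amp = amp[s])
  }
  list(clean = canvas, params = list(n_structures = nSpots))
}

.cleanFibers <- function(cfg, branchProb = 0.05) {
  n <- cfg$imageSize
  canvas <- matrix(0, n, n)
  nSeeds <- sample(3:6, 1L)
  # stack of walkers: each row (row, col, angle)
  stack <- lapply(seq_len(nSeeds), function(i) {
    c(stats::runif(1, n * 0.3, n * 0.7), stats::runif(1, n * 0.3, n * 0.7),
      stats::runif(1, 0, 2 * pi))
  })
  amp <- stats::runif(1, 0.75, 1)
  # walk lengths calibrated so tubular coverage stays in the 5-50%
  # foreground band of a fiber-dominated ROI
  maxSteps <- 150L
  totalSteps <- 0L
  nBranches <- 0L
  while (length(stack) && totalSteps < 800L) {
    w <- stack[[1]]
    stack <- stack[-1]
    r <- w[1]; cc <- w[2]; a <- w[3]
    for (s in seq_len(maxSteps)) {
      totalSteps <- totalSteps + 1L
      r <- r + sin(a)
      cc <- cc + cos(a)
      if (r < 2 || r > n - 1 || cc < 2 || cc > n - 1) break
      canvas <- .stampDisc(canvas, r, cc, r = 1.5, amp = amp)
      a <- a + stats::rnorm(1, 0, 0.15)
      if (stats::runif(1) < branchProb && length(stack) < 12L) {
        nBranches <- nBranches + 1L
        stack <- c(stack, list(c(r, cc, a + sample(c(-1, 1), 1L) *
                                   stats::runif(1, 0.7, 1.3))))
      }
    }
  }
  list(clean = canvas,
       params = list(n_structures = nSeeds, n_branches = nBranches))
}

.cleanRods <- function(cfg) {
  n <- cfg$imageSize
  canvas <- matrix(0, n, n)
  occupied <- matrix(FALSE, n, n)
  nRods <- sample(5:12, 1L)
  drawn <- 0L
  margin <- 6
  for (k in seq_len(nRods)) {
    placed <- FALSE
    for (try in seq_len(200L)) {
      len <- stats::runif(1, 10, 25)
      a <- stats::runif(1, 0, pi)
      curv <- stats::rnorm(1, 0, 0.0015)
      r0 <- stats::runif(1, margin, n - margin)
      c0 <- stats::runif(1, margin, n - margin)
      tt <- seq(0, len, by = 0.5)
      rr <- r0 + tt * sin(a) + curv * tt^2 * cos(a)
      cc <- c0 + tt * cos(a) - curv * tt^2 * sin(a)
      if (any(rr < 3 | rr > n - 2 | cc < 3 | cc > n - 2)) next
      # disjointness: soft tube edges reach ~2 px from the skeleton, so
      # keep skeletons >= 5 px apart (Chebyshev) for a clean gap
      ir <- round(rr); ic <- round(cc)
      clear <- TRUE
      for (p in seq_along(ir)) {
        rwin <- max(1L, ir[p] - 4L):min(n, ir[p] + 4L)
        cwin <- max(1L, ic[p] - 4L):min(n, ic[p] + 4L)
        if (any(occupied[rwin, cwin])) { clear <- FALSE; break }
      }
      if (!clear) next
      amp <- stats::runif(1, 0.6, 1)
      for (p in seq_along(rr)) {
        canvas <- .stampDisc(canvas, rr[p], cc[p], r = 1.5, amp = amp)
        occupied[ir[p], ic[p]] <- TRUE
      }
      placed <- TRUE
      drawn <- drawn + 1L
      break
    }
    if (!placed) break
  }
  list(clean = canvas, params = list(n_structures = drawn))
}

.CLEAN_PAINTERS <- list(
  puncta = .cleanPuncta, fiber = .cleanFibers, rod = .cleanRods
)

#' Generate one synthetic morphology image
#'
#' @param class `"fiber"`, `"puncta"` or `"rod"`.
#' @param cfg a [synthConfig()]; its `seed` makes the image reproducible.
#' @param clean return the noise-free signal instead of the noisy render.
#' @return a [MorphImage] (8-bit); attribute `params` records the number
#'   of structures drawn.
#' @export
makeSyntheticROI <- function(class = c("fiber", "puncta", "rod"),
                             cfg = synthConfig(), clean = FALSE) {
  class <- match.arg(class)
  withSeed(cfg$seed, {
    sig <- .CLEAN_PAINTERS[[class]](cfg)
    signal <- cfg$backgroundLevel + (1 - cfg$backgroundLevel) * sig$clean
    img <- if (clean) {
      MorphImage(round(.clip(signal, 0, 1) * 255), 8L, pixelSizeUm = 0.035)
    } else {
      .renderNoisy(signal, cfg)
    }
    attr(img, "params") <- sig$params
    img
  })
}

#' @rdname makeSyntheticROI
#' @export
makePuncta <- function(cfg = synthConfig(), clean = FALSE) {
  makeSyntheticROI("puncta", cfg, clean)
}

#' @rdname makeSyntheticROI
#' @export
makeFibers <- function(cfg = synthConfig(), clean = FALSE) {
  makeSyntheticROI("fiber", cfg, clean)
}

#' @rdname makeSyntheticROI
#' @export
makeRods <- function(cfg = synthConfig(), clean = FALSE) {
  makeSyntheticROI("rod", cfg, clean)
}

# default morphology mixtures for the two-condition mode: treatment shifts
# mass from fibers toward puncta (fragmentation)
.CONDITION_MIXTURES <- list(
  untreated = c(fiber = 0.50, puncta = 0.20, rod = 0.30),
  treated = c(fiber = 0.20, puncta = 0.55, rod = 0.25)
)

#' Generate a labeled synthetic dataset
#'
#' In `"morphology"` mode, `nPerClass` images of each class are generated
#' with the class name as label. In `"condition"` mode each image's
#' morphology is drawn from a per-condition mixture (treatment shifts
#' weight from fibers to puncta, mimicking fragmentation) and the label is
#' the condition.
#'
#' @param nPerClass images per class (or per condition).
#' @param mode `"morphology"` or `"condition"`.
#' @param cfg a [synthConfig()] (its seed field is ignored here).
#' @param seed root seed; every image gets its own derived seed.
#' @param classes morphology classes used in `"morphology"` mode.
#' @param mixtures named list of mixture weight vectors for `"condition"`
#'   mode; weights must sum to 1.
#' @return list with `images` (list of [MorphImage]) and `manifest`
#'   (data.frame: roi_id, class_label, morphology, seed, n_structures).
#' @export
makeDataset <- function(nPerClass = 30L, mode = c("morphology", "condition"),
                        cfg = synthConfig(), seed = 1L,
                        classes = c("fiber", "puncta", "rod"),
                        mixtures = .CONDITION_MIXTURES) {
  mode <- match.arg(mode)
  if (mode == "morphology") {
    stopifnot(length(classes) >= 2L,
              all(classes %in% names(.CLEAN_PAINTERS)))
    labels <- rep(classes, each = nPerClass)
    morph <- labels
  } else {
    conds <- names(mixtures)
    stopifnot(length(conds) >= 2L)
    for (m in mixtures) {
      stopifnot(abs(sum(m) - 1) < 1e-8, all(names(m) %in% names(.CLEAN_PAINTERS)))
    }
    labels <- rep(conds, each = nPerClass)
    morph <- withSeed(seed, unlist(lapply(conds, function(cd) {
      sample(names(mixtures[[cd]]), nPerClass, replace = TRUE,
             prob = mixtures[[cd]])
    })))
  }
  n <- length(labels)
  seeds <- .seedStream(seed + 1L, n)
  images <- vector("list", n)
  nStruct <- integer(n)
  for (i in seq_len(n)) {
    ci <- cfg
    ci$seed <- seeds[i]
    images[[i]] <- makeSyntheticROI(morph[i], ci)
    nStruct[i] <- attr(images[[i]], "params")$n_structures
  }
  manifest <- data.frame(
    roi_id = sprintf("roi_%04d", seq_len(n)),
    class_label = labels,
    morphology = morph,
    seed = seeds,
    n_structures = nStruct,
    stringsAsFactors = FALSE
  )
  list(images = images, manifest = manifest)
}
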
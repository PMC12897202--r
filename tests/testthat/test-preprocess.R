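# Pre-processing chain: TIFF I/O, saturation rescale, CLAHE, adaptive
# Wiener filter, Gaussian smoothing, ROI extraction.

test_that("TIFF round trips preserve intensities and bit depth", {
  d <- withr::local_tempdir()
  z8 <- MorphImage(matrix(0, 69, 69), 8L)
  p8 <- file.path(d, "zero.tif")
  writeImage2D(z8, p8)
  r8 <- readImage2D(p8)
  expect_equal(pixels(r8), matrix(0, 69, 69))
  expect_equal(bitDepth(r8), 8L)

  set.seed(4)
  m16 <- matrix(sample.int(65536L, 32 * 32) - 1L, 32, 32)
  p16 <- file.path(d, "r16.tif")
  writeImage2D(MorphImage(m16, 16L), p16)
  expect_equal(pixels(readImage2D(p16)), m16)
  expect_equal(bitDepth(readImage2D(p16)), 16L)

  # RGB written without a channel selection must error; with one, reads
  rgb <- array(runif(12 * 12 * 3), c(12, 12, 3))
  prgb <- file.path(d, "rgb.tif")
  tiff::writeTIFF(rgb, prgb, bits.per.sample = 8L)
  expect_error(readImage2D(prgb), "multi-channel")
  expect_equal(dim(pixels(readImage2D(prgb, channel = 2))), c(12L, 12L))
  expect_error(readImage2D(file.path(d, "absent.tif")), "not found")
})

test_that("saturation rescale maps the 1% quantiles onto full range", {
  # constant image: degenerate quantiles, unchanged
  cst <- MorphImage(matrix(40, 10, 10), 8L)
  expect_message(out <- saturateRescale(cst), "degenerate")
  expect_equal(pixels(out), pixels(cst))

  # 100-px ramp 0..99 at 1% saturation: linear map of [q01, q99] onto
  # [0, 255]; expected values via the hand-evaluated type-7 quantile map
  ramp <- MorphImage(matrix(0:99, 10, 10), 8L)
  out <- pixels(saturateRescale(ramp, 0.01, 0.01))
  qlo <- 0.99
  qhi <- 98.01
  expected <- pmin(pmax((0:99 - qlo) / (qhi - qlo), 0), 1) * 255
  expect_equal(as.vector(out), expected, tolerance = 1e-12)
  expect_equal(round(out[2, 1]), 0)   # value 1 -> 0 on the integer grid
  expect_equal(round(out[9, 10]), 255) # value 98 -> 255

  # range contract on arbitrary images with >= 2 distinct quantiles
  set.seed(7)
  img <- MorphImage(matrix(sample.int(200L, 400, TRUE), 20, 20), 8L)
  out <- pixels(saturateRescale(img))
  expect_equal(min(out), 0)
  expect_equal(max(out), 255)
})

test_that("CLAHE preserves degenerate and two-tone structure", {
  cst <- clahe(MorphImage(matrix(120, 32, 32), 8L), tiles = c(4L, 4L))
  expect_equal(length(unique(as.vector(pixels(cst)))), 1L)

  # two-tone 25%/75% in a repeating pattern (every tile sees the same
  # histogram, so the interpolated mapping is spatially constant)
  pat <- matrix(c(200, 30, 30, 30), 2, 2)
  two <- MorphImage(pat[rep(1:2, 16), rep(1:2, 16)], 8L)
  out <- clahe(two, tiles = c(4L, 4L))
  expect_equal(length(unique(as.vector(pixels(out)))), 2L)

  # coarser tile grid than image: reduced to 1x1 with a warning
  expect_warning(clahe(MorphImage(matrix(1:16, 4, 4), 8L),
                       tiles = c(8L, 8L)), "1x1")
})

test_that("CLAHE with clip = 1 equals a brute-force tile equalizer", {
  set.seed(42)
  img <- MorphImage(matrix(sample.int(256L, 64 * 64, TRUE) - 1L, 64, 64), 8L)
  tiles <- c(4L, 4L)
  nbins <- 256L
  out <- pixels(clahe(img, tiles = tiles, clip = 1, nbins = nbins))

  # independent per-pixel implementation: per-tile unclipped CDF mapping,
  # bilinear interpolation between the four nearest tile centers
  x <- pixels(img)
  tileH <- 64 / tiles[1]
  tileW <- 64 / tiles[2]
  binOf <- function(v) min(floor(v / (255 + 1e-9) * nbins) + 1, nbins)
  tileMap <- array(0, c(nbins, tiles[1], tiles[2]))
  for (ty in 1:tiles[1]) {
    for (tx in 1:tiles[2]) {
      px <- x[((ty - 1) * tileH + 1):(ty * tileH),
              ((tx - 1) * tileW + 1):(tx * tileW)]
      h <- numeric(nbins)
      for (v in px) h[binOf(v)] <- h[binOf(v)] + 1
      tileMap[, ty, tx] <- cumsum(h) / length(px) * 255
    }
  }
  ref <- matrix(0, 64, 64)
  for (r in 1:64) {
    for (cc in 1:64) {
      gy <- min(max((r - 0.5) / tileH - 0.5, 0), tiles[1] - 1)
      gx <- min(max((cc - 0.5) / tileW - 0.5, 0), tiles[2] - 1)
      y0 <- floor(gy); x0 <- floor(gx)
      y1 <- min(y0 + 1, tiles[1] - 1); x1 <- min(x0 + 1, tiles[2] - 1)
      wy <- gy - y0; wx <- gx - x0
      b <- binOf(x[r, cc])
      ref[r, cc] <-
        (1 - wy) * ((1 - wx) * tileMap[b, y0 + 1, x0 + 1] +
                    wx * tileMap[b, y0 + 1, x1 + 1]) +
        wy * ((1 - wx) * tileMap[b, y1 + 1, x0 + 1] +
              wx * tileMap[b, y1 + 1, x1 + 1])
    }
  }
  expect_equal(out, ref, tolerance = 1e-9)
})

test_that("adaptive Wiener filter matches its defining formula", {
  cst <- wienerAdaptive(MorphImage(matrix(7, 12, 12), 8L))
  expect_equal(pixels(cst), matrix(7, 12, 12))

  imp <- matrix(0, 11, 11)
  imp[6, 6] <- 200
  out <- pixels(wienerAdaptive(MorphImage(imp, 8L)))
  expect_lt(out[6, 6], 200) # low-pass: center attenuated toward local mean

  # brute-force per-pixel oracle on a random image
  set.seed(9)
  x <- matrix(sample.int(256L, 256, TRUE) - 1L, 16, 16)
  w <- 3L
  m <- (w - 1L) %/% 2L
  pad <- rbind(x[m:1, ], x, x[16:(16 - m + 1), ])
  pad <- cbind(pad[, m:1], pad, pad[, 16:(16 - m + 1)])
  mu <- matrix(0, 16, 16)
  s2 <- matrix(0, 16, 16)
  for (r in 1:16) {
    for (cc in 1:16) {
      win <- pad[r:(r + 2 * m), cc:(cc + 2 * m)]
      mu[r, cc] <- mean(win)
      s2[r, cc] <- mean(win^2) - mean(win)^2
    }
  }
  nu2 <- mean(s2)
  ref <- mu + pmax(s2 - nu2, 0) / pmax(s2, nu2) * (x - mu)
  expect_equal(pixels(wienerAdaptive(MorphImage(x, 8L), 3L)), ref,
               tolerance = 1e-9)
})

test_that("Gaussian smoothing is normalized, mean-conserving and exact on ramps", {
  cst <- gaussianSmooth(MorphImage(matrix(3, 9, 9), 8L), 0.5)
  expect_equal(pixels(cst), matrix(3, 9, 9), tolerance = 1e-12)

  imp <- matrix(0, 21, 21)
  imp[11, 11] <- 1
  out <- pixels(gaussianSmooth(MorphImage(imp, 8L), 0.8))
  expect_equal(sum(out), 1, tolerance = 1e-12) # kernel normalization
  # separable kernel reproduced exactly at the center cross
  r <- ceiling(4 * 0.8)
  k <- dnorm(seq(-r, r), sd = 0.8)
  k <- k / sum(k)
  expect_equal(out[11, 11 + (-r:r)], k * k[r + 1], tolerance = 1e-12)

  # linear ramp is an eigenfunction of symmetric smoothing in the interior
  ramp <- matrix(rep(1:30, each = 30), 30, 30)
  sm <- pixels(gaussianSmooth(MorphImage(ramp, 8L), 0.5))
  expect_equal(sm[10:20, 10:20], ramp[10:20, 10:20], tolerance = 1e-9)
  expect_equal(mean(sm), mean(ramp), tolerance = 1e-9) # mean conservation
})

test_that("ROI extraction crops exactly and refuses out-of-bounds centers", {
  set.seed(2)
  m <- matrix(sample.int(256L, 200 * 200, TRUE) - 1L, 200, 200)
  img <- MorphImage(m, 8L)

  whole <- extractROIs(MorphImage(m[1:69, 1:69], 8L),
                       centers = cbind(35L, 35L), size = 69L)
  expect_equal(pixels(whole[[1]]), m[1:69, 1:69])

  centers <- rbind(c(35L, 35L), c(35L, 130L), c(130L, 35L), c(130L, 130L))
  rois <- extractROIs(img, centers, size = 69L)
  expect_length(rois, 4L)
  expect_equal(pixels(rois[[2]]), m[1:69, 96:164])
  expect_equal(pixels(rois[[4]]), m[96:164, 96:164])

  expect_error(extractROIs(img, cbind(10L, 100L), size = 69L),
               "\\(10, 100\\)")
})

test_that("the full chain is deterministic, shape-preserving and flat on flats", {
  cst <- MorphImage(matrix(77, 69, 69), 8L)
  out <- preprocessImage(cst)
  expect_equal(length(unique(as.vector(pixels(out)))), 1L)
  expect_equal(dim(out), c(69L, 69L))

  img <- makePuncta(synthConfig(seed = 5))
  a <- preprocessImage(img)
  b <- preprocessImage(img)
  expect_identical(pixels(a), pixels(b)) # bit-identical rerun
  expect_equal(bitDepth(a), 8L)
  expect_true(all(pixels(a) == round(pixels(a)))) # re-quantized at chain end
})

test_that("Wiener filtering never increases variance of pure-noise images", {
  for (s in 1:5) {
    set.seed(s)
    x <- matrix(rnorm(32 * 32, 128, 20), 32, 32)
    x <- pmin(pmax(round(x), 0), 255)
    out <- pixels(wienerAdaptive(MorphImage(x, 8L), 3L))
    expect_lte(var(as.vector(out)), var(as.vector(x)))
  }
})
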
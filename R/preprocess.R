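# Image pre-processing chain for confocal mitochondria images:
# quantile saturation rescale -> CLAHE -> adaptive Wiener -> Gaussian smooth,
# followed by fixed-size ROI extraction. All stages operate in floating
# point within the declared dynamic range; integer re-quantization happens
# once, at the end of the chain.

#' Read a single-channel 2D TIFF as a MorphImage
#'
#' @param path path to a TIFF file.
#' @param channel for multi-channel images, the 1-based channel to read;
#'   reading a multi-channel image without naming a channel is an error.
#' @param pixelSizeUm optional physical pixel size to record.
#' @return a [MorphImage] with integer intensities and the bit depth of the
#'   file (8 or 16).
#' @export
readImage2D <- function(path, channel = NULL, pixelSizeUm = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tiff::readTIFF(path, as.is = TRUE, all = FALSE)
  if (is.list(raw)) stop("multi-page TIFF not supported: ", path)
  if (length(dim(raw)) == 3L) {
    if (is.null(channel)) {
      stop(
        "multi-channel TIFF (", dim(raw)[3],
        " channels); pass `channel` to select one: ", path
      )
    }
    if (channel < 1L || channel > dim(raw)[3]) {
      stop("channel ", channel, " out of range for ", path)
    }
    raw <- raw[, , channel]
  }
  if (length(dim(raw)) != 2L) stop("not a 2D image: ", path)
  mx <- max(raw)
  depth <- attr(raw, "bits.per.sample")
  if (is.null(depth)) depth <- if (mx > 255) 16L else 8L
  if (!(depth %in% c(8L, 16L))) stop("unsupported bit depth ", depth, ": ", path)
  MorphImage(raw, bitDepth = as.integer(depth), pixelSizeUm = pixelSizeUm)
}

#' Write a MorphImage to TIFF
#'
#' Intensities are rounded to the integer grid of the image's bit depth.
#' @param img a [MorphImage].
#' @param path output path.
#' @export
writeImage2D <- function(img, path) {
  stopifnot(is(img, "MorphImage"))
  hi <- 2^img@bitDepth - 1
  m <- round(.clip(img@pixels, 0, hi))
  tiff::writeTIFF(m / hi, path, bits.per.sample = img@bitDepth)
  invisible(path)
}

#' Pre-processing configuration
#'
#' Defaults follow the conventional adaptive-equalization settings for this
#' chain: saturate the bottom and top 1% of intensities, 8x8 CLAHE tiles
#' with a clip fraction of 0.01 over 256 histogram bins, a 3x3 adaptive
#' Wiener window, and a Gaussian kernel with a standard deviation of 0.5 px.
#'
#' @param satLowFrac,satHighFrac fractions of pixels saturated at the
#'   bottom/top of the intensity range (each in `[0, 0.5)`).
#' @param claheTiles integer length-2, CLAHE tile grid (rows, cols).
#' @param claheClip histogram clip limit as a fraction of the tile pixel
#'   count.
#' @param claheBins number of histogram bins for CLAHE.
#' @param wienerWindow odd window size (>= 3) for the adaptive Wiener filter.
#' @param gaussSigma standard deviation (pixels) of the Gaussian smoother.
#' @return a named list of validated settings.
#' @export
preprocessConfig <- function(satLowFrac = 0.01, satHighFrac = 0.01,
                             claheTiles = c(8L, 8L), claheClip = 0.01,
                             claheBins = 256L, wienerWindow = 3L,
                             gaussSigma = 0.5) {
  stopifnot(
    satLowFrac >= 0, satLowFrac < 0.5,
    satHighFrac >= 0, satHighFrac < 0.5,
    length(claheTiles) == 2L, all(claheTiles >= 1L),
    claheClip > 0, claheBins >= 2L,
    wienerWindow >= 3L, wienerWindow %% 2L == 1L,
    gaussSigma > 0
  )
  list(
    satLowFrac = satLowFrac, satHighFrac = satHighFrac,
    claheTiles = as.integer(claheTiles), claheClip = claheClip,
    claheBins = as.integer(claheBins), wienerWindow = as.integer(wienerWindow),
    gaussSigma = gaussSigma
  )
}

#' Saturation rescale (percentile contrast stretch)
#'
#' Linearly maps the `[q_low, q_high]` intensity quantiles onto the full
#' dynamic range, clipping values outside. Quantiles use linear
#' interpolation (R type 7). A constant image (degenerate quantiles) is
#' returned unchanged with a message.
#'
#' @param img a [MorphImage].
#' @param lowFrac,highFrac saturated fractions at each end (default 0.01).
#' @return a [MorphImage], same bit depth, floating-point intensities
#'   spanning `[0, 2^bitDepth - 1]`.
#' @export
saturateRescale <- function(img, lowFrac = 0.01, highFrac = 0.01) {
  stopifnot(is(img, "MorphImage"), lowFrac >= 0, lowFrac < 0.5,
            highFrac >= 0, highFrac < 0.5)
  x <- img@pixels
  qq <- .q(x, c(lowFrac, 1 - highFrac))
  if (qq[1] >= qq[2]) {
    message("saturateRescale: degenerate quantiles, image returned unchanged")
    return(img)
  }
  hi <- 2^img@bitDepth - 1
  out <- .clip((x - qq[1]) / (qq[2] - qq[1]), 0, 1) * hi
  initialize(img, pixels = out)
}

# Per-tile clipped-histogram CDF mappings. Returns list(maps = bins x tiles
# matrix of output intensities, edges = bin edges).
.claheTileMaps <- function(xp, tileH, tileW, nTiles, clip, nbins, hi) {
  nty <- nTiles[1]
  ntx <- nTiles[2]
  tilePix <- tileH * tileW
  clipCount <- clip * tilePix
  # bin index per pixel over the full dynamic range
  bin <- pmin(floor(xp / (hi + 1e-9) * nbins) + 1L, nbins)
  maps <- matrix(0, nbins, nty * ntx)
  for (ty in seq_len(nty)) {
    for (tx in seq_len(ntx)) {
      rows <- ((ty - 1L) * tileH + 1L):(ty * tileH)
      cols <- ((tx - 1L) * tileW + 1L):(tx * tileW)
      h <- tabulate(bin[rows, cols], nbins)
      excess <- sum(pmax(h - clipCount, 0))
      h <- pmin(h, clipCount) + excess / nbins
      cdf <- cumsum(h) / tilePix
      maps[, (ty - 1L) * ntx + tx] <- cdf * hi
    }
  }
  maps
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-wise histogram equalization in which each tile's histogram is
#' clipped at `clip` times the tile pixel count, the excess redistributed
#' uniformly over all bins (one pass), and per-pixel output obtained by
#' bilinear interpolation between the mappings of the four nearest tile
#' centers. The image is mirror-padded on the bottom/right to a multiple of
#' the tile size. With `clip = 1` no clipping occurs and the result is
#' plain tile-wise adaptive equalization.
#'
#' @param img a [MorphImage].
#' @param tiles integer length-2 tile grid (rows, cols); a grid coarser
#'   than the image is reduced to 1x1 with a warning.
#' @param clip clip limit as a fraction of the tile pixel count.
#' @param nbins number of histogram bins.
#' @return a [MorphImage] spanning the full dynamic range.
#' @export
clahe <- function(img, tiles = c(8L, 8L), clip = 0.01, nbins = 256L) {
  stopifnot(is(img, "MorphImage"), length(tiles) == 2L, clip > 0, nbins >= 2L)
  x <- img@pixels
  hi <- 2^img@bitDepth - 1
  nr <- nrow(x)
  nc <- ncol(x)
  tiles <- as.integer(tiles)
  if (any(c(nr, nc) %/% tiles < 1L)) {
    warning("tile grid coarser than image; reduced to 1x1")
    tiles <- c(1L, 1L)
  }
  tileH <- ceiling(nr / tiles[1])
  tileW <- ceiling(nc / tiles[2])
  padR <- tiles[1] * tileH - nr
  padC <- tiles[2] * tileW - nc
  xp <- x
  if (padR > 0L) xp <- rbind(xp, xp[nr:(nr - padR + 1L), , drop = FALSE])
  if (padC > 0L) xp <- cbind(xp, xp[, ncol(xp):(ncol(xp) - padC + 1L), drop = FALSE])
  maps <- .claheTileMaps(xp, tileH, tileW, tiles, clip, nbins, hi)

  # bilinear interpolation between tile-center mappings
  bin <- pmin(floor(x / (hi + 1e-9) * nbins) + 1L, nbins)
  ri <- row(x)
  ci <- col(x)
  # continuous tile coordinate of each pixel (tile centers at 0.5, 1.5, ...)
  gy <- .clip((ri - 0.5) / tileH - 0.5, 0, tiles[1] - 1)
  gx <- .clip((ci - 0.5) / tileW - 0.5, 0, tiles[2] - 1)
  y0 <- pmin(floor(gy), tiles[1] - 1L)
  x0 <- pmin(floor(gx), tiles[2] - 1L)
  y1 <- pmin(y0 + 1L, tiles[1] - 1L)
  x1 <- pmin(x0 + 1L, tiles[2] - 1L)
  wy <- gy - y0
  wx <- gx - x0
  ntx <- tiles[2]
  m00 <- maps[cbind(as.vector(bin), as.vector(y0 * ntx + x0 + 1L))]
  m01 <- maps[cbind(as.vector(bin), as.vector(y0 * ntx + x1 + 1L))]
  m10 <- maps[cbind(as.vector(bin), as.vector(y1 * ntx + x0 + 1L))]
  m11 <- maps[cbind(as.vector(bin), as.vector(y1 * ntx + x1 + 1L))]
  out <- (1 - wy) * ((1 - wx) * m00 + wx * m01) + wy * ((1 - wx) * m10 + wx * m11)
  dim(out) <- dim(x)
  initialize(img, pixels = .clip(out, 0, hi))
}

#' Pixel-wise adaptive Wiener filter
#'
#' For each pixel, with local mean \eqn{\mu} and local variance
#' \eqn{\sigma^2} over a `window` x `window` neighborhood (symmetric
#' boundary padding) and noise power \eqn{\nu^2} estimated as the mean of
#' all local variances:
#' \deqn{out = \mu + \frac{\max(\sigma^2 - \nu^2, 0)}{\max(\sigma^2, \nu^2)}(x - \mu)}
#' with \eqn{out = \mu} where \eqn{\sigma^2 = \nu^2 = 0}. This is the
#' classic locally adaptive minimum mean-square-error smoother: flat
#' regions are averaged, high-variance structure is preserved.
#'
#' @param img a [MorphImage].
#' @param window odd neighborhood size, >= 3.
#' @return a [MorphImage].
#' @export
wienerAdaptive <- function(img, window = 3L) {
  stopifnot(is(img, "MorphImage"), window >= 3L, window %% 2L == 1L)
  x <- img@pixels
  mom <- .localMoments(x, as.integer(window))
  mu <- mom$mean
  sig2 <- pmax(mom$meansq - mu^2, 0)
  nu2 <- mean(sig2)
  denom <- pmax(sig2, nu2)
  gain <- ifelse(denom > 0, pmax(sig2 - nu2, 0) / denom, 0)
  out <- mu + gain * (x - mu)
  hi <- 2^img@bitDepth - 1
  initialize(img, pixels = .clip(out, 0, hi))
}

#' Gaussian smoothing
#'
#' Separable convolution with a normalized Gaussian kernel truncated at
#' 4 sigma, using symmetric boundary padding (so the mean intensity is
#' conserved to numerical tolerance).
#'
#' @param img a [MorphImage].
#' @param sigma kernel standard deviation in pixels (> 0).
#' @return a [MorphImage].
#' @export
gaussianSmooth <- function(img, sigma = 0.5) {
  stopifnot(is(img, "MorphImage"), sigma > 0)
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  out <- .sepConvolve(img@pixels, k)
  hi <- 2^img@bitDepth - 1
  initialize(img, pixels = .clip(out, 0, hi))
}

#' Run the full pre-processing chain
#'
#' Saturation rescale, CLAHE, adaptive Wiener filtering and Gaussian
#' smoothing, in that order, in floating point; the result is re-quantized
#' to the integer grid of the input bit depth at the end of the chain.
#'
#' @param img a [MorphImage].
#' @param config a [preprocessConfig()] list.
#' @return a [MorphImage] with integer intensities.
#' @export
preprocessImage <- function(img, config = preprocessConfig()) {
  out <- saturateRescale(img, config$satLowFrac, config$satHighFrac)
  out <- clahe(out, config$claheTiles, config$claheClip, config$claheBins)
  out <- wienerAdaptive(out, config$wienerWindow)
  out <- gaussianSmooth(out, config$gaussSigma)
  hi <- 2^img@bitDepth - 1
  initialize(out, pixels = round(.clip(out@pixels, 0, hi)))
}

#' Extract fixed-size square ROIs
#'
#' Crops `size` x `size` regions centered on the requested pixels. Every
#' ROI must lie fully inside the image: no padding is ever applied, and an
#' out-of-bounds request is an error naming the offending center.
#'
#' @param img a [MorphImage].
#' @param centers two-column matrix (row, col) of 1-based ROI centers; or
#'   the string `"grid"` for the maximal set of non-overlapping ROIs.
#' @param size ROI edge length in pixels (default 69, an odd size so the
#'   center pixel is well defined).
#' @return a list of [MorphImage] crops; for `"grid"`, with a
#'   `centers` attribute recording the grid.
#' @export
extractROIs <- function(img, centers, size = 69L) {
  stopifnot(is(img, "MorphImage"), size >= 1L)
  size <- as.integer(size)
  d <- dim(img@pixels)
  if (identical(centers, "grid")) {
    nby <- d[1] %/% size
    nbx <- d[2] %/% size
    if (nby < 1L || nbx < 1L) stop("image smaller than one ROI")
    cy <- (seq_len(nby) - 1L) * size + (size + 1L) %/% 2L
    cx <- (seq_len(nbx) - 1L) * size + (size + 1L) %/% 2L
    centers <- as.matrix(expand.grid(row = cy, col = cx))
  }
  centers <- as.matrix(centers)
  stopifnot(ncol(centers) == 2L)
  lo <- (size - 1L) %/% 2L
  hiOff <- size - 1L - lo
  out <- vector("list", nrow(centers))
  for (i in seq_len(nrow(centers))) {
    r <- centers[i, 1]
    cc <- centers[i, 2]
    r0 <- r - lo
    r1 <- r + hiOff
    c0 <- cc - lo
    c1 <- cc + hiOff
    if (r0 < 1L || c0 < 1L || r1 > d[1] || c1 > d[2]) {
      stop(sprintf(
        "ROI at center (%d, %d) with size %d exceeds the %dx%d image",
        r, cc, size, d[1], d[2]
      ))
    }
    out[[i]] <- initialize(img, pixels = img@pixels[r0:r1, c0:c1, drop = FALSE])
  }
  attr(out, "centers") <- centers
  out
}
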
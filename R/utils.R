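# Internal numerical helpers shared across the pre-processing and feature
# modules. All image filtering in this package uses symmetric (mirror)
# boundary padding so that smoothing conserves the mean intensity.

# log-guard used inside every entropy computation (base-2 logs throughout)
.EPS <- 2^-52

.log2e <- function(p) log2(p + .EPS)

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals never disturb
#' the caller's RNG stream.
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stream of per-item seeds (< 2^31) from one root seed.
.seedStream <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max, n))
}

# Mirror-pad a matrix by `m` rows/cols on every side (symmetric padding:
# the edge pixel is not repeated; pad of m reflects rows m..1).
.mirrorPad <- function(x, m) {
  if (m == 0L) return(x)
  nr <- nrow(x)
  nc <- ncol(x)
  stopifnot(m < nr, m < nc)
  ri <- c(m:1, seq_len(nr), nr - seq_len(m) + 1L)
  ci <- c(m:1, seq_len(nc), nc - seq_len(m) + 1L)
  x[ri, ci, drop = FALSE]
}

# Separable 1D convolution along rows then columns of a mirror-padded
# matrix; `kernel` has odd length. Returns a matrix of the original size.
.sepConvolve <- function(x, kernel) {
  k <- length(kernel)
  stopifnot(k %% 2L == 1L)
  m <- (k - 1L) %/% 2L
  xp <- .mirrorPad(x, m)
  nr <- nrow(x)
  nc <- ncol(x)
  # along columns (vertical pass)
  v <- matrix(0, nr, nc + 2L * m)
  for (t in seq_len(k)) {
    v <- v + kernel[t] * xp[t:(t + nr - 1L), , drop = FALSE]
  }
  out <- matrix(0, nr, nc)
  for (t in seq_len(k)) {
    out <- out + kernel[t] * v[, t:(t + nc - 1L), drop = FALSE]
  }
  out
}

# Box mean and mean-of-squares over a w x w window (odd w), mirror padding.
.localMoments <- function(x, w) {
  m <- (w - 1L) %/% 2L
  kern <- rep(1 / w, w)
  mu <- .sepConvolve(x, kern)
  mu2 <- .sepConvolve(x * x, kern)
  list(mean = mu, meansq = mu2)
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# population moments; zero-variance convention: skewness/kurtosis -> 0
.popSkewKurt <- function(x) {
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  if (m2 <= 0) return(c(skewness = 0, kurtosis = 0))
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  c(skewness = m3 / m2^1.5, kurtosis = m4 / m2^2)
}

# quantiles: linear interpolation (type 7) everywhere in the package
.q <- function(x, p) unname(stats::quantile(x, p, type = 7, names = FALSE))
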
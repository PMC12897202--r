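# Shared fixtures built in code at test time.

# random integer-valued ROI as a MorphImage (8-bit range)
randomROI <- function(n = 16L, m = n, ngApprox = 8L, seed = 1L, bw = 25) {
  set.seed(seed)
  vals <- sample.int(ngApprox, n * m, replace = TRUE)
  MorphImage(matrix((vals - 1L) * bw + sample.int(bw, n * m, replace = TRUE) - 1L,
                    n, m), bitDepth = 8L)
}

# simulated feature table (in feature space, not via images): three classes
# with partially overlapping Gaussian features, fibers/rods closer together
simFeatureTable <- function(nPerClass = 20L, nFeatures = 10L, sep = 2,
                            seed = 1L) {
  set.seed(seed)
  classes <- c("fiber", "puncta", "rod")
  centers <- rbind(
    fiber = c(rep(0, nFeatures)),
    puncta = c(rep(sep, nFeatures)),
    rod = c(rep(0.6 * sep, nFeatures)) # closer to fiber: the hard pair
  )
  x <- NULL
  y <- character(0)
  for (cl in classes) {
    x <- rbind(x, sweep(matrix(rnorm(nPerClass * nFeatures), nPerClass),
                        2L, centers[cl, ], "+"))
    y <- c(y, rep(cl, nPerClass))
  }
  colnames(x) <- paste0("f", seq_len(nFeatures))
  rownames(x) <- sprintf("s%03d", seq_along(y))
  list(x = x, y = y)
}

# memoized 30/30/30 preprocessed synthetic feature table used by the
# end-to-end and directional acceptance checks
.sharedEnv <- new.env(parent = emptyenv())

sharedFeatureTable <- function(seed = 11L) {
  key <- paste0("ft", seed)
  if (is.null(.sharedEnv[[key]])) {
    ds <- makeDataset(nPerClass = 30L, seed = seed)
    .sharedEnv[[key]] <- extractFeatureTable(
      ds$images, ds$manifest$class_label, ds$manifest$roi_id,
      preprocess = preprocessConfig(), seed = seed
    )
  }
  .sharedEnv[[key]]
}
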
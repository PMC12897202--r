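# Standardization, recursive feature elimination, and the two classifiers.

test_that("scaler standardizes training data and never sees test folds", {
  set.seed(1)
  x <- matrix(rnorm(200, 5, 3), 20, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  sc <- fitScaler(x)
  z <- applyScaler(sc, x)
  expect_equal(unname(colMeans(z)), rep(0, 10), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 10), tolerance = 1e-12)

  # no leakage: the training-fold transform is a pure function of the
  # training rows, however the held-out rows or labels change
  tr <- 1:12
  sc1 <- fitScaler(x[tr, ])
  x2 <- x
  x2[13:20, ] <- matrix(rnorm(80, 100, 50), 8, 10)
  sc2 <- fitScaler(x2[tr, ])
  expect_identical(sc1, sc2)
})

test_that("RFE recovers planted informative features and honors nKeep", {
  # 200 samples x 25 features, exactly 5 carry the class signal
  set.seed(7)
  n <- 200L
  x <- matrix(rnorm(n * 25), n, 25, dimnames = list(NULL, paste0("f", 1:25)))
  y <- rep(c("a", "b"), each = n / 2)
  informative <- paste0("f", 1:5)
  x[y == "b", 1:5] <- x[y == "b", 1:5] + 1.5
  sel <- rfeCV(x, nKeep = 20L, labels = y, cvFolds = 0L, seed = 7)
  expect_length(retainedFeatures(sel), 20L)
  expect_true(all(informative %in% retainedFeatures(sel)))
  # the planted features carry all the signal: they should head the ranking
  expect_true(all(featureRanking(sel)$rank[
    match(informative, featureRanking(sel)$feature)
  ] <= 10))

  # identity selection when nKeep equals the feature count
  selAll <- rfeCV(x, nKeep = 25L, labels = y, cvFolds = 0L, seed = 7)
  expect_setequal(retainedFeatures(selAll), colnames(x))

  # a duplicated column gets an adjacent-rank twin; size contract holds
  xdup <- cbind(x, f1dup = x[, 1])
  seld <- rfeCV(xdup, nKeep = 20L, labels = y, cvFolds = 0L, seed = 7)
  expect_length(retainedFeatures(seld), 20L)

  # constant features are dropped with a warning before ranking
  xconst <- cbind(x, fconst = 1)
  expect_warning(rfeCV(xconst, nKeep = 20L, labels = y, cvFolds = 0L,
                       seed = 7), "constant")
})

test_that("RFE is deterministic and reports an accuracy curve", {
  sim <- simFeatureTable(nPerClass = 15L, seed = 3)
  s1 <- rfeCV(sim$x, nKeep = 5L, labels = sim$y, cvFolds = 3L, seed = 11)
  s2 <- rfeCV(sim$x, nKeep = 5L, labels = sim$y, cvFolds = 3L, seed = 11)
  expect_identical(featureRanking(s1), featureRanking(s2))
  expect_identical(s1@accuracyCurve, s2@accuracyCurve)
  expect_true(nrow(s1@accuracyCurve) > 1)
  expect_true(all(s1@accuracyCurve$cv_accuracy >= 0 &
                  s1@accuracyCurve$cv_accuracy <= 1))
})

test_that("decision trees split separable toys perfectly", {
  # 1D two-class toy: single split suffices
  x <- matrix(c(seq(-2, -0.1, length.out = 20),
                seq(0.1, 2, length.out = 20)), ncol = 1,
              dimnames = list(NULL, "x1"))
  y <- rep(c("neg", "pos"), each = 20)
  m <- fitDecisionTree(x, labels = y)
  expect_equal(mean(predictClasses(m, x) == y), 1)
  expect_equal(nrow(m@fit$frame[m@fit$frame$var != "<leaf>", ]), 1L)

  # three classes, one perfectly predictive feature: two splits, depth 2
  x3 <- matrix(rep(c(0, 5, 10), each = 15) + runif(45, -1, 1), ncol = 1,
               dimnames = list(NULL, "x1"))
  y3 <- rep(c("a", "b", "c"), each = 15)
  m3 <- fitDecisionTree(x3, labels = y3)
  expect_equal(mean(predictClasses(m3, x3) == y3), 1)
  expect_equal(nrow(m3@fit$frame[m3@fit$frame$var != "<leaf>", ]), 2L)
})

test_that("label-shuffled CV accuracy sits at the permutation null", {
  set.seed(42)
  n <- 120L
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- sample(rep(c("a", "b", "c"), each = n / 3)) # labels independent of x
  rpt <- repeatedStratifiedCV(x, list(kind = "dt"),
                              cvSpec(10L, 1L, seed = 42), labels = y,
                              roc = FALSE)
  # binomial null: p = 1/3, n = 120 pooled predictions
  se3 <- sqrt(1 / 3 * 2 / 3 / n)
  expect_lt(abs(cvAccuracy(rpt)[["mean"]] - 1 / 3), 3 * se3 + 0.05)
})

test_that("one-vs-rest SVM separates blobs and scores consistently", {
  set.seed(5)
  mkblob <- function(cx, cy, n = 20) cbind(rnorm(n, cx, 0.3), rnorm(n, cy, 0.3))
  x <- rbind(mkblob(0, 0), mkblob(4, 0), mkblob(0, 4))
  colnames(x) <- c("u", "v")
  y <- rep(c("a", "b", "c"), each = 20)
  for (kern in c("radial", "linear")) {
    m <- fitOvrSVM(x, labels = y, kernel = kern)
    expect_equal(mean(predictClasses(m, x) == y), 1)
  }
  m <- fitOvrSVM(x, labels = y)
  sc <- predictScores(m, x)
  expect_equal(dim(sc), c(60L, 3L))
  expect_identical(colnames(sc), c("a", "b", "c"))
  # argmax of decision values is the prediction
  expect_identical(predictClasses(m, x),
                   colnames(sc)[max.col(sc, ties.method = "first")])
  # single sample: score vector has one entry per class
  expect_equal(dim(predictScores(m, x[1, , drop = FALSE])), c(1L, 3L))
})

test_that("score ties resolve to the earlier class in fixed order", {
  # an uninformative root-only tree gives identical class probabilities;
  # the documented tie rule picks the earliest label
  set.seed(8)
  x <- matrix(rnorm(30), 30, 1, dimnames = list(NULL, "f"))
  y <- rep(c("a", "b", "c"), each = 10)
  m <- fitDecisionTree(x, labels = y,
                       control = rpart::rpart.control(minsplit = 100L))
  sc <- predictScores(m, x)
  expect_true(all(sc == 1 / 3)) # degenerate scores: three-way tie
  expect_true(all(predictClasses(m, x) == "a"))
  expect_true(all(abs(rowSums(sc) - 1) < 1e-12)) # DT rows sum to 1
})

test_that("the fit-select-fit pipeline is reproducible under one seed", {
  sim <- simFeatureTable(nPerClass = 12L, seed = 2)
  run <- function() {
    sel <- rfeCV(sim$x, nKeep = 4L, labels = sim$y, cvFolds = 0L, seed = 99)
    m <- fitOvrSVM(sim$x, sel, labels = sim$y, seed = 99)
    predictScores(m, sim$x)
  }
  expect_identical(run(), run())
})

test_that("SVM outperforms the decision tree on most synthetic tables", {
  # moderate-overlap three-morphology feature tables; margin methods
  # should win on most seeds
  wins <- 0L
  for (s in 1:10) {
    sim <- simFeatureTable(nPerClass = 15L, sep = 1.4, seed = s)
    accS <- cvAccuracy(repeatedStratifiedCV(
      sim$x, list(kind = "ovr-svm"), cvSpec(3L, 1L, seed = s),
      labels = sim$y, roc = FALSE
    ))[["mean"]]
    accD <- cvAccuracy(repeatedStratifiedCV(
      sim$x, list(kind = "dt"), cvSpec(3L, 1L, seed = s),
      labels = sim$y, roc = FALSE
    ))[["mean"]]
    if (accS >= accD) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})
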
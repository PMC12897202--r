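# The 93-feature suite: worked examples per family, degenerate-case
# conventions, and equivalence with the brute-force oracles.

test_that("first-order features follow the population-moment definitions", {
  fv <- firstorderFeatures(matrix(1:4, 2, 2))
  expect_equal(unname(fv["Mean"]), 2.5)
  expect_equal(unname(fv["Minimum"]), 1)
  expect_equal(unname(fv["Maximum"]), 4)
  expect_equal(unname(fv["Energy"]), 30)

  cst <- firstorderFeatures(matrix(42, 3, 3))
  expect_equal(unname(cst["Variance"]), 0)
  expect_equal(unname(cst["Skewness"]), 0) # zero-variance convention
  expect_equal(unname(cst["Kurtosis"]), 0)

  # brute-force population moments on a skewed sample
  v <- c(1, 1, 1, 10)
  fv2 <- firstorderFeatures(matrix(v, 2, 2))
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  expect_equal(unname(fv2["Skewness"]), mean((v - mu)^3) / m2^1.5)
  expect_equal(unname(fv2["Kurtosis"]), mean((v - mu)^4) / m2^2)
})

test_that("GLCM matrices count symmetric co-occurrences", {
  checker <- matrix(rep(c(1, 2), 8), 4, 4)
  checker[, c(2, 4)] <- 3 - checker[, c(2, 4)] # proper checkerboard
  q <- quantizeFixedBinWidth((checker - 1) * 25, 25)
  expect_equal(nGrayLevels(q), 2L)
  mats <- glcmMatrix(q)
  H <- mats[[1]] # horizontal offset (0,1)
  expect_equal(H[1, 2], 0.5)
  expect_equal(H[2, 1], 0.5)
  expect_equal(H[1, 1], 0)
  expect_equal(H[2, 2], 0)
  for (m in mats) expect_equal(sum(m), 1) # normalization per angle

  qc <- quantizeFixedBinWidth(matrix(5, 4, 4), 25)
  for (m in glcmMatrix(qc)) expect_equal(m[1, 1], 1)
  expect_error(glcmMatrix(new("QuantizedROI",
    levels = matrix(1L, 1, 1), ng = 1L,
    mask = matrix(TRUE, 1, 1), binWidth = 25
  )), "no valid")
})

test_that("GLCM features honor degenerate conventions and worked examples", {
  cst <- glcmFeatures(quantizeFixedBinWidth(matrix(9, 4, 4), 25))
  expect_equal(unname(cst["Contrast"]), 0)
  expect_equal(unname(cst["JointEntropy"]), 0, tolerance = 1e-12)
  expect_equal(unname(cst["MaximumProbability"]), 1)
  expect_equal(unname(cst["Correlation"]), 1) # zero-marginal-variance rule

  # 2x2 ROI with four distinct levels: horizontal and vertical matrices
  # each have 4 equiprobable symmetric entries -> joint entropy 2 bits
  roi <- matrix(c(0, 50, 25, 75), 2, 2)
  q <- quantizeFixedBinWidth(roi, 25)
  mats <- glcmMatrix(q)
  horiz <- mats[[1]]
  vert <- mats[[3]]
  h2 <- function(P) -sum(P[P > 0] * log2(P[P > 0]))
  expect_equal(h2(horiz), 2, tolerance = 1e-9)
  expect_equal(h2(vert), 2, tolerance = 1e-9)
})

test_that("GLRLM features match single-run hand evaluations", {
  # 1x4 constant ROI. Per direction: horizontal one run of length 4
  # (LRE 16, SRE 1/16, RP 1/4); the other three directions see four
  # singleton runs (all emphases 1). Averages follow.
  fv <- glrlmFeatures(quantizeFixedBinWidth(matrix(10, 1, 4), 25))
  expect_equal(unname(fv["LongRunEmphasis"]), (16 + 1 + 1 + 1) / 4)
  expect_equal(unname(fv["ShortRunEmphasis"]), (1 / 16 + 1 + 1 + 1) / 4)
  expect_equal(unname(fv["RunPercentage"]), (1 / 4 + 1 + 1 + 1) / 4)

  # alternating 1x4 ROI: singleton runs in every direction
  alt <- glrlmFeatures(quantizeFixedBinWidth(matrix(c(0, 25, 0, 25), 1, 4), 25))
  expect_equal(unname(alt["ShortRunEmphasis"]), 1)
  expect_equal(unname(alt["LongRunEmphasis"]), 1)
  expect_equal(unname(alt["RunPercentage"]), 1)
})

test_that("GLSZM features count 8-connected equal-level zones", {
  cst <- glszmFeatures(quantizeFixedBinWidth(matrix(3, 3, 3), 25))
  expect_equal(unname(cst["ZonePercentage"]), 1 / 9)

  roi <- matrix(c(1, 1, 1, 2, 2, 2), 2, 3) * 25 # [[1,1,2],[1,2,2]] pattern
  roi <- rbind(c(1, 1, 2), c(1, 2, 2)) * 25
  fv <- glszmFeatures(quantizeFixedBinWidth(roi, 25))
  expect_equal(unname(fv["ZonePercentage"]), 1 / 3) # 2 zones, 6 pixels
  expect_equal(unname(fv["SizeZoneNonUniformity"]), 2) # 2^2 / 2

  # under 8-connectivity a two-tone checkerboard collapses to 2 zones
  # (diagonal same-level pixels touch); all-singleton zones need all
  # levels distinct
  checker <- outer(1:4, 1:4, function(r, cc) (r + cc) %% 2) * 25
  ck <- glszmFeatures(quantizeFixedBinWidth(checker, 25))
  expect_equal(unname(ck["ZonePercentage"]), 2 / 16)
  expect_equal(unname(ck["LargeAreaEmphasis"]), 64) # two zones of size 8

  allDistinct <- matrix(seq(0, by = 25, length.out = 16), 4, 4)
  ad <- glszmFeatures(quantizeFixedBinWidth(allDistinct, 25))
  expect_equal(unname(ad["SmallAreaEmphasis"]), 1) # 16 singleton zones
  expect_equal(unname(ad["ZonePercentage"]), 1)
})

test_that("NGTDM features follow the neighbor-mean enumeration", {
  cst <- ngtdmFeatures(quantizeFixedBinWidth(matrix(99, 5, 5), 25))
  expect_equal(unname(cst["Coarseness"]), 1e6) # capped degenerate case
  expect_equal(unname(cst["Complexity"]), 0)
  expect_equal(unname(cst["Contrast"]), 0)

  # 3x3 with a single center level 2 in a ring of level 1:
  # s_2 = |2 - 1| = 1; s_1 = 4*(1/3) + 4*(1/5) (corners, edges)
  roi <- matrix(0, 3, 3)
  roi[2, 2] <- 25
  tb <- mitomorph:::.ngtdmTable(quantizeFixedBinWidth(roi, 25))
  expect_equal(tb$s, c(4 / 3 + 4 / 5, 1), tolerance = 1e-12)
  expect_equal(tb$n, c(8L, 1L))
})

test_that("GLDM dependence sizes include the center pixel", {
  # constant 3x3, alpha 0: corners depend on 3 neighbors (j=4), edges on 5
  # (j=6), center on 8 (j=9) -> LDE = (4*16 + 4*36 + 81)/9
  fv <- gldmFeatures(quantizeFixedBinWidth(matrix(7, 3, 3), 25))
  expect_equal(unname(fv["LargeDependenceEmphasis"]), 289 / 9)

  # conservation: row sums of the dependence matrix = per-level counts
  set.seed(21)
  m <- matrix(sample.int(120L, 64, TRUE), 8, 8)
  q <- quantizeFixedBinWidth(m, 25)
  M <- gldmMatrix(q)
  expect_equal(unname(rowSums(M)), tabulate(grayLevels(q), nGrayLevels(q)))

  # checkerboard vs brute-force oracle (convention-sensitive case)
  checker <- outer(1:4, 1:4, function(r, cc) (r + cc) %% 2) * 25
  lv <- oracleQuantize(checker, 25)
  expect_equal(
    unname(gldmFeatures(quantizeFixedBinWidth(checker, 25))),
    unname(oracleGldm(lv, max(lv))),
    tolerance = 1e-12
  )
})

test_that("the assembled 93-vector is complete, ordered and deterministic", {
  roi <- makeRods(synthConfig(seed = 33))
  fv <- extractAllFeatures(roi)
  expect_length(fv, 93L)
  expect_identical(names(fv), featureNames93())
  expect_equal(as.integer(table(sub("_.*", "", names(fv)))[
    c("firstorder", "glcm", "glrlm", "glszm", "ngtdm", "gldm")
  ]), c(18L, 24L, 16L, 16L, 5L, 14L))
  expect_identical(fv, extractAllFeatures(roi)) # determinism

  # 4-direction averaging makes texture families invariant to 90-degree
  # rotation (first-order trivially so)
  rot <- MorphImage(t(pixels(roi))[ncol(pixels(roi)):1, ], 8L)
  fr <- extractAllFeatures(rot)
  idx <- grepl("^(glcm|glrlm)_", names(fv))
  expect_equal(fv[idx], fr[idx], tolerance = 1e-9)
})

test_that("all 93 features match the brute-force oracles on random ROIs", {
  # small random ROIs, coarse levels; the full >=100-ROI sweep runs in the
  # acceptance suite -- this is the per-module gate
  for (s in 1:12) {
    n <- sample(4:12, 1)
    roi <- randomROI(n, n, ngApprox = sample(3:8, 1), seed = 100 + s)
    got <- extractAllFeatures(roi)
    want <- oracleAll93(pixels(roi))
    expect_equal(unname(got), unname(want[names(got)]), tolerance = 1e-9,
                 info = paste("seed", 100 + s))
  }
})

test_that("probability normalizations and feature bounds hold", {
  for (s in 1:10) {
    roi <- randomROI(10, 10, ngApprox = 6, seed = 300 + s)
    q <- quantizeFixedBinWidth(roi, 25)
    for (m in glcmMatrix(q)) expect_equal(sum(m), 1, tolerance = 1e-12)
    fv <- extractAllFeatures(roi)
    expect_gt(fv[["glrlm_RunPercentage"]], 0)
    expect_lte(fv[["glrlm_RunPercentage"]], 1)
    expect_gt(fv[["glszm_ZonePercentage"]], 0)
    expect_lte(fv[["glszm_ZonePercentage"]], 1)
    expect_gt(fv[["glrlm_ShortRunEmphasis"]], 0)
    expect_lte(fv[["glrlm_ShortRunEmphasis"]], 1)
    expect_gt(fv[["glszm_SmallAreaEmphasis"]], 0)
    expect_lte(fv[["glszm_SmallAreaEmphasis"]], 1)
    expect_gt(fv[["gldm_SmallDependenceEmphasis"]], 0)
    expect_lte(fv[["gldm_SmallDependenceEmphasis"]], 1)
    expect_gte(fv[["glcm_Imc2"]], 0)
    expect_lt(fv[["glcm_Imc2"]], 1)
    expect_gt(fv[["glcm_MaximumProbability"]], 0)
    expect_lte(fv[["glcm_MaximumProbability"]], 1)
  }
})

test_that("feature tables round-trip through CSV with metadata", {
  ds <- makeDataset(nPerClass = 3L, seed = 9)
  se <- extractFeatureTable(ds$images, ds$manifest$class_label,
                            ds$manifest$roi_id, seed = 9)
  expect_equal(dim(se), c(93L, 9L))
  d <- withr::local_tempdir()
  p <- file.path(d, "features.csv")
  writeFeatureTable(se, p)
  expect_true(file.exists(paste0(p, ".meta.json")))
  back <- readFeatureTable(p)
  expect_equal(featureMatrix(back), featureMatrix(se), tolerance = 1e-12)
  expect_equal(classLabels(back), classLabels(se))
})
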
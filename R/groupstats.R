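# Per-feature two-group statistics: MAD-based outlier replacement,
# Shapiro-Wilk normality testing, and a normality-gated choice between
# Welch's unequal-variance t-test and the two-sided Mann-Whitney U test.
# The MAD here is the raw median absolute deviation (no 1.4826 normal
# consistency factor): the outlier bounds are median +/- k * MAD with
# k = 2.1 by default.

#' Replace MAD outliers with NA
#'
#' Values outside `median(x) +/- k * MAD` (MAD = median absolute deviation
#' from the median, unscaled) are replaced by `NA`; order and length are
#' preserved. Applied once, not iterated. When MAD is zero, only values
#' exactly equal to the median survive, with a warning.
#'
#' @param x numeric vector (>= 3 finite values); existing `NA`s pass
#'   through.
#' @param k scaling factor (default 2.1).
#' @return numeric vector with outliers as `NA`, with attributes
#'   `n_replaced` and `bounds`.
#' @export
madOutlierReplace <- function(x, k = 2.1) {
  stopifnot(k > 0)
  fin <- is.finite(x)
  if (sum(fin) < 3L) stop("need at least 3 finite values")
  med <- stats::median(x[fin])
  madRaw <- stats::median(abs(x[fin] - med))
  if (madRaw == 0) {
    warning("MAD is zero: only exact-median values retained")
  }
  lo <- med - k * madRaw
  hi <- med + k * madRaw
  out <- x
  drop <- fin & (x < lo | x > hi)
  out[drop] <- NA_real_
  attr(out, "n_replaced") <- sum(drop)
  attr(out, "bounds") <- c(lower = lo, upper = hi)
  out
}

#' Shapiro-Wilk normality test
#'
#' @param x numeric vector; `NA`s are dropped; needs 3..5000 values.
#' @return list with `statistic` (W) and `p.value`; a degenerate
#'   (zero-range) sample yields `NA` with a warning.
#' @export
normalityTest <- function(x) {
  v <- x[is.finite(x)]
  if (length(v) < 3L || length(v) > 5000L) {
    stop("Shapiro-Wilk requires 3..5000 finite values")
  }
  if (diff(range(v)) == 0) {
    warning("constant sample: normality undefined")
    return(list(statistic = NA_real_, p.value = NA_real_))
  }
  st <- stats::shapiro.test(v)
  list(statistic = unname(st$statistic), p.value = st$p.value)
}

#' Compare two groups for one feature
#'
#' Shapiro-Wilk is run per group; when both groups look normal
#' (p > `normalAlpha`), Welch's unequal-variance t-test is used, otherwise
#' the two-sided Mann-Whitney U test (exact when the combined sample is
#' <= 20 without ties, normal approximation with tie correction above).
#' A degenerate normality result (constant group) routes to Mann-Whitney.
#'
#' @param a,b numeric vectors (>= 3 finite values each); `NA`s dropped.
#' @param alpha significance level (default 0.05).
#' @param normalAlpha normality-test level (default 0.05).
#' @param test `"auto"` (normality-gated choice, the default) or an
#'   explicit `"welch"` / `"mann-whitney"` override.
#' @return list: `test` ("welch" or "mann-whitney"), `statistic`,
#'   `p.value`, `significant`, `normality_p` (length 2), `n` (length 2).
#' @export
compareGroups <- function(a, b, alpha = 0.05, normalAlpha = 0.05,
                          test = c("auto", "welch", "mann-whitney")) {
  test <- match.arg(test)
  av <- a[is.finite(a)]
  bv <- b[is.finite(b)]
  if (length(av) < 3L || length(bv) < 3L) {
    stop("need at least 3 finite values per group")
  }
  pa <- tryCatch(normalityTest(av)$p.value, warning = function(w) NA_real_)
  pb <- tryCatch(normalityTest(bv)$p.value, warning = function(w) NA_real_)
  bothNormal <- !is.na(pa) && !is.na(pb) && pa > normalAlpha && pb > normalAlpha
  useWelch <- switch(test, auto = bothNormal, welch = TRUE,
                     "mann-whitney" = FALSE)

  if (useWelch) {
    ht <- stats::t.test(av, bv, var.equal = FALSE)
    test <- "welch"
  } else {
    exact <- (length(av) + length(bv)) <= 20L && !anyDuplicated(c(av, bv))
    ht <- suppressWarnings(
      stats::wilcox.test(av, bv, exact = exact, correct = TRUE)
    )
    test <- "mann-whitney"
  }
  list(
    test = test,
    statistic = unname(ht$statistic),
    p.value = ht$p.value,
    significant = ht$p.value < alpha,
    normality_p = c(a = pa, b = pb),
    n = c(a = length(av), b = length(bv))
  )
}

.stars <- function(p) {
  if (is.na(p)) return("")
  if (p < 1e-4) return("****")
  if (p < 1e-3) return("***")
  if (p < 0.01) return("**")
  if (p < 0.05) return("*")
  "ns"
}

#' Per-feature two-group comparison table
#'
#' Runs the full statistics chain for every feature of a feature table:
#' MAD outlier replacement per feature per group, then the normality-gated
#' two-group test. No multiple-testing correction is applied by default;
#' set `adjust = "BH"` for Benjamini-Hochberg adjusted significance.
#'
#' @param table feature table ([extractFeatureTable()]) or
#'   samples-by-features matrix.
#' @param groups vector with two distinct values splitting the samples
#'   (defaults to the table's class labels).
#' @param k MAD scaling factor.
#' @param alpha significance level.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame: feature, group means, per-group n after outlier
#'   removal, test, statistic, p, significant, stars.
#' @export
compareFeatureTables <- function(table, groups = NULL, k = 2.1,
                                 alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  x <- if (is(table, "SummarizedExperiment")) featureMatrix(table) else as.matrix(table)
  if (is.null(groups)) groups <- classLabels(table)
  g <- factor(groups)
  if (nlevels(g) != 2L) stop("exactly two groups required")
  ga <- levels(g)[1]
  gb <- levels(g)[2]

  rows <- lapply(colnames(x), function(feat) {
    a <- madOutlierReplace(x[g == ga, feat], k)
    b <- madOutlierReplace(x[g == gb, feat], k)
    res <- tryCatch(compareGroups(a, b, alpha), error = function(e) NULL)
    if (is.null(res)) {
      return(data.frame(
        feature = feat, mean_a = NA_real_, mean_b = NA_real_,
        n_a = sum(is.finite(a)), n_b = sum(is.finite(b)),
        test = NA_character_, statistic = NA_real_, p = NA_real_,
        significant = NA, stringsAsFactors = FALSE
      ))
    }
    data.frame(
      feature = feat,
      mean_a = mean(a, na.rm = TRUE), mean_b = mean(b, na.rm = TRUE),
      n_a = res$n[["a"]], n_b = res$n[["b"]],
      test = res$test, statistic = res$statistic, p = res$p.value,
      significant = res$significant, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  }
  out$stars <- vapply(if (adjust == "BH") out$p_adj else out$p, .stars,
                      character(1))
  names(out)[names(out) == "mean_a"] <- paste0("mean_", ga)
  names(out)[names(out) == "mean_b"] <- paste0("mean_", gb)
  names(out)[names(out) == "n_a"] <- paste0("n_", ga)
  names(out)[names(out) == "n_b"] <- paste0("n_", gb)
  out
}
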
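# Model evaluation: repeated stratified k-fold cross-validation with the
# scaler / feature selector / model refit inside each training fold,
# pooled confusion matrices, per-class precision/recall/F1, and one-vs-rest
# ROC curves with percentile-bootstrap AUC confidence intervals.

#' Cross-validation specification
#'
#' Two schemes are conventional for this pipeline: 10-fold stratified CV
#' for the decision tree, and repeated 2-fold CV with 3 repetitions for the
#' one-vs-rest SVM.
#'
#' @param nFolds folds per repeat (>= 2).
#' @param nRepeats number of repeats.
#' @param stratified preserve class proportions across folds.
#' @param seed RNG seed for the partitioning.
#' @return named list.
#' @export
cvSpec <- function(nFolds = 10L, nRepeats = 1L, stratified = TRUE,
                   seed = 1L) {
  stopifnot(nFolds >= 2L, nRepeats >= 1L)
  list(
    nFolds = as.integer(nFolds), nRepeats = as.integer(nRepeats),
    stratified = isTRUE(stratified), seed = as.integer(seed)
  )
}

#' Stratified fold assignment
#'
#' Assigns samples to `k` folds preserving class proportions: within each
#' class, shuffled indices are dealt round-robin, so every fold receives
#' at least one sample of every class whenever each class has >= k samples.
#'
#' @param y factor (or vector) of class labels.
#' @param k number of folds.
#' @param seed RNG seed.
#' @param stratified set `FALSE` for a plain shuffled split.
#' @return integer vector of fold ids in `1..k`.
#' @export
stratifiedFolds <- function(y, k, seed = 1L, stratified = TRUE) {
  y <- factor(y)
  n <- length(y)
  folds <- integer(n)
  withSeed(seed, {
    if (stratified) {
      for (cl in levels(y)) {
        idx <- sample(which(y == cl))
        folds[idx] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      folds <- rep_len(seq_len(k), n)[sample.int(n)]
    }
  })
  folds
}

#' Per-class precision, recall and F1 from a confusion matrix
#'
#' Rows are true classes, columns predictions. Zero-division cases
#' (a class never predicted, or with no true samples) yield 0 and are
#' flagged in the `undefined` column.
#'
#' @param confusion square matrix of non-negative counts.
#' @return list with `perClass` (data.frame) and `accuracy`.
#' @export
classificationReport <- function(confusion) {
  cm <- as.matrix(confusion)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (any(cm < 0)) stop("negative counts")
  classes <- rownames(cm)
  if (is.null(classes)) classes <- as.character(seq_len(nrow(cm)))
  tp <- diag(cm)
  colS <- colSums(cm)
  rowS <- rowSums(cm)
  precision <- ifelse(colS > 0, tp / colS, 0)
  recall <- ifelse(rowS > 0, tp / rowS, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  list(
    perClass = data.frame(
      class = classes,
      precision = unname(precision),
      recall = unname(recall),
      f1 = unname(f1),
      support = unname(rowS),
      undefined = unname(colS == 0 | rowS == 0),
      stringsAsFactors = FALSE
    ),
    accuracy = sum(tp) / sum(cm)
  )
}

# ---- ROC / AUC ----

#' Empirical ROC curve by threshold sweep
#'
#' All distinct score values are used as thresholds (predict positive when
#' `score >= t`), giving the full staircase from (0,0) to (1,1).
#'
#' @param scores numeric scores, larger = more positive.
#' @param positive logical (or 0/1) vector marking the positive class.
#' @return data.frame with `threshold`, `fpr`, `tpr`, sorted by increasing
#'   false-positive rate.
#' @export
rocCurve <- function(scores, positive) {
  positive <- as.logical(positive)
  stopifnot(length(scores) == length(positive))
  nPos <- sum(positive)
  nNeg <- sum(!positive)
  if (nPos == 0L || nNeg == 0L) stop("need both classes for a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- positive[ord]
  tps <- cumsum(p)
  fps <- cumsum(!p)
  last <- c(diff(s) != 0, TRUE) # keep one point per distinct threshold
  data.frame(
    threshold = c(Inf, s[last]),
    fpr = c(0, fps[last] / nNeg),
    tpr = c(0, tps[last] / nPos)
  )
}

#' Area under an ROC curve (trapezoidal rule)
#'
#' @param scores numeric scores.
#' @param positive logical positive-class indicator.
#' @return AUC in `[0, 1]`.
#' @export
aucFromScores <- function(scores, positive) {
  rc <- rocCurve(scores, positive)
  sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + utils::tail(rc$tpr, -1)) / 2)
}

#' One-vs-rest ROC analysis with bootstrap confidence intervals
#'
#' Computes per-class one-vs-rest ROC curves and AUCs from a score matrix,
#' with percentile confidence intervals over `nBoot` bootstrap resamples of
#' the test set (resampling stratified by class so no resample degenerates
#' to a single class; any degenerate unstratified resample would be redrawn
#' and counted). The macro AUC is the unweighted mean of per-class AUCs.
#'
#' @param scores samples-by-classes score matrix (or a vector for binary
#'   problems scored toward the second class level).
#' @param labels true class labels.
#' @param nBoot bootstrap resamples (default 1000).
#' @param ci confidence level (default 0.95).
#' @param seed RNG seed.
#' @param stratified stratify resamples by class (default TRUE).
#' @return list: `auc` data.frame (class, auc, ci_lo, ci_hi plus a macro
#'   row), `curves` (named list of ROC data.frames), `redraws` (count of
#'   redrawn degenerate resamples).
#' @export
bootstrapROC <- function(scores, labels, nBoot = 1000L, ci = 0.95,
                         seed = 1L, stratified = TRUE) {
  labels <- factor(labels)
  if (is.null(dim(scores))) {
    stopifnot(nlevels(labels) == 2L)
    scores <- cbind(-scores, scores)
    colnames(scores) <- levels(labels)
  }
  scores <- as.matrix(scores)
  stopifnot(nrow(scores) == length(labels))
  classes <- colnames(scores)
  stopifnot(all(levels(labels) %in% classes))
  alpha <- (1 - ci) / 2
  n <- length(labels)

  curves <- list()
  aucs <- numeric(0)
  los <- numeric(0)
  his <- numeric(0)
  redraws <- 0L

  seeds <- .seedStream(seed, length(classes))
  for (k in seq_along(classes)) {
    cl <- classes[k]
    pos <- labels == cl
    sc <- scores[, cl]
    curves[[cl]] <- rocCurve(sc, pos)
    aucHat <- aucFromScores(sc, pos)

    bootA <- withSeed(seeds[k], {
      posIdx <- which(pos)
      negIdx <- which(!pos)
      vapply(seq_len(nBoot), function(b) {
        if (stratified) {
          idx <- c(
            sample(posIdx, length(posIdx), replace = TRUE),
            sample(negIdx, length(negIdx), replace = TRUE)
          )
        } else {
          idx <- sample.int(n, n, replace = TRUE)
          while (length(unique(pos[idx])) < 2L) {
            redraws <<- redraws + 1L
            idx <- sample.int(n, n, replace = TRUE)
          }
        }
        aucFromScores(sc[idx], pos[idx])
      }, numeric(1))
    })
    aucs <- c(aucs, aucHat)
    los <- c(los, .q(bootA, alpha))
    his <- c(his, .q(bootA, 1 - alpha))
  }

  aucDf <- data.frame(
    class = c(classes, "macro"),
    auc = c(aucs, mean(aucs)),
    ci_lo = c(los, NA_real_),
    ci_hi = c(his, NA_real_),
    stringsAsFactors = FALSE
  )
  list(auc = aucDf, curves = curves, redraws = redraws)
}

# ---- repeated stratified CV driver ----

#' Repeated stratified cross-validation of a model specification
#'
#' For every repeat and fold, the scaler, the (optional) feature selector
#' and the model are refit on the training fold only, and the held-out fold
#' is scored: there is no information leakage from test folds. Accuracy is
#' reported as mean +/- standard deviation across all folds of all repeats;
#' the confusion matrix pools every test-fold prediction; out-of-fold
#' scores are pooled for the optional bootstrap ROC analysis.
#'
#' @param table feature table or samples-by-features matrix.
#' @param modelSpec list describing the model: `kind` (`"dt"` or
#'   `"ovr-svm"`) plus hyperparameters passed to the fitter
#'   ([fitDecisionTree()] / [fitOvrSVM()]).
#' @param cv a [cvSpec()] list.
#' @param labels labels when `table` is a matrix.
#' @param selection optional fixed [FeatureSelection] applied as-is;
#'   alternatively `nKeep` triggers RFE inside every training fold.
#' @param nKeep when non-`NULL`, run [rfeCV()] with this retained-set size
#'   inside each training fold.
#' @param roc run [bootstrapROC()] on the pooled out-of-fold scores.
#' @param nBoot bootstrap resamples for the ROC CIs.
#' @return an [EvalReport].
#' @export
repeatedStratifiedCV <- function(table, modelSpec = list(kind = "ovr-svm"),
                                 cv = cvSpec(), labels = NULL,
                                 selection = NULL, nKeep = NULL,
                                 roc = TRUE, nBoot = 1000L) {
  x <- if (is(table, "SummarizedExperiment")) featureMatrix(table) else as.matrix(table)
  y <- factor(if (is.null(labels)) classLabels(table) else labels)
  stopifnot(nrow(x) == length(y))
  if (min(table(y)) < cv$nFolds) {
    stop("every class must have at least nFolds samples")
  }
  kind <- match.arg(modelSpec$kind, c("ovr-svm", "dt"))
  hyper <- modelSpec[setdiff(names(modelSpec), "kind")]
  classes <- levels(y)

  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(true = classes, predicted = classes))
  foldAcc <- numeric(0)
  allScores <- NULL
  allLabels <- character(0)
  seeds <- .seedStream(cv$seed, cv$nRepeats * cv$nFolds + cv$nRepeats)

  si <- 0L
  for (rep_ in seq_len(cv$nRepeats)) {
    si <- si + 1L
    folds <- stratifiedFolds(y, cv$nFolds, seeds[si], cv$stratified)
    for (f in seq_len(cv$nFolds)) {
      si <- si + 1L
      te <- folds == f
      xtr <- x[!te, , drop = FALSE]
      ytr <- droplevels(y[!te])
      sel <- selection
      if (!is.null(nKeep)) {
        sel <- rfeCV(xtr, nKeep = nKeep, labels = ytr, cvFolds = 0L,
                     seed = seeds[si])
      }
      model <- if (kind == "dt") {
        do.call(fitDecisionTree, c(
          list(table = xtr, selection = sel, labels = ytr, seed = seeds[si]),
          hyper
        ))
      } else {
        do.call(fitOvrSVM, c(
          list(table = xtr, selection = sel, labels = ytr, seed = seeds[si]),
          hyper
        ))
      }
      xte <- x[te, , drop = FALSE]
      pred <- predictClasses(model, xte)
      truth <- as.character(y[te])
      foldAcc <- c(foldAcc, mean(pred == truth))
      for (i in seq_along(pred)) {
        confusion[truth[i], pred[i]] <- confusion[truth[i], pred[i]] + 1L
      }
      sc <- predictScores(model, xte)
      full <- matrix(NA_real_, nrow(sc), length(classes),
                     dimnames = list(NULL, classes))
      full[, colnames(sc)] <- sc
      allScores <- rbind(allScores, full)
      allLabels <- c(allLabels, truth)
    }
  }

  crep <- classificationReport(confusion)
  aucDf <- data.frame()
  details <- list(
    scores = allScores, labels = allLabels, modelSpec = modelSpec, cv = cv
  )
  if (roc) {
    ok <- !apply(is.na(allScores), 1L, any)
    rr <- bootstrapROC(allScores[ok, , drop = FALSE], allLabels[ok],
                       nBoot = nBoot, seed = cv$seed)
    aucDf <- rr$auc
    details$curves <- rr$curves
  }
  new("EvalReport",
    accuracy = c(mean = mean(foldAcc), sd = stats::sd(foldAcc)),
    foldAccuracy = foldAcc,
    confusion = confusion,
    perClass = crep$perClass,
    auc = aucDf,
    details = details
  )
}
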
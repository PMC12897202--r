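# Classification core: z-score standardization, recursive feature
# elimination ranked by linear one-vs-rest SVM coefficient magnitudes, and
# the two classifiers (decision tree; one-vs-rest SVM with argmax of
# decision values). Standardization is applied for margin-based methods
# (SVM, RFE) and not for trees, which are scale-invariant.

# ---- scaler ----

#' Fit a per-feature z-score scaler
#'
#' @param x samples-by-features numeric matrix.
#' @return list with `center` and `scale` (features with zero spread get
#'   scale 1 so they pass through unchanged).
#' @export
fitScaler <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

#' Apply a fitted scaler
#'
#' @param scaler from [fitScaler()].
#' @param x samples-by-features matrix with the same columns.
#' @return standardized matrix.
#' @export
applyScaler <- function(scaler, x) {
  sweep(sweep(x, 2L, scaler$center[colnames(x)]), 2L,
        scaler$scale[colnames(x)], "/")
}

# ---- internal: one-vs-rest linear/RBF SVM on a plain matrix ----

# gamma following the "scale" heuristic: 1 / (n_features * var(x))
.gammaScale <- function(x) {
  v <- stats::var(as.vector(x))
  if (!is.finite(v) || v <= 0) v <- 1
  1 / (ncol(x) * v)
}

# Fit one binary SVM per class; x must already be standardized.
.fitOvr <- function(x, y, kernel, cost, gamma, seed) {
  classes <- levels(y)
  fits <- withSeed(seed, lapply(classes, function(cl) {
    yb <- factor(ifelse(y == cl, "pos", "rest"), levels = c("pos", "rest"))
    e1071::svm(x, yb,
      kernel = kernel, cost = cost, gamma = gamma,
      scale = FALSE, probability = FALSE
    )
  }))
  names(fits) <- classes
  fits
}

# decision-value matrix (samples x classes), positive = toward the class
.ovrDecision <- function(fits, x) {
  dv <- vapply(names(fits), function(cl) {
    pr <- predict(fits[[cl]], x, decision.values = TRUE)
    d <- attr(pr, "decision.values")
    # e1071 reports the value for levels[1] vs levels[2]; column name tells
    # the orientation
    sgn <- if (colnames(d)[1] == "pos/rest") 1 else -1
    sgn * d[, 1]
  }, numeric(nrow(x)))
  matrix(dv, nrow = nrow(x), dimnames = list(rownames(x), names(fits)))
}

# aggregate linear OvR-SVM weights into one importance per feature
.linearImportance <- function(fits, featNames) {
  w2 <- numeric(length(featNames))
  names(w2) <- featNames
  for (f in fits) {
    w <- crossprod(f$coefs, f$SV) # 1 x p
    w2 <- w2 + as.numeric(w)^2
  }
  sqrt(w2)
}

# ---- RFE ----

#' Recursive feature elimination with a linear OvR-SVM ranking
#'
#' Iteratively fits a linear one-vs-rest SVM on standardized features and
#' removes the single feature with the smallest aggregated coefficient
#' magnitude (root-sum-square over the per-class weight vectors) until
#' `nKeep` remain. Constant (zero-variance) features are dropped before
#' ranking, with a warning. Optionally reports a stratified
#' cross-validation accuracy curve as a function of retained-set size.
#'
#' @param table a feature table ([extractFeatureTable()]) or a
#'   samples-by-features matrix with `labels`.
#' @param nKeep number of features to retain (default 20).
#' @param labels class labels when `table` is a plain matrix.
#' @param cost linear-SVM cost parameter.
#' @param cvFolds folds for the accuracy curve (0 disables the curve).
#' @param seed RNG seed; the procedure is deterministic under a fixed seed.
#' @return a [FeatureSelection].
#' @export
rfeCV <- function(table, nKeep = 20L, labels = NULL, cost = 1,
                  cvFolds = 5L, seed = 1L) {
  x <- if (is(table, "SummarizedExperiment")) featureMatrix(table) else as.matrix(table)
  y <- factor(if (is.null(labels)) classLabels(table) else labels)
  stopifnot(nlevels(y) >= 2L, nrow(x) == length(y))
  if (anyNA(x)) stop("missing values in feature matrix")
  nKeep <- as.integer(nKeep)
  stopifnot(nKeep >= 1L, nKeep <= ncol(x))

  const <- apply(x, 2L, function(v) max(v) == min(v))
  if (any(const)) {
    warning("dropping ", sum(const), " constant feature(s) before ranking: ",
            paste(utils::head(colnames(x)[const], 5L), collapse = ", "))
    x <- x[, !const, drop = FALSE]
    if (nKeep > ncol(x)) stop("nKeep exceeds the number of usable features")
  }

  seeds <- .seedStream(seed, ncol(x) + 1L)
  remaining <- colnames(x)
  elimOrder <- character(0)
  step <- 0L
  while (length(remaining) > nKeep) {
    step <- step + 1L
    xs <- x[, remaining, drop = FALSE]
    sc <- fitScaler(xs)
    xz <- applyScaler(sc, xs)
    fits <- .fitOvr(xz, y, "linear", cost, 1 / ncol(xz), seeds[step])
    imp <- .linearImportance(fits, remaining)
    # ties broken toward the later column for a deterministic order
    worst <- remaining[max(which(imp == min(imp)))]
    elimOrder <- c(worst, elimOrder)
    remaining <- setdiff(remaining, worst)
  }

  # final importance orders the retained set
  xs <- x[, remaining, drop = FALSE]
  sc <- fitScaler(xs)
  fits <- .fitOvr(applyScaler(sc, xs), y, "linear", cost, 1 / ncol(xs),
                  seeds[length(seeds)])
  impFinal <- .linearImportance(fits, remaining)
  retained <- remaining[order(-impFinal, remaining)]

  allFeats <- c(retained, elimOrder)
  ranking <- data.frame(
    feature = allFeats,
    rank = seq_along(allFeats),
    retained = seq_along(allFeats) <= nKeep,
    stringsAsFactors = FALSE
  )

  curve <- data.frame(n_features = integer(0), cv_accuracy = numeric(0))
  if (cvFolds >= 2L) {
    sizes <- unique(round(seq(nKeep, length(allFeats), length.out = 8L)))
    accs <- vapply(sizes, function(m) {
      feats <- allFeats[seq_len(m)]
      .cvAccuracyQuick(x[, feats, drop = FALSE], y, cvFolds, cost,
                       seeds[length(seeds)])
    }, numeric(1))
    curve <- data.frame(n_features = sizes, cv_accuracy = accs)
  }

  new("FeatureSelection",
    ranking = ranking, retained = retained, accuracyCurve = curve
  )
}

# small stratified-CV accuracy helper used for the RFE curve
.cvAccuracyQuick <- function(x, y, k, cost, seed) {
  folds <- stratifiedFolds(y, k, seed)
  hits <- 0L
  for (f in seq_len(k)) {
    te <- folds == f
    sc <- fitScaler(x[!te, , drop = FALSE])
    fits <- .fitOvr(applyScaler(sc, x[!te, , drop = FALSE]), droplevels(y[!te]),
                    "linear", cost, 1 / ncol(x), seed)
    dv <- .ovrDecision(fits, applyScaler(sc, x[te, , drop = FALSE]))
    pred <- colnames(dv)[max.col(dv, ties.method = "first")]
    hits <- hits + sum(pred == as.character(y[te]))
  }
  hits / length(y)
}

# ---- classifiers ----

# resolve (x, y) from table/selection arguments shared by the two fitters
.designMatrix <- function(table, selection, labels) {
  x <- if (is(table, "SummarizedExperiment")) featureMatrix(table) else as.matrix(table)
  y <- factor(if (is.null(labels)) classLabels(table) else labels)
  if (!is.null(selection)) {
    feats <- if (is(selection, "FeatureSelection")) selection@retained else selection
    missing <- setdiff(feats, colnames(x))
    if (length(missing)) stop("selected features absent from table: ",
                              paste(missing, collapse = ", "))
    x <- x[, feats, drop = FALSE]
  }
  if (nlevels(y) < 2L) stop("need at least two classes")
  list(x = x, y = y)
}

#' Fit a decision-tree classifier
#'
#' Axis-aligned threshold tree (Gini impurity) grown without cost-complexity
#' pruning, mirroring the common default of growing the full tree.
#' Multiclass prediction takes the argmax of the leaf class probabilities;
#' in two-class mode the positive class is predicted when its conditional
#' probability exceeds `threshold` (default 0.5).
#'
#' @param table feature table or samples-by-features matrix.
#' @param selection optional [FeatureSelection] (or character vector) to
#'   restrict the features.
#' @param labels labels when `table` is a matrix.
#' @param threshold two-class decision threshold.
#' @param control an [rpart::rpart.control()] list.
#' @param seed RNG seed (surrogate-split tie-breaks).
#' @return a [TrainedModel].
#' @export
fitDecisionTree <- function(table, selection = NULL, labels = NULL,
                            threshold = 0.5,
                            control = rpart::rpart.control(
                              cp = 0, minsplit = 2L, minbucket = 1L,
                              xval = 0L
                            ),
                            seed = 1L) {
  d <- .designMatrix(table, selection, labels)
  df <- data.frame(.y = d$y, d$x, check.names = FALSE)
  fit <- withSeed(seed, rpart::rpart(
    .y ~ ., data = df, method = "class",
    parms = list(split = "gini"), control = control
  ))
  new("TrainedModel",
    kind = "dt", fit = fit, classes = levels(d$y), scaler = list(),
    features = colnames(d$x), threshold = threshold,
    params = list(control = control)
  )
}

#' Fit a one-vs-rest SVM classifier
#'
#' One binary margin classifier per class on z-score standardized features;
#' prediction is the argmax of the per-class decision values, ties broken
#' by the fixed class order. Supports linear and RBF kernels.
#'
#' @param table feature table or samples-by-features matrix.
#' @param selection optional [FeatureSelection] or character vector.
#' @param labels labels when `table` is a matrix.
#' @param kernel `"radial"` (default) or `"linear"`.
#' @param cost soft-margin cost.
#' @param gamma RBF width; `NULL` uses the `1/(p * var)` "scale" heuristic.
#' @param seed RNG seed.
#' @return a [TrainedModel].
#' @export
fitOvrSVM <- function(table, selection = NULL, labels = NULL,
                      kernel = c("radial", "linear"), cost = 1,
                      gamma = NULL, seed = 1L) {
  kernel <- match.arg(kernel)
  d <- .designMatrix(table, selection, labels)
  sc <- fitScaler(d$x)
  xz <- applyScaler(sc, d$x)
  if (is.null(gamma)) gamma <- .gammaScale(xz)
  fits <- .fitOvr(xz, d$y, kernel, cost, gamma, seed)
  new("TrainedModel",
    kind = "ovr-svm", fit = fits, classes = levels(d$y), scaler = sc,
    features = colnames(d$x), threshold = 0.5,
    params = list(kernel = kernel, cost = cost, gamma = gamma)
  )
}

#' Per-class scores for new data
#'
#' Decision trees return class-probability estimates (rows sum to 1);
#' one-vs-rest SVMs return decision-function values.
#'
#' @param model a [TrainedModel].
#' @param table feature table or samples-by-features matrix.
#' @return numeric matrix, one row per sample, one column per class.
#' @export
predictScores <- function(model, table) {
  stopifnot(is(model, "TrainedModel"))
  x <- if (is(table, "SummarizedExperiment")) featureMatrix(table) else as.matrix(table)
  missing <- setdiff(model@features, colnames(x))
  if (length(missing)) stop("features missing from input: ",
                            paste(utils::head(missing, 5L), collapse = ", "))
  x <- x[, model@features, drop = FALSE]
  if (model@kind == "dt") {
    pr <- predict(model@fit, data.frame(x, check.names = FALSE),
                  type = "prob")
    pr[, model@classes, drop = FALSE]
  } else {
    .ovrDecision(model@fit, applyScaler(model@scaler, x))[, model@classes,
                                                          drop = FALSE]
  }
}

#' Predicted class labels
#'
#' Argmax of [predictScores()]; ties go to the earlier class in the fixed
#' class order. A two-class decision tree applies the model's decision
#' threshold to the probability of the second (positive) class.
#'
#' @param model a [TrainedModel].
#' @param table feature table or matrix.
#' @return character vector of predicted labels.
#' @export
predictClasses <- function(model, table) {
  sc <- predictScores(model, table)
  if (model@kind == "dt" && length(model@classes) == 2L) {
    pos <- model@classes[2L]
    return(ifelse(sc[, pos] > model@threshold, pos, model@classes[1L]))
  }
  model@classes[max.col(sc, ties.method = "first")]
}
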
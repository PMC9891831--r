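# --- learner primitives ----------------------------------------------------
# A layer holds 18 learners: six boosted-tree (xgboost, 20 rounds, depth 3,
# eta 0.3), six random forests and six extremely-randomized-tree forests
# (ranger, 20 trees; ERT = splitrule "extratrees" on the full sample).
# Within a type the six copies differ only by seed.  All learners run
# single-threaded so fits are bit-reproducible.

layerLearnerTypes <- function() rep(c("xgb", "rf", "ert"), each = 6L)

fitOneLearner <- function(type, x, y, seed, numTrees = 20L) {
  if (type == "xgb") {
    d <- xgboost::xgb.DMatrix(data = x, label = as.integer(y == "positive"))
    booster <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 3L,
                    eta = 0.3, nthread = 1L, seed = seed),
      data = d, nrounds = numTrees, verbose = 0)
    list(type = type, raw = xgboost::xgb.save.raw(booster))
  } else {
    extra <- type == "ert"
    fit <- ranger::ranger(
      x = x, y = y, num.trees = numTrees, probability = TRUE,
      seed = seed, num.threads = 1L,
      splitrule = if (extra) "extratrees" else "gini",
      num.random.splits = 1L,
      replace = !extra, sample.fraction = 1)
    list(type = type, model = fit)
  }
}

predictOneLearner <- function(learner, x) {
  lev <- c("negative", "positive")
  if (learner$type == "xgb") {
    booster <- xgboost::xgb.load.raw(learner$raw)
    pos <- predict(booster, xgboost::xgb.DMatrix(data = x))
    cbind(negative = 1 - pos, positive = pos)
  } else {
    p <- predict(learner$model, data = x, num.threads = 1L)$predictions
    p[, lev, drop = FALSE]
  }
}

# Stratified fold assignment: within each class, a seeded shuffle is dealt
# round-robin into k folds.
stratifiedFolds <- function(labels, k, seed) {
  k <- as.integer(k)
  if (k < 2L) stopData("k must be >= 2")
  small <- names(which(table(labels) < k))
  if (length(small))
    stopData("class(es) smaller than k = ", k, ": ",
             paste(small, collapse = ", "))
  fold <- integer(length(labels))
  withSeed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# --- layer fitting ---------------------------------------------------------

#' Fit one cascade layer
#'
#' Fits the 18 learners of a layer and returns, alongside the fully fitted
#' learners, an n x 36 matrix of out-of-fold class probabilities (internal
#' stratified 3-fold): the augmentation features a deeper layer trains on
#' are never predictions of models fitted on the same rows.  Columns are
#' learner-major, class within learner (`L01_negative`, `L01_positive`,
#' `L02_negative`, ...).
#'
#' @param x Numeric n x d feature matrix (with column names).
#' @param y Label factor with levels `negative`, `positive`; both classes
#'   must have at least `oofFolds` members.
#' @param seed Integer seed for this layer.
#' @param numTrees Trees / boosting rounds per learner (default 20).
#' @param oofFolds Internal folds for out-of-fold probabilities (default 3).
#' @return List with elements `learners` (list of 18 fitted learners) and
#'   `oof` (n x 36 matrix).
#' @export
fitLayer <- function(x, y, seed, numTrees = 20L, oofFolds = 3L) {
  if (nlevels(droplevels(y)) < 2L)
    stopData("labels contain a single class; cannot fit a layer")
  if (any(table(y) < 2L)) stopData("need at least 2 samples per class")
  types <- layerLearnerTypes()
  fold <- stratifiedFolds(y, min(oofFolds, min(table(y))), seed)
  nFold <- max(fold)
  learners <- vector("list", length(types))
  oof <- matrix(NA_real_, nrow = nrow(x), ncol = 2L * length(types))
  colnames(oof) <- paste0("L", sprintf("%02d", rep(seq_along(types), each = 2L)),
                          "_", c("negative", "positive"))
  for (l in seq_along(types)) {
    lseed <- (seed + 1009L * l) %% .Machine$integer.max
    for (f in seq_len(nFold)) {
      tr <- fold != f
      fit <- fitOneLearner(types[[l]], x[tr, , drop = FALSE], y[tr],
                           seed = lseed + f, numTrees = numTrees)
      oof[!tr, (2L * l - 1L):(2L * l)] <-
        predictOneLearner(fit, x[!tr, , drop = FALSE])
    }
    learners[[l]] <- fitOneLearner(types[[l]], x, y, seed = lseed,
                                   numTrees = numTrees)
  }
  list(learners = learners, oof = oof)
}

predictLayer <- function(layer, x) {
  probs <- lapply(layer$learners, predictOneLearner, x = x)
  out <- do.call(cbind, probs)
  colnames(out) <- paste0("L", sprintf("%02d", rep(seq_along(probs), each = 2L)),
                          "_", c("negative", "positive"))
  out
}

#' Augment a feature matrix with class-probability columns
#'
#' Pure column concatenation: the original features first, then the 36
#' probability columns in their fixed order.
#'
#' @param features n x d matrix.
#' @param probs n x 36 class-probability matrix from the previous layer.
#' @return n x (d + 36) matrix.
#' @export
augmentFeatures <- function(features, probs) {
  if (nrow(features) != nrow(probs))
    stopData("row count mismatch: ", nrow(features), " features vs ",
             nrow(probs), " probability rows")
  cbind(features, probs)
}

# Mean class-probability across the 18 learners of a 36-column block.
meanClassProbs <- function(probs36) {
  neg <- probs36[, seq(1L, ncol(probs36), by = 2L), drop = FALSE]
  pos <- probs36[, seq(2L, ncol(probs36), by = 2L), drop = FALSE]
  cbind(negative = rowMeans(neg), positive = rowMeans(pos))
}

# --- cascade ---------------------------------------------------------------

#' Fit a cascade forest
#'
#' Layers are added one at a time.  Each layer's validation score is the
#' accuracy of its averaged out-of-fold probabilities on the training
#' labels; training stops as soon as a layer fails to improve on the best
#' score so far (patience 1) or at `maxLayers`, and the model is truncated
#' at the best-scoring layer.  From the second layer on, the input is the
#' original feature matrix augmented with the previous layer's 36
#' out-of-fold probability columns.
#'
#' @param x Numeric n x d feature matrix with column names.
#' @param y Labels: factor (`negative`/`positive`), character, or 0/1.
#' @param maxLayers Maximum number of layers (default 10, >= 1).
#' @param numTrees Trees / boosting rounds per learner (default 20).
#' @param oofFolds Internal folds for augmentation probabilities (default 3).
#' @param seed Master seed; fixes every learner seed, so refits are
#'   bit-identical.
#' @return A [CascadeForest-class].
#' @examples
#' \donttest{
#' lps <- generateDataset(30, 30, effect = 0.8, seed = 1)
#' m <- featurizeDataset(lps, "dpc")
#' fit <- fitCascade(m, classLabels(lps), maxLayers = 2, seed = 1)
#' fit
#' }
#' @export
fitCascade <- function(x, y, maxLayers = 10L, numTrees = 20L,
                       oofFolds = 3L, seed = 1L) {
  maxLayers <- as.integer(maxLayers)
  if (maxLayers < 1L) stopData("maxLayers must be >= 1")
  y <- coerceLabels(y, nrow(x))
  if (length(y) != nrow(x)) stopData("length(y) must equal nrow(x)")
  if (nlevels(droplevels(y)) < 2L) stopData("labels contain a single class")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  layers <- list()
  history <- numeric(0)
  current <- x
  best <- -Inf
  for (l in seq_len(maxLayers)) {
    layer <- fitLayer(current, y, seed = (seed + 7919L * l) %% .Machine$integer.max,
                      numTrees = numTrees, oofFolds = oofFolds)
    avg <- meanClassProbs(layer$oof)
    pred <- ifelse(avg[, "positive"] >= avg[, "negative"],
                   "positive", "negative")
    score <- mean(pred == as.character(y))
    layers[[l]] <- layer
    history[l] <- score
    if (score <= best) break
    best <- score
    current <- augmentFeatures(x, layer$oof)
  }
  stopLayer <- which.max(history)
  new("CascadeForest",
      layers = layers[seq_len(stopLayer)],
      inputDim = ncol(x), featureNames = colnames(x),
      stopLayer = stopLayer, history = history,
      classLevels = c("negative", "positive"),
      config = list(maxLayers = maxLayers, numTrees = numTrees,
                    oofFolds = oofFolds, seed = seed))
}

#' Class probabilities from a cascade forest
#'
#' Propagates features through the kept layers (re-augmenting with each
#' layer's probability output) and returns the final layer's class
#' probabilities, averaged over its 18 learners.  Rows sum to 1; the
#' predicted label is the argmax, with ties going to the positive class.
#'
#' @param model A [CascadeForest-class].
#' @param x Feature matrix whose columns match the training layout.
#' @return n x 2 matrix with columns `negative`, `positive`.
#' @export
predictProba <- function(model, x) {
  if (ncol(x) != model@inputDim)
    stopData("feature width mismatch: model expects ", model@inputDim,
             " columns, got ", ncol(x))
  if (is.null(colnames(x))) colnames(x) <- model@featureNames
  current <- x
  probs36 <- NULL
  for (l in seq_len(model@stopLayer)) {
    probs36 <- predictLayer(model@layers[[l]], current)
    if (l < model@stopLayer) current <- augmentFeatures(x, probs36)
  }
  meanClassProbs(probs36)
}

#' Predicted labels from a cascade forest
#'
#' @param model A [CascadeForest-class].
#' @param x Feature matrix.
#' @return Factor of predicted labels (`negative`/`positive`); ties predict
#'   positive.
#' @export
predictLabels <- function(model, x) {
  p <- predictProba(model, x)
  factor(ifelse(p[, "positive"] >= p[, "negative"], "positive", "negative"),
         levels = c("negative", "positive"))
}

#' @describeIn CascadeForest-class `predict` method: returns class
#'   probabilities (`type = "prob"`) or labels (`type = "class"`).
#' @param object A fitted `CascadeForest`.
#' @param newdata Feature matrix.
#' @param type `"prob"` or `"class"`.
#' @param ... Ignored.
#' @export
setMethod("predict", "CascadeForest",
  function(object, newdata, type = c("prob", "class"), ...) {
    type <- match.arg(type)
    if (type == "prob") predictProba(object, newdata)
    else predictLabels(object, newdata)
  })

# --- persistence -----------------------------------------------------------

#' Save / load a cascade forest model archive
#'
#' The archive records a format version, the feature layout and the
#' descriptor configuration; `loadCascade()` refuses archives with an
#' unknown version or a corrupt payload, and prediction refuses matrices
#' whose layout does not match.
#'
#' @param model A [CascadeForest-class].
#' @param path File path for the archive.
#' @param meta Optional list of featurization metadata (descriptor, index
#'   table values, APAAC parameters) stored alongside the model.
#' @return `saveCascade()`: `path`, invisibly. `loadCascade()`: a list with
#'   elements `model` and `meta`.
#' @export
saveCascade <- function(model, path, meta = list()) {
  stopifnot(is(model, "CascadeForest"))
  saveRDS(list(format = "fegsForest-cascade", version = 1L,
               model = model, meta = meta), path)
  invisible(path)
}

#' @rdname saveCascade
#' @export
loadCascade <- function(path) {
  if (!file.exists(path)) stopData("model archive not found: ", path)
  obj <- tryCatch(readRDS(path), error = function(e)
    stopData("cannot read model archive '", path, "': ",
             conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, "fegsForest-cascade"))
    stopData("'", path, "' is not a cascade model archive")
  if (!identical(obj$version, 1L))
    stopData("unsupported model archive version: ", obj$version)
  if (!is(obj$model, "CascadeForest"))
    stopData("corrupt model archive: payload is not a CascadeForest")
  list(model = obj$model, meta = obj$meta %||% list())
}
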
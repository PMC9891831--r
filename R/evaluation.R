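#' Confusion counts of a binary prediction
#'
#' @param truth True labels (factor/character `negative`/`positive`, or 0/1).
#' @param predicted Predicted labels, same encoding.
#' @return Named list with integer elements `TP`, `TN`, `FP`, `FN`.
#' @export
confusionCounts <- function(truth, predicted) {
  truth <- coerceLabels(truth, length(truth))
  predicted <- coerceLabels(predicted, length(predicted))
  if (length(truth) != length(predicted))
    stopData("truth and predicted must have equal length")
  list(TP = sum(truth == "positive" & predicted == "positive"),
       TN = sum(truth == "negative" & predicted == "negative"),
       FP = sum(truth == "negative" & predicted == "positive"),
       FN = sum(truth == "positive" & predicted == "negative"))
}

#' Threshold-dependent classification metrics
#'
#' Accuracy, sensitivity (recall on positives), specificity, Matthews
#' correlation coefficient and F1 from confusion counts.  Any metric whose
#' denominator is zero is defined as 0 (a documented convention; the
#' formulas are undefined there).
#'
#' @param TP,TN,FP,FN Nonnegative counts.  Alternatively pass the list from
#'   [confusionCounts()] as `TP`.
#' @return Named numeric vector: `ACC`, `SN`, `SP`, `MCC`, `F1`.
#' @examples
#' classificationMetrics(9, 9, 1, 1)  # ACC 0.9, MCC 0.8
#' @export
classificationMetrics <- function(TP, TN = NULL, FP = NULL, FN = NULL) {
  if (is.list(TP)) {
    c0 <- TP; TP <- c0$TP; TN <- c0$TN; FP <- c0$FP; FN <- c0$FN
  }
  counts <- c(TP, TN, FP, FN)
  if (any(counts < 0)) stopData("confusion counts must be nonnegative")
  total <- TP + TN + FP + FN
  if (total == 0) stopData("no evaluated samples")
  safe <- function(num, den) if (den == 0) 0 else num / den
  mccDen <- sqrt(as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  c(ACC = safe(TP + TN, total),
    SN = safe(TP, TP + FN),
    SP = safe(TN, TN + FP),
    MCC = safe(as.numeric(TP) * TN - as.numeric(FP) * FN, mccDen),
    F1 = safe(2 * TP, 2 * TP + FP + FN))
}

#' ROC AUC by the Mann-Whitney rank statistic
#'
#' AUC computed as the normalized Mann-Whitney U statistic with midranks
#' for ties — the probability that a random positive scores above a random
#' negative, counting ties as 1/2.  Equal scores for all samples give
#' exactly 0.5.
#'
#' @param scores Numeric positive-class scores.
#' @param labels Labels (`negative`/`positive`, or 0/1); both classes must
#'   be present.
#' @return AUC in \[0, 1\].
#' @export
rocAuc <- function(scores, labels) {
  labels <- coerceLabels(labels, length(labels))
  if (length(scores) != length(labels))
    stopData("scores and labels must have equal length")
  nPos <- sum(labels == "positive")
  nNeg <- sum(labels == "negative")
  if (nPos == 0L || nNeg == 0L)
    stopData("AUC requires both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == "positive"]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

evalFromPredictions <- function(truth, probs) {
  pred <- ifelse(probs[, "positive"] >= probs[, "negative"],
                 "positive", "negative")
  m <- classificationMetrics(confusionCounts(truth, pred))
  auc <- if (length(unique(truth)) < 2L) NA_real_
         else rocAuc(probs[, "positive"], truth)
  c(m, AUC = auc)
}

#' Stratified k-fold cross-validation of the cascade forest
#'
#' Splits samples into k stratified folds (class proportions preserved; a
#' seeded shuffle keeps the assignment reproducible), fits the cascade on
#' k - 1 folds and evaluates on the held-out fold, then aggregates.  By
#' default metrics are averaged over folds; `pooled = TRUE` instead pools
#' the per-sample predictions and computes one set of metrics from the
#' summed confusion counts (AUC from the pooled scores).
#'
#' @param x Feature matrix.
#' @param y Labels.
#' @param k Number of folds (default 10); every class must have >= k
#'   members.  `k = n` gives leave-one-out (per-fold AUC is then undefined
#'   and averaged over defined folds only).
#' @param seed Seed for fold assignment and model fitting.
#' @param pooled Aggregate by pooling predictions instead of averaging
#'   per-fold metrics.
#' @param ... Passed to [fitCascade()] (`maxLayers`, `numTrees`, ...).
#' @return An [EvalReport-class]; `foldMetrics()` gives the per-fold table.
#' @export
kfoldCrossVal <- function(x, y, k = 10L, seed = 1L, pooled = FALSE, ...) {
  y <- coerceLabels(y, nrow(x))
  fold <- stratifiedFolds(y, k, seed)
  perFold <- vector("list", max(fold))
  poolProbs <- matrix(NA_real_, nrow(x), 2L,
                      dimnames = list(NULL, c("negative", "positive")))
  for (f in seq_len(max(fold))) {
    tr <- fold != f
    model <- fitCascade(x[tr, , drop = FALSE], y[tr],
                        seed = (seed + 104729L * f) %% .Machine$integer.max,
                        ...)
    probs <- predictProba(model, x[!tr, , drop = FALSE])
    poolProbs[!tr, ] <- probs
    perFold[[f]] <- evalFromPredictions(y[!tr], probs)
  }
  folds <- as.data.frame(do.call(rbind, perFold))
  folds <- cbind(fold = seq_len(nrow(folds)), folds)
  metrics <- if (pooled) evalFromPredictions(y, poolProbs)
             else colMeans(folds[, -1L, drop = FALSE], na.rm = TRUE)
  new("EvalReport", metrics = metrics, folds = folds)
}

#' Train once, evaluate once on an independent test set
#'
#' Row names of the two matrices are treated as sample identifiers and must
#' be disjoint (set `allowOverlap = TRUE` only for resubstitution smoke
#' tests).
#'
#' @param xTrain,yTrain Training feature matrix and labels.
#' @param xTest,yTest Test feature matrix and labels.
#' @param seed Seed for model fitting.
#' @param allowOverlap Skip the id-disjointness check.
#' @param ... Passed to [fitCascade()].
#' @return An [EvalReport-class] (no fold table).
#' @export
independentTest <- function(xTrain, yTrain, xTest, yTest, seed = 1L,
                            allowOverlap = FALSE, ...) {
  overlap <- intersect(rownames(xTrain), rownames(xTest))
  if (!allowOverlap && length(overlap))
    stopData("train/test id overlap: ", paste(overlap, collapse = ", "))
  model <- fitCascade(xTrain, yTrain, seed = seed, ...)
  probs <- predictProba(model, xTest)
  new("EvalReport",
      metrics = evalFromPredictions(coerceLabels(yTest, nrow(xTest)), probs),
      folds = data.frame())
}
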
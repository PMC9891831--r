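# File-based pipeline: thin wrappers tying the modules into the
# featurize -> train -> cross-validate -> independent-test -> predict
# workflow.  Each function is pure with respect to (inputs, config, seed):
# rerunning with identical arguments produces identical artifacts.

featurizeFile <- function(fasta, descriptor, table = NULL,
                          lambda = 5L, w = 0.05) {
  seqs <- readProteinFasta(fasta)
  cleaned <- suppressWarnings(cleanDataset(seqs))
  dropped <- setdiff(names(seqs), names(cleaned))
  if (length(dropped))
    message("dropped ", length(dropped), " sequence(s) after cleaning: ",
            paste(dropped, collapse = ", "))
  m <- featurizeDataset(cleaned, descriptor = descriptor, table = table,
                        lambda = lambda, w = w)
  message("featurized ", nrow(m), " sequence(s); descriptor = ", descriptor,
          ", dimension = ", ncol(m))
  m
}

loadLabeledFeatures <- function(fasta, labels, descriptor, table = NULL,
                                lambda = 5L, w = 0.05) {
  m <- featurizeFile(fasta, descriptor, table, lambda, w)
  lab <- readLabels(labels)
  miss <- setdiff(rownames(m), lab$id)
  if (length(miss))
    stopData("no label for sequence(s): ", paste(miss, collapse = ", "))
  list(x = m, y = lab$label[match(rownames(m), lab$id)])
}

#' Pipeline commands
#'
#' File-based entry points mirroring the CLI (`inst/scripts/fegsforest.R`):
#' `runSimulate()` writes a synthetic FASTA + label file; `runFeaturize()`
#' writes a feature matrix; `runCrossval()` runs stratified k-fold CV and
#' writes a JSON report plus a per-fold table; `runTrain()` fits and
#' archives a model; `runIndependentTest()` fits on a training pair and
#' evaluates on a disjoint test pair; `runPredict()` writes per-sequence
#' labels and probabilities for a FASTA file, in input order.
#'
#' @param outFasta,outLabels,out,modelOut,reportOut Output file paths.
#' @param nPos,nNeg,lengthRange,effect See [generateDataset()].
#' @param fasta,labels,trainFasta,trainLabels,testFasta,testLabels Input
#'   paths (FASTA and two-column `id<TAB>0/1` label files).
#' @param descriptor One of `fegs`, `apaac`, `dpc`, `aac`.
#' @param tablePath Optional TSV physicochemical index table (FEGS); the
#'   bundled 158-property table when `NULL`.
#' @param lambda,w APAAC parameters.
#' @param k Number of CV folds.
#' @param seed Integer seed.
#' @param model Path of a model archive written by `runTrain()`.
#' @param ... Passed to [fitCascade()] / [kfoldCrossVal()].
#' @return See each command's description; paths are returned invisibly,
#'   reports as [EvalReport-class].
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
runSimulate <- function(outFasta, outLabels, nPos, nNeg,
                        lengthRange = c(50L, 400L), effect = 0.5, seed = 1L) {
  lps <- generateDataset(nPos, nNeg, lengthRange = lengthRange,
                         effect = effect, seed = seed)
  writeProteinFasta(lps, outFasta)
  writeLabels(lps, outLabels)
  invisible(lps)
}

#' @rdname pipeline
#' @export
runFeaturize <- function(fasta, out, descriptor = "fegs", tablePath = NULL,
                         lambda = 5L, w = 0.05) {
  table <- if (!is.null(tablePath)) readPhysChemTable(tablePath)
  m <- featurizeFile(fasta, descriptor, table, lambda, w)
  writeFeatureMatrix(m, out)
  invisible(out)
}

#' @rdname pipeline
#' @export
runCrossval <- function(fasta, labels, reportOut = NULL, descriptor = "fegs",
                        tablePath = NULL, k = 10L, seed = 1L,
                        lambda = 5L, w = 0.05, ...) {
  table <- if (!is.null(tablePath)) readPhysChemTable(tablePath)
  d <- loadLabeledFeatures(fasta, labels, descriptor, table, lambda, w)
  rep <- kfoldCrossVal(d$x, d$y, k = k, seed = seed, ...)
  if (!is.null(reportOut)) writeEvalReport(rep, reportOut)
  rep
}

#' @rdname pipeline
#' @export
runTrain <- function(fasta, labels, modelOut, descriptor = "fegs",
                     tablePath = NULL, seed = 1L, lambda = 5L, w = 0.05, ...) {
  table <- if (!is.null(tablePath)) readPhysChemTable(tablePath)
  if (descriptor == "fegs" && is.null(table)) table <- defaultPhysChemTable()
  d <- loadLabeledFeatures(fasta, labels, descriptor, table, lambda, w)
  model <- fitCascade(d$x, d$y, seed = seed, ...)
  message("cascade: ", length(model@layers), " layer(s) kept (stop layer ",
          model@stopLayer, ")")
  meta <- list(descriptor = descriptor,
               tableValues = if (!is.null(table)) propertyValues(table),
               lambda = lambda, w = w)
  saveCascade(model, modelOut, meta = meta)
  invisible(model)
}

#' @rdname pipeline
#' @export
runIndependentTest <- function(trainFasta, trainLabels, testFasta, testLabels,
                               reportOut = NULL, descriptor = "fegs",
                               tablePath = NULL, seed = 1L,
                               lambda = 5L, w = 0.05, ...) {
  table <- if (!is.null(tablePath)) readPhysChemTable(tablePath)
  tr <- loadLabeledFeatures(trainFasta, trainLabels, descriptor, table,
                            lambda, w)
  te <- loadLabeledFeatures(testFasta, testLabels, descriptor, table,
                            lambda, w)
  rep <- independentTest(tr$x, tr$y, te$x, te$y, seed = seed, ...)
  if (!is.null(reportOut)) writeEvalReport(rep, reportOut)
  rep
}

#' @rdname pipeline
#' @export
runPredict <- function(model, fasta, out) {
  archive <- loadCascade(model)
  seqs <- readProteinFasta(fasta)
  if (!length(seqs)) {
    write.table(data.frame(id = character(0), label = character(0),
                           prob_positive = numeric(0)),
                out, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  cleaned <- suppressWarnings(cleanDataset(seqs))
  meta <- archive$meta
  table <- if (!is.null(meta$tableValues)) physChemTable(meta$tableValues)
  m <- featurizeDataset(cleaned, descriptor = meta$descriptor %||% "fegs",
                        table = table, lambda = meta$lambda %||% 5L,
                        w = meta$w %||% 0.05)
  if (!identical(colnames(m), archive$model@featureNames))
    stopData("feature layout mismatch between model archive and input ",
             "(descriptor or index table differ)")
  probs <- predictProba(archive$model, m)
  lab <- ifelse(probs[, "positive"] >= probs[, "negative"],
                "positive", "negative")
  write.table(data.frame(id = rownames(m), label = lab,
                         prob_positive = probs[, "positive"]),
              out, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Write an evaluation report
#'
#' Writes the aggregate metrics as JSON; if the report holds per-fold rows,
#' a sibling `<path>.folds.tsv` table is written too.
#'
#' @param report An [EvalReport-class].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
writeEvalReport <- function(report, path) {
  jsonlite::write_json(as.list(reportMetrics(report)), path,
                       auto_unbox = TRUE, digits = NA)
  if (nrow(foldMetrics(report)))
    write.table(foldMetrics(report), paste0(path, ".folds.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
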
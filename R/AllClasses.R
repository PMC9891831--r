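#' @importClassesFrom Biostrings AAStringSet
NULL

#' Labeled protein sequence set
#'
#' A set of protein sequences (as a [Biostrings::AAStringSet]) with optional
#' binary class labels.  Labels use the factor levels `"negative"`,
#' `"positive"`; a zero-length label vector marks a prediction-only set.
#'
#' @slot sequences An `AAStringSet`; names are the sequence identifiers.
#' @slot labels A factor with levels `negative`, `positive`, either one per
#'   sequence or length zero.
#' @export
setClass("LabeledProteinSet",
  slots = c(sequences = "AAStringSet", labels = "factor"))

setValidity("LabeledProteinSet", function(object) {
  n <- length(object@sequences)
  if (length(object@labels) != 0L && length(object@labels) != n)
    return("labels must be empty or match the number of sequences")
  if (!identical(levels(object@labels), c("negative", "positive")))
    return("labels must be a factor with levels 'negative', 'positive'")
  if (anyNA(object@labels))
    return("labels must not contain NA")
  ids <- names(object@sequences)
  if (n > 0L && (is.null(ids) || any(!nzchar(ids))))
    return("all sequences must be named")
  if (anyDuplicated(ids))
    return(paste("duplicate sequence ids:",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  TRUE
})

#' Construct a LabeledProteinSet
#'
#' @param sequences An `AAStringSet` (or named character vector) of protein
#'   sequences.
#' @param labels Class labels: a factor/character with values in
#'   `negative`/`positive`, a numeric/logical vector (1/TRUE = positive), or
#'   `NULL` for a prediction-only set.
#' @return A [LabeledProteinSet-class] object.
#' @examples
#' lps <- LabeledProteinSet(c(a = "ACDE", b = "MKVL"), c(1, 0))
#' classLabels(lps)
#' @export
LabeledProteinSet <- function(sequences, labels = NULL) {
  if (is.character(sequences))
    sequences <- Biostrings::AAStringSet(sequences)
  labels <- coerceLabels(labels, length(sequences))
  new("LabeledProteinSet", sequences = sequences, labels = labels)
}

coerceLabels <- function(labels, n) {
  lev <- c("negative", "positive")
  if (is.null(labels)) return(factor(character(0), levels = lev))
  if (is.logical(labels) || is.numeric(labels))
    labels <- lev[as.integer(labels != 0) + 1L]
  labels <- factor(as.character(labels), levels = lev)
  if (anyNA(labels))
    stopData("labels must be 0/1 or 'negative'/'positive'")
  labels
}

#' @describeIn LabeledProteinSet-class Number of sequences.
#' @param x,object A `LabeledProteinSet`.
#' @export
setMethod("length", "LabeledProteinSet", function(x) length(x@sequences))

#' Accessors for LabeledProteinSet
#'
#' `proteins()` returns the underlying `AAStringSet`; `classLabels()` the
#' label factor (zero-length for prediction-only sets); `sequenceIds()` the
#' identifiers.
#'
#' @param x A [LabeledProteinSet-class].
#' @return See each accessor's description.
#' @export
proteins <- function(x) x@sequences

#' @rdname proteins
#' @export
classLabels <- function(x) x@labels

#' @rdname proteins
#' @export
sequenceIds <- function(x) names(x@sequences)

setMethod("show", "LabeledProteinSet", function(object) {
  n <- length(object)
  cat("LabeledProteinSet with", n, "sequences\n")
  if (length(object@labels)) {
    tab <- table(object@labels)
    cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  } else cat("  labels: none (prediction mode)\n")
  if (n) {
    w <- Biostrings::width(object@sequences)
    cat("  lengths:", min(w), "-", max(w), "residues\n")
  }
})

#' Subset a LabeledProteinSet
#' @param x A `LabeledProteinSet`.
#' @param i Index vector.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "LabeledProteinSet", function(x, i, j, ..., drop = TRUE) {
  lab <- if (length(x@labels)) x@labels[i] else x@labels
  new("LabeledProteinSet", sequences = x@sequences[i], labels = lab)
})

#' Physicochemical index table
#'
#' A matrix of P physicochemical properties (rows, named by property id)
#' by the 20 standard amino acids (columns, alphabetical one-letter order).
#' Rows with all 20 values identical are disallowed: such indices induce no
#' amino-acid ordering and are eliminated at load time.
#'
#' @slot values Numeric P x 20 matrix; rownames are property identifiers,
#'   colnames the amino-acid one-letter codes.
#' @export
setClass("PhysChemTable", slots = c(values = "matrix"))

setValidity("PhysChemTable", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (ncol(v) != 20L || !identical(colnames(v), aminoAcids()))
    return("values must have 20 columns named by the amino acids A..Y")
  if (nrow(v) < 1L) return("table must contain at least one property")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)) || any(!nzchar(rownames(v))))
    return("property names (rownames) must be unique and non-empty")
  if (any(!is.finite(v))) return("all property values must be finite")
  const <- apply(v, 1L, function(r) length(unique(r)) == 1L)
  if (any(const))
    return(paste("degenerate index (all 20 values identical):",
                 paste(rownames(v)[const], collapse = ", ")))
  TRUE
})

#' @describeIn PhysChemTable-class Number of properties P.
#' @param x,object A `PhysChemTable`.
#' @export
setMethod("nrow", "PhysChemTable", function(x) nrow(x@values))

#' Property values of a PhysChemTable
#' @param x A [PhysChemTable-class].
#' @return The numeric P x 20 matrix.
#' @export
propertyValues <- function(x) x@values

#' @rdname propertyValues
#' @export
propertyNames <- function(x) rownames(x@values)

setMethod("show", "PhysChemTable", function(object) {
  cat("PhysChemTable with", nrow(object@values), "properties x 20 amino acids\n")
  cat("  first properties:",
      paste(head(rownames(object@values), 3L), collapse = ", "), "...\n")
})

#' Cone geometry for one physicochemical property
#'
#' The 20 amino acids, ranked by a property value from lowest to highest,
#' are placed on the unit base circle of a right circular cone of height 1:
#' the residue with rank i sits at (cos(2*pi*i/20), sin(2*pi*i/20), 1).  Each
#' ordered dipeptide (a, b) maps to the pair point phi(a) + phi(b)/4, at
#' height z = 1.25.
#'
#' @slot property Property identifier (character).
#' @slot ordering Named integer vector: rank 1..20 for each amino acid.
#' @slot vertices 20 x 3 matrix of vertex points, rownames = amino acids.
#' @slot pairs 400 x 3 matrix of pair points, rownames = dipeptides.
#' @export
setClass("ConeGeometry",
  slots = c(property = "character", ordering = "integer",
            vertices = "matrix", pairs = "matrix"))

setValidity("ConeGeometry", function(object) {
  if (!identical(sort(names(object@ordering)), aminoAcids()))
    return("ordering must be named by the 20 amino acids")
  if (!identical(sort(as.integer(object@ordering)), 1:20))
    return("ordering must be a permutation of ranks 1..20")
  if (!identical(dim(object@vertices), c(20L, 3L)))
    return("vertices must be 20 x 3")
  if (!identical(dim(object@pairs), c(400L, 3L)))
    return("pairs must be 400 x 3")
  TRUE
})

setMethod("show", "ConeGeometry", function(object) {
  o <- names(sort(object@ordering))
  cat("ConeGeometry for property", object@property, "\n")
  cat("  ranking (low -> high):", paste(o, collapse = ""), "\n")
})

#' Cascade forest model
#'
#' A fitted cascade deep-forest classifier.  Each layer holds 18 learners
#' (six boosted-tree, six random-forest, six extremely-randomized-tree, 20
#' trees/boosting rounds each); from the second layer on, the input is the
#' original feature matrix augmented with the previous layer's 36
#' class-probability columns.  `history` records each fitted layer's
#' out-of-fold accuracy; `stopLayer` is the (first) layer maximizing it, and
#' the kept model is truncated there.
#'
#' @slot layers List of fitted layers (each a list of 18 learners).
#' @slot inputDim Integer: number of raw input features d.
#' @slot featureNames Character: column layout the model expects.
#' @slot stopLayer Integer index of the last kept layer.
#' @slot history Numeric: per-layer validation (out-of-fold) accuracy, for
#'   every layer that was fitted (kept or not).
#' @slot classLevels Character(2): `c("negative", "positive")`.
#' @slot config List of hyperparameters used at fit time.
#' @export
setClass("CascadeForest",
  slots = c(layers = "list", inputDim = "integer", featureNames = "character",
            stopLayer = "integer", history = "numeric",
            classLevels = "character", config = "list"))

setValidity("CascadeForest", function(object) {
  if (length(object@layers) < 1L) return("model must contain at least one layer")
  if (object@stopLayer != length(object@layers))
    return("model must be truncated at stopLayer")
  if (length(object@history) < object@stopLayer)
    return("history must cover every kept layer")
  if (!identical(object@classLevels, c("negative", "positive")))
    return("classLevels must be c('negative','positive')")
  TRUE
})

setMethod("show", "CascadeForest", function(object) {
  cat("CascadeForest:", length(object@layers), "layer(s),",
      object@inputDim, "input features\n")
  cat("  per-layer OOF accuracy:",
      paste(sprintf("%.4f", object@history), collapse = ", "), "\n")
  cat("  kept through layer", object@stopLayer, "\n")
})

#' Evaluation report
#'
#' Threshold-dependent confusion-matrix metrics plus ROC AUC, with a
#' per-fold breakdown when produced by cross-validation.
#'
#' @slot metrics Named numeric: ACC, SN, SP, MCC, F1, AUC.
#' @slot folds data.frame with one row per fold (empty for single
#'   evaluations).
#' @export
setClass("EvalReport", slots = c(metrics = "numeric", folds = "data.frame"))

#' Metrics of an EvalReport
#' @param x An [EvalReport-class].
#' @return `reportMetrics()`: named numeric vector. `foldMetrics()`: a
#'   data.frame of per-fold metrics (zero rows unless cross-validated).
#' @export
reportMetrics <- function(x) x@metrics

#' @rdname reportMetrics
#' @export
foldMetrics <- function(x) x@folds

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport\n")
  m <- object@metrics
  for (k in names(m)) cat(sprintf("  %-4s %.4f\n", k, m[[k]]))
  if (nrow(object@folds))
    cat("  (", nrow(object@folds), "folds )\n")
})
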
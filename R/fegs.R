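#' Build the 3D graphical curve of a protein sequence
#'
#' Starting at the origin, the curve advances by the vertex point of the
#' first residue and then, for each subsequent position i, by the pair point
#' of the dipeptide ending at i.  A sequence of N residues therefore yields
#' N + 1 points, and every step adds a nonzero vector (all step vectors have
#' z of 1 or 1.25).
#'
#' @param seq A single cleaned sequence (character scalar or `AAString`),
#'   length >= 2.
#' @param geometry A [ConeGeometry-class] built from one property.
#' @return An (N + 1) x 3 numeric matrix of curve points; first row is the
#'   origin.
#' @examples
#' g <- coneGeometry(setNames(1:20, aminoAcids()), "toy")
#' buildCurve("ACDE", g)
#' @export
buildCurve <- function(seq, geometry) {
  s <- splitResidues(seq)
  n <- length(s)
  if (n < 2L) stopData("curve construction requires at least 2 residues")
  steps <- matrix(0, nrow = n, ncol = 3L)
  steps[1L, ] <- geometry@vertices[s[1L], ]
  if (n >= 2L) {
    dip <- paste0(s[-n], s[-1L])
    steps[2:n, ] <- geometry@pairs[dip, , drop = FALSE]
  }
  pts <- rbind(c(0, 0, 0), apply(steps, 2L, cumsum))
  dimnames(pts) <- list(paste0("P", 0:n), c("x", "y", "z"))
  pts
}

splitResidues <- function(seq) {
  s <- strsplit(as.character(seq), "", fixed = TRUE)[[1L]]
  bad <- !(s %in% aminoAcids())
  if (any(bad))
    stopData("residue(s) outside the 20-letter alphabet: ",
             paste(unique(s[bad]), collapse = ", "),
             " (run cleanSequence first)")
  s
}

#' Distance-quotient matrix of a curve
#'
#' For curve points P_1..P_L (the synthetic origin P_0 is excluded, so L is
#' the sequence length), the off-diagonal entry M_ij is the Euclidean
#' distance between P_i and P_j divided by the summed lengths of the curve
#' edges between them (the classic ED/GD quotient); the diagonal is zero.
#' Entries lie in (0, 1] and the matrix is symmetric; an adjacent pair has
#' quotient exactly 1.
#'
#' @param curve Curve matrix from [buildCurve()] (first row = origin).
#' @return L x L symmetric numeric matrix with zero diagonal.
#' @export
distanceQuotientMatrix <- function(curve) {
  p <- curve[-1L, , drop = FALSE]
  L <- nrow(p)
  if (L < 2L) stopData("distance-quotient matrix requires L >= 2")
  eu <- as.matrix(dist(p))
  edge <- sqrt(rowSums(diff(p)^2))
  pref <- c(0, cumsum(edge))
  gd <- abs(outer(pref, pref, "-"))
  m <- eu / ifelse(gd == 0, 1, gd)
  diag(m) <- 0
  dimnames(m) <- NULL
  m
}

#' Leading-eigenvalue feature of a distance-quotient matrix
#'
#' The largest eigenvalue of the symmetric nonnegative matrix M, scaled by
#' the sequence length L.  The scaling removes gross length dependence so
#' features of long and short proteins are comparable; nonnegativity of the
#' result follows from Perron-Frobenius (zero trace forces the extreme
#' eigenvalue of largest magnitude to be the positive one).
#'
#' @param m Symmetric nonnegative matrix with zero diagonal.
#' @param L Sequence length used for scaling (defaults to `nrow(m)`).
#' @return A single nonnegative number, lambda_1(M) / L.
#' @examples
#' eigenFeature(matrix(c(0, 1, 1, 0), 2), 2)  # 0.5
#' @export
eigenFeature <- function(m, L = nrow(m)) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stopData("m must be a square matrix")
  if (any(!is.finite(m))) stopData("matrix contains non-finite entries")
  if (max(abs(m - t(m))) > 1e-8) stopData("matrix must be symmetric")
  lam <- eigen(m, symmetric = TRUE, only.values = TRUE)$values[1L]
  lam / L
}

#' Amino-acid composition (AAC)
#'
#' Normalized frequency of each of the 20 amino acids, in alphabetical
#' column order; sums to 1.
#'
#' @param seq A cleaned sequence (character scalar or `AAString`), length >= 1.
#' @return Named numeric vector of length 20.
#' @examples
#' aac("ACDE")
#' @export
aac <- function(seq) {
  s <- splitResidues(seq)
  if (!length(s)) stopData("aac is undefined on an empty sequence")
  counts <- table(factor(s, levels = aminoAcids()))
  v <- as.numeric(counts) / length(s)
  names(v) <- aminoAcids()
  v
}

#' Dipeptide composition (DPC)
#'
#' Normalized frequency of each of the 400 ordered dipeptides, in
#' lexicographic column order (AA, AC, ..., YY); sums to 1.
#'
#' @param seq A cleaned sequence, length >= 2.
#' @return Named numeric vector of length 400.
#' @examples
#' dpc("ACAC")[c("AC", "CA")]
#' @export
dpc <- function(seq) {
  s <- splitResidues(seq)
  n <- length(s)
  if (n < 2L) stopData("dpc requires at least 2 residues")
  dip <- paste0(s[-n], s[-1L])
  counts <- table(factor(dip, levels = dipeptides()))
  v <- as.numeric(counts) / (n - 1L)
  names(v) <- dipeptides()
  v
}

# Per-property leading-eigenvalue features, fast C++ path.  Equivalent to
# buildCurve -> distanceQuotientMatrix -> eigenFeature for every property of
# the table (asserted in the test suite).
fegsLambdas <- function(seq, table, ranks = NULL) {
  s <- splitResidues(seq)
  if (length(s) < 2L) stopData("FEGS requires at least 2 residues")
  codes <- match(s, aminoAcids())
  if (is.null(ranks)) ranks <- tableRanks(table)
  lam <- cpp_fegs_lambdas(codes, ranks, 1e-12, 10000L)
  names(lam) <- paste0("lambda_", propertyNames(table))
  lam
}

# 20 x P rank matrix of a table (rank 1 = lowest value, alphabetical
# tie-break), memoized on the table object.
tableRanks <- function(table) {
  r <- attr(table@values, "rankCache")
  if (is.null(r)) r <- apply(propertyValues(table), 1L, rankAminoAcids)
  r
}

cacheRanks <- function(table) {
  attr(table@values, "rankCache") <- apply(propertyValues(table), 1L,
                                           rankAminoAcids)
  table
}

#' FEGS feature vector of one sequence
#'
#' Concatenates, in fixed order: one leading-eigenvalue curve feature per
#' physicochemical property (P values), the 20 AAC frequencies, and the 400
#' DPC frequencies — P + 420 dimensions, 578 with the default 158-property
#' table.
#'
#' @param seq A cleaned sequence, length >= 2.
#' @param table A [PhysChemTable-class]; default [defaultPhysChemTable()].
#' @return Named numeric vector of length `nrow(table) + 420`.
#' @examples
#' v <- fegsVector("MKVLACDEFGHIKLMNPQRSTVWY")
#' length(v)  # 578
#' @export
fegsVector <- function(seq, table = defaultPhysChemTable()) {
  c(fegsLambdas(seq, table),
    stats::setNames(aac(seq), paste0("AAC_", aminoAcids())),
    stats::setNames(dpc(seq), paste0("DPC_", dipeptides())))
}

#' Featurize a dataset
#'
#' Computes the chosen descriptor for every sequence; row order matches the
#' dataset, row names are the sequence ids, column names give the layout.
#' Any sequence failing a descriptor precondition aborts with its id named.
#'
#' @param x A [LabeledProteinSet-class] or `AAStringSet` of cleaned
#'   sequences.
#' @param descriptor One of `"fegs"`, `"apaac"`, `"dpc"`, `"aac"`.
#' @param table [PhysChemTable-class] for FEGS (default table if `NULL`).
#' @param lambda,w APAAC parameters (see [apaac()]).
#' @return Numeric n x D matrix (D = P + 420, 20 + 2*lambda, 400 or 20).
#' @export
featurizeDataset <- function(x, descriptor = c("fegs", "apaac", "dpc", "aac"),
                             table = NULL, lambda = 5L, w = 0.05) {
  descriptor <- match.arg(descriptor)
  seqs <- if (is(x, "LabeledProteinSet")) proteins(x) else x
  if (descriptor == "fegs") {
    if (is.null(table)) table <- defaultPhysChemTable()
    table <- cacheRanks(table)
  }
  fun <- switch(descriptor,
    fegs = function(s) fegsVector(s, table),
    apaac = function(s) apaac(s, lambda = lambda, w = w),
    dpc = dpc,
    aac = aac)
  ids <- names(seqs)
  chr <- as.character(seqs)
  rows <- vector("list", length(chr))
  for (i in seq_along(chr)) {
    rows[[i]] <- tryCatch(fun(chr[[i]]), error = function(e)
      stopData("featurization failed for sequence '", ids[[i]], "': ",
               conditionMessage(e)))
  }
  if (!length(rows)) {
    width <- switch(descriptor,
      fegs = nrow(table) + 420L, apaac = 20L + 2L * lambda,
      dpc = 400L, aac = 20L)
    cn <- switch(descriptor,
      fegs = c(paste0("lambda_", propertyNames(table)),
               paste0("AAC_", aminoAcids()), paste0("DPC_", dipeptides())),
      apaac = apaacLayout(lambda),
      dpc = paste0("DPC_", dipeptides()),
      aac = paste0("AAC_", aminoAcids()))
    m <- matrix(numeric(0), nrow = 0L, ncol = width,
                dimnames = list(NULL, cn))
    attr(m, "descriptor") <- descriptor
    return(m)
  }
  m <- do.call(rbind, rows)
  rownames(m) <- ids
  attr(m, "descriptor") <- descriptor
  m
}

#' Write / read a feature matrix as annotated TSV
#'
#' The file carries `#`-prefixed header comment lines recording the
#' descriptor and dimension, then a header row (`id` + column names) and one
#' row per sequence.
#'
#' @param m Feature matrix from [featurizeDataset()].
#' @param path File path.
#' @return `writeFeatureMatrix()`: `path`, invisibly;
#'   `readFeatureMatrix()`: the matrix with the descriptor attribute
#'   restored.
#' @export
writeFeatureMatrix <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# descriptor: ",
                      attr(m, "descriptor") %||% "unknown"),
               paste0("# dimension: ", ncol(m))), con)
  writeLines(paste(c("id", colnames(m)), collapse = "\t"), con)
  if (nrow(m)) {
    body <- apply(m, 1L, function(r)
      paste(format(r, digits = 17, scientific = TRUE, trim = TRUE),
            collapse = "\t"))
    writeLines(paste(rownames(m), body, sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path) {
  if (!file.exists(path)) stopData("feature matrix file not found: ", path)
  hdr <- readLines(path, n = 10L)
  desc <- sub("^# descriptor: ", "", grep("^# descriptor:", hdr, value = TRUE))
  df <- read.delim(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (length(desc)) attr(m, "descriptor") <- desc
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
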
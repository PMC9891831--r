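#' Default physicochemical index table (158 properties)
#'
#' Builds the package's default [PhysChemTable-class]: 158 amino-acid index
#' entries drawn from the AAindex collection bundled with \pkg{seqinr}.
#' Entries with missing values or with all 20 values identical (which induce
#' no ordering) are eliminated; the remainder are sorted by accession and
#' the first 158 are kept, so the selection is deterministic and the FEGS
#' vector has its canonical 578 dimensions.  The exact 158-index selection
#' used by the original FEGS software is not published; this table is a
#' documented, reproducible stand-in, and any user table can be supplied
#' instead via [readPhysChemTable()] or [physChemTable()].
#'
#' @param n Number of properties to keep (default 158).
#' @return A [PhysChemTable-class] with `n` properties; rownames are AAindex
#'   accessions.
#' @examples
#' tab <- defaultPhysChemTable()
#' nrow(tab)
#' @export
defaultPhysChemTable <- function(n = 158L) {
  key <- paste0("physchem_", n)
  if (!is.null(.pkgenv[[key]])) return(.pkgenv[[key]])
  e <- new.env()
  utils::data("aaindex", package = "seqinr", envir = e)
  aaindex <- e$aaindex
  ok <- vapply(aaindex, function(a)
    !anyNA(a$I) && length(unique(a$I)) > 1L, logical(1))
  aaindex <- aaindex[ok]
  aaindex <- aaindex[order(names(aaindex))]
  if (length(aaindex) < n)
    stopData("only ", length(aaindex), " usable AAindex entries available")
  aaindex <- aaindex[seq_len(n)]
  three <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
             Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
             L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
             S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val")
  vals <- t(vapply(aaindex, function(a) a$I[three[aminoAcids()]],
                   numeric(20)))
  colnames(vals) <- aminoAcids()
  rownames(vals) <- names(aaindex)
  tab <- new("PhysChemTable", values = vals)
  .pkgenv[[key]] <- tab
  tab
}

#' Construct a PhysChemTable from a matrix
#'
#' @param values Numeric P x 20 matrix (or data.frame); columns named by the
#'   20 one-letter amino-acid codes (any order; they are re-ordered
#'   alphabetically), rows named by property.
#' @return A [PhysChemTable-class].
#' @export
physChemTable <- function(values) {
  values <- as.matrix(values)
  if (is.null(colnames(values)) ||
      !setequal(colnames(values), aminoAcids()))
    stopData("index table must have the 20 amino-acid one-letter codes as columns")
  values <- values[, aminoAcids(), drop = FALSE]
  if (is.null(rownames(values)))
    rownames(values) <- paste0("P", seq_len(nrow(values)))
  new("PhysChemTable", values = values)
}

#' Read a physicochemical index table from a TSV file
#'
#' Format: tab-separated; header row with amino-acid one-letter codes;
#' one property per row with its name in the first column.
#'
#' @param path Path to the table file.
#' @return A [PhysChemTable-class].
#' @export
readPhysChemTable <- function(path) {
  if (!file.exists(path)) stopData("index table file not found: ", path)
  df <- read.delim(path, header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  physChemTable(m)
}

#' Rank the 20 amino acids by a property
#'
#' Assigns rank 1 to the amino acid with the smallest property value and
#' rank 20 to the largest; ties are broken by one-letter code, alphabetical
#' first.
#'
#' @param values Named numeric vector of 20 property values (names = amino
#'   acids).
#' @return Named integer vector of ranks 1..20 (names = amino acids, in
#'   alphabetical order).
#' @examples
#' v <- setNames(1:20, aminoAcids())
#' rankAminoAcids(v)
#' @export
rankAminoAcids <- function(values) {
  if (length(values) != 20L || !setequal(names(values), aminoAcids()))
    stopData("need one value for each of the 20 amino acids")
  values <- values[aminoAcids()]
  if (length(unique(values)) == 1L)
    stopData("degenerate index: all 20 values identical")
  ord <- order(values, names(values))
  ranks <- integer(20L)
  ranks[ord] <- 1:20
  names(ranks) <- names(values)
  ranks
}

#' Vertex points on the cone base circle
#'
#' The amino acid with rank i is placed at
#' `(cos(2*pi*i/20), sin(2*pi*i/20), 1)` — the base circle of a right
#' circular cone of height 1.
#'
#' @param ordering Named integer rank vector from [rankAminoAcids()].
#' @return 20 x 3 numeric matrix, rownames = amino acids.
#' @export
vertexPoints <- function(ordering) {
  ang <- 2 * pi * ordering / 20
  m <- cbind(x = cos(ang), y = sin(ang), z = rep(1, 20L))
  rownames(m) <- names(ordering)
  m
}

#' Pair points for the 400 ordered dipeptides
#'
#' `phi(a, b) = phi(a) + phi(b) / 4`; all pair points lie at height
#' z = 1.25.
#'
#' @param vertices 20 x 3 vertex-point matrix from [vertexPoints()].
#' @return 400 x 3 numeric matrix, rownames = dipeptides in lexicographic
#'   order.
#' @export
pairPoints <- function(vertices) {
  aa <- aminoAcids()
  first <- rep(seq_len(20L), each = 20L)
  second <- rep(seq_len(20L), times = 20L)
  m <- vertices[first, , drop = FALSE] + 0.25 * vertices[second, , drop = FALSE]
  rownames(m) <- dipeptides()
  m
}

#' Build the cone geometry for one property
#'
#' @param values Named numeric vector of 20 property values.
#' @param property Property identifier used for display.
#' @return A [ConeGeometry-class].
#' @examples
#' g <- coneGeometry(setNames(1:20, aminoAcids()), "toy")
#' g
#' @export
coneGeometry <- function(values, property = "property") {
  ordering <- rankAminoAcids(values)
  v <- vertexPoints(ordering)
  new("ConeGeometry", property = as.character(property),
      ordering = ordering, vertices = v, pairs = pairPoints(v))
}
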
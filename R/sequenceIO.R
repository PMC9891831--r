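#' Read protein sequences from a FASTA file
#'
#' Parses a (possibly multi-line) FASTA file into an `AAStringSet`.
#' Residues are upper-cased; nothing else is altered — removal of ambiguous
#' residues is a separate, explicit step ([cleanSequence()]).  The sequence
#' identifier is the header text up to the first whitespace.
#'
#' @param path Path to a FASTA-formatted text file.
#' @return An `AAStringSet`, one element per record, in file order.
#' @details Errors on a sequence line appearing before any `>` header
#'   (naming the offending line number) and on duplicate identifiers.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACDE", ">b", "MKVL"), tf)
#' readProteinFasta(tf)
#' @export
readProteinFasta <- function(path) {
  if (!file.exists(path)) stopData("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meaningful <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), ";"))
  if (length(meaningful) && !startsWith(trimws(lines[meaningful[1L]]), ">"))
    stopData("malformed FASTA: sequence line before any header at line ",
             meaningful[1L], " of ", path)
  if (!length(meaningful)) return(Biostrings::AAStringSet())
  raw <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids))
    stopData("duplicate sequence ids in ", path, ": ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(raw))
  bad <- grepl("[^A-Z]", seqs)
  if (any(bad))
    stopData("non-letter characters in sequence(s): ",
             paste(ids[bad], collapse = ", "))
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write protein sequences to a FASTA file
#'
#' @param x An `AAStringSet` or [LabeledProteinSet-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeProteinFasta <- function(x, path) {
  if (is(x, "LabeledProteinSet")) x <- proteins(x)
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}

#' Remove ambiguous residues from a protein sequence
#'
#' Drops the ambiguous/nonstandard one-letter codes B, J, O, X, U and Z,
#' leaving only the 20 standard amino acids.  Idempotent.
#'
#' @param raw Character vector of upper-case letter strings.
#' @return Character vector of cleaned sequences (possibly shorter).
#' @examples
#' cleanSequence("ACBDXZ")  # "ACD"
#' @export
cleanSequence <- function(raw) {
  raw <- as.character(raw)
  bad <- grepl("[^A-Z]", raw)
  if (any(bad))
    stopData("sequence contains non-letter characters: ",
             paste(substr(raw[bad], 1L, 20L), collapse = ", "))
  gsub("[BJOXUZ]", "", raw)
}

#' Clean every sequence of a dataset
#'
#' Applies [cleanSequence()] to each sequence; sequences shorter than 2
#' residues after cleaning are dropped with a warning (the descriptors are
#' undefined on them).
#'
#' @param x A [LabeledProteinSet-class] or `AAStringSet`.
#' @return An object of the same class with cleaned sequences.
#' @export
cleanDataset <- function(x) {
  lps <- if (is(x, "LabeledProteinSet")) x else LabeledProteinSet(x)
  seqs <- cleanSequence(as.character(proteins(lps)))
  keep <- nchar(seqs) >= 2L
  if (any(!keep))
    warning("dropping ", sum(!keep), " sequence(s) shorter than 2 residues ",
            "after cleaning: ",
            paste(sequenceIds(lps)[!keep], collapse = ", "))
  ss <- Biostrings::AAStringSet(seqs[keep])
  names(ss) <- sequenceIds(lps)[keep]
  lab <- classLabels(lps)
  out <- new("LabeledProteinSet", sequences = ss,
             labels = if (length(lab)) lab[keep] else lab)
  if (is(x, "LabeledProteinSet")) out else proteins(out)
}

#' Read a two-column label file
#'
#' Expects tab-separated lines `id<TAB>label` with label 1 (positive) or 0
#' (negative); no header.
#'
#' @param path Path to the label file.
#' @return A data.frame with columns `id` and `label` (factor
#'   negative/positive).
#' @export
readLabels <- function(path) {
  if (!file.exists(path)) stopData("label file not found: ", path)
  df <- read.delim(path, header = FALSE, col.names = c("id", "label"),
                   colClasses = c("character", "character"))
  if (!all(df$label %in% c("0", "1", "negative", "positive")))
    stopData("labels must be 0/1 or negative/positive in ", path)
  lab <- ifelse(df$label %in% c("1", "positive"), "positive", "negative")
  data.frame(id = df$id, label = factor(lab, levels = c("negative", "positive")))
}

#' Write a two-column label file
#' @param x A [LabeledProteinSet-class] with labels.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeLabels <- function(x, path) {
  if (!length(classLabels(x))) stopData("dataset carries no labels")
  df <- data.frame(id = sequenceIds(x),
                   label = as.integer(classLabels(x) == "positive"))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Join sequences with a label table
#'
#' @param sequences An `AAStringSet`.
#' @param labels A data.frame as returned by [readLabels()].
#' @return A [LabeledProteinSet-class]; errors if any sequence id lacks a
#'   label.
#' @export
labelDataset <- function(sequences, labels) {
  ids <- names(sequences)
  miss <- setdiff(ids, labels$id)
  if (length(miss))
    stopData("no label for sequence(s): ", paste(miss, collapse = ", "))
  lab <- labels$label[match(ids, labels$id)]
  LabeledProteinSet(sequences, lab)
}
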
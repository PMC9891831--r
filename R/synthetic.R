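# Background amino-acid frequencies approximating the Swiss-Prot
# composition; rows of the base transition matrix all equal this vector, so
# the negative class is a stationary first-order chain with realistic
# composition.
backgroundFrequencies <- function() {
  f <- c(A = 0.0826, C = 0.0137, D = 0.0546, E = 0.0674, F = 0.0386,
         G = 0.0708, H = 0.0227, I = 0.0593, K = 0.0582, L = 0.0965,
         M = 0.0241, N = 0.0406, P = 0.0472, Q = 0.0393, R = 0.0553,
         S = 0.0661, T = 0.0535, V = 0.0687, W = 0.0110, Y = 0.0292)
  f / sum(f)
}

#' Signature dipeptides of the synthetic positive class
#'
#' A fixed set of 30 ordered dipeptides whose transition probabilities are
#' inflated in the positive class.  Fixed so that generated benchmarks are
#' comparable across runs and machines.
#'
#' @return Character vector of 30 dipeptides.
#' @export
signatureDipeptides <- function() {
  c("AK", "AC", "CV", "DG", "DE", "EL", "FM", "GS", "GH", "HT",
    "IW", "IK", "KY", "LA", "LM", "MC", "ND", "NP", "PE", "QF",
    "QR", "RG", "SH", "ST", "TI", "VK", "VW", "WL", "YM", "YA")
}

# Positive-class transition law: a mixture of the background chain and a
# "signature" chain that concentrates each row's mass on its signature
# successors (proportionally to background within them).  The mixture
# weight is the saturating map w = 1 - exp(-effect): proportional to
# `effect` near zero, never exceeding full replacement, so any effect >= 0
# is valid.
positiveTransitionMatrix <- function(effect) {
  aa <- aminoAcids()
  bg <- backgroundFrequencies()
  base <- matrix(rep(bg, each = 20L), nrow = 20L, dimnames = list(aa, aa))
  sig <- matrix(0, 20L, 20L, dimnames = list(aa, aa))
  first <- substr(signatureDipeptides(), 1L, 1L)
  second <- substr(signatureDipeptides(), 2L, 2L)
  for (a in aa) {
    succ <- second[first == a]
    if (length(succ)) sig[a, succ] <- bg[succ] / sum(bg[succ])
    else sig[a, ] <- base[a, ]
  }
  w <- 1 - exp(-effect)
  (1 - w) * base + w * sig
}

sampleChain <- function(n, init, trans) {
  aa <- aminoAcids()
  cumInit <- cumsum(init)
  cumTrans <- t(apply(trans, 1L, cumsum))
  idx <- integer(n)
  idx[1L] <- findInterval(runif(1L), cumInit) + 1L
  for (i in seq_len(n - 1L))
    idx[i + 1L] <- findInterval(runif(1L), cumTrans[idx[i], ]) + 1L
  paste(aa[idx], collapse = "")
}

#' Generate a two-class synthetic protein dataset
#'
#' Sequences are drawn from a first-order Markov chain over the 20 standard
#' amino acids with Swiss-Prot-like background composition.  The positive
#' class's transition matrix is a mixture `(1 - w) * background + w *
#' signature` with `w = 1 - exp(-effect)`, where the signature law
#' concentrates each row's mass on its successors among the 30
#' [signatureDipeptides()].  `effect = 0` makes the two classes identically
#' distributed; the perturbation grows proportionally with small `effect`
#' and saturates at full replacement, planting an order-dependent dipeptide
#' signal that composition alone cannot fully capture.  Lengths are uniform
#' on `lengthRange`.  Fully reproducible from `seed`.
#'
#' @param nPos,nNeg Number of positive / negative sequences (>= 0).
#' @param lengthRange Integer \[min, max\] residue lengths, min >= 10;
#'   default c(50, 400), covering typical immunoglobulin-domain scales.
#' @param effect Class-separation strength >= 0; default 0.5.
#' @param seed Integer seed.
#' @return A [LabeledProteinSet-class] with ids `pos_0001`, ...,
#'   `neg_0001`, ...
#' @examples
#' lps <- generateDataset(5, 5, effect = 0.5, seed = 42)
#' lps
#' @export
generateDataset <- function(nPos, nNeg, lengthRange = c(50L, 400L),
                            effect = 0.5, seed = 1L) {
  nPos <- as.integer(nPos); nNeg <- as.integer(nNeg)
  if (nPos < 0L || nNeg < 0L) stopData("sequence counts must be >= 0")
  lengthRange <- as.integer(lengthRange)
  if (length(lengthRange) != 2L || lengthRange[1L] < 10L ||
      lengthRange[2L] < lengthRange[1L])
    stopData("lengthRange must be [min, max] with min >= 10")
  if (effect < 0) stopData("effect must be >= 0")
  bg <- backgroundFrequencies()
  negT <- matrix(rep(bg, each = 20L), nrow = 20L,
                 dimnames = list(aminoAcids(), aminoAcids()))
  posT <- positiveTransitionMatrix(effect)
  withSeed(seed, {
    lens <- sample(seq(lengthRange[1L], lengthRange[2L]),
                   nPos + nNeg, replace = TRUE)
    seqs <- character(nPos + nNeg)
    for (i in seq_len(nPos)) seqs[i] <- sampleChain(lens[i], bg, posT)
    for (i in seq_len(nNeg)) seqs[nPos + i] <- sampleChain(lens[nPos + i], bg, negT)
  })
  ids <- c(sprintf("pos_%04d", seq_len(nPos)),
           sprintf("neg_%04d", seq_len(nNeg)))
  ss <- Biostrings::AAStringSet(seqs)
  names(ss) <- ids
  LabeledProteinSet(ss, rep(c("positive", "negative"), c(nPos, nNeg)))
}
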
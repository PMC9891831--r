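# Hydropathy scales used by amphiphilic pseudo amino-acid composition:
# hydrophobicity (Tanford-style values as used in classic PseAAC work) and
# hydrophilicity (Hopp-Woods).  Standardized to zero mean / unit population
# variance over the 20 residues before the correlation sums.
apaacScales <- function() {
  hb <- c(A =  0.62, C = 0.29, D = -0.90, E = -0.74, F = 1.19,
          G =  0.48, H = -0.40, I = 1.38, K = -1.50, L = 1.06,
          M =  0.64, N = -0.78, P = 0.12, Q = -0.85, R = -2.53,
          S = -0.18, T = -0.05, V = 1.08, W = 0.81, Y = 0.26)
  hl <- c(A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5,
          G =  0.0, H = -0.5, I = -1.8, K = 3.0, L = -1.8,
          M = -1.3, N = 0.2, P = 0.0, Q = 0.2, R = 3.0,
          S =  0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3)
  std <- function(h) {
    h <- h[aminoAcids()]
    (h - mean(h)) / sqrt(mean((h - mean(h))^2))
  }
  list(hydrophobicity = std(hb), hydrophilicity = std(hl))
}

apaacLayout <- function(lambda) {
  c(paste0("AAC_", aminoAcids()),
    paste0("tau", rep(seq_len(lambda), each = 2L),
           c("_hydrophobicity", "_hydrophilicity")))
}

#' Amphiphilic pseudo amino-acid composition (APAAC)
#'
#' The 20 normalized residue frequencies followed by 2*lambda
#' sequence-order correlation factors: for each tier k = 1..lambda,
#' `tau_{2k-1} = mean_i H1(s_i) H1(s_{i+k})` over the standardized
#' hydrophobicity scale and `tau_{2k}` likewise for hydrophilicity.  The
#' vector is normalized so all 20 + 2*lambda entries sum to 1, with the
#' correlation block weighted by `w`.  Correlation factors (and hence the
#' tail entries) may be negative, since the scales are centered.
#'
#' @param seq A cleaned sequence of length > `lambda`.
#' @param lambda Correlation depth (tiers), integer >= 1; default 5.
#' @param w Weight of the correlation block, > 0; default 0.05.
#' @return Named numeric vector of length `20 + 2 * lambda`, summing to 1.
#' @examples
#' length(apaac("MKVLACDEFGHIKLMNPQRSTVWY"))  # 30
#' @export
apaac <- function(seq, lambda = 5L, w = 0.05) {
  lambda <- as.integer(lambda)
  if (lambda < 1L) stopData("lambda must be >= 1")
  if (w <= 0) stopData("w must be > 0")
  s <- splitResidues(seq)
  n <- length(s)
  if (n <= lambda)
    stopData("sequence '", as.character(seq), "' has length ", n,
             " <= lambda = ", lambda)
  sc <- apaacScales()
  h1 <- sc$hydrophobicity[s]
  h2 <- sc$hydrophilicity[s]
  tau <- numeric(2L * lambda)
  for (k in seq_len(lambda)) {
    i <- seq_len(n - k)
    tau[2L * k - 1L] <- sum(h1[i] * h1[i + k]) / (n - k)
    tau[2L * k] <- sum(h2[i] * h2[i + k]) / (n - k)
  }
  f <- aac(paste(s, collapse = ""))
  denom <- 1 + w * sum(tau)
  if (denom <= 0) stopData("degenerate APAAC normalization (denominator <= 0)")
  out <- c(f, w * tau) / denom
  names(out) <- apaacLayout(lambda)
  out
}
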
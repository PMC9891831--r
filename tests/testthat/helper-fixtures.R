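# Shared fixtures: tiny deterministic sequences, geometries and tables used
# across the test files.  Everything is generated in code.

aaAlphabet <- fegsForest::aminoAcids()

# Random cleaned sequences of given lengths under a local seed.
randomSequences <- function(n, minLen = 10L, maxLen = 60L, seed = 1L) {
  r <- local({
    set.seed(seed)
    lens <- sample(minLen:maxLen, n, replace = TRUE)
    vapply(lens, function(L)
      paste(sample(aaAlphabet, L, replace = TRUE), collapse = ""),
      character(1))
  })
  stats::setNames(r, sprintf("s%03d", seq_len(n)))
}

# Identity property table: values 1..20 in alphabetical order, so rank(aa)
# equals its alphabetical position (A = 1 ... Y = 20).
identityValues <- stats::setNames(1:20, aaAlphabet)

# A small 3-property table for fast FEGS runs.
tinyTable <- function() {
  v <- rbind(ident = identityValues,
             rev = stats::setNames(20:1, aaAlphabet),
             mix = stats::setNames(c(7, 3, 19, 1, 12, 5, 16, 9, 2, 14,
                                     20, 6, 11, 8, 15, 4, 18, 10, 13, 17),
                                   aaAlphabet))
  fegsForest::physChemTable(v)
}

writeTempFasta <- function(lines) {
  tf <- tempfile(fileext = ".fasta")
  writeLines(lines, tf)
  tf
}

# Brute-force path length between curve points i < j: explicit edge-by-edge
# summation, independent of the prefix-sum implementation.
brutePathLength <- function(points, i, j) {
  total <- 0
  for (k in i:(j - 1))
    total <- total + sqrt(sum((points[k + 1, ] - points[k, ])^2))
  total
}

# Independent R-side power iteration oracle for the leading eigenvalue.
powerIterationLambda <- function(m, iter = 5000, tol = 1e-14) {
  v <- rep(1 / sqrt(nrow(m)), nrow(m))
  lam <- 0
  for (i in seq_len(iter)) {
    w <- m %*% v + 0.05 * max(rowSums(m)) * v
    lamNew <- sum(w * v)
    v <- w / sqrt(sum(w^2))
    if (abs(lamNew - lam) < tol * max(1, abs(lamNew))) break
    lam <- lamNew
  }
  sum((m %*% v) * v) / sum(v * v)
}


# Independent brute-force APAAC oracle: explicit double loop over the
# standard amphiphilic PseAAC sums, sharing no code with apaac().
bruteApaac <- function(s, lambda, w) {
  aa <- fegsForest::aminoAcids()
  std <- function(h) (h - mean(h)) / sqrt(sum((h - mean(h))^2) / 20)
  h1 <- std(c(A = 0.62, C = 0.29, D = -0.90, E = -0.74, F = 1.19, G = 0.48,
              H = -0.40, I = 1.38, K = -1.50, L = 1.06, M = 0.64, N = -0.78,
              P = 0.12, Q = -0.85, R = -2.53, S = -0.18, T = -0.05, V = 1.08,
              W = 0.81, Y = 0.26)[aa])
  h2 <- std(c(A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5, G = 0.0,
              H = -0.5, I = -1.8, K = 3.0, L = -1.8, M = -1.3, N = 0.2,
              P = 0.0, Q = 0.2, R = 3.0, S = 0.3, T = -0.4, V = -1.5,
              W = -3.4, Y = -2.3)[aa])
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  tau <- numeric(2 * lambda)
  for (k in seq_len(lambda)) {
    s1 <- 0; s2 <- 0
    for (i in seq_len(n - k)) {
      s1 <- s1 + h1[[ch[i]]] * h1[[ch[i + k]]]
      s2 <- s2 + h2[[ch[i]]] * h2[[ch[i + k]]]
    }
    tau[2 * k - 1] <- s1 / (n - k)
    tau[2 * k] <- s2 / (n - k)
  }
  f <- vapply(aa, function(a) sum(ch == a), numeric(1)) / n
  unname(c(f, w * tau) / (1 + w * sum(tau)))
}

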
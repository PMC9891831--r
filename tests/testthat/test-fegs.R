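test_that("curves start at the origin, add one point per residue, never stall", {
  g <- coneGeometry(identityValues, "ident")
  for (s in randomSequences(5, 5, 40, seed = 2)) {
    cur <- buildCurve(s, g)
    expect_equal(unname(cur[1, ]), c(0, 0, 0))
    expect_identical(nrow(cur), nchar(s) + 1L)
    steps <- diff(cur)
    expect_true(all(rowSums(steps^2) > 0))
  }
})

test_that("curve steps follow the vertex-then-pair-point rule", {
  # A has rank 20 when it carries the largest value
  vals <- stats::setNames(c(20, 1:19), aaAlphabet)
  g <- coneGeometry(vals, "toy")
  cur <- buildCurve("AA", g)
  expect_equal(unname(cur[2, ]), c(1, 0, 1), tolerance = 1e-12)
  expect_equal(unname(cur[3, ]), c(2.25, 0, 2.25), tolerance = 1e-12)
  # generic: step i >= 2 equals the pair point of the trailing dipeptide
  g2 <- coneGeometry(identityValues, "ident")
  s <- "MKVLAC"
  cur2 <- buildCurve(s, g2)
  expect_equal(unname(cur2[2, ] - cur2[1, ]), unname(g2@vertices["M", ]))
  for (i in 2:6) {
    dip <- substr(s, i - 1, i)
    expect_equal(unname(cur2[i + 1, ] - cur2[i, ]), unname(g2@pairs[dip, ]),
                 tolerance = 1e-12)
  }
  expect_error(buildCurve("A", g2), "at least 2")
  expect_error(buildCurve("AXB", g2), "alphabet")
})

test_that("distance-quotient matrix is symmetric, zero-diagonal, in (0,1]", {
  g <- coneGeometry(identityValues, "ident")
  for (s in randomSequences(4, 8, 30, seed = 5)) {
    m <- distanceQuotientMatrix(buildCurve(s, g))
    L <- nchar(s)
    expect_identical(dim(m), c(L, L))
    expect_equal(m, t(m), tolerance = 1e-12)
    expect_equal(unname(diag(m)), rep(0, L))
    off <- m[upper.tri(m)]
    expect_true(all(off > 0 & off <= 1 + 1e-12))
    # adjacent points: straight line equals the single edge
    expect_equal(unname(m[cbind(1:(L - 1), 2:L)]), rep(1, L - 1),
                 tolerance = 1e-12)
  }
})

test_that("collinear equal-step curves have all off-diagonal quotients 1", {
  # a poly-A curve after the first step is collinear with equal pair steps
  g <- coneGeometry(identityValues, "ident")
  m <- distanceQuotientMatrix(buildCurve(strrep("A", 12), g))
  inner <- m[2:12, 2:12]
  expect_equal(inner[upper.tri(inner)],
               rep(1, sum(upper.tri(inner))), tolerance = 1e-12)
})

test_that("prefix-sum path lengths match brute-force edge summation", {
  g <- coneGeometry(identityValues, "ident")
  for (s in randomSequences(3, 10, 30, seed = 9)) {
    cur <- buildCurve(s, g)
    p <- cur[-1, , drop = FALSE]
    L <- nrow(p)
    m <- distanceQuotientMatrix(cur)
    for (i in seq_len(L - 1)) for (j in (i + 1):L) {
      eu <- sqrt(sum((p[i, ] - p[j, ])^2))
      expect_equal(m[i, j], eu / brutePathLength(p, i, j), tolerance = 1e-10)
    }
  }
})

test_that("eigen feature: closed forms and power-iteration oracle agree", {
  expect_equal(eigenFeature(matrix(c(0, 1, 1, 0), 2), 2), 0.5)
  expect_error(eigenFeature(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  expect_error(eigenFeature(matrix(c(0, NA, NA, 0), 2)), "finite")
  set.seed(31)
  for (rep in 1:5) {
    a <- matrix(runif(50 * 50), 50)
    m <- (a + t(a)) / 2
    diag(m) <- 0
    dense <- eigenFeature(m, 1)
    expect_gte(dense, 0)
    expect_equal(dense, powerIterationLambda(m), tolerance = 1e-8)
    expect_equal(dense, fegsForest:::cpp_leading_eigenvalue(m, 1e-13, 20000L),
                 tolerance = 1e-8)
  }
})

test_that("AAC and DPC are normalized with fixed layouts", {
  expect_equal(aac("AAAA")[["A"]], 1)
  expect_true(all(aac("AAAA")[-1] == 0))
  a <- aac("ACDE")
  expect_equal(unname(a[c("A", "C", "D", "E")]), rep(0.25, 4))
  expect_equal(sum(a), 1)
  d <- dpc("AAA")
  expect_equal(d[["AA"]], 1)
  d2 <- dpc("ACAC")
  expect_equal(d2[["AC"]], 2 / 3)
  expect_equal(d2[["CA"]], 1 / 3)
  for (s in randomSequences(5, 5, 40, seed = 13)) {
    expect_equal(sum(aac(s)), 1)
    expect_equal(sum(dpc(s)), 1)
    expect_true(all(aac(s) >= 0) && all(dpc(s) >= 0))
  }
  expect_error(dpc("A"), "at least 2")
  expect_identical(names(a), aminoAcids())
  expect_identical(names(d), dipeptides())
})

test_that("AAC is permutation-invariant; DPC only under dipeptide-preserving ones", {
  s <- "ACDEFGAC"
  perm <- "CAGFEDCA"  # reversal: same residue multiset, different dipeptides
  expect_equal(aac(s), aac(perm))
  expect_false(isTRUE(all.equal(dpc(s), dpc(perm))))
  # a permutation preserving the dipeptide multiset preserves DPC exactly
  expect_equal(dpc("ACACA"), dpc("CACAC"))
})

test_that("fegs vector has length P + 420 and the documented layout", {
  v <- fegsVector("MKVLACDEFGHIKLMNPQRSTVWY")
  expect_length(v, 578L)
  expect_identical(sum(startsWith(names(v), "lambda_")), 158L)
  v2 <- fegsVector("MKVLAC", tinyTable())
  expect_length(v2, 423L)
  one <- physChemTable(rbind(only = identityValues))
  expect_length(fegsVector("MKVLAC", one), 421L)
})

test_that("batch FEGS path agrees with the granular R route", {
  tab <- tinyTable()
  for (s in randomSequences(4, 10, 50, seed = 21)) {
    v <- fegsVector(s, tab)
    for (p in seq_len(nrow(tab))) {
      g <- coneGeometry(propertyValues(tab)[p, ], propertyNames(tab)[p])
      lam <- eigenFeature(distanceQuotientMatrix(buildCurve(s, g)))
      expect_equal(unname(v[p]), lam, tolerance = 1e-8)
    }
    expect_equal(unname(v[4:23]), unname(aac(s)))
    expect_equal(unname(v[24:423]), unname(dpc(s)))
  }
})

test_that("anagrams share AAC but generally differ in eigen features", {
  v1 <- fegsVector("ACDE", tinyTable())
  v2 <- fegsVector("CADE", tinyTable())
  expect_equal(v1[startsWith(names(v1), "AAC_")],
               v2[startsWith(names(v2), "AAC_")])
  expect_false(isTRUE(all.equal(v1[1:3], v2[1:3])))
})

test_that("length-doubling keeps the eigen feature bounded", {
  tab <- physChemTable(rbind(ident = identityValues))
  for (s in randomSequences(5, 10, 40, seed = 33)) {
    lam1 <- fegsVector(s, tab)[[1]]
    lam2 <- fegsVector(paste0(s, s), tab)[[1]]
    expect_lte(lam2, 2 * lam1 + 1)
  }
})

test_that("featurizeDataset rows match per-sequence vectors; empty input ok", {
  lps <- generateDataset(3, 2, lengthRange = c(15, 30), seed = 8)
  tab <- tinyTable()
  m <- featurizeDataset(lps, "fegs", table = tab)
  expect_identical(dim(m), c(5L, 423L))
  expect_identical(rownames(m), sequenceIds(lps))
  expect_equal(m[2, ], fegsVector(as.character(proteins(lps))[2], tab))
  empty <- featurizeDataset(LabeledProteinSet(character(0)), "fegs",
                            table = tab)
  expect_identical(dim(empty), c(0L, 423L))
  expect_identical(colnames(empty), colnames(m))
  bad <- LabeledProteinSet(c(ok = "ACDEF", short = "AC", tiny = "A"))
  expect_error(featurizeDataset(bad, "dpc"), "tiny")
})

test_that("featurization is deterministic across calls", {
  s <- randomSequences(1, 40, 40, seed = 44)
  expect_identical(fegsVector(s, tinyTable()), fegsVector(s, tinyTable()))
})

test_that("feature matrices round-trip through annotated TSV", {
  lps <- generateDataset(3, 3, lengthRange = c(15, 25), seed = 6)
  m <- featurizeDataset(lps, "dpc")
  tf <- tempfile(fileext = ".tsv")
  writeFeatureMatrix(m, tf)
  back <- readFeatureMatrix(tf)
  expect_equal(unclass(back), unclass(m)[, , drop = FALSE],
               ignore_attr = TRUE)
  expect_identical(attr(back, "descriptor"), "dpc")
  expect_identical(rownames(back), rownames(m))
})
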
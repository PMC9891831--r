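# Small, fast fixture: DPC features of a well-separated synthetic set.
cascadeFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      lps <- generateDataset(24, 24, lengthRange = c(40, 80), effect = 1,
                             seed = 19)
      cache <<- list(x = featurizeDataset(lps, "dpc"),
                     y = classLabels(lps))
    }
    cache
  }
})

test_that("a fitted layer returns 36 out-of-fold probability columns", {
  d <- cascadeFixture()
  layer <- fitLayer(d$x, d$y, seed = 3)
  expect_length(layer$learners, 18L)
  expect_identical(dim(layer$oof), c(nrow(d$x), 36L))
  expect_false(anyNA(layer$oof))
  # each learner's two columns form a distribution
  for (l in 1:18) {
    block <- layer$oof[, (2 * l - 1):(2 * l)]
    expect_equal(unname(rowSums(block)), rep(1, nrow(d$x)), tolerance = 1e-9)
    expect_true(all(block >= -1e-12 & block <= 1 + 1e-12))
  }
})

test_that("layer fitting rejects degenerate labels", {
  d <- cascadeFixture()
  yOne <- factor(rep("positive", nrow(d$x)),
                 levels = c("negative", "positive"))
  expect_error(fitLayer(d$x, yOne, seed = 1), "single class")
})

test_that("augmentation is pure concatenation with shape checks", {
  m <- matrix(rnorm(12), 3, dimnames = list(NULL, paste0("f", 1:4)))
  p <- matrix(runif(3 * 36), 3)
  a <- augmentFeatures(m, p)
  expect_identical(dim(a), c(3L, 40L))
  expect_identical(a[, 1:4], m)
  expect_equal(unname(a[, 5:40]), unname(p))
  expect_error(augmentFeatures(m, p[1:2, ]), "mismatch")
  z <- augmentFeatures(m[0, , drop = FALSE], p[0, , drop = FALSE])
  expect_identical(dim(z), c(0L, 40L))
  # feature width bookkeeping: d = 578 would give 614 augmented columns
  expect_identical(578L + 36L, 614L)
})

test_that("cascade separates strong synthetic signal and predicts coherently", {
  d <- cascadeFixture()
  model <- fitCascade(d$x, d$y, maxLayers = 3, seed = 7)
  expect_s4_class(model, "CascadeForest")
  p <- predictProba(model, d$x)
  expect_equal(unname(rowSums(p)), rep(1, nrow(d$x)), tolerance = 1e-9)
  expect_gte(mean(predictLabels(model, d$x) == d$y), 0.95)
  # permuting rows permutes outputs identically
  perm <- rev(seq_len(nrow(d$x)))
  expect_equal(predictProba(model, d$x[perm, ]), p[perm, ])
  # S4 predict method mirrors the functional interface
  expect_equal(predict(model, d$x), p)
  expect_identical(predict(model, d$x, type = "class"),
                   predictLabels(model, d$x))
})

test_that("fixed seed reproduces the fit bit-exactly; width is checked", {
  d <- cascadeFixture()
  m1 <- fitCascade(d$x, d$y, maxLayers = 2, seed = 42)
  m2 <- fitCascade(d$x, d$y, maxLayers = 2, seed = 42)
  expect_identical(predictProba(m1, d$x), predictProba(m2, d$x))
  expect_identical(m1@history, m2@history)
  expect_error(predictProba(m1, d$x[, 1:10]), "expects 400.*got 10")
})

test_that("maxLayers cap and stop rule are honored", {
  d <- cascadeFixture()
  m1 <- fitCascade(d$x, d$y, maxLayers = 1, seed = 5)
  expect_length(m1@layers, 1L)
  expect_error(fitCascade(d$x, d$y, maxLayers = 0, seed = 5), ">= 1")
  m3 <- fitCascade(d$x, d$y, maxLayers = 3, seed = 5)
  expect_identical(m3@stopLayer, which.max(m3@history))
  expect_true(all(m3@history[m3@stopLayer] >= m3@history))
  expect_lte(length(m3@layers), 3L)
})

test_that("single-layer cascade equals the plain 18-learner ensemble mean", {
  d <- cascadeFixture()
  model <- fitCascade(d$x, d$y, maxLayers = 1, seed = 23)
  p <- predictProba(model, d$x)
  per <- fegsForest:::predictLayer(model@layers[[1]], d$x)
  manual <- cbind(negative = rowMeans(per[, seq(1, 35, 2)]),
                  positive = rowMeans(per[, seq(2, 36, 2)]))
  expect_equal(p, manual, tolerance = 1e-12)
})

test_that("pure-noise labels stay near the majority rate and stop early", {
  lps <- generateDataset(20, 20, lengthRange = c(40, 60), effect = 0,
                         seed = 29)
  x <- featurizeDataset(lps, "aac")
  yNoise <- local({set.seed(31); factor(sample(c("negative", "positive"),
                                               40, replace = TRUE),
                                        levels = c("negative", "positive"))})
  model <- fitCascade(x, yNoise, maxLayers = 4, seed = 3)
  expect_lte(length(model@layers), 4L)
  base <- max(table(yNoise)) / 40
  expect_lt(abs(model@history[model@stopLayer] - base), 0.25)
})

test_that("model archives round-trip and refuse corrupt payloads", {
  d <- cascadeFixture()
  model <- fitCascade(d$x, d$y, maxLayers = 1, seed = 13)
  tf <- tempfile(fileext = ".rds")
  saveCascade(model, tf, meta = list(descriptor = "dpc"))
  back <- loadCascade(tf)
  expect_identical(back$meta$descriptor, "dpc")
  expect_equal(predictProba(back$model, d$x), predictProba(model, d$x))
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(format = "something-else"), bad)
  expect_error(loadCascade(bad), "not a cascade model archive")
  txt <- tempfile()
  writeLines("not an rds", txt)
  expect_error(loadCascade(txt), "cannot read")
  expect_error(loadCascade(tempfile()), "not found")
})
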
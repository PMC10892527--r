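# Confusion matrices and accuracy measures.

test_that("confusion matrix equals an exhaustive tally", {
  yt <- c(1L, 2L, 3L, 1L, 2L, 1L)
  yp <- c(1L, 3L, 3L, 2L, 2L, 1L)
  cm <- confusionMatrix(yt, yp, K = 3L)
  # brute-force oracle
  ref <- matrix(0L, 3L, 3L)
  for (i in seq_along(yt)) ref[yt[i], yp[i]] <- ref[yt[i], yp[i]] + 1L
  expect_identical(counts(cm), ref)
  expect_identical(sum(counts(cm)), length(yt))

  ident <- confusionMatrix(1:3, 1:3)
  eye <- diag(3L); storage.mode(eye) <- "integer"
  expect_identical(counts(ident), eye)

  empty <- confusionMatrix(integer(0), integer(0), K = 2L)
  expect_identical(counts(empty), matrix(0L, 2L, 2L))

  expect_error(confusionMatrix(1:3, 1:2), "length")
  expect_error(confusionMatrix(c(1L, 4L), c(1L, 1L), K = 3L), "1..3")
})

test_that("producer's and user's accuracy reproduce the optimal-run table", {
  cw <- classwiseAccuracy(optimalRunMatrix())
  expect_equal(roundHalfUp2(cw$pa), c(98.96, 98.72, 99.53))
  expect_equal(roundHalfUp2(cw$ua), c(97.34, 99.84, 99.24))
})

test_that("the initial-run table's internally consistent entries reproduce", {
  cw <- classwiseAccuracy(initialRunMatrix())
  # indicator-species row and column are consistent with the printed table
  expect_equal(roundHalfUp2(cw$pa)[2], 99.44)
  expect_equal(roundHalfUp2(cw$ua)[2], 99.15)
  # the remaining printed entries are NOT reproducible from the matrix; the
  # matrix arithmetic itself gives these values (e.g. the non-vegetation UA
  # column sums to 3445 with 3367 correct -> 97.74, not the printed 95.6)
  expect_equal(roundHalfUp2(cw$pa), c(94.53, 99.44, 98.85))
  expect_equal(roundHalfUp2(cw$ua), c(97.06, 99.15, 97.74))
})

test_that("summary metrics match hand arithmetic and known edge cases", {
  sm <- summaryMetrics(optimalRunMatrix())
  expect_equal(sm$oa, 100 * 8986 / 9070)
  expect_equal(roundHalfUp2(sm$oa), 99.07)

  diagCM <- confusionMatrix(rep(1:3, 4L), rep(1:3, 4L))
  smD <- summaryMetrics(diagCM)
  expect_equal(smD$oa, 100)
  expect_equal(smD$aa, 100)
  expect_equal(smD$kappa, 1)

  flat <- new("ConfusionMatrix", counts = matrix(1L, 2, 2),
              classes = c("a", "b"))
  expect_equal(summaryMetrics(flat)$kappa, 0)

  # always-predict-class-1 on a balanced 3-class set
  cm1 <- confusionMatrix(rep(1:3, each = 10L), rep(1L, 30L))
  sm1 <- summaryMetrics(cm1)
  expect_equal(sm1$oa, 100 / 3, tolerance = 1e-9)
  expect_equal(sm1$kappa, 0)
})

test_that("AA is the unweighted and OA the count-weighted mean of PA", {
  cm <- optimalRunMatrix()
  cw <- classwiseAccuracy(cm)
  sm <- summaryMetrics(cm)
  expect_equal(sm$aa, mean(cw$pa))
  w <- rowSums(counts(cm)) / sum(counts(cm))
  expect_equal(sm$oa, sum(w * cw$pa))
})

test_that("kappa is invariant under simultaneous row/column permutation", {
  cm <- optimalRunMatrix()
  perm <- c(3L, 1L, 2L)
  pcm <- new("ConfusionMatrix", counts = counts(cm)[perm, perm],
             classes = cm@classes[perm])
  expect_equal(summaryMetrics(pcm)$kappa, summaryMetrics(cm)$kappa)
})

test_that("kappa is 1 exactly when the off-diagonal is empty (>= 2 classes)", {
  offDiag <- counts(optimalRunMatrix()); offDiag[1, 2] <- 0L
  set.seed(2)
  for (i in 1:5) {
    m <- matrix(as.integer(rpois(9, 50)), 3, 3)
    cmR <- new("ConfusionMatrix", counts = m, classes = letters[1:3])
    k <- summaryMetrics(cmR)$kappa
    if (sum(m) - sum(diag(m)) == 0L) expect_equal(k, 1)
    else expect_lt(k, 1)
  }
  pure <- new("ConfusionMatrix", counts = diag(c(5L, 9L, 2L)),
              classes = letters[1:3])
  expect_equal(summaryMetrics(pure)$kappa, 1)
})

test_that("empty classes yield NA (not zero) and are excluded from AA", {
  cm <- confusionMatrix(c(1L, 1L, 2L), c(1L, 2L, 2L), K = 3L)
  cw <- classwiseAccuracy(cm)
  expect_true(is.na(cw$pa[3]))
  expect_true(is.na(cw$ua[3]))
  expect_warning(sm <- summaryMetrics(cm), "excluded")
  expect_equal(sm$aa, mean(cw$pa[1:2]))
})

test_that("percent rounding is half away from zero at two decimals", {
  expect_equal(roundHalfUp2(98.955), 98.96)
  expect_equal(roundHalfUp2(0.005), 0.01)
  rep <- metricsReport(c(1L, 1L, 2L, 2L), c(1L, 1L, 2L, 1L))
  fm <- formatMetrics(rep)
  expect_identical(names(fm), c("class", "pa", "ua", "oa", "aa", "kappa"))
})

test_that("classification map matches the patch-dataset prediction path", {
  scene <- generateScene(quickSceneConfig(seed = 8L, H = 24L, W = 24L))
  red <- pcaReduce(sceneCube(scene), 0.95)
  ds <- extractPatches(red$scores, sceneLabels(scene), 5L)
  spec <- smallRNetSpec(red$model@nBands, 5L, widths = c(4L, 4L, 8L, 8L))
  model <- instantiateNetwork(spec, 1L)
  map <- renderClassificationMap(model, red$scores, 5L)
  expect_identical(dim(labelCodes(map)), c(24L, 24L))
  # predictions at labeled coords equal the evaluate path
  direct <- predictModel(model, ds)$class
  atCoords <- labelCodes(map)[patchCoords(ds) + 1L]
  expect_identical(atCoords, direct)
})

test_that("a constant-output model renders a single-colour map", {
  scene <- generateScene(quickSceneConfig(seed = 9L, H = 16L, W = 16L))
  red <- pcaReduce(sceneCube(scene), 0.95)
  spec <- smallRNetSpec(red$model@nBands, 5L, widths = c(4L, 4L, 8L, 8L))
  model <- instantiateNetwork(spec, 2L)
  # force class 2: zero the head weights, stack its bias
  headW <- grep("^fc.*\\.W$", names(model@params), value = TRUE)
  headB <- grep("^fc.*\\.b$", names(model@params), value = TRUE)
  model@params[[headW]] <- model@params[[headW]] * 0
  model@params[[headB]] <- c(-50, 50, -50)
  png <- file.path(tempdir(), "map.png")
  map <- renderClassificationMap(model, red$scores, 5L, pngPath = png)
  expect_identical(unique(as.vector(labelCodes(map))), 2L)
  expect_true(file.exists(png))
  badTable <- data.frame(id = 1:2, name = c("a", "b"), color = c("#000001", "#000002"))
  expect_error(renderClassificationMap(model, red$scores, 5L,
                                       classTable = badTable), "missing")
})
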
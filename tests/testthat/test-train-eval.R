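# Training loop, evaluation, repetition, cross-validation, sweeps.

# One shared small setup for the training tests.
localSetup <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      scene <- generateScene(quickSceneConfig(seed = 21L, H = 40L, W = 40L))
      cache <<- prepareSplits(scene, 0.95, 5L)
    }
    cache
  }
})

test_that("one epoch on a small set yields finite loss and full history", {
  su <- localSetup()
  spec <- smallRNetSpec(su$bands, 5L, widths = c(4L, 8L, 8L, 16L))
  small <- subsetPatches(su$train, 1:10)
  fit <- trainModel(spec, small, trainConfig(epochs = 1L, batchSize = 4L,
                                             seed = 2L))
  expect_identical(nrow(fit@history), 1L)
  expect_true(is.finite(fit@history$loss[1]))
})

test_that("same config and seed reproduce the loss history exactly", {
  su <- localSetup()
  spec <- smallRNetSpec(su$bands, 5L, widths = c(4L, 8L, 8L, 16L))
  sub <- subsetPatches(su$train, 1:60)
  cfg <- trainConfig(epochs = 2L, batchSize = 16L, seed = 7L)
  f1 <- trainModel(spec, sub, cfg)
  f2 <- trainModel(spec, sub, cfg)
  expect_identical(f1@history$loss, f2@history$loss)
  expect_identical(f1@model@params, f2@model@params)
  f3 <- trainModel(spec, sub, trainConfig(epochs = 2L, batchSize = 16L,
                                          seed = 8L))
  expect_false(identical(f1@history$loss, f3@history$loss))
})

test_that("training on the separable scene learns: loss falls, OA beats majority", {
  su <- localSetup()
  spec <- smallRNetSpec(su$bands, 5L, widths = c(4L, 8L, 8L, 16L))
  fit <- trainModel(spec, su$train, trainConfig(epochs = 4L, seed = 3L))
  h <- fit@history
  expect_lt(h$loss[nrow(h)], h$loss[1])
  rep <- evaluateModel(fit, su$test)
  majority <- 100 * max(table(patchLabels(su$test))) / nSamples(su$test)
  expect_gt(rep@oa, majority)
})

test_that("training errors are informative", {
  su <- localSetup()
  spec <- smallRNetSpec(su$bands, 5L, widths = c(4L, 8L, 8L, 16L))
  expect_error(trainModel(spec, su$train,
                          trainConfig(epochs = 1L, learningRate = -1)),
               "learningRate")
  bad <- subsetPatches(su$train, 1:5)
  bad@labels <- rep(7L, 5L)
  expect_error(trainModel(spec, bad, trainConfig(epochs = 1L)), "classes")
})

test_that("evaluation equals metrics computed by hand on stored predictions", {
  su <- localSetup()
  spec <- smallRNetSpec(su$bands, 5L, widths = c(4L, 8L, 8L, 16L))
  fit <- trainModel(spec, subsetPatches(su$train, 1:80),
                    trainConfig(epochs = 1L, seed = 5L))
  pred <- predictModel(fit@model, su$test)$class
  rep <- evaluateModel(fit, su$test)
  byHand <- metricsReport(patchLabels(su$test), pred, K = 3L)
  expect_equal(rep@oa, byHand@oa)
  expect_equal(rep@pa, byHand@pa)
  expect_identical(counts(rep@cm), counts(byHand@cm))
})

test_that("repeated runs aggregate correctly", {
  su <- localSetup()
  spec <- smallRNetSpec(su$bands, 5L, widths = c(4L, 8L, 8L, 16L))
  data <- list(train = subsetPatches(su$train, 1:60),
               test = subsetPatches(su$test, 1:40), validation = NULL)
  cfg <- trainConfig(epochs = 1L, seed = 9L)
  one <- repeatExperiment(spec, data, cfg, nRuns = 1L)
  expect_identical(nrow(one$runs), 1L)
  expect_equal(unname(one$mean["oa"]), one$runs$oa[1])
  expect_equal(unname(one$sd["oa"]), 0)

  three <- repeatExperiment(spec, data, cfg, nRuns = 3L)
  expect_gte(unname(three$mean["oa"]), min(three$runs$oa))
  expect_lte(unname(three$mean["oa"]), max(three$runs$oa))
})

test_that("K-fold partitions are exact and near-balanced for K in {3,5,7,9}", {
  su <- localSetup()
  full <- su$full
  for (K in c(3L, 5L, 7L, 9L)) {
    folds <- grassRNet:::.foldAssignments(full, K, seed = 13L)
    expect_identical(length(folds), nSamples(full))
    expect_true(all(folds %in% seq_len(K)))
    # every sample in exactly one fold; per-class fold counts differ <= 1
    for (k in sort(unique(patchLabels(full)))) {
      tab <- tabulate(folds[patchLabels(full) == k], K)
      expect_lte(max(tab) - min(tab), 1L)
    }
  }
  expect_error(kfoldCV(subsetPatches(full, 1:5), 10L,
                       smallRNetSpec(su$bands, 5L), trainConfig(epochs = 1L)),
               "exceeds|at least")
})

test_that("kfoldCV runs end to end and reports population variance", {
  scene <- generateScene(quickSceneConfig(seed = 31L, H = 24L, W = 24L,
                                          unlabeledFraction = 0.5))
  red <- pcaReduce(sceneCube(scene), 0.95)
  ds <- extractPatches(red$scores, sceneLabels(scene), 5L)
  spec <- smallRNetSpec(red$model@nBands, 5L, widths = c(4L, 4L, 8L, 8L))
  res <- kfoldCV(ds, 3L, spec, trainConfig(epochs = 1L, seed = 4L))
  expect_identical(res@K, 3L)
  expect_equal(res@meanAccuracy, mean(res@foldAccuracy))
  expect_equal(res@varAccuracy, mean((res@foldAccuracy - res@meanAccuracy)^2))
})

test_that("ablation suite emits the four-config table with correct flags", {
  su <- localSetup()
  data <- list(train = subsetPatches(su$train, 1:60),
               test = subsetPatches(su$test, 1:40))
  tab <- ablationSuite(data, trainConfig(epochs = 1L, seed = 2L),
                       widths = c(4L, 4L, 8L, 8L), stemKernel = c(3L, 3L, 3L))
  expect_identical(nrow(tab), 4L)
  expect_identical(tab$config, c("a", "b", "c", "d"))
  expect_identical(tab$firstBranch, c(FALSE, TRUE, FALSE, TRUE))
  expect_identical(tab$secondBranch, c(FALSE, FALSE, TRUE, TRUE))
  expect_true(all(tab$conv3d))
  expect_true(all(is.finite(tab$oa)))
})

test_that("the plain-3D ablation config contains no spectral-only kernels", {
  spec <- build3DRNetO(widths = c(4L, 4L, 8L, 8L), bands = 6L, patchSize = 5L,
                       branches = c(FALSE, FALSE))
  tab <- layerTable(spec)
  expect_false(any(tab$kernel == "3x1x1"))
  withBranch <- build3DRNetO(widths = c(4L, 4L, 8L, 8L), bands = 6L,
                             patchSize = 5L)
  expect_true(any(layerTable(withBranch)$kernel == "3x1x1"))
})

test_that("hyperparameter sweep produces one row per grid cell", {
  su <- localSetup()
  full <- su$full
  cfg <- trainConfig(epochs = 1L, seed = 3L)
  lrTab <- hyperparameterSweep(full, list(learning_rate = c(0.001, 0.003)),
                               cfg, widths = c(4L, 4L, 8L, 8L))
  expect_identical(nrow(lrTab), 2L)
  expect_identical(lrTab$axis, rep("learning_rate", 2L))

  frTab <- hyperparameterSweep(full, list(train_fraction = c(0.2, 0.4)),
                               cfg, widths = c(4L, 4L, 8L, 8L))
  expect_identical(nrow(frTab), 2L)

  base <- hyperparameterSweep(full, list(), cfg, widths = c(4L, 4L, 8L, 8L))
  expect_identical(nrow(base), 1L)

  expect_error(hyperparameterSweep(full, list(bogus = 1), cfg), "unknown sweep axis")
})

test_that("the nine-point learning-rate grid is representable", {
  lrGrid <- c(0.0001, 0.0003, 0.0005, 0.001, 0.003, 0.005, 0.01, 0.03, 0.05)
  expect_identical(length(lrGrid), 9L)
  # cells are constructed without training when inspecting the grid shape
  cells <- lapply(lrGrid, function(l) trainConfig(learningRate = l))
  expect_identical(vapply(cells, function(c) c@learningRate, 0), lrGrid)
})
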
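# PCA reduction, patch extraction, splitting, standardization.

test_that("PCA retains exactly the rank of an affine low-rank scene", {
  set.seed(7)
  C <- 10L; H <- 6L; W <- 6L
  m <- runif(C); u <- rnorm(C); v <- rnorm(C)
  a <- rnorm(H * W); b <- rnorm(H * W)
  X <- outer(a, u) + outer(b, v) + rep(m, each = H * W)
  cube <- hyperspectralCube(array(X, c(H, W, C)))

  # independent oracle: eigendecomposition of the band covariance
  ev <- eigen(stats::cov(X), symmetric = TRUE, only.values = TRUE)$values
  expect_identical(sum(ev > 1e-10 * max(ev)), 2L)

  red <- pcaReduce(cube, 0.98)
  expect_identical(red$model@nBands, 2L)
  expect_identical(dim(cubeValues(red$scores)), c(H, W, 2L))
})

test_that("PCA rejects degenerate scenes and bad thresholds", {
  const <- hyperspectralCube(array(0.5, c(3, 3, 4)))
  expect_error(pcaReduce(const, 0.98), "degenerate")
  expect_error(pcaReduce(makeCube(), 0), "varianceThreshold")
  expect_error(pcaReduce(makeCube(), 1.2), "varianceThreshold")
})

test_that("PCA loadings are orthonormal, ratios sum to one, B is monotone in threshold and deterministic", {
  cube <- makeCube(8L, 9L, 12L, seed = 5L)
  red <- pcaReduce(cube, 0.9)
  L <- red$model@loadings
  expect_lt(max(abs(crossprod(L) - diag(ncol(L)))), 1e-8)
  expect_equal(sum(red$model@varRatio), 1, tolerance = 1e-8)
  expect_false(is.unsorted(rev(red$model@varRatio)))

  Bs <- vapply(c(0.5, 0.8, 0.9, 0.98, 1.0),
               function(t) pcaReduce(cube, t)$model@nBands, 0L)
  expect_false(is.unsorted(Bs))
  expect_identical(Bs[5], 12L)

  again <- pcaReduce(cube, 0.9)
  expect_identical(again$model@loadings, red$model@loadings)
  expect_identical(cubeValues(again$scores), cubeValues(red$scores))
})

test_that("PCA reconstruction error shrinks with B and vanishes at full rank", {
  cube <- makeCube(6L, 6L, 8L, seed = 9L)
  X <- matrix(cubeValues(cube), 36L, 8L)
  errs <- vapply(seq_len(8L), function(B) {
    pc <- stats::prcomp(X)
    rot <- pc$rotation[, seq_len(B), drop = FALSE]
    rec <- sweep(sweep(X, 2, pc$center) %*% rot %*% t(rot), 2, -pc$center)
    sqrt(sum((rec - X)^2))
  }, 0)
  expect_true(all(diff(errs) <= 1e-10))
  expect_lt(errs[8] / sqrt(sum(X^2)), 1e-6)
})

test_that("patch extraction centres each labeled pixel and conserves the label histogram", {
  cube <- makeCube(5L, 5L, 3L, seed = 2L)
  lab <- labelMap(matrix(rep(1:5, 5), 5, 5) %% 3L + 1L)
  ds <- extractPatches(cube, lab, 3L)
  expect_identical(nSamples(ds), 25L)
  expect_identical(dim(patchArray(ds))[1:3], c(3L, 3L, 3L))
  for (i in c(1L, 7L, 25L)) {
    rc <- patchCoords(ds)[i, ] + 1L
    expect_equal(patchArray(ds)[, 2L, 2L, i],
                 as.vector(cubeValues(cube)[rc[1], rc[2], ]))
    expect_identical(patchLabels(ds)[i], labelCodes(lab)[rc[1], rc[2]])
  }
  expect_identical(as.vector(table(patchLabels(ds))),
                   as.vector(table(labelCodes(lab)[labelCodes(lab) > 0])))
})

test_that("reflect padding mirrors rows/cols about the edge pixel", {
  cube <- makeCube(5L, 5L, 2L, seed = 4L)
  lab <- labelMap(matrix(c(1L, rep(0L, 24L)), 5, 5))  # only corner (0,0)
  ds <- extractPatches(cube, lab, 3L, padMode = "reflect")
  p <- patchArray(ds)[, , , 1L]
  v <- cubeValues(cube)
  # patch position (-1,-1) reflects to scene (1,1) (0-based), i.e. row 2 col 2
  expect_equal(p[, 1L, 1L], as.vector(v[2, 2, ]))
  # patch row -1, col 0 -> scene (1, 0)
  expect_equal(p[, 1L, 2L], as.vector(v[2, 1, ]))
  expect_equal(p[, 2L, 1L], as.vector(v[1, 2, ]))

  dz <- extractPatches(cube, lab, 3L, padMode = "zero")
  expect_equal(patchArray(dz)[, 1L, 1L, 1L], rep(0, 2))
})

test_that("patch extraction validates S and labels", {
  cube <- makeCube(5L, 5L, 2L)
  lab <- makeLabels(5L, 5L)
  expect_error(extractPatches(cube, lab, 4L), "odd")
  none <- labelMap(matrix(0L, 5, 5))
  expect_error(extractPatches(cube, none, 3L), "no labeled")
  big <- extractPatches(makeCube(20L, 20L, 2L), makeLabels(20L, 20L), 9L)
  expect_identical(dim(patchArray(big))[2:3], c(9L, 9L))
})

test_that("stratified split follows the floor rule (7224 -> 5056 at 0.7)", {
  # two classes of 10 at 0.7/0/0.3
  ds <- extractPatches(makeCube(4L, 5L, 2L),
                       labelMap(matrix(rep(1:2, 10L), 4, 5)), 3L)
  parts <- stratifiedSplit(ds, splitSpec(0.7, 0, 0.3, seed = 1L))
  expect_identical(as.vector(table(patchLabels(parts$train))), c(7L, 7L))
  expect_identical(as.vector(table(patchLabels(parts$test))), c(3L, 3L))

  # the field protocol's largest class: floor(0.7 * 7224) = 5056
  expect_identical(floor(0.7 * 7224), 5056)
  expect_identical(floor(0.7 * 13708), 9595)   # vs 9596 printed; floor rule documented
})

test_that("splits partition exactly, are seed-deterministic and input-order invariant", {
  scene <- generateScene(quickSceneConfig(seed = 2L, H = 30L, W = 30L))
  red <- pcaReduce(sceneCube(scene), 0.95)
  ds <- extractPatches(red$scores, sceneLabels(scene), 5L)
  sp <- splitSpec(0.6, 0.1, 0.3, seed = 9L)
  parts <- stratifiedSplit(ds, sp)
  n <- vapply(parts, function(p) if (is.null(p)) 0L else nSamples(p), 0L)
  expect_identical(sum(n), nSamples(ds))
  keys <- lapply(parts, function(p)
    if (is.null(p)) character(0) else
      paste(patchCoords(p)[, 1], patchCoords(p)[, 2]))
  expect_identical(length(unique(unlist(keys))), nSamples(ds))  # no overlap

  again <- stratifiedSplit(ds, sp)
  expect_identical(sort(keys$train), sort(paste(patchCoords(again$train)[, 1],
                                                patchCoords(again$train)[, 2])))

  # shuffled input order, same seed -> same membership
  set.seed(3)
  perm <- sample.int(nSamples(ds))
  dsPerm <- subsetPatches(ds, perm)
  permParts <- stratifiedSplit(dsPerm, sp)
  expect_setequal(paste(patchCoords(permParts$train)[, 1],
                        patchCoords(permParts$train)[, 2]),
                  keys$train)

  other <- stratifiedSplit(ds, splitSpec(0.6, 0.1, 0.3, seed = 10L))
  expect_false(identical(sort(paste(patchCoords(other$train)[, 1],
                                    patchCoords(other$train)[, 2])),
                         sort(keys$train)))
  expect_identical(nSamples(other$train), nSamples(parts$train))
})

test_that("standardization fits on train only, guards refits, centres constant bands", {
  set.seed(11)
  mk <- function(n) patchDataset(array(rnorm(3 * 3 * 3 * n, 5, 2), c(3, 3, 3, n)),
                                 rep(1L, n), cbind(seq_len(n), seq_len(n)))
  tr <- mk(40L); te <- mk(10L)
  std <- standardizePatches(tr, te)
  m <- matrix(patchArray(std$train), 3)
  expect_equal(rowMeans(m), rep(0, 3), tolerance = 1e-12)
  expect_equal(sqrt(rowMeans(m^2)), rep(1, 3), tolerance = 1e-12)
  # test transformed with train constants, not its own
  expect_equal(patchArray(std[[2]]),
               array((patchArray(te) - std$scale$center) / std$scale$sd,
                     dim(patchArray(te))))
  expect_error(standardizePatches(std$train), "already standardized")

  constBand <- mk(20L)
  constBand@patches[2, , , ] <- 7
  stdC <- standardizePatches(constBand)
  expect_equal(unique(as.vector(patchArray(stdC$train)[2, , , ])), 0)
})
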
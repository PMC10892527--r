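# Programmatic fixtures shared across the suite.

# Deterministic random cube.
makeCube <- function(H = 4L, W = 5L, C = 6L, seed = 1L, wl = NULL) {
  set.seed(seed)
  hyperspectralCube(array(runif(H * W * C), c(H, W, C)),
                    wl %||% seq(400, 1000, length.out = C))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Label raster with every class present.
makeLabels <- function(H = 4L, W = 5L, K = 3L, seed = 1L, unlabeled = 0L) {
  set.seed(seed)
  codes <- matrix(sample.int(K, H * W, replace = TRUE), H, W)
  if (unlabeled > 0L) codes[sample.int(H * W, unlabeled)] <- 0L
  labelMap(codes)
}

# Small scene config used by the training tests: separable preset scaled to
# a quick footprint.
quickSceneConfig <- function(seed = 1L, H = 60L, W = 60L, ...) {
  sceneConfig(H = H, W = W, nBands = 64L, seed = seed, ...)
}

# Small dual-branch backbone for fast training.
smallRNetSpec <- function(bands, S = 9L, nClasses = 3L,
                          branches = c(TRUE, TRUE),
                          widths = c(8L, 16L, 32L, 64L)) {
  build3DRNetO(widths = widths, nClasses = nClasses, bands = bands,
               patchSize = S, blocks = c(1L, 1L, 1L, 1L), branches = branches)
}

# Scene -> standardized train/test patches (shared preprocessing shorthand).
prepareSplits <- function(scene, threshold = 0.98, S = 9L, splitSeed = 5L,
                          trainFrac = 0.7) {
  red <- pcaReduce(sceneCube(scene), threshold)
  ds <- extractPatches(red$scores, sceneLabels(scene), S)
  parts <- stratifiedSplit(ds, splitSpec(trainFrac, 0, 1 - trainFrac,
                                         seed = splitSeed))
  std <- standardizePatches(parts$train, parts$test)
  list(train = std$train, test = std[[2L]], bands = red$model@nBands,
       scores = red$scores, model = red$model, full = ds, scale = std$scale)
}

# Paper-printed confusion matrices used in the metrics tests (rows =
# reference class: group species, indicator species, non-vegetation).
optimalRunMatrix <- function() {
  m <- matrix(c(1900L, 6L, 14L,
                36L, 3696L, 12L,
                16L, 0L, 3390L), 3L, 3L, byrow = TRUE)
  new("ConfusionMatrix", counts = m,
      classes = c("S. breviflora", "A. frigida", "non-vegetation"))
}

initialRunMatrix <- function() {
  m <- matrix(c(1815L, 32L, 73L,
                16L, 3723L, 5L,
                39L, 0L, 3367L), 3L, 3L, byrow = TRUE)
  new("ConfusionMatrix", counts = m,
      classes = c("S. breviflora", "A. frigida", "non-vegetation"))
}

# Independent reimplementation of table rounding (half away from zero).
roundHalfUp2 <- function(x) sign(x) * floor(abs(x) * 100 + 0.5) / 100
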
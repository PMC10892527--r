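# PCA band reduction, patch extraction, splitting, standardization.

#' PCA band reduction of a hyperspectral scene
#'
#' Fits PCA on every scene pixel (labeled and unlabeled, so a full-scene
#' classification map stays consistent with the training data) and keeps the
#' minimal number of leading components whose cumulative explained-variance
#' ratio reaches `varianceThreshold`. At the field protocol's threshold of
#' 0.98 the authors' 256-band scenes retain 30 components; synthetic scenes
#' with three endmembers retain far fewer.
#'
#' Loadings follow a fixed sign convention (largest-magnitude element of
#' each component positive) so repeated fits are identical.
#'
#' @param cube a [HyperspectralCube-class].
#' @param varianceThreshold fraction in `(0, 1]`, default 0.98.
#' @return list with `scores` (an `H x W x B` [HyperspectralCube-class] of
#'   centred projections; "wavelengths" are component indices) and `model`
#'   (a [PCAModel-class]).
#' @export
pcaReduce <- function(cube, varianceThreshold = 0.98) {
  stopifnot(is(cube, "HyperspectralCube"))
  if (varianceThreshold <= 0 || varianceThreshold > 1)
    stopf("varianceThreshold must lie in (0, 1]")
  d <- dim(cube@values)
  X <- matrix(cube@values, d[1L] * d[2L], d[3L])
  if (nrow(unique(X)) < 2L)
    stopf("degenerate scene: all pixel spectra identical, PCA undefined")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  tot <- sum(ev)
  if (tot <= 0) stopf("degenerate scene: zero total variance")
  ratio <- ev / tot
  B <- as.integer(which(cumsum(ratio) >= varianceThreshold - 1e-12)[1L])
  rot <- pc$rotation[, seq_len(B), drop = FALSE]
  # deterministic sign: largest-|.| element of each column positive
  for (j in seq_len(B)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  scores <- sweep(X, 2L, pc$center) %*% rot
  model <- new("PCAModel", center = pc$center, loadings = rot,
               varRatio = ratio, nBands = B,
               threshold = varianceThreshold)
  list(scores = hyperspectralCube(array(scores, c(d[1L], d[2L], B)),
                                  seq_len(B)),
       model = model)
}

#' Project a cube onto a fitted PCA model
#'
#' @param model a [PCAModel-class].
#' @param cube a cube with the model's band count.
#' @return `H x W x B` score cube.
#' @export
pcaTransform <- function(model, cube) {
  stopifnot(is(model, "PCAModel"), is(cube, "HyperspectralCube"))
  d <- dim(cube@values)
  if (d[3L] != length(model@center)) stopf("band count does not match the PCA model")
  X <- sweep(matrix(cube@values, d[1L] * d[2L], d[3L]), 2L, model@center)
  hyperspectralCube(array(X %*% model@loadings, c(d[1L], d[2L], model@nBands)),
                    seq_len(model@nBands))
}

# Reflect-pad index map for coordinates 1..n extended by p on both sides
# (mirror about the edge pixel, edge not repeated: -1 -> 3 at p >= 2).
.reflectIndex <- function(n, p) {
  i <- seq.int(1L - p, n + p)
  i <- ifelse(i < 1L, 2L - i, i)
  ifelse(i > n, 2L * n - i, i)
}

#' Extract S x S x B patches around labeled pixels
#'
#' One patch per nonzero label, centred on the pixel; scene borders are
#' filled by reflection (default) so sparse-vegetation edges are not diluted
#' with artificial zero spectra, or by zero/edge padding.
#'
#' @param scores an `H x W x B` [HyperspectralCube-class] (typically PCA
#'   scores).
#' @param labels aligned [LabelMap-class]; pixels with code 0 are skipped.
#' @param S odd patch side (the field protocol uses 9).
#' @param padMode `"reflect"`, `"zero"` or `"edge"`.
#' @return A [PatchDataset-class].
#' @export
extractPatches <- function(scores, labels, S = 9L,
                           padMode = c("reflect", "zero", "edge")) {
  stopifnot(is(scores, "HyperspectralCube"), is(labels, "LabelMap"))
  padMode <- match.arg(padMode)
  S <- as.integer(S)
  if (S < 1L || S %% 2L == 0L) stopf("patch side S must be odd and >= 1, got %d", S)
  d <- dim(scores@values)
  H <- d[1L]; W <- d[2L]; B <- d[3L]
  if (!all(dim(labels@codes) == c(H, W)))
    stopf("labels %dx%d do not match scene %dx%d",
          nrow(labels@codes), ncol(labels@codes), H, W)
  lin <- which(labels@codes > 0L)
  if (length(lin) == 0L) stopf("no labeled pixels: empty dataset")
  p <- S %/% 2L

  # padded scene
  if (padMode == "reflect" && (H <= p || W <= p))
    stopf("scene too small for reflect padding at S = %d", S)
  ri <- switch(padMode,
    reflect = .reflectIndex(H, p),
    edge    = pmin(pmax(seq.int(1L - p, H + p), 1L), H),
    zero    = seq.int(1L - p, H + p))
  ci <- switch(padMode,
    reflect = .reflectIndex(W, p),
    edge    = pmin(pmax(seq.int(1L - p, W + p), 1L), W),
    zero    = seq.int(1L - p, W + p))
  if (padMode == "zero") {
    padded <- array(0, c(H + 2L * p, W + 2L * p, B))
    padded[p + seq_len(H), p + seq_len(W), ] <- scores@values
  } else {
    padded <- scores@values[ri, ci, , drop = FALSE]
  }
  Hp <- H + 2L * p; Wp <- W + 2L * p
  padFlat <- matrix(padded, Hp * Wp, B)

  r <- ((lin - 1L) %% H) + 1L          # 1-based line
  cc <- ((lin - 1L) %/% H) + 1L        # 1-based sample
  N <- length(lin)
  patches <- array(0, c(B, S, S, N))
  for (si in seq_len(S)) for (sj in seq_len(S)) {
    pr <- r + (si - 1L)                # row in padded (offset -p..p shifted by +p)
    pc <- cc + (sj - 1L)
    patches[, si, sj, ] <- t(padFlat[pr + Hp * (pc - 1L), , drop = FALSE])
  }
  patchDataset(patches, labels@codes[lin],
               cbind(line = r - 1L, sample = cc - 1L))
}

#' Subset a PatchDataset
#'
#' @param ds a [PatchDataset-class].
#' @param idx sample indices.
#' @export
subsetPatches <- function(ds, idx) {
  patchDataset(ds@patches[, , , idx, drop = FALSE], ds@labels[idx],
               ds@coords[idx, , drop = FALSE], ds@scaled,
               ds@scaleCenter, ds@scaleSD)
}

#' Stratified train/validation/test split
#'
#' Within each class, `floor(fraction * n)` samples go to train and to
#' validation; the remainder goes to test. Assignment is a seeded shuffle of
#' the class's samples ordered by their (line, sample) coordinates, so the
#' split is invariant to the order samples were extracted in and exactly
#' reproducible from the seed. At the 7:3 field ratio a class of 7224
#' samples yields 5056 training samples.
#'
#' @param ds a [PatchDataset-class].
#' @param spec a [SplitSpec-class].
#' @return list of [PatchDataset-class]: `train`, `validation`, `test`
#'   (empty fractions give NULL entries).
#' @export
stratifiedSplit <- function(ds, spec = splitSpec()) {
  stopifnot(is(ds, "PatchDataset"), is(spec, "SplitSpec"))
  f <- spec@fractions
  classes <- sort(unique(ds@labels))
  assign <- integer(nSamples(ds))       # 1 train, 2 val, 3 test
  groups <- if (spec@stratified) {
    lapply(classes, function(k) which(ds@labels == k))
  } else list(seq_len(nSamples(ds)))
  withSeed(spec@seed, {
    for (gi in seq_along(groups)) {
      idx <- groups[[gi]]
      # stable key: order by source coordinates before shuffling, so the
      # split does not depend on extraction order
      idx <- idx[order(ds@coords[idx, 1L], ds@coords[idx, 2L])]
      n <- length(idx)
      nTr <- floor(f[1L] * n)
      nVa <- floor(f[2L] * n)
      if (spec@stratified && f[1L] > 0 && nTr == 0L)
        warnf("class %d has no training samples at fraction %.3g",
              classes[gi], f[1L])
      perm <- idx[sample.int(n)]
      assign[perm] <- 3L
      assign[perm[seq_len(nTr)]] <- 1L
      if (nVa > 0L) assign[perm[nTr + seq_len(nVa)]] <- 2L
    }
  })
  pick <- function(code) {
    idx <- which(assign == code)
    if (length(idx) == 0L) return(NULL)
    subsetPatches(ds, idx)
  }
  list(train = pick(1L), validation = pick(2L), test = pick(3L))
}

#' Standardize patch datasets with constants fitted on the training split
#'
#' Per-band mean 0 / sd 1, computed on the training patches only and applied
#' to every split; constant bands are centred but not divided. Re-applying
#' to an already standardized dataset is refused (the transform is not
#' idempotent).
#'
#' @param train the training [PatchDataset-class].
#' @param ... further datasets (validation, test) transformed with the same
#'   constants; NULL entries pass through.
#' @return list with `train`, the transformed `...` datasets, and `scale`
#'   (list of `center`, `sd`).
#' @export
standardizePatches <- function(train, ...) {
  stopifnot(is(train, "PatchDataset"))
  if (train@scaled) stopf("dataset is already standardized")
  others <- list(...)
  B <- dim(train@patches)[1L]
  m <- matrix(train@patches, B)
  ctr <- rowMeans(m)
  sdv <- sqrt(rowMeans((m - ctr)^2))
  sdv[sdv == 0] <- 1                    # constant band: centre only
  applyScale <- function(ds) {
    if (is.null(ds)) return(NULL)
    if (ds@scaled) stopf("dataset is already standardized")
    d <- dim(ds@patches)
    out <- array((matrix(ds@patches, B) - ctr) / sdv, d)
    patchDataset(out, ds@labels, ds@coords, TRUE, ctr, sdv)
  }
  c(list(train = applyScale(train)), lapply(others, applyScale),
    list(scale = list(center = ctr, sd = sdv)))
}
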
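# Seeded training loop, repeated runs, K-fold CV, sweeps and ablations.

#' Train a model on standardized patch datasets
#'
#' Minimizes softmax cross-entropy with Adam (default; a fixed learning
#' rate spanning four orders of magnitude in the sweep grid is only
#' workable with an adaptive method) or SGD with momentum. Per-epoch data
#' order is a seeded shuffle; batch-norm layers use batch statistics during
#' training and accumulate running statistics for evaluation. The run is
#' deterministic given `cfg@seed`.
#'
#' @param spec a [NetworkSpec-class] (or an already instantiated
#'   [HsiModel-class], whose weights are then the starting point).
#' @param train training [PatchDataset-class], standardized.
#' @param cfg a [TrainConfig-class].
#' @param validation optional validation [PatchDataset-class], scored each
#'   epoch.
#' @param verbose print per-epoch progress.
#' @return A [TrainResult-class].
#' @export
trainModel <- function(spec, train, cfg = trainConfig(), validation = NULL,
                       verbose = FALSE) {
  stopifnot(is(train, "PatchDataset"))
  if (nSamples(train) == 0L) stopf("empty training set")
  model <- if (is(spec, "HsiModel")) spec else instantiateNetwork(spec, cfg@seed)
  K <- model@spec@nClasses
  if (max(train@labels) > K)
    stopf("labels exceed the network's %d classes", K)
  t0 <- proc.time()[["elapsed"]]
  params <- model@params
  bnStats <- model@bnStats
  opt <- .optInit(params, cfg@optimizer)
  N <- nSamples(train)
  history <- data.frame(epoch = seq_len(cfg@epochs), loss = NA_real_,
                        trainAccuracy = NA_real_, valAccuracy = NA_real_)
  withSeed(deriveSeed(cfg@seed, 17L), {
    for (ep in seq_len(cfg@epochs)) {
      ord <- sample.int(N)
      epLoss <- 0
      epHit <- 0L
      for (at in seq.int(1L, N, by = cfg@batchSize)) {
        idx <- ord[at:min(at + cfg@batchSize - 1L, N)]
        bi <- .batchInput(model, train@patches[, , , idx, drop = FALSE])
        y <- train@labels[idx]
        fw <- .forwardSeq(model@units, bi$x, bi$dims, params, bnStats,
                          TRUE, model@geo)
        bnStats <- fw$bnStats
        ls <- .softmaxCE(fw$out, y)
        if (!is.finite(ls$loss))
          stopf("divergence: non-finite loss at epoch %d", ep)
        acc <- new.env(parent = emptyenv()); acc$g <- list()
        .backwardSeq(model@units, ls$dlogits, fw$caches, params, acc)
        st <- .optStep(params, acc$g, opt, cfg)
        params <- st$params; opt <- st$opt
        epLoss <- epLoss + ls$loss * length(idx)
        epHit <- epHit + sum(max.col(t(fw$out), ties.method = "first") == y)
      }
      history$loss[ep] <- epLoss / N
      history$trainAccuracy[ep] <- epHit / N
      if (!is.null(validation) && nSamples(validation) > 0L) {
        mTmp <- model; mTmp@params <- params; mTmp@bnStats <- bnStats
        pv <- predictModel(mTmp, validation)
        history$valAccuracy[ep] <- mean(pv$class == validation@labels)
      }
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  acc %.4f", ep,
                        history$loss[ep], history$trainAccuracy[ep]))
    }
  })
  model@params <- params
  model@bnStats <- bnStats
  new("TrainResult", history = history, model = model, seed = cfg@seed,
      wallTime = proc.time()[["elapsed"]] - t0, config = cfg)
}

#' Evaluate a trained model on a test dataset
#'
#' Argmax predictions scored with the full metrics suite. Classes absent
#' from the test set have undefined producer's accuracy (NA, excluded from
#' AA).
#'
#' @param model an [HsiModel-class] or [TrainResult-class].
#' @param test a non-empty [PatchDataset-class].
#' @param classes optional class names.
#' @return A [MetricsReport-class].
#' @export
evaluateModel <- function(model, test, classes = NULL) {
  if (is(model, "TrainResult")) model <- model@model
  stopifnot(is(model, "HsiModel"), is(test, "PatchDataset"))
  if (nSamples(test) == 0L) stopf("empty test set")
  pred <- predictModel(model, test)$class
  suppressWarnings(
    metricsReport(test@labels, pred, K = model@spec@nClasses, classes = classes))
}

#' Repeat a training experiment and aggregate the metrics
#'
#' Runs differ only in their derived seed (base seed + run index). With
#' `mode = "reinit"` the split is fixed and only initialization/shuffling
#' varies; with `mode = "resplit"` each run redraws the stratified split
#' from the full dataset.
#'
#' @param spec a [NetworkSpec-class].
#' @param data for `"reinit"`: `list(train =, test =, validation =)` of
#'   standardized datasets; for `"resplit"`: the full unstandardized
#'   [PatchDataset-class].
#' @param cfg a [TrainConfig-class] (its seed is the base seed).
#' @param nRuns number of repetitions (the field protocol averages 10).
#' @param mode `"reinit"` or `"resplit"`.
#' @param split a [SplitSpec-class], used in `"resplit"` mode.
#' @return list with `runs` (data.frame of per-run OA/AA/kappa), `mean` and
#'   `sd` (named vectors).
#' @export
repeatExperiment <- function(spec, data, cfg = trainConfig(), nRuns = 10L,
                             mode = c("reinit", "resplit"),
                             split = splitSpec()) {
  mode <- match.arg(mode)
  if (nRuns < 1L) stopf("nRuns must be >= 1")
  rows <- vector("list", nRuns)
  for (r in seq_len(nRuns)) {
    runSeed <- deriveSeed(cfg@seed, r)
    runCfg <- cfg; runCfg@seed <- runSeed
    if (mode == "resplit") {
      stopifnot(is(data, "PatchDataset"))
      sp <- split; sp@seed <- runSeed
      parts <- stratifiedSplit(data, sp)
      std <- standardizePatches(parts$train, parts$validation, parts$test)
      tr <- std$train; va <- std[[2L]]; te <- std[[3L]]
    } else {
      tr <- data$train; va <- data$validation; te <- data$test
    }
    fit <- trainModel(spec, tr, runCfg, validation = va)
    rep <- evaluateModel(fit, te)
    rows[[r]] <- data.frame(run = r, seed = runSeed, oa = rep@oa, aa = rep@aa,
                            kappa = rep@kappa)
  }
  runs <- do.call(rbind, rows)
  agg <- function(f) vapply(runs[c("oa", "aa", "kappa")], f, 0)
  list(runs = runs, mean = agg(mean),
       sd = agg(function(x) if (length(x) > 1L) stats::sd(x) else 0))
}

#' Stratified K-fold cross-validation
#'
#' Splits every class into K near-equal folds (seeded shuffle, per-class
#' fold sizes differing by at most one), trains on K-1 folds and tests on
#' the held-out fold, each fold serving once as the test set. Reports the
#' per-fold overall accuracy, its mean, and its population variance.
#'
#' @param ds full [PatchDataset-class] (unstandardized; standardization is
#'   refit inside each fold).
#' @param K fold count (the protocol examines 3, 5, 7, 9).
#' @param spec a [NetworkSpec-class].
#' @param cfg a [TrainConfig-class].
#' @return A [CVResult-class].
#' @export
kfoldCV <- function(ds, K, spec, cfg = trainConfig()) {
  stopifnot(is(ds, "PatchDataset"))
  K <- as.integer(K)
  N <- nSamples(ds)
  if (K < 2L) stopf("K must be >= 2")
  if (K > N) stopf("K = %d exceeds the %d samples", K, N)
  counts <- table(ds@labels)
  if (any(counts < K))
    stopf("every class needs at least K samples for stratified %d-fold CV", K)
  folds <- integer(N)
  withSeed(deriveSeed(cfg@seed, 29L), {
    for (k in as.integer(names(counts))) {
      idx <- which(ds@labels == k)
      idx <- idx[order(ds@coords[idx, 1L], ds@coords[idx, 2L])]
      folds[idx[sample.int(length(idx))]] <-
        rep_len(seq_len(K), length(idx))
    }
  })
  acc <- numeric(K)
  for (f in seq_len(K)) {
    te <- subsetPatches(ds, which(folds == f))
    tr <- subsetPatches(ds, which(folds != f))
    std <- standardizePatches(tr, te)
    fit <- trainModel(spec, std$train, cfg)
    rep <- evaluateModel(fit, std[[2L]])
    acc[f] <- rep@oa
  }
  m <- mean(acc)
  new("CVResult", K = K, foldAccuracy = acc, meanAccuracy = m,
      varAccuracy = mean((acc - m)^2))
}

.foldAssignments <- function(ds, K, seed) {
  # exposed for partition testing
  N <- nSamples(ds)
  folds <- integer(N)
  withSeed(deriveSeed(seed, 29L), {
    for (k in sort(unique(ds@labels))) {
      idx <- which(ds@labels == k)
      idx <- idx[order(ds@coords[idx, 1L], ds@coords[idx, 2L])]
      folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(K), length(idx))
    }
  })
  folds
}

#' Dual-branch ablation suite
#'
#' Trains four configurations under identical data and derived seeds:
#' (a) plain 3D convolution blocks, (b) first branch only (spectral then
#' spatial), (c) second branch only (spatial then spectral), (d) both
#' branches with concatenation and fusion. Reports OA/AA/kappa per
#' configuration, optionally averaged over several seeds.
#'
#' @param data `list(train =, test =)` of standardized datasets.
#' @param cfg a [TrainConfig-class].
#' @param widths,blocks,a,stemKernel,poolWindow backbone settings passed to
#'   [build3DRNetO()].
#' @param nSeeds average each configuration over this many derived seeds.
#' @return data.frame with columns config, conv3d, firstBranch,
#'   secondBranch, oa, aa, kappa (and per-seed rows in `attr(,"runs")`).
#' @export
ablationSuite <- function(data, cfg = trainConfig(),
                          widths = c(8L, 16L, 32L, 64L),
                          blocks = c(1L, 1L, 1L, 1L), a = 3L,
                          stemKernel = c(3L, 5L, 5L),
                          poolWindow = c(2L, 2L, 2L), nSeeds = 1L) {
  flags <- list(a = c(FALSE, FALSE), b = c(TRUE, FALSE),
                c = c(FALSE, TRUE), d = c(TRUE, TRUE))
  bands <- dim(data$train@patches)[1L]
  S <- dim(data$train@patches)[2L]
  K <- max(data$train@labels, data$test@labels)
  runRows <- list()
  for (cfgName in names(flags)) {
    for (s in seq_len(nSeeds)) {
      spec <- build3DRNetO(widths = widths, a = a, stemKernel = stemKernel,
                           poolWindow = poolWindow, nClasses = K,
                           bands = bands, patchSize = S, blocks = blocks,
                           branches = flags[[cfgName]])
      runCfg <- cfg; runCfg@seed <- deriveSeed(cfg@seed, s)
      fit <- trainModel(spec, data$train, runCfg)
      rep <- evaluateModel(fit, data$test)
      runRows[[length(runRows) + 1L]] <- data.frame(
        config = cfgName, seed = runCfg@seed, oa = rep@oa, aa = rep@aa,
        kappa = rep@kappa)
    }
  }
  runs <- do.call(rbind, runRows)
  agg <- do.call(rbind, lapply(names(flags), function(nm) {
    sub <- runs[runs$config == nm, ]
    data.frame(config = nm, conv3d = TRUE,
               firstBranch = flags[[nm]][1L], secondBranch = flags[[nm]][2L],
               oa = mean(sub$oa), aa = mean(sub$aa), kappa = mean(sub$kappa))
  }))
  attr(agg, "runs") <- runs
  agg
}

#' Hyperparameter sweep
#'
#' Marginal (default) or full-Cartesian sweep over any of the axes
#' `learning_rate`, `stage_widths`, `train_fraction`, `pool_window`,
#' `stem_kernel`. Each cell rebuilds the split (train-fraction axis holds
#' validation at 0.1), restandardizes, trains under the cell's settings and
#' scores the test split.
#'
#' @param ds full [PatchDataset-class].
#' @param grid named list, e.g. `list(learning_rate = c(0.001, 0.003))`;
#'   `stage_widths`, `pool_window`, `stem_kernel` take lists of vectors.
#'   Empty grid: one baseline row.
#' @param cfg baseline [TrainConfig-class].
#' @param baseSplit baseline [SplitSpec-class] for axes that do not touch
#'   the split.
#' @param mode `"marginal"` (vary one axis at a time) or `"product"`.
#' @param widths,blocks,bands backbone defaults for cells that do not vary
#'   them.
#' @return data.frame, one row per cell (axis, value, oa, aa, kappa).
#' @export
hyperparameterSweep <- function(ds, grid, cfg = trainConfig(),
                                baseSplit = splitSpec(0.7, 0, 0.3),
                                mode = c("marginal", "product"),
                                widths = c(8L, 16L, 32L, 64L),
                                blocks = c(1L, 1L, 1L, 1L)) {
  mode <- match.arg(mode)
  known <- c("learning_rate", "stage_widths", "train_fraction",
             "pool_window", "stem_kernel")
  if (length(grid) && !all(names(grid) %in% known))
    stopf("unknown sweep axis: %s",
          paste(setdiff(names(grid), known), collapse = ", "))
  asList <- function(v) if (is.list(v)) v else as.list(v)
  baseline <- list(learning_rate = cfg@learningRate, stage_widths = widths,
                   train_fraction = baseSplit@fractions[1L],
                   pool_window = c(2L, 2L, 2L), stem_kernel = c(3L, 5L, 5L))
  cells <- if (length(grid) == 0L) {
    list(baseline)
  } else if (mode == "marginal") {
    out <- list()
    for (ax in names(grid)) for (v in asList(grid[[ax]])) {
      cell <- baseline; cell[[ax]] <- v
      cell$.axis <- ax
      out[[length(out) + 1L]] <- cell
    }
    out
  } else {
    dims <- lapply(grid, asList)
    idx <- do.call(expand.grid, lapply(dims, seq_along))
    lapply(seq_len(nrow(idx)), function(i) {
      cell <- baseline
      for (ax in names(dims)) cell[[ax]] <- dims[[ax]][[idx[i, ax]]]
      cell$.axis <- "product"
      cell
    })
  }
  K <- max(ds@labels)
  S <- dim(ds@patches)[2L]
  bands <- dim(ds@patches)[1L]
  rows <- lapply(seq_along(cells), function(i) {
    cell <- cells[[i]]
    frTrain <- cell$train_fraction
    sp <- if (!is.null(cell$.axis) && cell$.axis == "train_fraction") {
      splitSpec(frTrain, 0.1, 1 - frTrain - 0.1, seed = baseSplit@seed)
    } else {
      sp0 <- baseSplit
      sp0
    }
    parts <- stratifiedSplit(ds, sp)
    std <- standardizePatches(parts$train, parts$validation, parts$test)
    spec <- build3DRNetO(widths = as.integer(cell$stage_widths), a = 3L,
                         stemKernel = as.integer(cell$stem_kernel),
                         poolWindow = as.integer(cell$pool_window),
                         nClasses = K, bands = bands, patchSize = S,
                         blocks = blocks)
    runCfg <- cfg
    runCfg@learningRate <- cell$learning_rate
    fit <- trainModel(spec, std$train, runCfg, validation = std[[2L]])
    rep <- evaluateModel(fit, std[[3L]])
    data.frame(cell = i, axis = cell$.axis %||% "baseline",
               value = paste(format(cell[[cell$.axis %||% "learning_rate"]],
                                    trim = TRUE), collapse = "x"),
               oa = rep@oa, aa = rep@aa, kappa = rep@kappa)
  })
  do.call(rbind, rows)
}
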
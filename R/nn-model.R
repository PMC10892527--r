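# Instantiated trainable models.

#' HsiModel: an instantiated, trainable network
#'
#' Produced by [instantiateNetwork()]: the realized layer graph of a
#' [NetworkSpec-class] with seeded He-initialized weights, batch-norm
#' running statistics, and a geometry cache for the convolution index
#' tables.
#'
#' @slot spec the [NetworkSpec-class] it was built from.
#' @slot units realized layer graph (internal).
#' @slot params named list of weight arrays.
#' @slot bnStats named list of batch-norm running means/variances.
#' @slot geo environment caching shape-dependent gather indices.
#' @slot seed initialization seed.
#' @export
setClass("HsiModel",
  representation(spec = "NetworkSpec", units = "list", params = "list",
                 bnStats = "list", geo = "environment", seed = "integer"))

.collectParamUnits <- function(units, out = list()) {
  for (u in units) {
    out <- switch(u$type,
      conv = c(out, list(u)),
      bn = c(out, list(u)),
      linear = c(out, list(u)),
      res = .collectParamUnits(c(u$body, u$shortcut), out),
      par = .collectParamUnits(c(u$branches[[1L]], u$branches[[2L]]), out),
      out)
  }
  out
}

#' Instantiate a trainable model from a network specification
#'
#' Weights follow He initialization (convolutions and the linear head drawn
#' from `N(0, 2/fanIn)`); batch-norm scales start at 1, shifts at 0. The
#' draw is seeded, so equal seeds give bit-identical initial weights.
#'
#' @param spec a [NetworkSpec-class].
#' @param seed integer.
#' @return An [HsiModel-class].
#' @export
instantiateNetwork <- function(spec, seed = 1L) {
  stopifnot(is(spec, "NetworkSpec"))
  units <- .realizeUnits(spec)
  params <- list()
  bnStats <- list()
  withSeed(seed, {
    for (u in .collectParamUnits(units)) {
      if (u$type == "conv") {
        K <- prod(u$kernel) * u$cin
        params[[u$pid]] <- matrix(stats::rnorm(u$cout * K, 0, sqrt(2 / K)),
                                  u$cout, K)
      } else if (u$type == "bn") {
        params[[paste0(u$pid, ".g")]] <- rep(1, u$width)
        params[[paste0(u$pid, ".b")]] <- rep(0, u$width)
        bnStats[[u$pid]] <- list(mean = rep(0, u$width), var = rep(1, u$width))
      } else if (u$type == "linear") {
        params[[paste0(u$pid, ".W")]] <- matrix(
          stats::rnorm(u$cout * u$cin, 0, sqrt(2 / u$cin)), u$cout, u$cin)
        params[[paste0(u$pid, ".b")]] <- rep(0, u$cout)
      }
    }
  })
  new("HsiModel", spec = spec, units = units, params = params,
      bnStats = bnStats, geo = new.env(parent = emptyenv()),
      seed = as.integer(seed))
}

#' Enumerate the trainable scalars of an instantiated model
#'
#' Independent of [countParameters()]: simply totals the lengths of every
#' realized weight array.
#'
#' @param model an [HsiModel-class].
#' @return numeric total.
#' @export
enumerateParameters <- function(model) {
  stopifnot(is(model, "HsiModel"))
  sum(vapply(model@params, length, 0))
}

# Batch from a PatchDataset in the engine layout. 3D families take the
# patch as a single-channel B x S x S volume; the 2D family as a B-channel
# depth-1 S x S image. Both are reinterpretations of the same B x S x S x N
# storage.
.batchInput <- function(model, patches) {
  d <- dim(patches)
  inp <- model@spec@input
  if (d[1L] != (if (inp$channels == 1L) inp$depth else inp$channels) ||
      d[2L] != inp$height || d[3L] != inp$width)
    stopf("patch shape %s does not match the network input contract %dx%dx%d",
          paste(d[1:3], collapse = "x"),
          if (inp$channels == 1L) inp$depth else inp$channels,
          inp$height, inp$width)
  x <- patches
  dim(x) <- c(inp$channels, inp$depth * inp$height * inp$width, d[4L])
  list(x = x, dims = c(inp$depth, inp$height, inp$width))
}

# Full forward pass; train = TRUE uses batch statistics and returns caches.
.modelForward <- function(model, x, dims, train) {
  .forwardSeq(model@units, x, dims, model@params, model@bnStats, train, model@geo)
}

#' Class probabilities and predictions for a patch dataset
#'
#' Runs the model in evaluation mode (batch-norm running statistics) over
#' minibatches; every probability row is a softmax simplex point.
#'
#' @param model an [HsiModel-class].
#' @param ds a [PatchDataset-class] (or bare `B x S x S x N` array).
#' @param batchSize evaluation minibatch size.
#' @return list with `probs` (`N x K` matrix) and `class` (integer ids).
#' @export
predictModel <- function(model, ds, batchSize = 512L) {
  patches <- if (is(ds, "PatchDataset")) ds@patches else ds
  N <- dim(patches)[4L]
  K <- model@spec@nClasses
  probs <- matrix(0, N, K)
  for (at in seq.int(1L, N, by = batchSize)) {
    idx <- at:min(at + batchSize - 1L, N)
    bi <- .batchInput(model, patches[, , , idx, drop = FALSE])
    fw <- .modelForward(model, bi$x, bi$dims, train = FALSE)
    probs[idx, ] <- t(.softmaxProbs(fw$out))
  }
  list(probs = probs, class = max.col(probs, ties.method = "first"))
}
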
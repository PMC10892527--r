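# Declarative builders for the residual classification networks.
#
# Three families:
#   dgrnet    — 2D residual baseline: the B-band patch enters as a B-channel
#               S x S image (depth-1 volume internally).
#   3d_dgrnet — 3D analogue: the B x S x S patch enters as a single-channel
#               volume, so a x 1 x 1 kernels convolve the spectral axis.
#   3d_rnet_o — the dual-branch spectral/spatial residual network: each
#               block decomposes its convolutions into a spectral (a x 1 x 1)
#               and a spatial (1 x a x a) factor, runs the two orders in
#               parallel branches, concatenates and fuses with a 1 x 1 x 1
#               projection, then adds the residual shortcut.
#
# Conventions shared by every family: batch norm (affine) after every
# convolution, so convolutions carry no bias; stride-2 downsampling on all
# three axes at stage transitions with 1 x 1 x 1 projection shortcuts (the
# spectral extent floors at 1); global average pooling into a linear softmax
# head.

.stageBlocks <- function(depth) {
  switch(as.character(depth),
    "18" = list(n = c(2L, 2L, 2L, 2L), kind = "basic"),
    "34" = list(n = c(3L, 4L, 6L, 3L), kind = "basic"),
    "50" = list(n = c(3L, 4L, 6L, 3L), kind = "bottleneck"),
    stopf("unsupported depth %s (use 18, 34 or 50)", depth))
}

#' Configure one dual-branch spectral/spatial residual block
#'
#' Branch 1 applies a spectral convolution (`a x 1 x 1`) then a spatial one
#' (`1 x a x a`); branch 2 applies the same factors in the opposite order.
#' Branch outputs (each `outWidth` channels) are concatenated and fused by a
#' `1 x 1 x 1` convolution back to `outWidth` before the residual addition.
#' With a single branch enabled no concatenation or fusion is needed; with
#' both branches disabled the block degenerates to a plain `a x a x a`
#' basic residual block.
#'
#' @param inWidth,outWidth input/output channel widths.
#' @param a odd spectral/spatial kernel size.
#' @param stride 1, or 2 at stage transitions.
#' @param branches logical length-2: enable first / second branch.
#' @return a block-config list (kind, widths, kernel, stride, flags).
#' @export
dualBranchBlock <- function(inWidth, outWidth, a = 3L, stride = 1L,
                            branches = c(TRUE, TRUE)) {
  if (a %% 2L == 0L) stopf("kernel size a must be odd, got %d", a)
  if (!stride %in% c(1L, 2L)) stopf("stride must be 1 or 2")
  kind <- if (!any(branches)) "basic" else "dual"
  list(kind = kind, inWidth = as.integer(inWidth), outWidth = as.integer(outWidth),
       a = as.integer(a), stride = as.integer(stride),
       branch1 = branches[1L], branch2 = branches[2L], is3d = TRUE)
}

.basicBlock <- function(inWidth, outWidth, a, stride, is3d) {
  list(kind = "basic", inWidth = as.integer(inWidth),
       outWidth = as.integer(outWidth), a = as.integer(a),
       stride = as.integer(stride), is3d = is3d)
}

.bottleneckBlock <- function(inWidth, midWidth, a, stride, is3d) {
  list(kind = "bottleneck", inWidth = as.integer(inWidth),
       outWidth = 4L * as.integer(midWidth), midWidth = as.integer(midWidth),
       a = as.integer(a), stride = as.integer(stride), is3d = is3d)
}

.makeStages <- function(nBlocks, kind, widths, a, is3d, blockFun = NULL) {
  prev <- 64L                              # stem width
  stages <- vector("list", 4L)
  for (s in 1:4) {
    stage <- vector("list", nBlocks[s])
    for (b in seq_len(nBlocks[s])) {
      stride <- if (s > 1L && b == 1L) 2L else 1L
      stage[[b]] <- if (!is.null(blockFun)) {
        blockFun(prev, widths[s], a, stride)
      } else if (kind == "bottleneck") {
        .bottleneckBlock(prev, widths[s], a, stride, is3d)
      } else {
        .basicBlock(prev, widths[s], a, stride, is3d)
      }
      prev <- stage[[b]]$outWidth
    }
    stages[[s]] <- stage
  }
  stages
}

#' Build the 2D residual baseline (DGRNet)
#'
#' Standard residual topology: 7x7/2 stem into 64 channels, 3x3/2 max pool,
#' four stages of basic blocks (depths 18/34) or bottlenecks (depth 50) at
#' widths 64/128/256/512, global average pooling and a linear softmax head.
#' The B-band patch enters as a B-channel `S x S` image. At depth 34 with 30
#' input channels and 3 classes the network counts 21,370,883 trainable
#' parameters.
#'
#' @param depth 18, 34 or 50.
#' @param inChannels input bands `B` (default 30, the PCA retention at the
#'   0.98 variance threshold on a 256-band scene).
#' @param nClasses output classes.
#' @param patchSize odd spatial patch side `S` (default 9).
#' @return A [NetworkSpec-class].
#' @export
buildDGRNet <- function(depth = 34L, inChannels = 30L, nClasses = 3L,
                        patchSize = 9L) {
  cfg <- .stageBlocks(depth)
  new("NetworkSpec", family = "dgrnet",
      input = list(channels = as.integer(inChannels), depth = 1L,
                   height = as.integer(patchSize), width = as.integer(patchSize)),
      stem = list(kernel = c(1L, 7L, 7L), stride = 2L, width = 64L),
      pool = list(window = c(1L, 3L, 3L), stride = 2L),
      stages = .makeStages(cfg$n, cfg$kind, c(64L, 128L, 256L, 512L), 3L, FALSE),
      nClasses = as.integer(nClasses))
}

#' Build the plain 3D residual network (3D_DGRNet)
#'
#' 3D analogue of [buildDGRNet()]: the `B x S x S` patch enters as a
#' single-channel volume with the spectral axis as depth; 7x7x7 stem, 3x3x3
#' max pool, 3x3x3 block kernels, 1x1x1 projection shortcuts.
#'
#' @inheritParams buildDGRNet
#' @param bands spectral depth `B` of the input volume.
#' @return A [NetworkSpec-class].
#' @export
build3DDGRNet <- function(depth = 34L, nClasses = 3L, bands = 30L,
                          patchSize = 9L) {
  cfg <- .stageBlocks(depth)
  new("NetworkSpec", family = "3d_dgrnet",
      input = list(channels = 1L, depth = as.integer(bands),
                   height = as.integer(patchSize), width = as.integer(patchSize)),
      stem = list(kernel = c(7L, 7L, 7L), stride = 2L, width = 64L),
      pool = list(window = c(3L, 3L, 3L), stride = 2L),
      stages = .makeStages(cfg$n, cfg$kind, c(64L, 128L, 256L, 512L), 3L, TRUE),
      nClasses = as.integer(nClasses))
}

#' Build the dual-branch spectral/spatial residual network (3D_RNet-O)
#'
#' A 34-layer-style backbone (stage block counts 3,4,6,3 by default) whose
#' residual blocks are [dualBranchBlock()]s. The stem kernel, pooling window
#' and stage widths are the tunable hyperparameters; the optimal field
#' configuration is widths (128, 256, 512, 1024), stem (3,5,5) and pool
#' (2,2,2).
#'
#' @param widths length-4 non-decreasing stage widths.
#' @param a odd block kernel size.
#' @param stemKernel length-3 stem kernel, one of (7,7,7), (5,5,5), (3,3,3),
#'   (3,5,5), (5,7,7).
#' @param poolWindow length-3 pooling window, one of (3,3,3), (2,2,2),
#'   (1,1,1).
#' @param nClasses,bands,patchSize input contract as in [build3DDGRNet()].
#' @param blocks per-stage block counts (default the 34-layer 3,4,6,3;
#'   scaled-down experiments may use fewer).
#' @param branches logical length-2 enabling the two branches (the ablation
#'   axis; both FALSE reduces every block to plain 3D convolution).
#' @return A [NetworkSpec-class].
#' @export
build3DRNetO <- function(widths = c(128L, 256L, 512L, 1024L), a = 3L,
                         stemKernel = c(3L, 5L, 5L), poolWindow = c(2L, 2L, 2L),
                         nClasses = 3L, bands = 30L, patchSize = 9L,
                         blocks = c(3L, 4L, 6L, 3L),
                         branches = c(TRUE, TRUE)) {
  if (length(widths) != 4L) stopf("widths must have length 4")
  if (a %% 2L == 0L) stopf("kernel size a must be odd")
  if (any(stemKernel %% 2L == 0L)) stopf("stem kernel extents must be odd")
  blockFun <- function(inW, outW, a, stride)
    dualBranchBlock(inW, outW, a, stride, branches)
  new("NetworkSpec", family = "3d_rnet_o",
      input = list(channels = 1L, depth = as.integer(bands),
                   height = as.integer(patchSize), width = as.integer(patchSize)),
      stem = list(kernel = as.integer(stemKernel), stride = 2L, width = 64L),
      pool = list(window = as.integer(poolWindow), stride = 2L),
      stages = .makeStages(as.integer(blocks), "dual", as.integer(widths),
                           as.integer(a), TRUE, blockFun),
      nClasses = as.integer(nClasses))
}

## ---- parameter accounting --------------------------------------------------

.blockParamRows <- function(blk, stage, bi) {
  nm <- sprintf("stage%d.block%d", stage, bi)
  kv <- function(kd, kh, kw) c(kd, kh, kw)
  sp <- if (blk$is3d) blk$a else 1L        # spectral kernel extent
  rows <- list()
  addConv <- function(name, k, cin, cout)
    rows[[length(rows) + 1L]] <<- data.frame(
      name = paste0(nm, ".", name), op = "conv",
      kernel = paste(k, collapse = "x"), inWidth = cin, outWidth = cout,
      params = prod(k) * cin * cout)
  addBN <- function(name, w)
    rows[[length(rows) + 1L]] <<- data.frame(
      name = paste0(nm, ".", name), op = "bn", kernel = "",
      inWidth = w, outWidth = w, params = 2L * w)
  if (blk$kind == "basic") {
    k <- kv(sp, blk$a, blk$a)
    addConv("conv1", k, blk$inWidth, blk$outWidth); addBN("bn1", blk$outWidth)
    addConv("conv2", k, blk$outWidth, blk$outWidth); addBN("bn2", blk$outWidth)
  } else if (blk$kind == "bottleneck") {
    addConv("conv1", c(1L, 1L, 1L), blk$inWidth, blk$midWidth); addBN("bn1", blk$midWidth)
    addConv("conv2", kv(sp, blk$a, blk$a), blk$midWidth, blk$midWidth); addBN("bn2", blk$midWidth)
    addConv("conv3", c(1L, 1L, 1L), blk$midWidth, blk$outWidth); addBN("bn3", blk$outWidth)
  } else {                                  # dual
    both <- blk$branch1 && blk$branch2
    if (blk$branch1) {
      addConv("b1.spec", c(blk$a, 1L, 1L), blk$inWidth, blk$outWidth); addBN("b1.bn1", blk$outWidth)
      addConv("b1.spat", c(1L, blk$a, blk$a), blk$outWidth, blk$outWidth); addBN("b1.bn2", blk$outWidth)
    }
    if (blk$branch2) {
      addConv("b2.spat", c(1L, blk$a, blk$a), blk$inWidth, blk$outWidth); addBN("b2.bn1", blk$outWidth)
      addConv("b2.spec", c(blk$a, 1L, 1L), blk$outWidth, blk$outWidth); addBN("b2.bn2", blk$outWidth)
    }
    if (both) {
      addConv("fuse", c(1L, 1L, 1L), 2L * blk$outWidth, blk$outWidth)
      addBN("fuse.bn", blk$outWidth)
    }
  }
  if (blk$stride != 1L || blk$inWidth != blk$outWidth) {
    addConv("proj", c(1L, 1L, 1L), blk$inWidth, blk$outWidth)
    addBN("proj.bn", blk$outWidth)
  }
  do.call(rbind, rows)
}

#' Layer table of a network specification
#'
#' One row per parameterized layer (name, op, kernel, in/out widths, exact
#' parameter count); suitable for CSV export.
#'
#' @param spec a [NetworkSpec-class].
#' @return data.frame.
#' @export
layerTable <- function(spec) {
  stopifnot(is(spec, "NetworkSpec"))
  rows <- list(
    data.frame(name = "stem.conv", op = "conv",
               kernel = paste(spec@stem$kernel, collapse = "x"),
               inWidth = spec@input$channels, outWidth = spec@stem$width,
               params = prod(spec@stem$kernel) * spec@input$channels * spec@stem$width),
    data.frame(name = "stem.bn", op = "bn", kernel = "",
               inWidth = spec@stem$width, outWidth = spec@stem$width,
               params = 2L * spec@stem$width))
  for (s in seq_along(spec@stages))
    for (b in seq_along(spec@stages[[s]]))
      rows[[length(rows) + 1L]] <- .blockParamRows(spec@stages[[s]][[b]], s, b)
  last <- spec@stages[[length(spec@stages)]]
  headIn <- last[[length(last)]]$outWidth
  rows[[length(rows) + 1L]] <- data.frame(
    name = "head.linear", op = "linear", kernel = "",
    inWidth = headIn, outWidth = spec@nClasses,
    params = headIn * spec@nClasses + spec@nClasses)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname countParameters
#' @export
setMethod("countParameters", "NetworkSpec", function(spec) {
  as.double(sum(layerTable(spec)$params))
})

## ---- realization (spec -> engine units) ------------------------------------

.realizeBlock <- function(blk, idgen) {
  sp <- if (blk$is3d) blk$a else 1L
  conv <- function(k, cin, cout, stride = 1L)
    list(type = "conv", kernel = as.integer(k), stride = as.integer(stride),
         cin = as.integer(cin), cout = as.integer(cout), pid = idgen("conv"))
  bn <- function(w) list(type = "bn", width = as.integer(w), pid = idgen("bn"))
  relu <- list(type = "relu")
  shortcut <- if (blk$stride != 1L || blk$inWidth != blk$outWidth)
    list(conv(c(1L, 1L, 1L), blk$inWidth, blk$outWidth, blk$stride),
         bn(blk$outWidth))
  body <- if (blk$kind == "basic") {
    k <- c(sp, blk$a, blk$a)
    list(conv(k, blk$inWidth, blk$outWidth, blk$stride), bn(blk$outWidth), relu,
         conv(k, blk$outWidth, blk$outWidth), bn(blk$outWidth))
  } else if (blk$kind == "bottleneck") {
    list(conv(c(1L, 1L, 1L), blk$inWidth, blk$midWidth), bn(blk$midWidth), relu,
         conv(c(sp, blk$a, blk$a), blk$midWidth, blk$midWidth, blk$stride),
         bn(blk$midWidth), relu,
         conv(c(1L, 1L, 1L), blk$midWidth, blk$outWidth), bn(blk$outWidth))
  } else {
    b1 <- list(conv(c(blk$a, 1L, 1L), blk$inWidth, blk$outWidth, blk$stride),
               bn(blk$outWidth), relu,
               conv(c(1L, blk$a, blk$a), blk$outWidth, blk$outWidth),
               bn(blk$outWidth))
    b2 <- list(conv(c(1L, blk$a, blk$a), blk$inWidth, blk$outWidth, blk$stride),
               bn(blk$outWidth), relu,
               conv(c(blk$a, 1L, 1L), blk$outWidth, blk$outWidth),
               bn(blk$outWidth))
    if (blk$branch1 && blk$branch2) {
      list(list(type = "par", branches = list(b1, b2)),
           conv(c(1L, 1L, 1L), 2L * blk$outWidth, blk$outWidth),
           bn(blk$outWidth))
    } else if (blk$branch1) b1 else b2
  }
  list(type = "res", body = body, shortcut = shortcut)
}

.realizeUnits <- function(spec) {
  counter <- 0L
  idgen <- function(kind) {
    counter <<- counter + 1L
    sprintf("%s%03d", kind, counter)
  }
  units <- list(
    list(type = "conv", kernel = spec@stem$kernel, stride = spec@stem$stride,
         cin = spec@input$channels, cout = spec@stem$width, pid = idgen("conv")),
    list(type = "bn", width = spec@stem$width, pid = idgen("bn")),
    list(type = "relu"),
    list(type = "maxpool", window = spec@pool$window, stride = spec@pool$stride))
  for (st in spec@stages)
    for (blk in st)
      units[[length(units) + 1L]] <- .realizeBlock(blk, idgen)
  last <- spec@stages[[length(spec@stages)]]
  headIn <- last[[length(last)]]$outWidth
  units[[length(units) + 1L]] <- list(type = "gap")
  units[[length(units) + 1L]] <- list(type = "linear", cin = headIn,
                                      cout = spec@nClasses, pid = idgen("fc"))
  units
}
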
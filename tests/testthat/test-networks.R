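# Network builders, parameter accounting, instantiation.

test_that("the 2D baseline at depth 34 counts exactly 21,370,883 parameters", {
  spec <- buildDGRNet(34L, inChannels = 30L, nClasses = 3L)
  expect_identical(countParameters(spec), 21370883)
  # closed-form decomposition: 3-channel 3-class backbone + widened stem
  expect_identical(21286211 + 64 * 7 * 7 * (30 - 3), 21370883)
  expect_identical(countParameters(buildDGRNet(34L, 3L, 3L)), 21286211)
  expect_identical(countParameters(buildDGRNet(34L, 10L, 3L)),
                   21286211 + 64 * 7 * 7 * (10 - 3))
})

test_that("depth-18 topology: four stages of two basic blocks, 512-wide head", {
  spec <- buildDGRNet(18L, 30L, 3L)
  expect_identical(lengths(spec@stages), rep(2L, 4L))
  last <- spec@stages[[4]][[2]]
  expect_identical(last$outWidth, 512L)
  expect_identical(last$kind, "basic")
  expect_lt(countParameters(spec), countParameters(buildDGRNet(34L, 30L, 3L)))
  expect_error(buildDGRNet(27L), "unsupported depth")
})

test_that("the 3D residual network reconstructs the published parameter total", {
  spec <- build3DDGRNet(34L, 3L, 30L, 9L)
  expect_identical(countParameters(spec), 63471171)
  # all block kernels are 3x3x3
  tab <- layerTable(spec)
  blockConvs <- tab[tab$op == "conv" & grepl("conv[12]$", tab$name), ]
  expect_true(all(blockConvs$kernel == "3x3x3"))
  expect_identical(spec@input$channels, 1L)
  expect_identical(spec@input$depth, 30L)
  expect_identical(spec@input$height, 9L)
})

test_that("dual-branch block parameter count matches the closed form", {
  blk <- dualBranchBlock(64L, 64L, 3L)
  got <- sum(grassRNet:::.blockParamRows(blk, 1L, 1L)$params)
  # brute-force enumeration: two branches of (spectral + spatial) convs with
  # their BN pairs, plus the 1x1x1 fusion and its BN
  oracle <- 2 * (3 * 64 * 64 + 2 * 64 + 9 * 64 * 64 + 2 * 64) +
    128 * 64 + 2 * 64
  expect_identical(got, oracle)
  expect_identical(oracle, 107136)
})

test_that("dual-branch spec carries both kernel orders; flags degrade gracefully", {
  spec <- build3DRNetO(nClasses = 3L)
  tab <- layerTable(spec)
  b1 <- tab[grepl("b1", tab$name) & tab$op == "conv", "kernel"]
  b2 <- tab[grepl("b2", tab$name) & tab$op == "conv", "kernel"]
  expect_true(all(c("3x1x1", "1x3x3") %in% b1))
  expect_true(all(c("1x3x3", "3x1x1") %in% b2))
  # spectral kernel leads in branch 1, spatial leads in branch 2
  expect_identical(b1[1], "3x1x1")
  expect_identical(b2[1], "1x3x3")

  single <- build3DRNetO(nClasses = 3L, branches = c(TRUE, FALSE))
  tabS <- layerTable(single)
  expect_false(any(grepl("fuse", tabS$name)))
  expect_false(any(grepl("b2", tabS$name)))

  expect_error(build3DRNetO(a = 4L), "odd")
  expect_error(build3DRNetO(widths = c(64L, 128L)), "length 4")
  expect_error(dualBranchBlock(8L, 8L, a = 2L), "odd")
})

test_that("both branches off degenerates weight-for-weight to the plain 3D net", {
  off <- build3DRNetO(widths = c(64L, 128L, 256L, 512L), nClasses = 3L,
                      stemKernel = c(7L, 7L, 7L), poolWindow = c(3L, 3L, 3L),
                      branches = c(FALSE, FALSE))
  plain <- build3DDGRNet(34L, 3L, 30L, 9L)
  tOff <- layerTable(off); tPlain <- layerTable(plain)
  expect_identical(tOff$params, tPlain$params)
  expect_identical(tOff$kernel, tPlain$kernel)
  expect_identical(countParameters(off), countParameters(plain))
})

test_that("parameter counts grow strictly with stage widths and kernel size", {
  narrow <- build3DRNetO(widths = c(64L, 128L, 256L, 512L))
  wide <- build3DRNetO(widths = c(128L, 256L, 512L, 1024L))
  expect_lt(countParameters(narrow), countParameters(wide))
  a3 <- build3DRNetO(widths = c(8L, 16L, 32L, 64L))
  a5 <- build3DRNetO(widths = c(8L, 16L, 32L, 64L), a = 5L)
  expect_lt(countParameters(a3), countParameters(a5))
})

test_that("spec count equals the instantiated model's enumerated scalars across the grid", {
  grid <- list(
    buildDGRNet(18L, 5L, 3L, 9L),
    buildDGRNet(50L, 5L, 4L, 9L),
    build3DDGRNet(18L, 3L, 8L, 9L),
    build3DRNetO(widths = c(4L, 8L, 16L, 32L), nClasses = 3L, bands = 6L,
                 patchSize = 5L, blocks = c(1L, 2L, 1L, 1L)),
    build3DRNetO(widths = c(4L, 8L, 8L, 16L), a = 5L, nClasses = 2L,
                 bands = 6L, patchSize = 5L, branches = c(TRUE, FALSE)),
    build3DRNetO(widths = c(4L, 8L, 8L, 16L), nClasses = 3L, bands = 6L,
                 patchSize = 5L, branches = c(FALSE, FALSE)))
  for (spec in grid)
    expect_identical(countParameters(spec),
                     enumerateParameters(instantiateNetwork(spec, 1L)))
  # and the full-size 2D baseline
  expect_identical(enumerateParameters(instantiateNetwork(buildDGRNet(34L, 30L, 3L), 1L)),
                   21370883)
})

test_that("forward pass yields softmax simplex outputs of the right shape", {
  spec <- smallRNetSpec(6L, 5L, widths = c(4L, 8L, 8L, 16L))
  model <- instantiateNetwork(spec, 3L)
  x <- array(rnorm(6 * 5 * 5 * 4), c(6L, 5L, 5L, 4L))
  out <- predictModel(model, x)
  expect_identical(dim(out$probs), c(4L, 3L))
  expect_equal(rowSums(out$probs), rep(1, 4), tolerance = 1e-6)
  expect_true(all(out$probs >= 0))
  expect_true(all(out$class %in% 1:3))

  one <- predictModel(model, array(rnorm(6 * 25), c(6L, 5L, 5L, 1L)))
  expect_equal(sum(one$probs), 1, tolerance = 1e-6)

  expect_error(predictModel(model, array(0, c(6L, 7L, 7L, 1L))), "contract")
})

test_that("equal seeds give identical weights; different seeds differ", {
  spec <- smallRNetSpec(4L, 5L, widths = c(4L, 4L, 8L, 8L))
  m1 <- instantiateNetwork(spec, 11L)
  m2 <- instantiateNetwork(spec, 11L)
  m3 <- instantiateNetwork(spec, 12L)
  expect_identical(m1@params, m2@params)
  expect_false(identical(m1@params, m3@params))
})

test_that("declared stage widths match realized tensor widths (shape trace)", {
  spec <- smallRNetSpec(6L, 9L, widths = c(4L, 8L, 16L, 16L))
  model <- instantiateNetwork(spec, 1L)
  x <- array(rnorm(6 * 81 * 2), c(1L, 6L * 81L, 2L))
  # trace channel widths after every top-level unit
  widths <- integer(0)
  cur <- x; dims <- c(6L, 9L, 9L)
  for (u in model@units) {
    r <- grassRNet:::.forwardSeq(list(u), cur, dims, model@params,
                                 model@bnStats, FALSE, model@geo)
    cur <- r$out; dims <- r$dims
    if (u$type == "res") widths <- c(widths, dim(cur)[1L])
  }
  expect_identical(widths, c(4L, 8L, 16L, 16L))
  expect_identical(dim(cur)[1L], spec@nClasses)  # head output
})

test_that("residual blocks with stride 1 and equal widths preserve shape", {
  blk <- dualBranchBlock(8L, 8L, 3L, 1L)
  expect_null(grassRNet:::.realizeBlock(blk, function(k) paste0(k, "_x"))$shortcut)
  blk2 <- dualBranchBlock(8L, 16L, 3L, 1L)
  expect_false(is.null(grassRNet:::.realizeBlock(blk2, function(k) paste0(k, "_y"))$shortcut))
})
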
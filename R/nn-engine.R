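# Compact CPU engine for 3D/2D convolutional residual networks.
#
# Tensors travel as (C, P, N) arrays: channels, flattened volume positions
# (depth fastest, then height, then width), batch. Convolutions are im2col
# gathers followed by one BLAS matrix multiply; the gather index tables
# depend only on the input shape and are cached per layer. The 2D nets are
# the depth-1 special case of the same machinery.
#
# All layers implement forward (with cache) and backward (gradients w.r.t.
# input and parameters), enough for softmax cross-entropy training with
# Adam or SGD. Everything is deterministic given the R RNG seed.

.convOutDim <- function(n, k, s, p) {
  out <- (n + 2L * p - k) %/% s + 1L
  if (out < 1L) stopf("layer output dimension collapsed to %d (input %d, kernel %d)", out, n, k)
  out
}

# Geometry (pad map + gather index) for a conv-like op on input (C, D, H, W).
.convGeom <- function(kernel, stride, cin, dims, geo, key, clampWindow = FALSE) {
  id <- paste(key, paste(dims, collapse = "x"), sep = "|")
  if (!is.null(geo[[id]])) return(geo[[id]])
  pad <- (kernel - 1L) %/% 2L
  k <- kernel
  # pooling windows shrink on volumes smaller than the window (the spectral
  # axis of deep stages floors at extent 1); convolutions never need this
  # because odd kernels with (k-1)/2 padding always fit
  if (clampWindow) k <- pmin(kernel, dims + 2L * pad)
  D <- dims[1L]; H <- dims[2L]; W <- dims[3L]
  Dp <- D + 2L * pad[1L]; Hp <- H + 2L * pad[2L]; Wp <- W + 2L * pad[3L]
  Do <- .convOutDim(D, k[1L], stride, pad[1L])
  Ho <- .convOutDim(H, k[2L], stride, pad[2L])
  Wo <- .convOutDim(W, k[3L], stride, pad[3L])
  dIdx <- outer(seq_len(k[1L]), (seq_len(Do) - 1L) * stride, "+")       # kd x Do
  hIdx <- outer(seq_len(k[2L]), (seq_len(Ho) - 1L) * stride, "+")
  wIdx <- outer(seq_len(k[3L]), (seq_len(Wo) - 1L) * stride, "+")
  lin6 <- outer(outer(dIdx, (hIdx - 1L) * Dp, "+"), (wIdx - 1L) * (Dp * Hp), "+")
  # (kd, Do, kh, Ho, kw, Wo) -> (kd, kh, kw, Do, Ho, Wo)
  idxPos <- matrix(aperm(lin6, c(1L, 3L, 5L, 2L, 4L, 6L)),
                   k[1L] * k[2L] * k[3L], Do * Ho * Wo)
  # positions of the original volume inside the padded one
  dm <- pad[1L] + seq_len(D); hm <- pad[2L] + seq_len(H); wm <- pad[3L] + seq_len(W)
  posMap <- as.vector(outer(outer(dm, (hm - 1L) * Dp, "+"), (wm - 1L) * (Dp * Hp), "+"))
  g <- list(k = k, pad = pad, outDims = c(Do, Ho, Wo), Pp = Dp * Hp * Wp,
            idxPos = idxPos, posMap = posMap,
            idxFull = if (cin > 0L) {
              Kk <- nrow(idxPos)
              matrix(cin * (idxPos[rep(seq_len(Kk), each = cin), ] - 1L) +
                       seq_len(cin), Kk * cin, ncol(idxPos))
            })
  geo[[id]] <- g
  g
}

.padChannels <- function(x, dims, Pp, posMap, fill = 0) {
  d <- dim(x)
  xp <- array(fill, c(d[1L], Pp, d[3L]))
  xp[, posMap, ] <- x
  xp
}

## ---- convolution -----------------------------------------------------------

.convForward <- function(u, x, dims, params, geo) {
  W <- params[[u$pid]]
  g <- .convGeom(u$kernel, u$stride, u$cin, dims, geo, u$pid)
  N <- dim(x)[3L]
  xp <- .padChannels(x, dims, g$Pp, g$posMap)
  dim(xp) <- c(u$cin * g$Pp, N)
  M <- xp[as.vector(g$idxFull), , drop = FALSE]
  K <- nrow(g$idxFull); Po <- ncol(g$idxFull)
  dim(M) <- c(K, Po * N)
  y <- W %*% M
  dim(y) <- c(u$cout, Po, N)
  list(out = y, dims = g$outDims, cache = list(M = M, g = g, N = N))
}

.convBackward <- function(u, dy, cache, params) {
  g <- cache$g; N <- cache$N
  Po <- ncol(g$idxFull); K <- nrow(g$idxFull)
  dim(dy) <- c(u$cout, Po * N)
  dW <- dy %*% t(cache$M)
  dM <- crossprod(params[[u$pid]], dy)
  dim(dM) <- c(K * Po, N)
  idxVec <- as.vector(g$idxFull)
  acc <- rowsum(dM, group = idxVec, reorder = TRUE)
  dxp <- matrix(0, u$cin * g$Pp, N)
  dxp[as.integer(rownames(acc)), ] <- acc
  dim(dxp) <- c(u$cin, g$Pp, N)
  dx <- dxp[, g$posMap, , drop = FALSE]
  list(dx = dx, grads = stats::setNames(list(dW), u$pid))
}

## ---- batch normalization ---------------------------------------------------

.bnForward <- function(u, x, params, bnStats, train, eps = 1e-5, momentum = 0.1) {
  d <- dim(x)
  xm <- matrix(x, d[1L])
  g <- params[[paste0(u$pid, ".g")]]
  b <- params[[paste0(u$pid, ".b")]]
  if (train) {
    mu <- rowMeans(xm)
    xc <- xm - mu
    v <- rowMeans(xc * xc)
    invStd <- 1 / sqrt(v + eps)
    xhat <- xc * invStd
    st <- bnStats[[u$pid]]
    bnStats[[u$pid]] <- list(mean = (1 - momentum) * st$mean + momentum * mu,
                             var = (1 - momentum) * st$var + momentum * v)
    y <- g * xhat + b
    dim(y) <- d
    list(out = y, cache = list(xhat = xhat, invStd = invStd, d = d),
         bnStats = bnStats)
  } else {
    st <- bnStats[[u$pid]]
    y <- g * ((xm - st$mean) / sqrt(st$var + eps)) + b
    dim(y) <- d
    list(out = y, cache = NULL, bnStats = bnStats)
  }
}

.bnBackward <- function(u, dy, cache, params) {
  d <- cache$d
  m <- prod(d[-1L])
  dym <- matrix(dy, d[1L])
  xhat <- cache$xhat
  g <- params[[paste0(u$pid, ".g")]]
  dg <- rowSums(dym * xhat)
  db <- rowSums(dym)
  dxhat <- dym * g
  dx <- (cache$invStd / m) * (m * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  dim(dx) <- d
  grads <- list(dg, db)
  names(grads) <- paste0(u$pid, c(".g", ".b"))
  list(dx = dx, grads = grads)
}

## ---- max pooling -----------------------------------------------------------

.poolForward <- function(u, x, dims, geo) {
  g <- .convGeom(u$window, u$stride, 0L, dims, geo,
                 paste0("pool", paste(u$window, collapse = "")), clampWindow = TRUE)
  d <- dim(x)
  C <- d[1L]; N <- d[3L]
  xp <- .padChannels(x, dims, g$Pp, g$posMap, fill = -Inf)
  xP <- aperm(xp, c(2L, 1L, 3L))               # (Pp, C, N)
  dim(xP) <- c(g$Pp, C * N)
  Kk <- nrow(g$idxPos); Po <- ncol(g$idxPos)
  M <- xP[as.vector(g$idxPos), , drop = FALSE]
  dim(M) <- c(Kk, Po * C * N)
  amax <- max.col(t(M), ties.method = "first")
  y <- M[(seq_along(amax) - 1L) * Kk + amax]
  dim(y) <- c(Po, C, N)
  y <- aperm(y, c(2L, 1L, 3L))
  list(out = y, dims = g$outDims,
       cache = list(g = g, amax = amax, C = C, N = N, inDims = dims))
}

.poolBackward <- function(u, dy, cache) {
  g <- cache$g; C <- cache$C; N <- cache$N
  Kk <- nrow(g$idxPos); Po <- ncol(g$idxPos)
  dyP <- aperm(dy, c(2L, 1L, 3L))              # (Po, C, N)
  # source row in padded position space for every pooled output
  pout <- rep_len(seq_len(Po), Po * C * N)
  src <- g$idxPos[(pout - 1L) * Kk + cache$amax]
  colId <- rep(seq_len(C * N), each = Po)
  lin <- src + (colId - 1L) * g$Pp
  acc <- rowsum(as.vector(dyP), group = lin, reorder = TRUE)
  dxP <- numeric(g$Pp * C * N)
  dxP[as.integer(rownames(acc))] <- acc
  dim(dxP) <- c(g$Pp, C, N)
  dx <- aperm(dxP, c(2L, 1L, 3L))[, g$posMap, , drop = FALSE]
  dx
}

## ---- global average pool / linear / relu -----------------------------------

.gapForward <- function(x) {
  d <- dim(x)
  y <- colSums(aperm(x, c(2L, 1L, 3L)))        # (C, N), summed over P
  list(out = y / d[2L], cache = d)
}

.gapBackward <- function(dy, d) {
  nIdx <- rep(seq_len(d[3L]), each = d[2L])
  dx <- array(dy[, nIdx] / d[2L], d)
  dx
}

.linearForward <- function(u, x, params) {
  W <- params[[paste0(u$pid, ".W")]]
  b <- params[[paste0(u$pid, ".b")]]
  list(out = W %*% x + b, cache = x)
}

.linearBackward <- function(u, dy, x, params) {
  grads <- list(dy %*% t(x), rowSums(dy))
  names(grads) <- paste0(u$pid, c(".W", ".b"))
  list(dx = crossprod(params[[paste0(u$pid, ".W")]], dy), grads = grads)
}

## ---- structural forward / backward ----------------------------------------

# Forward over a unit list. Returns out, dims, caches (parallel tree) and
# updated bn stats.
.forwardSeq <- function(units, x, dims, params, bnStats, train, geo) {
  caches <- vector("list", length(units))
  for (i in seq_along(units)) {
    u <- units[[i]]
    r <- switch(u$type,
      conv = .convForward(u, x, dims, params, geo),
      bn = .bnForward(u, x, params, bnStats, train),
      relu = list(out = pmax(x, 0), cache = x > 0),
      maxpool = .poolForward(u, x, dims, geo),
      gap = .gapForward(x),
      linear = .linearForward(u, x, params),
      res = {
        body <- .forwardSeq(u$body, x, dims, params, bnStats, train, geo)
        bnStats <- body$bnStats
        if (is.null(u$shortcut)) {
          sc <- list(out = x, dims = dims, caches = NULL)
        } else {
          sc <- .forwardSeq(u$shortcut, x, dims, params, bnStats, train, geo)
          bnStats <- sc$bnStats
        }
        s <- body$out + sc$out
        list(out = pmax(s, 0), dims = body$dims,
             cache = list(body = body$caches, shortcut = sc$caches,
                          mask = s > 0))
      },
      par = {
        outs <- vector("list", length(u$branches))
        dimsOut <- NULL
        bcaches <- vector("list", length(u$branches))
        for (bi in seq_along(u$branches)) {
          br <- .forwardSeq(u$branches[[bi]], x, dims, params, bnStats, train, geo)
          bnStats <- br$bnStats
          outs[[bi]] <- br$out
          dimsOut <- br$dims
          bcaches[[bi]] <- br$caches
        }
        cs <- vapply(outs, function(o) dim(o)[1L], 0L)
        N <- dim(outs[[1L]])[3L]; P <- dim(outs[[1L]])[2L]
        y <- array(0, c(sum(cs), P, N))
        at <- 0L
        for (bi in seq_along(outs)) {
          y[at + seq_len(cs[bi]), , ] <- outs[[bi]]
          at <- at + cs[bi]
        }
        list(out = y, dims = dimsOut,
             cache = list(branches = bcaches, widths = cs))
      },
      stopf("unknown unit type '%s'", u$type))
    if (!is.null(r$bnStats)) bnStats <- r$bnStats
    if (!is.null(r$dims)) dims <- r$dims
    x <- r$out
    caches[[i]] <- list(cache = r$cache, dimsIn = NULL)
  }
  list(out = x, dims = dims, caches = caches, bnStats = bnStats)
}

# Backward over a unit list; accumulates parameter grads into `acc` (an
# environment used as a mutable accumulator).
.backwardSeq <- function(units, dy, caches, params, acc) {
  for (i in rev(seq_along(units))) {
    u <- units[[i]]
    ch <- caches[[i]]$cache
    dy <- switch(u$type,
      conv = {
        r <- .convBackward(u, dy, ch, params)
        .accumulate(acc, r$grads)
        r$dx
      },
      bn = {
        r <- .bnBackward(u, dy, ch, params)
        .accumulate(acc, r$grads)
        r$dx
      },
      relu = dy * ch,
      maxpool = .poolBackward(u, dy, ch),
      gap = .gapBackward(dy, ch),
      linear = {
        r <- .linearBackward(u, dy, ch, params)
        .accumulate(acc, r$grads)
        r$dx
      },
      res = {
        ds <- dy * ch$mask
        dxBody <- .backwardSeq(u$body, ds, ch$body, params, acc)
        if (is.null(u$shortcut)) dxBody + ds
        else dxBody + .backwardSeq(u$shortcut, ds, ch$shortcut, params, acc)
      },
      par = {
        at <- 0L
        dx <- NULL
        for (bi in seq_along(u$branches)) {
          dyb <- dy[at + seq_len(ch$widths[bi]), , , drop = FALSE]
          at <- at + ch$widths[bi]
          dxb <- .backwardSeq(u$branches[[bi]], dyb, ch$branches[[bi]], params, acc)
          dx <- if (is.null(dx)) dxb else dx + dxb
        }
        dx
      })
  }
  dy
}

.accumulate <- function(acc, grads) {
  for (nm in names(grads)) {
    cur <- acc$g[[nm]]
    acc$g[[nm]] <- if (is.null(cur)) grads[[nm]] else cur + grads[[nm]]
  }
  invisible(NULL)
}

## ---- loss and optimizers ---------------------------------------------------

.softmaxProbs <- function(logits) {
  m <- apply(logits, 2L, max)
  e <- exp(sweep(logits, 2L, m))
  sweep(e, 2L, colSums(e), "/")
}

.softmaxCE <- function(logits, y) {
  N <- length(y)
  p <- .softmaxProbs(logits)
  pick <- p[cbind(y, seq_len(N))]
  loss <- -mean(log(pmax(pick, 1e-300)))
  dlogits <- p
  dlogits[cbind(y, seq_len(N))] <- dlogits[cbind(y, seq_len(N))] - 1
  list(loss = loss, dlogits = dlogits / N)
}

.optInit <- function(params, optimizer) {
  zeros <- lapply(params, function(p) p * 0)   # preserves vector/matrix shape
  if (optimizer == "adam") list(m = zeros, v = zeros, t = 0L)
  else list(vel = zeros)
}

.optStep <- function(params, grads, opt, cfg) {
  lr <- cfg@learningRate
  if (cfg@weightDecay > 0)
    for (nm in names(grads)) grads[[nm]] <- grads[[nm]] + cfg@weightDecay * params[[nm]]
  if (cfg@optimizer == "adam") {
    opt$t <- opt$t + 1L
    b1 <- cfg@beta1; b2 <- cfg@beta2
    corr1 <- 1 - b1^opt$t; corr2 <- 1 - b2^opt$t
    for (nm in names(grads)) {
      g <- grads[[nm]]
      opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
      opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g * g
      params[[nm]] <- params[[nm]] -
        lr * (opt$m[[nm]] / corr1) / (sqrt(opt$v[[nm]] / corr2) + 1e-8)
    }
  } else {
    for (nm in names(grads)) {
      opt$vel[[nm]] <- cfg@momentum * opt$vel[[nm]] - lr * grads[[nm]]
      params[[nm]] <- params[[nm]] + opt$vel[[nm]]
    }
  }
  list(params = params, opt = opt)
}
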
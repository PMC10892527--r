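# Generics and accessors. Slot access from user code goes through these.

#' @describeIn HyperspectralCube-class cube dimensions `c(H, W, C)`.
#' @param x a HyperspectralCube.
#' @export
setMethod("dim", "HyperspectralCube", function(x) dim(x@values))

#' Accessors for cube, label and patch containers
#'
#' @param x the object.
#' @return `cubeValues`: the raw `H x W x C` array; `wavelengths`: nm per
#'   band; `labelCodes`: the integer `H x W` matrix; `classTable`: the class
#'   id/name/color table; `patchArray`: the `B x S x S x N` patch array;
#'   `patchLabels`, `patchCoords`: per-sample labels / (line, sample)
#'   coordinates; `nSamples`: patch count.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cubeValues", function(x) standardGeneric("cubeValues"))
#' @rdname accessors
#' @export
setMethod("cubeValues", "HyperspectralCube", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))
#' @rdname accessors
#' @export
setMethod("wavelengths", "HyperspectralCube", function(x) x@wavelengths)
#' @rdname accessors
#' @export
setMethod("wavelengths", "Spectrum", function(x) x@wavelengths)

#' @rdname accessors
#' @export
setGeneric("reflectance", function(x) standardGeneric("reflectance"))
#' @rdname accessors
#' @export
setMethod("reflectance", "Spectrum", function(x) x@reflectance)

#' @rdname accessors
#' @export
setGeneric("labelCodes", function(x) standardGeneric("labelCodes"))
#' @rdname accessors
#' @export
setMethod("labelCodes", "LabelMap", function(x) x@codes)

#' @rdname accessors
#' @export
setGeneric("classTable", function(x) standardGeneric("classTable"))
#' @rdname accessors
#' @export
setMethod("classTable", "LabelMap", function(x) x@classTable)

#' @rdname accessors
#' @export
setGeneric("patchArray", function(x) standardGeneric("patchArray"))
#' @rdname accessors
#' @export
setMethod("patchArray", "PatchDataset", function(x) x@patches)

#' @rdname accessors
#' @export
setGeneric("patchLabels", function(x) standardGeneric("patchLabels"))
#' @rdname accessors
#' @export
setMethod("patchLabels", "PatchDataset", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("patchCoords", function(x) standardGeneric("patchCoords"))
#' @rdname accessors
#' @export
setMethod("patchCoords", "PatchDataset", function(x) x@coords)

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setMethod("nSamples", "PatchDataset", function(x) dim(x@patches)[4L])

#' Count the trainable parameters of a network specification
#'
#' Walks the declarative layer graph and totals every trainable scalar:
#' convolution weights (convolutions carry no bias, since each is followed
#' by batch normalization), batch-norm scale and shift pairs, and the linear
#' head's weights and bias.
#'
#' @param spec a [NetworkSpec-class].
#' @return integer-valued numeric total.
#' @examples
#' countParameters(buildDGRNet(34, inChannels = 30, nClasses = 3))
#' @export
setGeneric("countParameters", function(spec) standardGeneric("countParameters"))

#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
#' @rdname accessors
#' @export
setMethod("counts", "ConfusionMatrix", function(x) x@counts)

setMethod("show", "HyperspectralCube", function(object) {
  d <- dim(object@values)
  wl <- object@wavelengths
  cat(sprintf("HyperspectralCube: %d lines x %d samples x %d bands\n", d[1], d[2], d[3]))
  cat(sprintf("  wavelengths: %.1f - %.1f nm\n", min(wl), max(wl)))
  cat(sprintf("  reflectance range: [%.4g, %.4g]\n",
              min(object@values), max(object@values)))
})

setMethod("show", "LabelMap", function(object) {
  cd <- object@codes
  cat(sprintf("LabelMap: %d x %d, %d labeled / %d pixels\n",
              nrow(cd), ncol(cd), sum(cd > 0), length(cd)))
  if (nrow(object@classTable)) {
    tab <- table(factor(cd[cd > 0], levels = object@classTable$id))
    for (i in seq_len(nrow(object@classTable)))
      cat(sprintf("  %d %-20s %6d px\n", object@classTable$id[i],
                  object@classTable$name[i], tab[i]))
  }
})

setMethod("show", "PatchDataset", function(object) {
  d <- dim(object@patches)
  cat(sprintf("PatchDataset: %d patches of %d x %d x %d (S x S x B)%s\n",
              d[4], d[2], d[3], d[1],
              if (object@scaled) ", standardized" else ""))
  tab <- table(object@labels)
  cat("  per class:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "NetworkSpec", function(object) {
  nblk <- sum(lengths(object@stages))
  cat(sprintf("NetworkSpec <%s>: %d stages / %d blocks, %d classes\n",
              object@family, length(object@stages), nblk, object@nClasses))
  cat(sprintf("  input: %d ch x %d x %d x %d; stem %s/%d -> %d; pool %s/%d\n",
              object@input$channels, object@input$depth, object@input$height,
              object@input$width,
              paste(object@stem$kernel, collapse = "x"), object@stem$stride,
              object@stem$width,
              paste(object@pool$window, collapse = "x"), object@pool$stride))
  cat(sprintf("  stage widths: %s; total params: %s\n",
              paste(vapply(object@stages, function(s) s[[length(s)]]$outWidth, 0),
                    collapse = ", "),
              format(countParameters(object), big.mark = ",")))
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (rows = reference, cols = predicted):\n")
  m <- object@counts
  dimnames(m) <- list(object@classes, object@classes)
  print(m)
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: OA %.2f%%  AA %.2f%%  kappa %.4f\n",
              object@oa, object@aa, object@kappa))
  for (i in seq_along(object@pa))
    cat(sprintf("  %-20s PA %6.2f%%  UA %6.2f%%\n", object@cm@classes[i],
                object@pa[i], object@ua[i]))
})

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf("SceneConfig: %d x %d x %d bands (%g-%g nm), seed %d\n",
              object@H, object@W, object@nBands,
              object@wavelengthRange[1], object@wavelengthRange[2], object@seed))
  cat(sprintf("  priors: %s; corr %g px; border %g px; noise sd %g; unlabeled %g\n",
              paste(signif(object@priors, 3), collapse = "/"),
              object@corrLength, object@borderWidth, object@noiseSD,
              object@unlabeledFraction))
})

setMethod("show", "SyntheticScene", function(object) {
  cat("SyntheticScene\n")
  show(object@cube)
  show(object@labels)
})

setMethod("show", "TrainResult", function(object) {
  h <- object@history
  cat(sprintf("TrainResult: %d epochs in %.1fs; final loss %.4f, train acc %.2f%%\n",
              nrow(h), object@wallTime, h$loss[nrow(h)],
              100 * h$trainAccuracy[nrow(h)]))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: K = %d, mean accuracy %.2f%%, variance %.4g\n",
              object@K, object@meanAccuracy, object@varAccuracy))
  cat("  folds:", paste(sprintf("%.2f", object@foldAccuracy), collapse = ", "), "\n")
})
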
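# Confusion-matrix construction and remote-sensing accuracy measures.
#
# Orientation is fixed: rows are the reference (true) class, columns the
# predicted class. Producer's accuracy (PA) is the row-wise diagonal share,
# user's accuracy (UA) the column-wise share. The remote-sensing literature
# is split on this; the convention here reproduces the field tables this
# package is validated against.

#' Build a confusion matrix from reference and predicted class ids
#'
#' @param yTrue,yPred integer vectors in `1..K`, equal length.
#' @param K class count (default: max id seen).
#' @param classes optional class names.
#' @return A [ConfusionMatrix-class]; `counts[i, j]` is the number of
#'   samples with reference class `i` predicted as `j`.
#' @export
confusionMatrix <- function(yTrue, yPred, K = NULL, classes = NULL) {
  if (length(yTrue) != length(yPred))
    stopf("yTrue (%d) and yPred (%d) differ in length", length(yTrue), length(yPred))
  yTrue <- as.integer(yTrue); yPred <- as.integer(yPred)
  if (is.null(K)) K <- max(1L, yTrue, yPred)
  K <- as.integer(K)
  if (length(yTrue) && (min(yTrue, yPred) < 1L || max(yTrue, yPred) > K))
    stopf("class ids must lie in 1..%d", K)
  m <- matrix(0L, K, K)
  if (length(yTrue)) {
    tab <- table(factor(yTrue, levels = seq_len(K)),
                 factor(yPred, levels = seq_len(K)))
    m <- matrix(as.integer(tab), K, K)
  }
  if (is.null(classes)) classes <- paste0("class_", seq_len(K))
  new("ConfusionMatrix", counts = m, classes = classes)
}

#' Per-class producer's and user's accuracy
#'
#' PA_i = 100 * counts[i,i] / rowSum_i (share of reference samples of class
#' i that were classified correctly); UA_j = 100 * counts[j,j] / colSum_j
#' (share of samples assigned to class j that truly belong to it). Classes
#' with an empty row (or column) have undefined PA (or UA), reported as NA.
#'
#' @param cm a [ConfusionMatrix-class].
#' @return list with numeric vectors `pa` and `ua` (percent).
#' @export
classwiseAccuracy <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  m <- cm@counts
  rs <- rowSums(m); cs <- colSums(m)
  pa <- ifelse(rs > 0, 100 * diag(m) / rs, NA_real_)
  ua <- ifelse(cs > 0, 100 * diag(m) / cs, NA_real_)
  list(pa = pa, ua = ua)
}

#' Overall accuracy, average accuracy and kappa
#'
#' OA = 100 * trace/total; AA = unweighted mean of the defined per-class
#' producer's accuracies; kappa = (p_o - p_e) / (1 - p_e) with
#' p_o = trace/total and p_e = sum_i row_i * col_i / total^2.
#'
#' @param cm a [ConfusionMatrix-class] with at least one sample.
#' @return list with `oa`, `aa` (percent) and `kappa`.
#' @export
summaryMetrics <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  m <- cm@counts
  total <- sum(m)
  if (total == 0) stopf("empty confusion matrix")
  po <- sum(diag(m)) / total
  pe <- sum(rowSums(m) * colSums(m)) / total^2
  pa <- classwiseAccuracy(cm)$pa
  if (anyNA(pa)) warnf("classes with no reference samples excluded from AA")
  kappa <- if (pe >= 1) 1 else (po - pe) / (1 - pe)
  list(oa = 100 * po, aa = mean(pa, na.rm = TRUE), kappa = kappa)
}

#' Full metrics report from predictions
#'
#' @param yTrue,yPred class ids.
#' @param K,classes as in [confusionMatrix()].
#' @return A [MetricsReport-class].
#' @export
metricsReport <- function(yTrue, yPred, K = NULL, classes = NULL) {
  cm <- confusionMatrix(yTrue, yPred, K, classes)
  cw <- classwiseAccuracy(cm)
  sm <- suppressWarnings(summaryMetrics(cm))
  new("MetricsReport", oa = sm$oa, aa = sm$aa, kappa = sm$kappa,
      pa = cw$pa, ua = cw$ua, cm = cm)
}

#' Format a metrics report the way accuracy tables are printed
#'
#' Percent values at two decimals, half away from zero.
#'
#' @param report a [MetricsReport-class].
#' @return data.frame of rounded values.
#' @export
formatMetrics <- function(report) {
  stopifnot(is(report, "MetricsReport"))
  data.frame(class = report@cm@classes,
             pa = roundHalfUp(report@pa),
             ua = roundHalfUp(report@ua),
             oa = roundHalfUp(report@oa),
             aa = roundHalfUp(report@aa),
             kappa = roundHalfUp(report@kappa, 3L))
}

#' Classify every scene pixel and render the classification map
#'
#' Extracts the `S x S x B` patch around each pixel of the (PCA-reduced,
#' standardized) scene, predicts its class, and returns the label image;
#' optionally colours it with the class palette and writes a PNG.
#'
#' @param model an [HsiModel-class].
#' @param scores `H x W x B` score cube matching the model's input bands.
#' @param S odd patch side matching the model's spatial contract.
#' @param classTable class table (id, name, color) used for colouring.
#' @param scale optional `list(center, sd)` from [standardizePatches()],
#'   applied to every patch before prediction.
#' @param pngPath optional output PNG path.
#' @param mask optional [LabelMap-class]; pixels with code 0 are blacked
#'   out in the PNG (unlabeled-background overlay).
#' @param padMode border policy as in [extractPatches()].
#' @return A [LabelMap-class] of predictions for every pixel.
#' @export
renderClassificationMap <- function(model, scores, S = 9L, classTable = NULL,
                                    scale = NULL, pngPath = NULL, mask = NULL,
                                    padMode = "reflect") {
  stopifnot(is(model, "HsiModel"), is(scores, "HyperspectralCube"))
  d <- dim(scores@values)
  allLab <- labelMap(matrix(1L, d[1L], d[2L]))
  ds <- extractPatches(scores, allLab, S, padMode)
  if (!is.null(scale)) {
    B <- dim(ds@patches)[1L]
    ds <- patchDataset(array((matrix(ds@patches, B) - scale$center) / scale$sd,
                             dim(ds@patches)),
                       ds@labels, ds@coords, TRUE, scale$center, scale$sd)
  }
  pred <- predictModel(model, ds)$class
  codes <- matrix(0L, d[1L], d[2L])
  codes[cbind(ds@coords[, 1L] + 1L, ds@coords[, 2L] + 1L)] <- pred
  K <- model@spec@nClasses
  if (is.null(classTable))
    classTable <- data.frame(id = seq_len(K),
                             name = paste0("class_", seq_len(K)),
                             color = grDevices::hcl.colors(K, "Dark 3"),
                             stringsAsFactors = FALSE)
  if (!all(seq_len(K) %in% classTable$id))
    stopf("palette is missing one or more of the %d classes", K)
  out <- labelMap(codes, classTable)
  if (!is.null(pngPath)) {
    shown <- out
    if (!is.null(mask)) {
      cd <- codes
      cd[labelCodes(mask) == 0L] <- 0L
      shown <- labelMap(cd, classTable)
    }
    writeLabelPNG(shown, pngPath)
  }
  out
}
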
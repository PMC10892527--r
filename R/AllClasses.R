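#' @import methods
NULL

#' HyperspectralCube: a reflectance cube with per-band wavelengths
#'
#' Container for a hyperspectral scene: an `H x W x C` array of reflectance
#' (lines x samples x bands, the ENVI convention) together with the
#' wavelength, in nanometres, of every band. Reflectance is dimensionless;
#' vegetation scenes typically stay within `[0, ~1.2]` after radiometric
#' correction. Both raw scenes and PCA score "cubes" use this class (scores
#' are centred and may be negative; wavelengths are then component indices).
#'
#' @slot values numeric array, `H x W x C`, all finite.
#' @slot wavelengths numeric of length `C`, strictly increasing.
#' @slot meta free-form acquisition metadata (list).
#'
#' @seealso [hyperspectralCube()], [readENVICube()], [centerCrop()]
#' @export
setClass("HyperspectralCube",
  representation(values = "array", wavelengths = "numeric", meta = "list"),
  validity = function(object) {
    v <- object@values
    if (length(dim(v)) != 3L) return("values must be a 3-d array (lines x samples x bands)")
    if (any(dim(v) < 1L)) return("all cube dimensions must be >= 1")
    if (!all(is.finite(v))) return("cube values must all be finite")
    wl <- object@wavelengths
    if (length(wl) != dim(v)[3L]) return("wavelengths length must equal the band count")
    if (length(wl) > 1L && any(diff(wl) <= 0)) return("wavelengths must be strictly increasing")
    TRUE
  })

#' Construct a HyperspectralCube
#'
#' @param values `H x W x C` numeric array (lines x samples x bands).
#' @param wavelengths per-band wavelengths in nm; defaults to band indices.
#' @param meta optional metadata list.
#' @return A [HyperspectralCube-class] object.
#' @examples
#' cube <- hyperspectralCube(array(runif(2 * 3 * 4), c(2, 3, 4)))
#' dim(cube)
#' @export
hyperspectralCube <- function(values, wavelengths = NULL, meta = list()) {
  values <- array(as.double(values), dim = dim(values))
  if (is.null(wavelengths)) wavelengths <- as.double(seq_len(dim(values)[3L]))
  new("HyperspectralCube", values = values,
      wavelengths = as.double(wavelengths), meta = meta)
}

#' LabelMap: integer class raster aligned to a cube
#'
#' Per-pixel class codes for a scene, `0` meaning unlabeled background and
#' `1..K` the land-cover classes, plus a class table mapping each id to a
#' name and display colour.
#'
#' @slot codes integer matrix `H x W`.
#' @slot classTable data.frame with columns `id`, `name`, `color`.
#' @export
setClass("LabelMap",
  representation(codes = "matrix", classTable = "data.frame"),
  validity = function(object) {
    cd <- object@codes
    if (!is.numeric(cd)) return("codes must be numeric/integer")
    if (any(!is.finite(cd)) || any(cd < 0) || any(cd != round(cd)))
      return("codes must be non-negative integers (0 = unlabeled)")
    ct <- object@classTable
    if (nrow(ct) > 0L) {
      if (!all(c("id", "name", "color") %in% names(ct)))
        return("classTable needs columns id, name, color")
      if (max(cd) > 0 && !all(setdiff(unique(as.vector(cd)), 0L) %in% ct$id))
        return("every nonzero code must appear in classTable$id")
    }
    TRUE
  })

#' Construct a LabelMap
#'
#' @param codes integer matrix `H x W`; 0 marks unlabeled pixels.
#' @param classTable data.frame (`id`, `name`, `color`); built automatically
#'   from the codes present when omitted.
#' @return A [LabelMap-class].
#' @export
labelMap <- function(codes, classTable = NULL) {
  codes <- matrix(as.integer(codes), nrow = nrow(codes))
  if (is.null(classTable)) {
    ids <- sort(setdiff(unique(as.vector(codes)), 0L))
    pal <- if (length(ids)) grDevices::hcl.colors(length(ids), "Dark 3")
           else character(0)
    classTable <- data.frame(id = ids,
                             name = if (length(ids)) paste0("class_", ids)
                                    else character(0),
                             color = pal,
                             stringsAsFactors = FALSE)
  }
  new("LabelMap", codes = codes, classTable = classTable)
}

#' Spectrum: a single reflectance curve
#'
#' @slot reflectance numeric, one value per band.
#' @slot wavelengths numeric, nm, same length.
#' @export
setClass("Spectrum",
  representation(reflectance = "numeric", wavelengths = "numeric"),
  validity = function(object) {
    if (length(object@reflectance) != length(object@wavelengths))
      return("reflectance and wavelengths must have equal length")
    if (!all(is.finite(object@reflectance))) return("reflectance must be finite")
    TRUE
  })

#' @rdname Spectrum-class
#' @param reflectance,wavelengths numeric vectors of equal length.
#' @export
Spectrum <- function(reflectance, wavelengths = seq_along(reflectance)) {
  new("Spectrum", reflectance = as.double(reflectance),
      wavelengths = as.double(wavelengths))
}

#' PCAModel: fitted principal-component band reduction
#'
#' Holds the band means, the orthonormal loadings, and the explained-variance
#' ratios from which the retained component count was chosen.
#'
#' @slot center numeric, per-band means (length `C`).
#' @slot loadings `C x B` matrix of retained orthonormal components.
#' @slot varRatio explained-variance ratios, length `C`, descending, sum 1.
#' @slot nBands retained component count `B` (minimal count whose cumulative
#'   ratio reaches the threshold).
#' @slot threshold the variance threshold used.
#' @export
setClass("PCAModel",
  representation(center = "numeric", loadings = "matrix",
                 varRatio = "numeric", nBands = "integer",
                 threshold = "numeric"),
  validity = function(object) {
    L <- object@loadings
    if (nrow(L) != length(object@center)) return("loadings rows must match band count")
    if (ncol(L) != object@nBands) return("loadings must have nBands columns")
    G <- crossprod(L)
    if (max(abs(G - diag(ncol(L)))) > 1e-8) return("loadings columns must be orthonormal")
    if (abs(sum(object@varRatio) - 1) > 1e-8) return("variance ratios must sum to 1")
    if (is.unsorted(rev(object@varRatio))) return("variance ratios must be descending")
    TRUE
  })

#' PatchDataset: 3D blocks around labeled pixels
#'
#' `N` samples of `S x S x B` reflectance blocks, each centred on a labeled
#' pixel, with the centre-pixel class and the source (line, sample)
#' coordinates. Stored band-first (`B x S x S x N`) so a sample flattens
#' directly into the network input layout.
#'
#' @slot patches numeric array `B x S x S x N`.
#' @slot labels integer `N`, classes in `1..K`.
#' @slot coords integer `N x 2` matrix of 0-based (line, sample).
#' @slot scaled logical; TRUE once [standardizePatches()] has been applied.
#' @slot scaleCenter,scaleSD per-band standardization constants (length `B`
#'   when scaled, else length 0).
#' @export
setClass("PatchDataset",
  representation(patches = "array", labels = "integer", coords = "matrix",
                 scaled = "logical", scaleCenter = "numeric", scaleSD = "numeric"),
  validity = function(object) {
    d <- dim(object@patches)
    if (length(d) != 4L) return("patches must be a 4-d array (B x S x S x N)")
    if (d[2L] != d[3L]) return("patches must be spatially square")
    if (d[2L] %% 2L == 0L) return("patch side S must be odd")
    if (length(object@labels) != d[4L]) return("one label per patch required")
    if (any(object@labels < 1L)) return("labels must be >= 1")
    if (nrow(object@coords) != d[4L] || ncol(object@coords) != 2L)
      return("coords must be an N x 2 matrix")
    if (!all(is.finite(object@patches))) return("patches must be finite")
    TRUE
  })

patchDataset <- function(patches, labels, coords, scaled = FALSE,
                         scaleCenter = numeric(0), scaleSD = numeric(0)) {
  new("PatchDataset", patches = patches, labels = as.integer(labels),
      coords = coords, scaled = scaled,
      scaleCenter = scaleCenter, scaleSD = scaleSD)
}

#' SplitSpec: train/validation/test allocation
#'
#' @slot fractions numeric of length 3 (train, validation, test) summing to 1.
#' @slot stratified logical; split within each class.
#' @slot seed integer RNG seed for the shuffle.
#' @export
setClass("SplitSpec",
  representation(fractions = "numeric", stratified = "logical", seed = "integer"),
  validity = function(object) {
    f <- object@fractions
    if (length(f) != 3L) return("fractions must be (train, validation, test)")
    if (any(f < 0) || any(f > 1)) return("each fraction must lie in [0, 1]")
    if (abs(sum(f) - 1) > 1e-12) return("fractions must sum to 1")
    TRUE
  })

#' @rdname SplitSpec-class
#' @param train,validation,test fractions in `[0,1]` summing to 1. The field
#'   protocol is 7:3 train:test; sweep experiments hold validation at 0.1.
#' @param stratified split per class (default TRUE).
#' @param seed integer seed.
#' @export
splitSpec <- function(train = 0.7, validation = 0, test = 1 - train - validation,
                      stratified = TRUE, seed = 1L) {
  new("SplitSpec", fractions = c(train, validation, test),
      stratified = stratified, seed = as.integer(seed))
}

#' NetworkSpec: declarative residual-network description
#'
#' A layer graph from which both a trainable model ([instantiateNetwork()])
#' and an exact trainable-parameter count ([countParameters()]) derive.
#' Built by [buildDGRNet()], [build3DDGRNet()] and [build3DRNetO()].
#'
#' @slot family one of `"dgrnet"`, `"3d_dgrnet"`, `"3d_rnet_o"`.
#' @slot input list: `channels`, `depth`, `height`, `width` of the input
#'   volume (2D nets: `channels = B`, `depth = 1`; 3D nets: one channel,
#'   `depth = B`).
#' @slot stem list: `kernel` (length-3), `stride`, `width`.
#' @slot pool list: `window` (length-3), `stride`.
#' @slot stages list of stages, each a list of block configs (see
#'   [dualBranchBlock()]).
#' @slot nClasses number of output classes.
#' @export
setClass("NetworkSpec",
  representation(family = "character", input = "list", stem = "list",
                 pool = "list", stages = "list", nClasses = "integer"),
  validity = function(object) {
    if (length(object@stages) < 1L) return("at least one stage required")
    widths <- vapply(object@stages, function(st) st[[length(st)]]$outWidth, 0)
    if (any(diff(widths) < 0)) return("stage output widths must be non-decreasing")
    prev <- object@stem$width
    for (st in object@stages) for (blk in st) {
      if (blk$inWidth != prev) return("block in/out widths must chain consistently")
      prev <- blk$outWidth
    }
    if (object@nClasses < 2L) return("need at least two classes")
    TRUE
  })

#' ConfusionMatrix: reference-by-predicted counts
#'
#' Rows are the reference (true) class, columns the predicted class —
#' producer's accuracy reads along rows, user's accuracy down columns.
#'
#' @slot counts `K x K` integer matrix.
#' @slot classes class names (length `K`).
#' @export
setClass("ConfusionMatrix",
  representation(counts = "matrix", classes = "character"),
  validity = function(object) {
    ct <- object@counts
    if (nrow(ct) != ncol(ct)) return("counts must be square")
    if (any(ct < 0) || any(ct != round(ct))) return("counts must be non-negative integers")
    if (length(object@classes) != nrow(ct)) return("one class name per row required")
    TRUE
  })

#' MetricsReport: accuracy summary for a classification
#'
#' Overall accuracy (OA), average accuracy (AA), kappa, and per-class
#' producer's (PA) and user's (UA) accuracy, with the underlying confusion
#' matrix. Percentages on the 0-100 scale; classes absent from the reference
#' (or never predicted) carry `NA` PA (or UA) and are excluded from AA.
#'
#' @slot oa,aa numeric percents.
#' @slot kappa numeric in `[-1, 1]`.
#' @slot pa,ua numeric per class (NA where undefined).
#' @slot cm the [ConfusionMatrix-class].
#' @export
setClass("MetricsReport",
  representation(oa = "numeric", aa = "numeric", kappa = "numeric",
                 pa = "numeric", ua = "numeric", cm = "ConfusionMatrix"))

#' SceneConfig: synthetic-scene generator settings
#'
#' Parameters of the simulated desert-grassland scene: three land-cover
#' classes (group species, drought-stressed indicator species, and
#' non-vegetation), patchy community layout, mixed border pixels and sensor
#' noise. See [sceneConfig()] for defaults and their rationale.
#'
#' @slot H,W scene dimensions (lines, samples).
#' @slot nBands raw band count.
#' @slot wavelengthRange nm, length 2.
#' @slot classParams per-class endmember parameter lists.
#' @slot classNames length-3 character.
#' @slot priors target class fractions, sum 1.
#' @slot corrLength patchiness correlation length in pixels.
#' @slot borderWidth mixing half-width in pixels.
#' @slot noiseSD iid Gaussian noise sd in reflectance units.
#' @slot brightnessSD sd of the smooth multiplicative illumination field
#'   (within-class brightness variability; 0 disables).
#' @slot unlabeledFraction fraction of pixels hidden from the public labels.
#' @slot seed integer.
#' @export
setClass("SceneConfig",
  representation(H = "integer", W = "integer", nBands = "integer",
                 wavelengthRange = "numeric", classParams = "list",
                 classNames = "character", priors = "numeric",
                 corrLength = "numeric", borderWidth = "numeric",
                 noiseSD = "numeric", brightnessSD = "numeric",
                 unlabeledFraction = "numeric", seed = "integer"),
  validity = function(object) {
    if (abs(sum(object@priors) - 1) > 1e-9) return("priors must sum to 1")
    if (object@noiseSD < 0) return("noiseSD must be >= 0")
    if (object@brightnessSD < 0) return("brightnessSD must be >= 0")
    if (object@borderWidth < 0) return("borderWidth must be >= 0")
    fl <- vapply(object@classParams, function(p) p$flatness %||% 0, 0)
    if (any(fl < 0 | fl > 1)) return("flatness must lie in [0, 1]")
    if (object@unlabeledFraction < 0 || object@unlabeledFraction >= 1)
      return("unlabeledFraction must lie in [0, 1)")
    if (length(object@classParams) != length(object@priors))
      return("one classParams entry per prior required")
    TRUE
  })

#' SyntheticScene: generated cube, public labels and ground truth
#'
#' @slot cube the generated [HyperspectralCube-class].
#' @slot labels public [LabelMap-class] with the unlabeled fraction set to 0.
#' @slot truth full ground-truth [LabelMap-class] (no unlabeled pixels),
#'   retained for scoring.
#' @slot config the [SceneConfig-class] used.
#' @export
setClass("SyntheticScene",
  representation(cube = "HyperspectralCube", labels = "LabelMap",
                 truth = "LabelMap", config = "SceneConfig"))

#' TrainConfig: training-loop settings
#'
#' @slot learningRate positive; field protocol optimum is 0.003.
#' @slot epochs training epochs (the field protocol trains 200).
#' @slot batchSize patches per optimization step.
#' @slot optimizer `"adam"` or `"sgd"`.
#' @slot beta1,beta2 Adam moment decays.
#' @slot momentum SGD momentum.
#' @slot weightDecay L2 penalty (0 disables).
#' @slot seed integer; fixes shuffling and initialization.
#' @export
setClass("TrainConfig",
  representation(learningRate = "numeric", epochs = "integer",
                 batchSize = "integer", optimizer = "character",
                 beta1 = "numeric", beta2 = "numeric", momentum = "numeric",
                 weightDecay = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@learningRate <= 0) return("learningRate must be > 0")
    if (object@epochs < 1L) return("epochs must be >= 1")
    if (object@batchSize < 1L) return("batchSize must be >= 1")
    if (!object@optimizer %in% c("adam", "sgd")) return("optimizer must be adam or sgd")
    TRUE
  })

#' @rdname TrainConfig-class
#' @param learningRate,epochs,batchSize,optimizer,beta1,beta2,momentum,weightDecay,seed
#'   see slot documentation.
#' @export
trainConfig <- function(learningRate = 0.003, epochs = 200L, batchSize = 64L,
                        optimizer = c("adam", "sgd"), beta1 = 0.9,
                        beta2 = 0.999, momentum = 0.9, weightDecay = 0,
                        seed = 1L) {
  new("TrainConfig", learningRate = learningRate, epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), optimizer = match.arg(optimizer),
      beta1 = beta1, beta2 = beta2, momentum = momentum,
      weightDecay = weightDecay, seed = as.integer(seed))
}

#' TrainResult: outcome of one training run
#'
#' @slot history data.frame with one row per epoch (`epoch`, `loss`,
#'   `trainAccuracy`, `valAccuracy`).
#' @slot model the trained model (see [instantiateNetwork()]).
#' @slot seed seed used.
#' @slot wallTime elapsed seconds.
#' @slot config the [TrainConfig-class] snapshot.
#' @export
setClass("TrainResult",
  representation(history = "data.frame", model = "ANY", seed = "integer",
                 wallTime = "numeric", config = "TrainConfig"))

#' CVResult: K-fold cross-validation summary
#'
#' @slot K fold count.
#' @slot foldAccuracy per-fold overall accuracy (percent).
#' @slot meanAccuracy arithmetic mean of the folds.
#' @slot varAccuracy population variance of the folds (percent^2 scale,
#'   matching how K-CV stability is usually tabulated).
#' @export
setClass("CVResult",
  representation(K = "integer", foldAccuracy = "numeric",
                 meanAccuracy = "numeric", varAccuracy = "numeric"),
  validity = function(object) {
    if (length(object@foldAccuracy) != object@K) return("one accuracy per fold required")
    TRUE
  })

`%||%` <- function(a, b) if (is.null(a)) b else a
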
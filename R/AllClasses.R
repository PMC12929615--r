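#' @import methods
NULL

## ---------------------------------------------------------------------------
## Central containers.
##
## Grayscale images and binary masks travel as plain numeric matrices (S x S,
## intensities in [0, 1] resp. values in {0, 1}) -- the same convention as
## EBImage's imageData. The structured intermediates of the architecture
## (patch grids, logit fields, predictions, saliency maps, evaluation cases)
## are S4 classes with validity methods.
## ---------------------------------------------------------------------------

#' PatchGrid: a square image cut into non-overlapping square patches
#'
#' Patches are stored as a `p x p x P^2` array. Patch index `i` is 0-based and
#' row-major over the patch grid: `i = r * P + c` for grid row `r` and grid
#' column `c` (origin top-left), stored at array slice `i + 1`. Patch `(r, c)`
#' covers image rows `[r*p, (r+1)*p)` and columns `[c*p, (c+1)*p)` (half-open,
#' 0-based).
#'
#' @slot patches numeric array, `p x p x P^2`.
#' @slot gridSide integer `P`, patches per image side.
#' @slot patchSide integer `p`, pixels per patch side.
#' @slot imageSide integer `S = p * P`, pixels per image side.
#' @seealso [partitionImage()], [assembleImage()]
#' @export
setClass("PatchGrid",
  representation(
    patches = "array",
    gridSide = "integer",
    patchSide = "integer",
    imageSide = "integer"
  )
)

setValidity("PatchGrid", function(object) {
  d <- dim(object@patches)
  P <- object@gridSide
  p <- object@patchSide
  if (length(d) != 3L) return("patches must be a 3-d array")
  if (d[1] != p || d[2] != p) return("patch slices must be patchSide x patchSide")
  if (d[3] != P * P) return("number of patches must equal gridSide^2")
  if (object@imageSide != p * P) return("imageSide must equal patchSide * gridSide")
  TRUE
})

#' PatchLogitField: per-patch class logits
#'
#' Row `i + 1` of `logits` holds the length-`C` logit vector of patch `i`
#' (0-based row-major patch index, see [PatchGrid-class]). `source` records
#' whether the rows are raw pre-sigmoid patch logits or probability-scaled
#' patch logits (raw logits multiplied elementwise by the image-level
#' probabilities).
#'
#' @slot logits numeric matrix, `P^2 x C`.
#' @slot labels character vector of the `C` class names.
#' @slot gridSide integer `P`.
#' @slot patchSide integer `p`.
#' @slot source `"raw"` or `"scaled"`.
#' @export
setClass("PatchLogitField",
  representation(
    logits = "matrix",
    labels = "character",
    gridSide = "integer",
    patchSide = "integer",
    source = "character"
  )
)

setValidity("PatchLogitField", function(object) {
  if (nrow(object@logits) != object@gridSide^2)
    return("logit rows must equal gridSide^2")
  if (ncol(object@logits) != length(object@labels))
    return("logit columns must match number of labels")
  if (!all(is.finite(object@logits)))
    return("logits must be finite")
  if (!object@source %in% c("raw", "scaled"))
    return("source must be 'raw' or 'scaled'")
  TRUE
})

#' GlobalPrediction: image-level logits and probabilities
#'
#' `globalLogits` is the arithmetic mean over the rows of the originating
#' [PatchLogitField-class]; `probabilities` is its elementwise sigmoid. The
#' sigmoid is applied after averaging, never per patch.
#'
#' @slot globalLogits numeric length-`C` vector `Z`.
#' @slot probabilities numeric length-`C` vector in (0, 1).
#' @slot labels character vector of class names.
#' @export
setClass("GlobalPrediction",
  representation(
    globalLogits = "numeric",
    probabilities = "numeric",
    labels = "character"
  )
)

setValidity("GlobalPrediction", function(object) {
  C <- length(object@labels)
  if (length(object@globalLogits) != C || length(object@probabilities) != C)
    return("logits, probabilities and labels must have equal length")
  ## mathematically sigmoid is in (0, 1); the bounds are attainable only by
  ## floating-point underflow at |Z| beyond ~745
  if (any(object@probabilities < 0 | object@probabilities > 1))
    return("probabilities must lie within [0, 1]")
  TRUE
})

#' SaliencyMap: per-pixel signed attribution for one label
#'
#' Signed `S x S` field; positive values are evidence for the label, negative
#' values evidence against it, zero means no contribution. With
#' `offset == patchSide` the map is block-constant on the patch tiling.
#'
#' @slot values numeric `S x S` matrix.
#' @slot label the class name the map explains.
#' @slot source `"raw"` or `"scaled"` (which logits it was built from).
#' @slot offset integer shift offset `o` used to generate it.
#' @export
setClass("SaliencyMap",
  representation(
    values = "matrix",
    label = "character",
    source = "character",
    offset = "integer"
  )
)

setValidity("SaliencyMap", function(object) {
  if (nrow(object@values) != ncol(object@values))
    return("saliency map must be square")
  if (!all(is.finite(object@values)))
    return("saliency values must be finite")
  if (!object@source %in% c("raw", "scaled"))
    return("source must be 'raw' or 'scaled'")
  if (length(object@offset) != 1L || object@offset < 1L)
    return("offset must be a single positive integer")
  TRUE
})

#' EvalCase: one (image, label) localization-evaluation unit
#'
#' Carries the binary ground-truth label, the ground-truth segmentation mask
#' (0/1 matrix, or `NULL` when absent), the saliency map under evaluation, and
#' the pointing-game hit indicator once computed (`NA` until then).
#'
#' @slot imageId character identifier.
#' @slot label class name evaluated.
#' @slot truth integer ground-truth label, 0 or 1.
#' @slot gtMask 0/1 matrix or `NULL`.
#' @slot saliency a [SaliencyMap-class] or a bare numeric matrix.
#' @slot hit integer 0/1, `NA` until computed.
#' @export
setClass("EvalCase",
  representation(
    imageId = "character",
    label = "character",
    truth = "integer",
    gtMask = "ANY",
    saliency = "ANY",
    hit = "integer"
  ),
  prototype(hit = NA_integer_)
)

setValidity("EvalCase", function(object) {
  if (!object@truth %in% c(0L, 1L)) return("truth must be 0 or 1")
  if (!is.null(object@gtMask)) {
    if (!is.matrix(object@gtMask) || !all(object@gtMask %in% c(0, 1)))
      return("gtMask must be a 0/1 matrix or NULL")
  }
  if (!is.na(object@hit) && !object@hit %in% c(0L, 1L))
    return("hit must be NA, 0 or 1")
  TRUE
})

#' MetricReport: point estimate with percentile bootstrap interval
#'
#' @slot metric metric name.
#' @slot estimate point estimate on the full case set.
#' @slot lower,upper percentile 2.5% / 97.5% bootstrap bounds (`NA` when no
#'   resamples were requested).
#' @slot n number of cases.
#' @slot resamples bootstrap resamples drawn.
#' @slot skipped resamples on which the metric was undefined and skipped.
#' @export
setClass("MetricReport",
  representation(
    metric = "character",
    estimate = "numeric",
    lower = "numeric",
    upper = "numeric",
    n = "integer",
    resamples = "integer",
    skipped = "integer"
  )
)

setValidity("MetricReport", function(object) {
  if (object@resamples > 0L && !is.na(object@lower) && !is.na(object@upper)) {
    if (object@lower > object@upper) return("lower bound exceeds upper bound")
  }
  TRUE
})

## ---------------------------------------------------------------------------
## Encoders. The contract: a deterministic map from one p x p single-channel
## patch to a length-C logit vector, applied identically to every patch
## (shared parameters, no positional input). Batched evaluation operates on a
## matrix whose rows are patches flattened column-major (R's as.vector order).
## ---------------------------------------------------------------------------

#' Virtual parent of all patch encoders
#'
#' An encoder maps a single `p x p` patch to `C` class logits and is applied
#' identically to every patch: shared parameters, no access to patch position
#' or to other patches. This independence is the interpretability guarantee
#' of the architecture -- nothing can influence the image-level prediction
#' without appearing in some patch's logits.
#'
#' @slot labels character vector of the `C` class names.
#' @export
setClass("PatchEncoder", representation("VIRTUAL", labels = "character"))

#' Trainable two-layer perceptron patch encoder
#'
#' A compact trainable encoder honoring the patch-encoder contract: flattened
#' patch pixels -> ReLU hidden layer -> `C` linear logits. Trained with
#' [trainEncoder()].
#'
#' @slot W1 input-to-hidden weights, `p^2 x h`.
#' @slot b1 hidden bias, length `h`.
#' @slot W2 hidden-to-logit weights, `h x C`.
#' @slot b2 logit bias, length `C`.
#' @slot patchSide integer `p` the encoder accepts.
#' @export
setClass("MLPEncoder",
  contains = "PatchEncoder",
  representation(
    W1 = "matrix", b1 = "numeric",
    W2 = "matrix", b2 = "numeric",
    patchSide = "integer"
  )
)

setValidity("MLPEncoder", function(object) {
  if (nrow(object@W1) != object@patchSide^2)
    return("W1 rows must equal patchSide^2")
  if (ncol(object@W1) != length(object@b1)) return("W1/b1 shape mismatch")
  if (nrow(object@W2) != ncol(object@W1)) return("W1/W2 shape mismatch")
  if (ncol(object@W2) != length(object@b2)) return("W2/b2 shape mismatch")
  if (ncol(object@W2) != length(object@labels))
    return("output width must equal number of labels")
  TRUE
})

#' Trainable tiny convolutional patch encoder
#'
#' A compact convolutional encoder honoring the patch-encoder contract:
#' one valid (unpadded) square convolution with ReLU over the patch centered
#' by its own mean intensity, followed by a dense logit head over all
#' positions and filters plus the patch mean as one extra feature.
#' Mean-centering removes smooth background-intensity variation before the
#' shape-sensitive convolution while the appended mean keeps absolute
#' brightness visible; translation structure in the first layer makes it
#' markedly better than a flat perceptron at telling lesion shapes apart
#' wherever they land inside a patch. Trained with [trainEncoder()].
#'
#' @slot Wc convolution weights, `k^2 x F` (window flattened column-major).
#' @slot bc filter bias, length `F`.
#' @slot Wd dense head weights, `(nPos^2 * F + 1) x C`.
#' @slot bd logit bias, length `C`.
#' @slot patchSide integer `p` the encoder accepts.
#' @slot kernel convolution window side `k`.
#' @slot stride convolution stride.
#' @export
setClass("CNNEncoder",
  contains = "PatchEncoder",
  representation(
    Wc = "matrix", bc = "numeric",
    Wd = "matrix", bd = "numeric",
    patchSide = "integer", kernel = "integer", stride = "integer"
  )
)

setValidity("CNNEncoder", function(object) {
  k <- object@kernel
  if (nrow(object@Wc) != k^2) return("Wc rows must equal kernel^2")
  if (ncol(object@Wc) != length(object@bc)) return("Wc/bc shape mismatch")
  nPos <- (object@patchSide - k) %/% object@stride + 1L
  if (nPos < 1L) return("kernel larger than patch")
  if (nrow(object@Wd) != nPos^2 * ncol(object@Wc) + 1L)
    return("Wd rows must equal nPos^2 * filters + 1")
  if (ncol(object@Wd) != length(object@bd)) return("Wd/bd shape mismatch")
  if (ncol(object@Wd) != length(object@labels))
    return("output width must equal number of labels")
  TRUE
})

#' Function-backed patch encoder
#'
#' Wraps an arbitrary deterministic function as a patch encoder, mainly for
#' testing and for analytic reference encoders. `fun` receives one `p x p`
#' matrix and must return a length-`C` numeric vector; if `vectorized`, it
#' instead receives the whole `n x p^2` batch matrix (rows = column-major
#' flattened patches) and must return an `n x C` matrix.
#'
#' @slot fun the encoding function.
#' @slot vectorized logical, batch-matrix calling convention.
#' @export
setClass("FunEncoder",
  contains = "PatchEncoder",
  representation(fun = "function", vectorized = "logical")
)

## ---------------------------------------------------------------------------
## Generics
## ---------------------------------------------------------------------------

#' Evaluate an encoder on a batch of flattened patches
#'
#' @param encoder a [PatchEncoder-class].
#' @param x numeric matrix, `n x p^2`; each row one patch flattened
#'   column-major.
#' @return numeric `n x C` logit matrix.
#' @export
setGeneric("encoderLogits", function(encoder, x) standardGeneric("encoderLogits"))

#' Number of class labels
#' @param object an encoder, logit field or prediction.
#' @return integer `C`.
#' @export
setGeneric("nLabels", function(object) standardGeneric("nLabels"))

#' Class label names
#' @param object an encoder, logit field or prediction.
#' @return character vector of length `C`.
#' @export
setGeneric("labelNames", function(object) standardGeneric("labelNames"))

#' Raw values of a container
#'
#' Returns the numeric payload: the logit matrix of a [PatchLogitField-class],
#' the pixel grid of a [SaliencyMap-class].
#' @param object the container.
#' @return a numeric matrix.
#' @export
setGeneric("values", function(object) standardGeneric("values"))

#' Global (image-level) logits
#' @param object a [GlobalPrediction-class].
#' @return numeric vector `Z`.
#' @export
setGeneric("globalLogits", function(object) standardGeneric("globalLogits"))

#' Image-level class probabilities
#' @param object a [GlobalPrediction-class].
#' @return numeric vector `sigmoid(Z)`.
#' @export
setGeneric("probabilities", function(object) standardGeneric("probabilities"))

setMethod("nLabels", "PatchEncoder", function(object) length(object@labels))
setMethod("nLabels", "PatchLogitField", function(object) length(object@labels))
setMethod("nLabels", "GlobalPrediction", function(object) length(object@labels))
setMethod("labelNames", "PatchEncoder", function(object) object@labels)
setMethod("labelNames", "PatchLogitField", function(object) object@labels)
setMethod("labelNames", "GlobalPrediction", function(object) object@labels)
setMethod("values", "PatchLogitField", function(object) object@logits)
setMethod("values", "SaliencyMap", function(object) object@values)
setMethod("globalLogits", "GlobalPrediction", function(object) object@globalLogits)
setMethod("probabilities", "GlobalPrediction", function(object) object@probabilities)

setMethod("show", "PatchGrid", function(object) {
  cat(sprintf("PatchGrid: %d x %d patches of %d x %d px (image %d x %d)\n",
    object@gridSide, object@gridSide, object@patchSide, object@patchSide,
    object@imageSide, object@imageSide))
})

setMethod("show", "PatchLogitField", function(object) {
  cat(sprintf("PatchLogitField (%s): %d patches x %d labels [%s]\n",
    object@source, nrow(object@logits), nLabels(object),
    paste(object@labels, collapse = ", ")))
})

setMethod("show", "GlobalPrediction", function(object) {
  cat("GlobalPrediction\n")
  print(data.frame(label = object@labels, Z = object@globalLogits,
    probability = object@probabilities, row.names = NULL))
})

setMethod("show", "SaliencyMap", function(object) {
  cat(sprintf(
    "SaliencyMap '%s' (%s logits, offset %d): %d x %d, range [%.4g, %.4g]\n",
    object@label, object@source, object@offset,
    nrow(object@values), ncol(object@values),
    min(object@values), max(object@values)))
})

setMethod("show", "EvalCase", function(object) {
  cat(sprintf("EvalCase %s / %s: truth=%d, gt mask %s, hit=%s\n",
    object@imageId, object@label, object@truth,
    if (is.null(object@gtMask)) "absent"
    else sprintf("%d px", sum(object@gtMask)),
    ifelse(is.na(object@hit), "unset", object@hit)))
})

setMethod("show", "MetricReport", function(object) {
  ci <- if (object@resamples > 0L)
    sprintf(" [%.4f, %.4f] (%d resamples, %d skipped)",
      object@lower, object@upper, object@resamples, object@skipped)
  else ""
  cat(sprintf("%s = %.4f%s, n = %d\n",
    object@metric, object@estimate, ci, object@n))
})

setMethod("show", "MLPEncoder", function(object) {
  cat(sprintf(
    "MLPEncoder: %d x %d patch -> %d hidden -> %d labels [%s]\n",
    object@patchSide, object@patchSide, ncol(object@W1), nLabels(object),
    paste(object@labels, collapse = ", ")))
})

setMethod("show", "FunEncoder", function(object) {
  cat(sprintf("FunEncoder: %d labels%s\n", nLabels(object),
    if (object@vectorized) " (vectorized)" else ""))
})

#' Construct an evaluation case
#'
#' @param imageId image identifier.
#' @param label class name.
#' @param truth ground-truth binary label (0/1).
#' @param saliency a [SaliencyMap-class] or numeric matrix.
#' @param gtMask 0/1 matrix, or `NULL` when no mask is available.
#' @return an [EvalCase-class].
#' @export
evalCase <- function(imageId, label, truth, saliency, gtMask = NULL) {
  new("EvalCase", imageId = as.character(imageId), label = as.character(label),
    truth = as.integer(truth), gtMask = gtMask, saliency = saliency)
}
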
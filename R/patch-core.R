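## The architecture's arithmetic: partition -> independent per-patch encoding
## -> fixed arithmetic-mean aggregation -> sigmoid. Because the image-level
## logit is exactly the mean of the patch logits, each patch's contribution to
## every decision is known by construction -- no post-hoc attribution needed.

.checkGrayImage <- function(img, what = "image") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(what, " must be a numeric matrix")
  if (nrow(img) != ncol(img))
    stop(what, " must be square, got ", nrow(img), " x ", ncol(img))
  invisible(nrow(img))
}

## Numerically stable sigmoid: never exponentiates a large positive argument.
.sigmoid <- function(z) {
  out <- numeric(length(z))
  pos <- z >= 0
  out[pos] <- 1 / (1 + exp(-z[pos]))
  ez <- exp(z[!pos])
  out[!pos] <- ez / (1 + ez)
  out
}

## Linear indices (column-major into an S x S image) of the pixels of each
## patch: column i+1 holds patch i's pixels in column-major within-patch
## order. Cached per (S, p) since the training loop hits this repeatedly.
.patchIndexCache <- new.env(parent = emptyenv())

.patchIndices <- function(S, p) {
  key <- paste(S, p, sep = "/")
  hit <- .patchIndexCache[[key]]
  if (!is.null(hit)) return(hit)
  P <- S %/% p
  idx <- matrix(0L, p * p, P * P)
  within <- as.vector(outer(seq_len(p), (seq_len(p) - 1L) * S, "+")) # col-major p x p block at (1,1)
  for (r in 0:(P - 1L)) {
    for (cc in 0:(P - 1L)) {
      i <- r * P + cc
      idx[, i + 1L] <- within + r * p + cc * p * S
    }
  }
  .patchIndexCache[[key]] <- idx
  idx
}

## n_patches x p^2 matrix of flattened patches (row i+1 = patch i).
.patchMatrix <- function(img, p) {
  S <- nrow(img)
  idx <- .patchIndices(S, p)
  t(matrix(img[idx], nrow = nrow(idx)))
}

#' Partition a square image into non-overlapping patches
#'
#' Cuts an `S x S` image into a `P x P` grid of `p x p` patches, `P = S / p`.
#' Patch `i` (0-based, row-major, origin top-left) covers image rows
#' `[r*p, (r+1)*p)` and columns `[c*p, (c+1)*p)` with `i = r*P + c`. The
#' tiling is exact and non-overlapping; [assembleImage()] inverts it
#' bit-exactly.
#'
#' @param img numeric `S x S` matrix, intensities in `[0, 1]`.
#' @param patchSide patch side `p`; must divide `S`.
#' @return a [PatchGrid-class].
#' @examples
#' g <- partitionImage(matrix(runif(16), 4, 4), 2)
#' @export
partitionImage <- function(img, patchSide) {
  S <- .checkGrayImage(img)
  p <- as.integer(patchSide)
  if (p < 1L) stop("patchSide must be >= 1")
  if (S %% p != 0L)
    stop("image side ", S, " is not divisible by patch side ", p)
  P <- S %/% p
  pm <- .patchMatrix(img, p)
  new("PatchGrid",
    patches = array(t(pm), dim = c(p, p, P * P)),
    gridSide = P, patchSide = p, imageSide = S)
}

#' Reassemble an image from a patch grid
#'
#' Exact inverse of [partitionImage()].
#'
#' @param grid a [PatchGrid-class].
#' @return the `S x S` numeric matrix the grid tiles.
#' @export
assembleImage <- function(grid) {
  stopifnot(is(grid, "PatchGrid"))
  S <- grid@imageSide
  p <- grid@patchSide
  img <- matrix(NA_real_, S, S)
  idx <- .patchIndices(S, p)
  for (i in seq_len(dim(grid@patches)[3]))
    img[idx[, i]] <- grid@patches[, , i]
  img
}

#' Encode every patch of a grid independently
#'
#' Applies the shared encoder to each patch; row `i + 1` of the result is the
#' logit vector of patch `i`. Patches are evaluated as one batch but the
#' result is independent of batching or evaluation order (the encoder
#' contract forbids positional inputs and cross-patch state).
#'
#' @param grid a [PatchGrid-class].
#' @param encoder a [PatchEncoder-class].
#' @return a [PatchLogitField-class] with `source = "raw"`.
#' @export
encodePatches <- function(grid, encoder) {
  stopifnot(is(grid, "PatchGrid"), is(encoder, "PatchEncoder"))
  n <- dim(grid@patches)[3]
  x <- t(matrix(grid@patches, nrow = grid@patchSide^2, ncol = n))
  lg <- encoderLogits(encoder, x)
  if (ncol(lg) != nLabels(encoder))
    stop("encoder produced ", ncol(lg), " logits per patch, expected ",
      nLabels(encoder))
  new("PatchLogitField", logits = unname(lg), labels = labelNames(encoder),
    gridSide = grid@gridSide, patchSide = grid@patchSide, source = "raw")
}

#' Aggregate patch logits into the image-level prediction
#'
#' The global logit vector is the fixed arithmetic mean of the patch logit
#' rows, `Z = mean_i z_i`; the class probabilities are `sigmoid(Z)`. The
#' sigmoid is applied after averaging, never per patch, so no patch's
#' influence on the global logit is squashed.
#'
#' @param field a [PatchLogitField-class] (raw source).
#' @return a [GlobalPrediction-class].
#' @examples
#' f <- new("PatchLogitField", logits = matrix(c(1, -1, 2, -2), 4, 1),
#'   labels = "x", gridSide = 2L, patchSide = 1L, source = "raw")
#' aggregateLogits(f) # Z = 0, probability 0.5
#' @export
aggregateLogits <- function(field) {
  stopifnot(is(field, "PatchLogitField"))
  if (nrow(field@logits) == 0L) stop("empty logit field")
  bad <- which(!is.finite(field@logits), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-finite logit at patch index ", bad[1, 1] - 1L,
      " (label ", field@labels[bad[1, 2]], ")")
  Z <- colMeans(field@logits)
  new("GlobalPrediction", globalLogits = unname(Z),
    probabilities = .sigmoid(unname(Z)), labels = field@labels)
}

#' Probability-scaled patch logits
#'
#' Multiplies each patch logit elementwise by the image-level probability of
#' the same class: `scaled[i, k] = probability[k] * logits[i, k]`. This
#' injects a limited amount of global context into the per-patch attribution
#' while preserving each logit's sign (probabilities are strictly positive).
#'
#' @param field the raw [PatchLogitField-class].
#' @param prediction the [GlobalPrediction-class] derived from `field`.
#' @return a [PatchLogitField-class] with `source = "scaled"`.
#' @export
scalePatchLogits <- function(field, prediction) {
  stopifnot(is(field, "PatchLogitField"), is(prediction, "GlobalPrediction"))
  if (nLabels(field) != nLabels(prediction))
    stop("field has ", nLabels(field), " labels, prediction has ",
      nLabels(prediction))
  new("PatchLogitField",
    logits = sweep(field@logits, 2L, prediction@probabilities, "*"),
    labels = field@labels, gridSide = field@gridSide,
    patchSide = field@patchSide, source = "scaled")
}

#' Full forward pass: partition, encode, aggregate
#'
#' Composition of [partitionImage()], [encodePatches()] and
#' [aggregateLogits()]. With `patchSide` equal to the image side the model
#' degenerates to a plain image-level classifier: one patch, whose logits are
#' the global logits.
#'
#' @param img numeric `S x S` matrix in `[0, 1]`.
#' @param encoder a [PatchEncoder-class].
#' @param patchSide patch side `p` dividing `S`.
#' @return list with elements `prediction` ([GlobalPrediction-class]) and
#'   `field` (raw [PatchLogitField-class]).
#' @export
patchForward <- function(img, encoder, patchSide) {
  grid <- partitionImage(img, patchSide)
  field <- encodePatches(grid, encoder)
  list(prediction = aggregateLogits(field), field = field)
}
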
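## Saliency: the patch logits ARE the explanation. A block-constant map paints
## each patch with its logit for one label; shift-and-average smoothing
## translates the image over a sub-patch grid of offsets, recomputes the block
## map for each translate, aligns the maps back and averages them pixelwise.

#' Block-constant saliency map from a logit field
#'
#' Pixel `(y, x)` holds the chosen label's logit of the patch containing it
#' (patch row `floor(y/p)`, column `floor(x/p)`, 0-based); no interpolation.
#' Works on raw or probability-scaled fields. For a raw field, the pixel mean
#' of the map equals the global logit `Z[label]` exactly (block structure +
#' mean aggregation).
#'
#' @param field a [PatchLogitField-class], raw or scaled.
#' @param label label name or 1-based column index.
#' @param imageSide image side `S`; defaults to `p * P` from the field.
#' @return a [SaliencyMap-class] with `offset = p`.
#' @export
patchMap <- function(field, label, imageSide = NULL) {
  stopifnot(is(field, "PatchLogitField"))
  k <- .labelIndex(field@labels, label)
  p <- field@patchSide
  P <- field@gridSide
  S <- if (is.null(imageSide)) p * P else as.integer(imageSide)
  if (S != p * P)
    stop("imageSide ", S, " inconsistent with field geometry ", p, " x ", P)
  ## patch index (0-based row-major) laid out as a P x P matrix, expanded
  blocks <- matrix(field@logits[, k], nrow = P, ncol = P, byrow = TRUE)
  vals <- blocks[rep(seq_len(P), each = p), rep(seq_len(P), each = p)]
  new("SaliencyMap", values = unname(vals), label = field@labels[k],
    source = field@source, offset = p)
}

.labelIndex <- function(labels, label) {
  if (is.numeric(label)) {
    k <- as.integer(label)
    if (k < 1L || k > length(labels))
      stop("label index ", k, " out of range 1..", length(labels))
    return(k)
  }
  k <- match(label, labels)
  if (is.na(k)) stop("unknown label '", label, "'")
  k
}

#' Shift-and-average smoothed saliency map
#'
#' For each offset pair `(dy, dx)` in `{0, o, 2o, ..., p - o}^2` the patch
#' grid is shifted up-left by `(dy, dx)` over the zero-padded image (one
#' extra row and column of border patches keep every original pixel covered),
#' one forward pass encodes the shifted grid, the resulting block map is read
#' off in original image coordinates, and the `(p/o)^2` aligned maps are
#' averaged pixelwise with no border renormalization. `o = p` reproduces
#' [patchMap()] exactly (a single, unshifted grid); `o = 1` costs `p^2`
#' forward passes. For the scaled source, the image-level probabilities are
#' recomputed for every shift from the core (non-border) patches -- the
#' forward pass of the translated image -- since scaled logits are defined
#' per forward pass.
#'
#' @param img numeric `S x S` matrix in `[0, 1]`.
#' @param encoder a [PatchEncoder-class].
#' @param patchSide patch side `p`.
#' @param offset shift offset `o`; must divide `p`, `1 <= o <= p`.
#' @param label label name or index.
#' @param source `"raw"` or `"scaled"` patch logits.
#' @return a [SaliencyMap-class].
#' @export
shiftedSaliency <- function(img, encoder, patchSide, offset, label,
                            source = c("raw", "scaled")) {
  source <- match.arg(source)
  maps <- shiftedSaliencyStack(img, encoder, patchSide, offset, source)
  k <- .labelIndex(labelNames(encoder), label)
  new("SaliencyMap", values = maps[, , k], label = labelNames(encoder)[k],
    source = source, offset = as.integer(offset))
}

#' Smoothed saliency maps for all labels at once
#'
#' Same computation as [shiftedSaliency()] but returns the full `S x S x C`
#' stack, sharing the `(p/o)^2` forward passes across labels.
#'
#' @inheritParams shiftedSaliency
#' @return numeric array `S x S x C` (third dimension named by label).
#' @export
shiftedSaliencyStack <- function(img, encoder, patchSide, offset,
                                 source = c("raw", "scaled")) {
  source <- match.arg(source)
  S <- .checkGrayImage(img)
  p <- as.integer(patchSide)
  o <- as.integer(offset)
  if (o < 1L || o > p || p %% o != 0L)
    stop("offset ", o, " must divide patch side ", p, " (1 <= o <= p)")
  C <- nLabels(encoder)
  P <- S %/% p
  shifts <- seq(0L, p - o, by = o)
  Spad <- (P + 1L) * p
  ## core patches (grid row/col 0..P-1) of the padded grid are exactly the
  ## patches of the zero-padded translated image; border patches (index P)
  ## recover the content the translation pushes over the edge
  core <- as.vector(outer(0:(P - 1L) * (P + 1L), 0:(P - 1L), "+")) + 1L
  acc <- array(0, dim = c(S, S, C))
  for (dy in shifts) {
    for (dx in shifts) {
      pimg <- matrix(0, Spad, Spad)
      pimg[(dy + 1L):(dy + S), (dx + 1L):(dx + S)] <- img
      field <- encodePatches(partitionImage(pimg, p), encoder)
      lg <- field@logits
      if (source == "scaled") {
        Zcore <- colMeans(lg[core, , drop = FALSE])
        lg <- sweep(lg, 2L, .sigmoid(Zcore), "*")
      }
      for (k in seq_len(C)) {
        blocks <- matrix(lg[, k], nrow = P + 1L, ncol = P + 1L, byrow = TRUE)
        full <- blocks[rep(seq_len(P + 1L), each = p), rep(seq_len(P + 1L), each = p)]
        acc[, , k] <- acc[, , k] +
          full[(dy + 1L):(dy + S), (dx + 1L):(dx + S)]
      }
    }
  }
  acc <- acc / length(shifts)^2
  dimnames(acc) <- list(NULL, NULL, labelNames(encoder))
  acc
}

#' Render a saliency overlay image
#'
#' Blends the grayscale image with a diverging colormap centered at zero:
#' positive saliency tints red (evidence for the label), negative tints blue
#' (evidence against), near-zero values stay nearly transparent. The color
#' scale is symmetric about zero and anchored at `max |value|` of this map.
#'
#' @param img numeric `S x S` matrix in `[0, 1]`.
#' @param map a [SaliencyMap-class] of matching size.
#' @param path output PNG path.
#' @param maxAlpha peak blend weight at `|value| = max |value|`.
#' @return `path`, invisibly.
#' @export
renderOverlay <- function(img, map, path, maxAlpha = 0.6) {
  S <- .checkGrayImage(img)
  v <- if (is(map, "SaliencyMap")) map@values else map
  if (!all(dim(v) == c(S, S))) stop("saliency map and image sizes differ")
  M <- max(abs(v))
  w <- if (M > 0) v / M else v * 0
  alpha <- abs(w) * maxAlpha
  pos <- pmax(w, 0)
  neg <- pmax(-w, 0)
  colR <- 1 - neg
  colG <- 1 - pos - neg
  colB <- 1 - pos
  rgb <- array(0, dim = c(S, S, 3))
  rgb[, , 1] <- (1 - alpha) * img + alpha * colR
  rgb[, , 2] <- (1 - alpha) * img + alpha * colG
  rgb[, , 3] <- (1 - alpha) * img + alpha * colB
  ok <- tryCatch({
    png::writePNG(rgb, target = path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write overlay to '", path, "': ",
    conditionMessage(ok))
  invisible(path)
}

#' Serialize a saliency map to portable JSON
#'
#' Writes the side length, source, offset, label and the row-major pixel
#' values with full double precision.
#'
#' @param map a [SaliencyMap-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSaliencyMap <- function(map, path) {
  stopifnot(is(map, "SaliencyMap"))
  obj <- list(side = nrow(map@values), label = map@label,
    source = map@source, offset = map@offset,
    values = as.vector(t(map@values)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a saliency map written by [writeSaliencyMap()]
#'
#' @param path input path.
#' @return a [SaliencyMap-class].
#' @export
readSaliencyMap <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  S <- as.integer(obj$side)
  new("SaliencyMap",
    values = matrix(as.numeric(obj$values), S, S, byrow = TRUE),
    label = as.character(obj$label), source = as.character(obj$source),
    offset = as.integer(obj$offset))
}
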
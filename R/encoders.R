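#' Create a trainable perceptron patch encoder
#'
#' Builds an [MLPEncoder-class] with He-scaled Gaussian initialization, the
#' bundled trainable backbone for desk-scale experiments. Inputs are centered
#' by a fixed -0.5 shift (intensities live in `[0, 1]`) before the first
#' layer. Any architecture honoring the patch-encoder contract (shared
#' weights, no positional input) can stand in its place; the aggregation
#' arithmetic does not depend on the encoder family.
#'
#' @param patchSide patch side length `p` in pixels.
#' @param labels character vector of class names (its length sets `C`).
#' @param hidden hidden-layer width.
#' @param seed integer seed for weight initialization.
#' @return an [MLPEncoder-class].
#' @examples
#' enc <- mlpEncoder(16, c("a", "b"), hidden = 8, seed = 1)
#' encoderLogits(enc, matrix(runif(3 * 256), 3, 256))
#' @export
mlpEncoder <- function(patchSide, labels, hidden = 24L, seed = 1L) {
  patchSide <- as.integer(patchSide)
  stopifnot(patchSide >= 1L, hidden >= 1L, length(labels) >= 1L)
  d <- patchSide^2
  C <- length(labels)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  new("MLPEncoder",
    W1 = matrix(stats::rnorm(d * hidden, sd = sqrt(2 / d)), d, hidden),
    b1 = numeric(hidden),
    W2 = matrix(stats::rnorm(hidden * C, sd = sqrt(2 / hidden)), hidden, C),
    b2 = numeric(C),
    patchSide = patchSide,
    labels = as.character(labels))
}

#' Create a trainable tiny convolutional patch encoder
#'
#' Builds a [CNNEncoder-class]: one valid square convolution (window `kernel`,
#' given `stride`, `filters` output channels) with ReLU over the patch-mean
#' centered pixels, then a dense logit head over all positions and filters
#' plus the patch mean itself as one extra feature. He-scaled Gaussian
#' initialization, deterministic given `seed`.
#'
#' @param patchSide patch side `p` in pixels.
#' @param labels character vector of class names.
#' @param filters number of convolution filters.
#' @param kernel convolution window side.
#' @param stride convolution stride.
#' @param seed integer seed for weight initialization.
#' @return a [CNNEncoder-class].
#' @export
cnnEncoder <- function(patchSide, labels, filters = 12L, kernel = 5L,
                       stride = 2L, seed = 1L) {
  patchSide <- as.integer(patchSide)
  kernel <- as.integer(kernel)
  stride <- as.integer(stride)
  stopifnot(patchSide >= kernel, kernel >= 1L, stride >= 1L, filters >= 1L)
  nPos <- (patchSide - kernel) %/% stride + 1L
  C <- length(labels)
  k2 <- kernel^2
  nf <- nPos^2 * filters + 1L  # +1: the patch-mean intensity feature
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  new("CNNEncoder",
    Wc = matrix(stats::rnorm(k2 * filters, sd = sqrt(2 / k2)), k2, filters),
    bc = numeric(filters),
    Wd = matrix(stats::rnorm(nf * C, sd = sqrt(2 / nf)), nf, C),
    bd = numeric(C),
    patchSide = patchSide, kernel = kernel, stride = stride,
    labels = as.character(labels))
}

## Convolution geometry: for each output position, the column-major linear
## indices of its k x k input window within the flattened p x p patch.
## Output positions are ordered column-major over (row, col) offsets.
.convGeomCache <- new.env(parent = emptyenv())

.convGeometry <- function(p, k, stride) {
  key <- paste(p, k, stride, sep = "/")
  hit <- .convGeomCache[[key]]
  if (!is.null(hit)) return(hit)
  nPos <- (p - k) %/% stride + 1L
  win <- as.vector(outer(seq_len(k), (seq_len(k) - 1L) * p, "+"))  # window at (1,1)
  offs <- (seq_len(nPos) - 1L) * stride
  idxMap <- matrix(0L, k * k, nPos^2)
  pos <- 0L
  for (ox in offs) {       # column offset (column-major position order)
    for (oy in offs) {     # row offset
      pos <- pos + 1L
      idxMap[, pos] <- win + oy + ox * p
    }
  }
  out <- list(nPos = nPos, idxMap = idxMap)
  .convGeomCache[[key]] <- out
  out
}

setMethod("encoderLogits", "CNNEncoder", function(encoder, x) {
  stopifnot(is.matrix(x))
  if (ncol(x) != encoder@patchSide^2)
    stop("patch dimension ", ncol(x), " does not match encoder input ",
      encoder@patchSide^2)
  geo <- .convGeometry(encoder@patchSide, encoder@kernel, encoder@stride)
  n <- nrow(x)
  k2 <- encoder@kernel^2
  np2 <- geo$nPos^2
  mu <- rowMeans(x)
  A <- array((x - mu)[, as.vector(geo$idxMap)], c(n, k2, np2))
  B2 <- matrix(aperm(A, c(1, 3, 2)), n * np2, k2)
  H <- sweep(B2 %*% encoder@Wc, 2L, encoder@bc, "+")
  H[H < 0] <- 0
  dim(H) <- c(n, np2 * ncol(encoder@Wc))
  out <- sweep(cbind(H, mu - 0.5) %*% encoder@Wd, 2L, encoder@bd, "+")
  colnames(out) <- encoder@labels
  out
})

setMethod("show", "CNNEncoder", function(object) {
  geo <- .convGeometry(object@patchSide, object@kernel, object@stride)
  cat(sprintf(
    "CNNEncoder: %d x %d patch -> conv %dx%d/%d x%d (%d positions) -> %d labels\n",
    object@patchSide, object@patchSide, object@kernel, object@kernel,
    object@stride, ncol(object@Wc), geo$nPos^2, nLabels(object)))
})

#' Wrap a function as a patch encoder
#'
#' @param fun encoding function; see [FunEncoder-class] for the calling
#'   conventions.
#' @param labels character vector of class names.
#' @param vectorized if `TRUE`, `fun` receives the whole flattened-patch batch
#'   matrix at once.
#' @return a [FunEncoder-class].
#' @examples
#' constEnc <- funEncoder(function(patch) c(1, -1), c("pos", "neg"))
#' @export
funEncoder <- function(fun, labels, vectorized = FALSE) {
  new("FunEncoder", fun = fun, labels = as.character(labels),
    vectorized = isTRUE(vectorized))
}

setMethod("encoderLogits", "MLPEncoder", function(encoder, x) {
  stopifnot(is.matrix(x))
  if (ncol(x) != nrow(encoder@W1))
    stop("patch dimension ", ncol(x), " does not match encoder input ",
      nrow(encoder@W1))
  h <- (x - 0.5) %*% encoder@W1
  h <- sweep(h, 2L, encoder@b1, "+")
  h[h < 0] <- 0
  out <- h %*% encoder@W2
  out <- sweep(out, 2L, encoder@b2, "+")
  colnames(out) <- encoder@labels
  out
})

setMethod("encoderLogits", "FunEncoder", function(encoder, x) {
  stopifnot(is.matrix(x))
  C <- nLabels(encoder)
  if (encoder@vectorized) {
    out <- encoder@fun(x)
    if (!is.matrix(out) || nrow(out) != nrow(x) || ncol(out) != C)
      stop("vectorized encoder must return an n x ", C, " matrix")
  } else {
    p <- as.integer(round(sqrt(ncol(x))))
    if (p * p != ncol(x)) stop("flattened patches must be square")
    out <- matrix(NA_real_, nrow(x), C)
    for (i in seq_len(nrow(x))) {
      v <- encoder@fun(matrix(x[i, ], p, p))
      if (length(v) != C)
        stop("encoder returned ", length(v), " logits, expected ", C)
      out[i, ] <- as.numeric(v)
    }
  }
  colnames(out) <- encoder@labels
  out
})

## RNG bookkeeping: constructors and generators that seed internally must not
## disturb the caller's RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Derive a reproducible sub-stream seed
#'
#' All randomness in a run flows from one top-level seed; named sub-streams
#' (data generation, augmentation, initialization, bootstrap) get distinct
#' deterministic seeds so components are individually reproducible.
#'
#' @param seed top-level integer seed.
#' @param stream character stream name.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
deriveSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h * 9973) %% 2147483647)
}

#' Serialize an encoder to a portable JSON checkpoint
#'
#' Weights are written as plain JSON arrays with full double precision, plus a
#' small header (class, labels, patch side), so checkpoints are text and
#' portable across platforms.
#'
#' @param encoder an [MLPEncoder-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
saveEncoder <- function(encoder, path) {
  if (is(encoder, "MLPEncoder")) {
    obj <- list(
      class = "MLPEncoder",
      labels = encoder@labels,
      patchSide = encoder@patchSide,
      W1 = encoder@W1, b1 = encoder@b1,
      W2 = encoder@W2, b2 = encoder@b2)
  } else if (is(encoder, "CNNEncoder")) {
    obj <- list(
      class = "CNNEncoder",
      labels = encoder@labels,
      patchSide = encoder@patchSide,
      kernel = encoder@kernel, stride = encoder@stride,
      Wc = encoder@Wc, bc = encoder@bc,
      Wd = encoder@Wd, bd = encoder@bd)
  } else {
    stop("only MLPEncoder and CNNEncoder checkpoints are supported")
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
    matrix = "rowmajor")
  invisible(path)
}

#' Load an encoder checkpoint written by [saveEncoder()]
#'
#' @param path checkpoint file path.
#' @return an [MLPEncoder-class].
#' @export
loadEncoder <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  asMat <- function(m) { storage.mode(m) <- "double"; m }
  if (identical(obj$class, "MLPEncoder")) {
    new("MLPEncoder",
      W1 = asMat(obj$W1), b1 = as.numeric(obj$b1),
      W2 = asMat(obj$W2), b2 = as.numeric(obj$b2),
      patchSide = as.integer(obj$patchSide),
      labels = as.character(obj$labels))
  } else if (identical(obj$class, "CNNEncoder")) {
    new("CNNEncoder",
      Wc = asMat(obj$Wc), bc = as.numeric(obj$bc),
      Wd = asMat(obj$Wd), bd = as.numeric(obj$bd),
      patchSide = as.integer(obj$patchSide),
      kernel = as.integer(obj$kernel), stride = as.integer(obj$stride),
      labels = as.character(obj$labels))
  } else {
    stop("unsupported checkpoint class: ", obj$class)
  }
}
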
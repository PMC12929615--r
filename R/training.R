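## Weakly supervised training: the loss is multi-label binary cross-entropy
## on the image-level (global) outputs only -- no per-patch supervision, no
## masks. Gradients reach every patch through the shared encoder parameters
## and the fixed mean aggregation.

#' Training configuration
#'
#' @param epochs passes over the training set.
#' @param batchSize images per optimization step `B` (the encoder sees
#'   `B * P^2` patches per step).
#' @param peakLR peak learning rate of the one-cycle schedule.
#' @param warmupFrac fraction of total steps spent ramping linearly from 0 to
#'   `peakLR`; the remainder anneals with a cosine to `peakLR / 100`.
#' @param weightDecay decoupled (AdamW) weight-decay coefficient.
#' @param betas AdamW moment coefficients.
#' @param eps AdamW denominator stabilizer.
#' @param seed seed controlling shuffling and augmentation draws.
#' @param augment an [augmentConfig()] list, or `NULL` to train on the raw
#'   images.
#' @return validated configuration list.
#' @export
trainConfig <- function(epochs = 20L, batchSize = 16L, peakLR = 1e-4,
                        warmupFrac = 0.05, weightDecay = 1e-4,
                        betas = c(0.9, 0.999), eps = 1e-8, seed = 1L,
                        augment = augmentConfig()) {
  stopifnot(epochs >= 0L, batchSize >= 1L, peakLR > 0,
    warmupFrac > 0, warmupFrac < 1, weightDecay >= 0,
    length(betas) == 2L, all(betas > 0 & betas < 1))
  list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
    peakLR = peakLR, warmupFrac = warmupFrac, weightDecay = weightDecay,
    betas = betas, eps = eps, seed = as.integer(seed), augment = augment)
}

#' Augmentation configuration
#'
#' Random square crop covering a uniform fraction of the image area, resized
#' back to full size; rotation by a uniform angle; multiplicative brightness
#' with clipping to `[0, 1]`.
#'
#' @param cropRange area-fraction range of the random square crop.
#' @param rotRange rotation range in degrees.
#' @param brightRange multiplicative brightness factor range.
#' @return validated configuration list.
#' @export
augmentConfig <- function(cropRange = c(0.5, 1.0), rotRange = c(-5, 5),
                          brightRange = c(0.7, 1.3)) {
  stopifnot(length(cropRange) == 2L, cropRange[1] > 0, cropRange[2] <= 1,
    cropRange[1] <= cropRange[2], length(rotRange) == 2L,
    rotRange[1] <= rotRange[2], length(brightRange) == 2L,
    brightRange[1] > 0, brightRange[1] <= brightRange[2])
  list(cropRange = cropRange, rotRange = rotRange, brightRange = brightRange)
}

#' Randomly augment a grayscale image
#'
#' Crop -> resize -> rotate -> brightness -> clip, in that order. Crop and
#' rotation resampling are bilinear; rotation fills uncovered corners with
#' zeros. Consumes the current RNG stream, so results are deterministic given
#' the RNG state.
#'
#' @param img numeric `S x S` matrix in `[0, 1]`.
#' @param cfg an [augmentConfig()] list.
#' @return augmented `S x S` matrix in `[0, 1]`.
#' @export
augmentImage <- function(img, cfg = augmentConfig()) {
  S <- .checkGrayImage(img)
  frac <- stats::runif(1, cfg$cropRange[1], cfg$cropRange[2])
  side <- max(2L, round(S * sqrt(frac)))
  side <- min(side, S)
  y0 <- sample.int(S - side + 1L, 1L)
  x0 <- sample.int(S - side + 1L, 1L)
  out <- img[y0:(y0 + side - 1L), x0:(x0 + side - 1L)]
  if (side != S)
    out <- EBImage::imageData(EBImage::resize(out, w = S, h = S,
      filter = "bilinear"))
  ang <- stats::runif(1, cfg$rotRange[1], cfg$rotRange[2])
  if (ang != 0)
    out <- EBImage::imageData(EBImage::rotate(out, ang, filter = "bilinear",
      output.dim = c(S, S), bg.col = 0))
  bf <- stats::runif(1, cfg$brightRange[1], cfg$brightRange[2])
  out <- out * bf
  out[out < 0] <- 0
  out[out > 1] <- 1
  matrix(out, S, S)
}

#' One-cycle learning rate
#'
#' Linear warmup from 0 to the peak over the first `warmupFrac` of steps,
#' then cosine annealing to `peakLR / 100`.
#'
#' @param step 1-based step number.
#' @param totalSteps total optimization steps.
#' @param peakLR peak learning rate.
#' @param warmupFrac warmup fraction.
#' @return learning rate for `step`.
#' @export
oneCycleLR <- function(step, totalSteps, peakLR, warmupFrac) {
  warm <- max(1, ceiling(warmupFrac * totalSteps))
  if (step <= warm) return(peakLR * step / warm)
  floorLR <- peakLR / 100
  prog <- (step - warm) / max(1, totalSteps - warm)
  floorLR + (peakLR - floorLR) * (1 + cos(pi * prog)) / 2
}

## ---------------------------------------------------------------------------
## Trainable-encoder internals. Each trainable encoder family provides a
## caching forward pass and a backprop step; the trainer and AdamW are
## generic over the named parameter slots (names starting with "W" receive
## decoupled weight decay).
## ---------------------------------------------------------------------------

setGeneric(".trainForward", function(enc, X) standardGeneric(".trainForward"))
setGeneric(".trainBackward", function(enc, fwd, X, dL)
  standardGeneric(".trainBackward"))
setGeneric(".paramSlots", function(enc) standardGeneric(".paramSlots"))

setMethod(".paramSlots", "MLPEncoder", function(enc) c("W1", "b1", "W2", "b2"))

## Inputs are centered by the encoder's fixed -0.5 shift.
setMethod(".trainForward", "MLPEncoder", function(enc, X) {
  H <- sweep((X - 0.5) %*% enc@W1, 2L, enc@b1, "+")
  H[H < 0] <- 0
  L <- sweep(H %*% enc@W2, 2L, enc@b2, "+")
  list(H = H, L = L)
})

setMethod(".trainBackward", "MLPEncoder", function(enc, fwd, X, dL) {
  dW2 <- crossprod(fwd$H, dL)
  db2 <- colSums(dL)
  dH <- dL %*% t(enc@W2)
  dH[fwd$H <= 0] <- 0
  dW1 <- crossprod(X - 0.5, dH)
  db1 <- colSums(dH)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
})

setMethod(".paramSlots", "CNNEncoder", function(enc) c("Wc", "bc", "Wd", "bd"))

## The patch is centered by its own mean before the convolution (removing the
## smooth background-intensity nuisance); the mean itself re-enters the dense
## head as one extra feature so absolute brightness stays visible.
setMethod(".trainForward", "CNNEncoder", function(enc, X) {
  geo <- .convGeometry(enc@patchSide, enc@kernel, enc@stride)
  n <- nrow(X)
  k2 <- enc@kernel^2
  np2 <- geo$nPos^2
  mu <- rowMeans(X)
  A <- array((X - mu)[, as.vector(geo$idxMap)], c(n, k2, np2))
  B2 <- matrix(aperm(A, c(1, 3, 2)), n * np2, k2)
  H <- sweep(B2 %*% enc@Wc, 2L, enc@bc, "+")
  H[H < 0] <- 0
  Hm <- H
  dim(Hm) <- c(n, np2 * ncol(enc@Wc))
  Feat <- cbind(Hm, mu - 0.5)
  L <- sweep(Feat %*% enc@Wd, 2L, enc@bd, "+")
  list(B2 = B2, H = H, Feat = Feat, L = L, n = n, np2 = np2)
})

setMethod(".trainBackward", "CNNEncoder", function(enc, fwd, X, dL) {
  dWd <- crossprod(fwd$Feat, dL)
  dbd <- colSums(dL)
  dFeat <- dL %*% t(enc@Wd)
  dH <- dFeat[, -ncol(dFeat), drop = FALSE]
  dim(dH) <- c(fwd$n * fwd$np2, ncol(enc@Wc))
  dH[fwd$H <= 0] <- 0
  dWc <- crossprod(fwd$B2, dH)
  dbc <- colSums(dH)
  list(Wc = dWc, bc = dbc, Wd = dWd, bd = dbd)
})

## Mean-aggregated BCE loss and parameter gradients for one batch.
## X: (B*P2) x p^2 patch rows grouped image-major; Y: B x C labels.
.batchGradients <- function(enc, X, Y, P2) {
  B <- nrow(Y)
  fwd <- .trainForward(enc, X)
  grp <- rep(seq_len(B), each = P2)
  Z <- rowsum(fwd$L, grp) / P2                     # B x C global logits
  ## stable BCE from logits, mean over images and labels
  loss <- mean(pmax(Z, 0) - Z * Y + log1p(exp(-abs(Z))))
  dZ <- (matrix(.sigmoid(as.vector(Z)), B) - Y) / (B * ncol(Y))
  dL <- dZ[grp, , drop = FALSE] / P2               # (B*P2) x C
  grads <- .trainBackward(enc, fwd, X, dL)
  list(loss = loss, grads = grads, Z = Z)
}

.adamwInit <- function(enc) {
  nms <- .paramSlots(enc)
  zero <- lapply(nms, function(nm) slot(enc, nm) * 0)
  names(zero) <- nms
  list(m = zero, v = zero, t = 0L)
}

.adamwStep <- function(enc, grads, st, lr, cfg) {
  st$t <- st$t + 1L
  b1 <- cfg$betas[1]; b2 <- cfg$betas[2]
  for (nm in .paramSlots(enc)) {
    grad <- grads[[nm]]
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * grad
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * grad^2
    mhat <- st$m[[nm]] / (1 - b1^st$t)
    vhat <- st$v[[nm]] / (1 - b2^st$t)
    wd <- if (startsWith(nm, "W")) cfg$weightDecay else 0
    slot(enc, nm) <- slot(enc, nm) -
      lr * (mhat / (sqrt(vhat) + cfg$eps) + wd * slot(enc, nm))
  }
  list(enc = enc, st = st)
}

#' Train a patch encoder from image-level labels
#'
#' Per step: optionally augment each image, cut it into patches, run the
#' shared encoder on the whole patch batch, average the patch logits per
#' image into global logits, and backpropagate the multi-label binary
#' cross-entropy between `sigmoid(Z)` and the labels -- computed on the
#' global outputs only -- through the shared parameters with AdamW under a
#' one-cycle schedule. Fully seeded: equal seeds and configs reproduce equal
#' loss curves.
#'
#' @param images list of `S x S` matrices in `[0, 1]`.
#' @param labels `n x C` 0/1 matrix (columns named by label).
#' @param encoder a trainable encoder ([MLPEncoder-class] or
#'   [CNNEncoder-class]; its `patchSide` sets `p`).
#' @param cfg a [trainConfig()] list.
#' @param valImages,valLabels optional held-out set; when given, the history
#'   records label-mean validation AUROC per epoch.
#' @return list: `encoder` (trained), `history` (data.frame with epoch, mean
#'   loss, validation AUROC).
#' @export
trainEncoder <- function(images, labels, encoder, cfg = trainConfig(),
                         valImages = NULL, valLabels = NULL) {
  stopifnot(is(encoder, "PatchEncoder"), is.list(images), is.matrix(labels))
  if (!existsMethod(".paramSlots", class(encoder)))
    stop(class(encoder), " is not trainable")
  n <- length(images)
  if (nrow(labels) != n) stop("images and labels disagree in length")
  if (ncol(labels) != nLabels(encoder))
    stop("label matrix has ", ncol(labels), " columns, encoder expects ",
      nLabels(encoder))
  p <- encoder@patchSide
  S <- nrow(images[[1]])
  if (S %% p != 0L) stop("image side ", S, " not divisible by patch side ", p)
  P2 <- (S %/% p)^2
  history <- data.frame(epoch = integer(0), loss = numeric(0),
    val_auroc = numeric(0))
  if (cfg$epochs == 0L)
    return(list(encoder = encoder, history = history))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  stepsPerEpoch <- ceiling(n / cfg$batchSize)
  totalSteps <- stepsPerEpoch * cfg$epochs
  st <- .adamwInit(encoder)
  step <- 0L
  ## without augmentation the patch decomposition is fixed; extract it once
  patchCache <- if (is.null(cfg$augment))
    lapply(images, .patchMatrix, p = p)
  else NULL
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    epLoss <- 0; nb <- 0L
    for (b0 in seq(1L, n, by = cfg$batchSize)) {
      idx <- ord[b0:min(b0 + cfg$batchSize - 1L, n)]
      B <- length(idx)
      if (is.null(patchCache)) {
        X <- matrix(0, B * P2, p * p)
        for (j in seq_len(B)) {
          im <- augmentImage(images[[idx[j]]], cfg$augment)
          X[((j - 1L) * P2 + 1L):(j * P2), ] <- .patchMatrix(im, p)
        }
      } else {
        X <- do.call(rbind, patchCache[idx])
      }
      Y <- labels[idx, , drop = FALSE]
      g <- .batchGradients(encoder, X, Y, P2)
      step <- step + 1L
      lr <- oneCycleLR(step, totalSteps, cfg$peakLR, cfg$warmupFrac)
      upd <- .adamwStep(encoder, g$grads, st, lr, cfg)
      encoder <- upd$enc; st <- upd$st
      epLoss <- epLoss + g$loss; nb <- nb + 1L
    }
    va <- NA_real_
    if (!is.null(valImages)) {
      sc <- predictImages(valImages, encoder)
      va <- mean(vapply(seq_len(ncol(valLabels)), function(k) {
        a <- suppressWarnings(aurocScore(sc$probabilities[, k], valLabels[, k]))
        a
      }, numeric(1)), na.rm = TRUE)
    }
    history <- rbind(history,
      data.frame(epoch = ep, loss = epLoss / nb, val_auroc = va))
  }
  list(encoder = encoder, history = history)
}

#' Predict image-level probabilities for a set of images
#'
#' @param images list of `S x S` matrices.
#' @param encoder a trained [PatchEncoder-class] with a `patchSide` slot, or
#'   any encoder with `patchSide` given explicitly.
#' @param patchSide patch side; defaults to the encoder's own.
#' @return list with `probabilities` and `logits`, both `n x C` matrices with
#'   label column names.
#' @export
predictImages <- function(images, encoder, patchSide = NULL) {
  if (is.null(patchSide)) {
    if (!.hasMethod_patchSide(encoder))
      stop("patchSide must be given for this encoder")
    patchSide <- encoder@patchSide
  }
  C <- nLabels(encoder)
  n <- length(images)
  Z <- matrix(NA_real_, n, C, dimnames = list(NULL, labelNames(encoder)))
  for (i in seq_len(n)) {
    fwd <- patchForward(images[[i]], encoder, patchSide)
    Z[i, ] <- globalLogits(fwd$prediction)
  }
  list(probabilities = matrix(.sigmoid(as.vector(Z)), n, C,
    dimnames = dimnames(Z)), logits = Z)
}

.hasMethod_patchSide <- function(encoder) {
  "patchSide" %in% slotNames(class(encoder))
}
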
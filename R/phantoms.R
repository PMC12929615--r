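## Synthetic chest-phantom generator: a smooth elliptical "thorax" background
## with Gaussian pixel noise, plus per-label localized lesions (disk, ellipse
## or bar) of configurable contrast, with exact pixel ground-truth masks. An
## optional shortcut mode stamps a bright corner marker correlated with one
## label, emulating the laterality-marker shortcut known from chest
## radiograph datasets.

#' Phantom generation specification
#'
#' Defaults describe the desk-scale study conditions: 128 x 128 images on an
#' 8 x 8 grid of 16 x 16 patches; three labels with locally distinguishable
#' lesion types (a bright disk, a dark ellipse, a thin bright bar) at high
#' contrast against the 0.12-0.55 thorax background; two to three lesions
#' per positive label (mean ground-truth mask area fraction about 0.05);
#' prevalence one half per label; background noise sd 0.05.
#'
#' @param imageSide image side `S` in pixels.
#' @param labels character vector of label names (length `C`).
#' @param shapes per-label lesion shape, each one of `"disk"`, `"ellipse"`,
#'   `"bar"`.
#' @param radiusRange per-label 2-column matrix (or length-2 vector recycled)
#'   of lesion radius bounds in pixels.
#' @param contrast per-label additive intensity contrast in `[-0.5, 0.5]`.
#' @param countRange integer lesion-count bounds per positive label.
#' @param prevalence per-label Bernoulli prevalence in `(0, 1)` (or exactly
#'   0/1 for degenerate designs).
#' @param noiseSd background Gaussian noise sd.
#' @param shortcut `NULL`, or a list with elements `corner` (one of `"tl"`,
#'   `"tr"`, `"bl"`, `"br"`), `size` (marker side, px), `intensity` (stamped
#'   value), `labelIndex` (which label it correlates with), `rho`
#'   (correlation strength in `[0, 1]`: probability of the marker given label
#'   1, and of its absence given label 0).
#' @return validated specification list.
#' @export
phantomSpec <- function(imageSide = 128L,
                        labels = c("disk", "ellipse", "bar"),
                        shapes = c("disk", "ellipse", "bar"),
                        radiusRange = matrix(c(8, 14, 10, 18, 12, 20),
                          nrow = length(labels), ncol = 2, byrow = TRUE),
                        contrast = c(0.45, -0.42, 0.40),
                        countRange = c(2L, 3L),
                        prevalence = rep(0.5, length(labels)),
                        noiseSd = 0.05,
                        shortcut = NULL) {
  C <- length(labels)
  if (length(shapes) == 1L) shapes <- rep(shapes, C)
  if (length(contrast) == 1L) contrast <- rep(contrast, C)
  if (length(prevalence) == 1L) prevalence <- rep(prevalence, C)
  if (is.vector(radiusRange) && length(radiusRange) == 2L)
    radiusRange <- matrix(radiusRange, C, 2, byrow = TRUE)
  stopifnot(imageSide >= 8L, length(shapes) == C, length(contrast) == C,
    length(prevalence) == C, nrow(radiusRange) == C,
    all(shapes %in% c("disk", "ellipse", "bar")),
    all(abs(contrast) <= 0.5), all(prevalence >= 0 & prevalence <= 1),
    noiseSd >= 0, all(countRange >= 1L), countRange[1] <= countRange[2])
  if (any(radiusRange[, 2] >= imageSide / 2))
    stop("lesion radius must be below half the image side")
  if (!is.null(shortcut)) {
    stopifnot(shortcut$corner %in% c("tl", "tr", "bl", "br"),
      shortcut$size >= 1, shortcut$size + 4 <= imageSide,
      shortcut$rho >= 0, shortcut$rho <= 1,
      shortcut$labelIndex >= 1, shortcut$labelIndex <= C)
  }
  list(imageSide = as.integer(imageSide), labels = as.character(labels),
    shapes = shapes, radiusRange = radiusRange, contrast = contrast,
    countRange = as.integer(countRange), prevalence = prevalence,
    noiseSd = noiseSd, shortcut = shortcut)
}

.thoraxBackground <- function(S, noiseSd) {
  ax <- (seq_len(S) - (S + 1) / 2) / (0.46 * S)
  rho2 <- outer(ax^2 / 0.78, ax^2, "+")  # taller than wide, chest-like
  bg <- 0.12 + 0.43 * pmax(0, 1 - rho2)
  if (noiseSd > 0) bg <- bg + matrix(stats::rnorm(S * S, sd = noiseSd), S, S)
  bg
}

.lesionMask <- function(S, shape, r, cy, cx, theta) {
  ys <- outer(seq_len(S) - cy, rep(1, S))
  xs <- outer(rep(1, S), seq_len(S) - cx)
  u <- ys * cos(theta) + xs * sin(theta)
  v <- -ys * sin(theta) + xs * cos(theta)
  m <- switch(shape,
    disk = (ys^2 + xs^2) <= r^2,
    ellipse = (u / r)^2 + (v / (0.55 * r))^2 <= 1,
    bar = abs(u) <= r & abs(v) <= max(2, r / 5))
  mode(m) <- "integer"
  m
}

#' Generate one phantom image with exact ground truth
#'
#' Draws the background (smooth elliptical gradient plus noise), then for
#' each label a Bernoulli presence draw; present labels get 1 or more lesions
#' at uniform random positions fully inside the image, stamped additively
#' with the label's contrast, and an exact pixel mask. The lesion-free
#' counterfactual (identical background and noise) is returned alongside, so
#' oracle saliency ceilings can be computed. Intensities are clipped to
#' `[0, 1]` at the end. Consumes the current RNG stream.
#'
#' @param spec a [phantomSpec()] list.
#' @return list: `image` (S x S in `[0, 1]`), `counterfactual` (same, no
#'   lesions, no marker), `truth` (named 0/1 vector), `masks` (named list of
#'   0/1 matrices, empty matrix when label absent), `meta` (lesion geometry
#'   and marker state).
#' @export
makePhantom <- function(spec) {
  S <- spec$imageSide
  C <- length(spec$labels)
  bg <- .thoraxBackground(S, spec$noiseSd)
  img <- bg
  truth <- stats::setNames(integer(C), spec$labels)
  masks <- stats::setNames(vector("list", C), spec$labels)
  lesions <- list()
  for (k in seq_len(C)) {
    masks[[k]] <- matrix(0L, S, S)
    truth[k] <- stats::rbinom(1, 1, spec$prevalence[k])
    if (truth[k] == 1L) {
      cnt <- spec$countRange[1] +
        sample.int(spec$countRange[2] - spec$countRange[1] + 1L, 1L) - 1L
      for (j in seq_len(cnt)) {
        r <- stats::runif(1, spec$radiusRange[k, 1], spec$radiusRange[k, 2])
        margin <- ceiling(r) + 1L
        cy <- margin + sample.int(S - 2L * margin + 1L, 1L) - 1L
        cx <- margin + sample.int(S - 2L * margin + 1L, 1L) - 1L
        theta <- stats::runif(1, 0, pi)
        m <- .lesionMask(S, spec$shapes[k], r, cy, cx, theta)
        img <- img + spec$contrast[k] * m
        masks[[k]][m == 1L] <- 1L
        lesions[[length(lesions) + 1L]] <- list(label = spec$labels[k],
          shape = spec$shapes[k], r = r, cy = cy, cx = cx, theta = theta)
      }
    }
  }
  marker <- FALSE
  if (!is.null(spec$shortcut)) {
    res <- injectShortcut(img, truth, spec)
    img <- res$image
    marker <- res$marker
  }
  clip <- function(x) { x[x < 0] <- 0; x[x > 1] <- 1; x }
  list(image = clip(img), counterfactual = clip(bg), truth = truth,
    masks = masks, meta = list(lesions = lesions, marker = marker))
}

.markerPixels <- function(S, corner, size) {
  inset <- 3L
  ys <- switch(corner,
    tl = , tr = inset + seq_len(size),
    bl = , br = S - inset - size + seq_len(size))
  xs <- switch(corner,
    tl = , bl = inset + seq_len(size),
    tr = , br = S - inset - size + seq_len(size))
  list(ys = ys, xs = xs)
}

#' Stamp a shortcut corner marker correlated with a label
#'
#' With probability `rho` given the correlated label is 1 (and `1 - rho`
#' given it is 0) a square marker of exactly the configured intensity is
#' stamped at the configured corner. `rho = 1` makes the marker a perfect
#' proxy for the label -- the canonical shortcut-learning trap. Consumes the
#' current RNG stream.
#'
#' @param img `S x S` image matrix.
#' @param truth named 0/1 label vector.
#' @param spec a [phantomSpec()] with non-`NULL` `shortcut`.
#' @return list: `image` (possibly stamped), `marker` (logical, stamped?).
#' @export
injectShortcut <- function(img, truth, spec) {
  sc <- spec$shortcut
  if (is.null(sc)) stop("spec has no shortcut mode configured")
  S <- nrow(img)
  if (sc$size + 4 > S) stop("marker exceeds image bounds")
  y <- truth[sc$labelIndex]
  pOn <- if (y == 1) sc$rho else 1 - sc$rho
  on <- stats::runif(1) < pOn
  if (on) {
    px <- .markerPixels(S, sc$corner, as.integer(sc$size))
    img[px$ys, px$xs] <- sc$intensity
  }
  list(image = img, marker = on)
}

#' Generate a batch of phantoms in memory
#'
#' @param spec a [phantomSpec()] list.
#' @param n number of phantoms.
#' @param seed integer seed (the batch is deterministic given it).
#' @return list of [makePhantom()] results.
#' @export
makePhantoms <- function(spec, n, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  lapply(seq_len(n), function(i) makePhantom(spec))
}

#' Write a phantom dataset to disk
#'
#' Writes `n` grayscale PNG images, a label table CSV (column `path`
#' followed by one 0/1 column per label), per-positive-label masks in both
#' PNG (0/255) and run-length-encoded JSON, disjoint train/validation/test
#' split manifests, and a machine-readable `manifest.json` recording the
#' seed, the specification and the file inventory. Deterministic given
#' `seed`.
#'
#' @param spec a [phantomSpec()] list.
#' @param n number of images.
#' @param outDir output directory (created if missing).
#' @param seed integer seed.
#' @param splits named fractions for train/val/test, summing to 1.
#' @param force overwrite an existing non-empty directory.
#' @return the manifest, invisibly.
#' @export
makeDataset <- function(spec, n, outDir, seed = 1L,
                        splits = c(train = 0.7, val = 0.15, test = 0.15),
                        force = FALSE) {
  stopifnot(n >= 1L, abs(sum(splits) - 1) < 1e-8)
  if (dir.exists(outDir) && length(list.files(outDir)) > 0 && !force)
    stop("output directory ", outDir, " is not empty; use force = TRUE")
  ok <- dir.create(file.path(outDir, "images"), recursive = TRUE,
    showWarnings = FALSE)
  dir.create(file.path(outDir, "masks"), recursive = TRUE,
    showWarnings = FALSE)
  if (!dir.exists(file.path(outDir, "images")))
    stop("cannot create output directory ", outDir)
  phantoms <- makePhantoms(spec, n, seed)
  ids <- sprintf("img_%05d", seq_len(n))
  paths <- file.path("images", paste0(ids, ".png"))
  lab <- matrix(0L, n, length(spec$labels),
    dimnames = list(NULL, spec$labels))
  maskFiles <- character(0)
  for (i in seq_len(n)) {
    png::writePNG(phantoms[[i]]$image, file.path(outDir, paths[i]))
    lab[i, ] <- phantoms[[i]]$truth
    for (k in seq_along(spec$labels)) {
      if (phantoms[[i]]$truth[k] == 1L) {
        stem <- file.path("masks", paste0(ids[i], "_", spec$labels[k]))
        writeMaskPNG(phantoms[[i]]$masks[[k]],
          file.path(outDir, paste0(stem, ".png")))
        writeMaskJSON(phantoms[[i]]$masks[[k]],
          file.path(outDir, paste0(stem, ".json")))
        maskFiles <- c(maskFiles, paste0(stem, ".png"), paste0(stem, ".json"))
      }
    }
  }
  tab <- data.frame(path = paths, lab, check.names = FALSE)
  writeLabelTable(tab, file.path(outDir, "labels.csv"))
  ## deterministic split on a dedicated substream
  old <- .Random.seed_save()
  set.seed(deriveSeed(seed, "split"))
  ord <- sample.int(n)
  .Random.seed_restore(old)
  nTr <- round(splits[["train"]] * n)
  nVa <- round(splits[["val"]] * n)
  sp <- list(train = ids[ord[seq_len(nTr)]],
    val = ids[ord[nTr + seq_len(min(nVa, n - nTr))]],
    test = ids[ord[setdiff(seq_len(n), seq_len(nTr + nVa))]])
  for (s in names(sp))
    writeLines(sort(sp[[s]]), file.path(outDir, paste0(s, ".txt")))
  manifest <- list(seed = as.integer(seed), n = as.integer(n),
    spec = spec[setdiff(names(spec), "radiusRange")],
    radiusRange = spec$radiusRange,
    splits = lapply(sp, sort), labels = spec$labels,
    package_version = as.character(utils::packageVersion("patchlogit")))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(manifest)
}
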
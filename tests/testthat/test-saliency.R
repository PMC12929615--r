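# Block saliency maps, shift-and-average smoothing, overlays.

makeField <- function(logits, P, p, labels = "x", source = "raw") {
  new("PatchLogitField", logits = logits, labels = labels,
    gridSide = as.integer(P), patchSide = as.integer(p), source = source)
}

test_that("patch map is block-constant with the right block geometry", {
  lg <- matrix(0, 4, 1); lg[1, 1] <- 3  # patch 0 (top-left)
  m <- patchMap(makeField(lg, 2, 2), "x")
  expect_equal(values(m)[1:2, 1:2], matrix(3, 2, 2))
  expect_true(all(values(m)[3:4, ] == 0) && all(values(m)[1:2, 3:4] == 0))

  # row-major patch indexing: patch 1 is top-RIGHT
  lg2 <- matrix(0, 4, 1); lg2[2, 1] <- 5
  m2 <- patchMap(makeField(lg2, 2, 2), "x")
  expect_equal(values(m2)[1:2, 3:4], matrix(5, 2, 2))

  # constant field -> spatially constant map
  mC <- patchMap(makeField(matrix(2.5, 9, 1), 3, 4), "x")
  expect_true(all(values(mC) == 2.5))

  expect_error(patchMap(makeField(lg, 2, 2), 2), "out of range")
})

test_that("pixel mean of a raw block map equals the global logit", {
  withr::with_seed(21, {
    for (i in 1:20) {
      lg <- matrix(rnorm(16 * 2), 16, 2)
      f <- makeField(lg, 4, 3, labels = c("a", "b"))
      Z <- globalLogits(aggregateLogits(f))
      expect_lt(abs(mean(values(patchMap(f, "a"))) - Z[1]), 1e-6)
      expect_lt(abs(mean(values(patchMap(f, "b"))) - Z[2]), 1e-6)
    }
  })
})

test_that("offset o = p reproduces the block map exactly and uses one forward pass", {
  withr::with_seed(3, {
    img <- matrix(runif(24 * 24), 24, 24)
    inner <- randomLinearEncoder(6, "x", seed = 4)
    ce <- countingEncoder(inner)
    sm <- shiftedSaliency(img, ce$encoder, 6, 6, "x")
    expect_equal(ce$counter$calls, 1L)
    direct <- patchMap(encodePatches(partitionImage(img, 6), inner), "x")
    expect_equal(values(sm), values(direct))
  })
})

test_that("offset o = 1 performs p^2 forward passes and o in between (p/o)^2", {
  withr::with_seed(4, {
    img <- matrix(runif(16 * 16), 16, 16)
    inner <- randomLinearEncoder(4, "x", seed = 5)
    ce <- countingEncoder(inner)
    invisible(shiftedSaliency(img, ce$encoder, 4, 1, "x"))
    expect_equal(ce$counter$calls, 16L)  # p^2 with p = 4
    ce2 <- countingEncoder(inner)
    invisible(shiftedSaliency(img, ce2$encoder, 4, 2, "x"))
    expect_equal(ce2$counter$calls, 4L)  # (p/o)^2
  })
})

test_that("a constant encoder yields a spatially constant smoothed map for every offset", {
  img <- matrix(runif(16 * 16), 16, 16)
  cst <- constantEncoder(c(1.7))
  for (o in c(1, 2, 4)) {
    sm <- shiftedSaliency(img, cst, 4, o, 1)
    expect_true(all(abs(values(sm) - 1.7) < 1e-12))
  }
})

test_that("offsets that do not divide the patch side are rejected", {
  img <- matrix(0.5, 16, 16)
  cst <- constantEncoder(0)
  expect_error(shiftedSaliency(img, cst, 4, 3, 1), "divide")
  expect_error(shiftedSaliency(img, cst, 4, 0, 1), "divide|offset")
})

test_that("smoothed values stay within the range of contributing shifted maps", {
  # every pixel of the averaged map must lie in [min, max] of the values the
  # individual shifted-grid maps assign to it; independent reconstruction
  # via explicit padded images and patchMap on the enlarged grid
  withr::with_seed(6, {
    S <- 16L; p <- 4L; o <- 2L; P <- S %/% p
    img <- matrix(runif(S * S), S, S)
    enc <- randomLinearEncoder(4, "x", seed = 7)
    shifts <- seq(0L, p - o, by = o)
    aligned <- list()
    for (dy in shifts) for (dx in shifts) {
      pimg <- matrix(0, (P + 1) * p, (P + 1) * p)
      pimg[(dy + 1):(dy + S), (dx + 1):(dx + S)] <- img
      mv <- values(patchMap(encodePatches(partitionImage(pimg, p), enc), "x"))
      aligned[[length(aligned) + 1L]] <- mv[(dy + 1):(dy + S), (dx + 1):(dx + S)]
    }
    sm <- values(shiftedSaliency(img, enc, p, o, "x"))
    lo <- Reduce(pmin, aligned); hi <- Reduce(pmax, aligned)
    expect_true(all(sm >= lo - 1e-12 & sm <= hi + 1e-12))
    expect_equal(sm, Reduce(`+`, aligned) / length(aligned))
  })
})

test_that("shifting the image by a whole patch shifts the block map by a patch", {
  withr::with_seed(8, {
    img <- matrix(runif(16 * 16), 16, 16)
    enc <- randomLinearEncoder(4, "x", seed = 9)
    p <- 4L
    base <- values(shiftedSaliency(img, enc, p, p, "x"))
    shifted <- matrix(0, 16, 16)
    shifted[(p + 1):16, ] <- img[1:(16 - p), ]
    sh <- values(shiftedSaliency(shifted, enc, p, p, "x"))
    # interior blocks move down by one block row; the new top row is border
    expect_equal(sh[(p + 1):16, ], base[1:(16 - p), ])
  })
})

test_that("scaled-source smoothing recomputes probabilities per shifted image", {
  # the probabilities scaling each shifted map must come from the forward
  # pass of that shift's translated image (its zero-padded S x S crop)
  withr::with_seed(10, {
    S <- 8L; p <- 4L; P <- S %/% p
    img <- matrix(runif(S * S), S, S)
    enc <- randomLinearEncoder(4, "x", seed = 11)
    stack <- shiftedSaliencyStack(img, enc, p, 2, source = "scaled")
    shifts <- c(0L, 2L)
    acc <- matrix(0, S, S)
    for (dy in shifts) for (dx in shifts) {
      t_img <- matrix(0, S, S)                       # paper's translated image
      t_img[(dy + 1):S, (dx + 1):S] <- img[1:(S - dy), 1:(S - dx)]
      yhat <- probabilities(patchForward(t_img, enc, p)$prediction)
      pimg <- matrix(0, (P + 1) * p, (P + 1) * p)    # covering grid
      pimg[(dy + 1):(dy + S), (dx + 1):(dx + S)] <- img
      mv <- values(patchMap(encodePatches(partitionImage(pimg, p), enc), "x"))
      acc <- acc + yhat * mv[(dy + 1):(dy + S), (dx + 1):(dx + S)]
    }
    expect_equal(stack[, , 1], acc / 4)
  })
})

test_that("overlay rendering encodes sign as red/blue and zero maps as the plain image", {
  tmp <- withr::local_tempdir()
  img <- matrix(runif(8 * 8), 8, 8)
  zero <- new("SaliencyMap", values = matrix(0, 8, 8), label = "x",
    source = "raw", offset = 8L)
  f0 <- file.path(tmp, "zero.png")
  renderOverlay(img, zero, f0)
  arr <- png::readPNG(f0)
  expect_equal(dim(arr)[3], 3L)
  for (k in 1:3) expect_lt(max(abs(arr[, , k] - img)), 2 / 255)

  vpos <- matrix(0, 8, 8); vpos[1:4, 1:4] <- 1
  mp <- new("SaliencyMap", values = vpos, label = "x", source = "raw",
    offset = 4L)
  fp <- file.path(tmp, "pos.png")
  renderOverlay(img, mp, fp)
  ap <- png::readPNG(fp)
  # red tint only on the positive block
  expect_true(mean(ap[1:4, 1:4, 1]) > mean(ap[1:4, 1:4, 3]))
  expect_lt(max(abs(ap[5:8, 5:8, 1] - img[5:8, 5:8])), 2 / 255)

  mn <- new("SaliencyMap", values = -vpos, label = "x", source = "raw",
    offset = 4L)
  fn <- file.path(tmp, "neg.png")
  renderOverlay(img, mn, fn)
  an <- png::readPNG(fn)
  # sign flip swaps the channel roles
  expect_equal(mean(ap[1:4, 1:4, 1]), mean(an[1:4, 1:4, 3]), tolerance = 2 / 255)
  expect_error(renderOverlay(img, mp, file.path(tmp, "no/dir/x.png")), "write")
})

test_that("saliency maps round-trip through the JSON serialization", {
  withr::with_seed(12, {
    m <- new("SaliencyMap", values = matrix(rnorm(36), 6, 6), label = "a",
      source = "scaled", offset = 2L)
    tmp <- withr::local_tempfile(fileext = ".json")
    writeSaliencyMap(m, tmp)
    m2 <- readSaliencyMap(tmp)
    expect_equal(values(m2), values(m))
    expect_equal(m2@label, "a")
    expect_equal(m2@source, "scaled")
    expect_equal(m2@offset, 2L)
  })
})
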
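# Shared encoder fixtures: analytic encoders with known behavior and an
# instrumented wrapper that counts forward passes (one count per batch of
# patches it is handed, i.e. per image-level forward).

constantEncoder <- function(v, labels = paste0("L", seq_along(v))) {
  funEncoder(function(patch) v, labels)
}

meanPixelEncoder <- function(labels = "mean") {
  funEncoder(function(X) {
    matrix(rowMeans(X), nrow(X), length(labels))
  }, labels, vectorized = TRUE)
}

# Vectorized linear encoder with a fixed random projection; cheap and
# input-sensitive, good for property loops.
randomLinearEncoder <- function(patchSide, labels, seed) {
  d <- patchSide^2
  W <- matrix(withr::with_seed(seed, rnorm(d * length(labels))), d)
  funEncoder(function(X) X %*% W, labels, vectorized = TRUE)
}

countingEncoder <- function(inner) {
  env <- new.env()
  env$calls <- 0L
  enc <- funEncoder(function(X) {
    env$calls <- env$calls + 1L
    encoderLogits(inner, X)
  }, labelNames(inner), vectorized = TRUE)
  list(encoder = enc, counter = env)
}

# Brute-force oracles used by several files ---------------------------------

bruteHit <- function(values, mask) {
  S <- nrow(values)
  best <- NULL
  for (y in seq_len(S)) {          # row-major scan: first hit of the max
    for (x in seq_len(S)) {
      if (is.null(best) || values[y, x] > best$v) best <- list(v = values[y, x], y = y, x = x)
    }
  }
  as.integer(mask[best$y, best$x] == 1)
}

bruteIoU <- function(a, b) {
  inter <- 0; uni <- 0
  for (i in seq_along(a)) {
    if (a[i] == 1 && b[i] == 1) inter <- inter + 1
    if (a[i] == 1 || b[i] == 1) uni <- uni + 1
  }
  inter / uni
}

bruteAuroc <- function(scores, truth) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}
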
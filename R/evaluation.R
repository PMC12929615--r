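## Localization-evaluation protocol: pointing-game hit rate, mean IoU over
## TP/FP/FN cases, per-label saliency threshold tuning, plus classification
## metrics (AUROC, Youden thresholds) and percentile bootstrap intervals.

.mapValues <- function(x) {
  if (is(x, "SaliencyMap")) x@values else x
}

#' Pointing-game hit indicator
#'
#' Locates the maximum-saliency pixel and returns 1 iff it lies inside the
#' ground-truth mask. Ties at the maximum are broken deterministically toward
#' the smallest row-major pixel index (scan rows left-to-right, top row
#' first, origin top-left). With `permissive = TRUE` a hit is instead scored
#' if any maximal pixel lies inside the mask.
#'
#' @param map a [SaliencyMap-class] or numeric matrix.
#' @param gtMask 0/1 matrix of the same size; must be non-empty.
#' @param permissive count a hit if any argmax pixel is inside the mask.
#' @return integer 0 or 1.
#' @export
hitIndicator <- function(map, gtMask, permissive = FALSE) {
  v <- .mapValues(map)
  if (!all(dim(v) == dim(gtMask))) stop("map and mask sizes differ")
  if (sum(gtMask) == 0)
    stop("hit indicator undefined for an empty ground-truth mask")
  mx <- max(v)
  idx <- which(v == mx)                    # column-major linear indices
  if (permissive) return(as.integer(any(gtMask[idx] == 1)))
  S <- nrow(v)
  ys <- (idx - 1L) %% S                    # 0-based row
  xs <- (idx - 1L) %/% S                   # 0-based col
  pick <- which.min(ys * ncol(v) + xs)     # smallest row-major key
  as.integer(gtMask[idx[pick]] == 1)
}

#' Fill the hit indicator of evaluation cases
#'
#' Computes [hitIndicator()] for every case with a non-empty ground-truth
#' mask; cases with absent or empty masks keep `hit = NA` and are excluded
#' from the hit-rate denominator.
#'
#' @param cases list of [EvalCase-class].
#' @param permissive see [hitIndicator()].
#' @return the list with `hit` slots filled.
#' @export
computeHits <- function(cases, permissive = FALSE) {
  lapply(cases, function(cs) {
    if (!is.null(cs@gtMask) && sum(cs@gtMask) > 0)
      cs@hit <- hitIndicator(cs@saliency, cs@gtMask, permissive)
    cs
  })
}

#' Pointing-game hit rate
#'
#' Mean of the hit indicators over the N cases that have one: the fraction of
#' cases whose maximum-saliency pixel falls inside the expert mask.
#'
#' @param cases list of [EvalCase-class] with hits computed (see
#'   [computeHits()]).
#' @return numeric hit rate in `[0, 1]`.
#' @export
hitRate <- function(cases) {
  h <- vapply(cases, function(cs) cs@hit, integer(1))
  h <- h[!is.na(h)]
  if (length(h) == 0L) stop("no cases with a computed hit indicator")
  mean(h)
}

#' Threshold a saliency map into a binary mask
#'
#' Strict inequality: pixel is 1 iff its value exceeds `threshold`, so a
#' threshold at or above the global maximum yields an empty mask.
#'
#' @param map a [SaliencyMap-class] or numeric matrix.
#' @param threshold finite scalar (or `-Inf` to select everything).
#' @return integer 0/1 matrix.
#' @export
binarizeMap <- function(map, threshold) {
  v <- .mapValues(map)
  out <- matrix(0L, nrow(v), ncol(v))
  out[v > threshold] <- 1L
  out
}

#' Intersection over union of two binary masks
#'
#' @param a,b 0/1 matrices of equal size, not both empty.
#' @return numeric IoU in `[0, 1]`.
#' @export
maskIoU <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mask sizes differ")
  uni <- sum(a == 1 | b == 1)
  if (uni == 0) stop("IoU undefined: both masks are empty")
  sum(a == 1 & b == 1) / uni
}

#' Case category for thresholded-saliency segmentation
#'
#' A true positive has a positive label and a non-empty predicted mask; a
#' false positive a negative label and a non-empty mask; a false negative a
#' positive label and an empty mask; a true negative a negative label and an
#' empty mask.
#'
#' @param truth binary ground-truth label.
#' @param predictedMask 0/1 matrix from [binarizeMap()].
#' @return one of `"TP"`, `"FP"`, `"FN"`, `"TN"`.
#' @export
caseCategory <- function(truth, predictedMask) {
  nonEmpty <- sum(predictedMask) >= 1
  if (truth == 1) {
    if (nonEmpty) "TP" else "FN"
  } else {
    if (nonEmpty) "FP" else "TN"
  }
}

.caseThreshold <- function(cs, thresholds) {
  if (length(thresholds) == 1L && is.null(names(thresholds)))
    return(thresholds)
  t <- thresholds[[cs@label]]
  if (is.null(t) || is.na(t)) stop("no threshold for label '", cs@label, "'")
  t
}

#' Mean intersection over union across TP/FP/FN cases
#'
#' Each case's saliency is thresholded with its label's threshold and
#' categorized with [caseCategory()]. True positives contribute
#' `IoU(predicted, ground truth)`; false positives and false negatives
#' contribute 0 (one of the two masks is empty, so the overlap is zero by
#' convention); true negatives are excluded. `mode = "tp_only"` averages over
#' true positives alone.
#'
#' @param cases list of [EvalCase-class]; label-positive cases must carry a
#'   ground-truth mask.
#' @param thresholds named per-label thresholds (or one unnamed scalar).
#' @param mode `"tp_fp_fn"` (default) or `"tp_only"`.
#' @return mean IoU over the included cases.
#' @export
meanIoU <- function(cases, thresholds, mode = c("tp_fp_fn", "tp_only")) {
  mode <- match.arg(mode)
  vals <- numeric(0)
  for (cs in cases) {
    pm <- binarizeMap(cs@saliency, .caseThreshold(cs, thresholds))
    cat. <- caseCategory(cs@truth, pm)
    if (cat. == "TN") next
    if (cat. == "TP") {
      if (is.null(cs@gtMask))
        stop("case ", cs@imageId, " is label-positive but has no mask")
      v <- maskIoU(pm, cs@gtMask)
      vals <- c(vals, v)
    } else if (mode == "tp_fp_fn") {
      vals <- c(vals, 0)
    }
  }
  if (length(vals) == 0L)
    stop("no TP/FP/FN cases to average (all true negatives?)")
  mean(vals)
}

#' Tune per-label saliency thresholds on validation cases
#'
#' For each label, candidate thresholds are `gridSize` quantiles of the
#' pooled saliency values of that label's validation cases (deduplicated,
#' plus a `-Inf` sentinel); the candidate maximizing the TP/FP/FN mean IoU is
#' returned, ties broken toward the larger threshold.
#'
#' @param cases validation list of [EvalCase-class].
#' @param gridSize number of quantile candidates per label.
#' @return named numeric vector of thresholds.
#' @export
tuneThresholds <- function(cases, gridSize = 100L) {
  labs <- unique(vapply(cases, function(cs) cs@label, character(1)))
  out <- stats::setNames(numeric(length(labs)), labs)
  for (lb in labs) {
    sub <- Filter(function(cs) cs@label == lb, cases)
    pooled <- unlist(lapply(sub, function(cs) as.vector(.mapValues(cs@saliency))))
    cand <- unique(stats::quantile(pooled, probs = seq(0, 1, length.out = gridSize),
      names = FALSE, type = 7))
    cand <- sort(unique(c(-Inf, cand)))
    if (length(cand) == 0L) stop("no threshold candidates for label ", lb)
    best <- -Inf; bestT <- NA_real_
    for (t in cand) {
      v <- tryCatch(meanIoU(sub, stats::setNames(t, NULL), mode = "tp_fp_fn"),
        error = function(e) NA_real_)
      if (is.na(v)) next
      if (v > best || (v == best && (is.na(bestT) || t > bestT))) {
        best <- v; bestT <- t
      }
    }
    if (is.na(bestT)) stop("threshold tuning degenerate for label ", lb,
      " (no candidate yields an evaluable mean IoU)")
    out[lb] <- bestT
  }
  out
}

#' Youden classification thresholds
#'
#' Per label, the score cut-off maximizing sensitivity + specificity on the
#' given (validation) cases, with prediction rule `score > threshold`.
#' Candidates are the midpoints between consecutive sorted unique scores plus
#' outer sentinels; ties are broken toward the larger threshold. Labels with
#' a single class present are skipped with a warning and reported as `NA`.
#'
#' @param scores numeric matrix `n x C` of per-case scores (columns named by
#'   label), or a vector for a single label.
#' @param truths matching 0/1 matrix or vector of ground-truth labels.
#' @return named numeric vector of thresholds (`NA` where skipped).
#' @export
classificationThresholds <- function(scores, truths) {
  if (is.vector(scores)) scores <- matrix(scores, ncol = 1)
  if (is.vector(truths)) truths <- matrix(truths, ncol = 1)
  stopifnot(all(dim(scores) == dim(truths)))
  labs <- colnames(scores)
  if (is.null(labs)) labs <- paste0("label", seq_len(ncol(scores)))
  out <- stats::setNames(rep(NA_real_, ncol(scores)), labs)
  for (k in seq_len(ncol(scores))) {
    s <- scores[, k]; y <- truths[, k]
    nPos <- sum(y == 1); nNeg <- sum(y == 0)
    if (nPos == 0 || nNeg == 0) {
      warning("label ", labs[k], " has a single class; threshold skipped")
      next
    }
    u <- sort(unique(s))
    cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
    best <- -Inf; bestT <- NA_real_
    for (t in cand) {
      sens <- sum(s > t & y == 1) / nPos
      spec <- sum(s <= t & y == 0) / nNeg
      j <- sens + spec
      if (j > best || (j == best && t > bestT)) {
        best <- j; bestT <- t
      }
    }
    out[k] <- bestT
  }
  out
}

#' Area under the ROC curve
#'
#' Probability that a uniformly drawn positive case outscores a uniformly
#' drawn negative case, ties counting one half -- the Mann-Whitney U
#' normalization, computed from midranks.
#'
#' @param scores numeric vector of case scores.
#' @param truths 0/1 vector of ground-truth labels.
#' @return AUROC in `[0, 1]`, or `NA` with a warning when a class is absent.
#' @export
aurocScore <- function(scores, truths) {
  stopifnot(length(scores) == length(truths))
  nPos <- sum(truths == 1); nNeg <- sum(truths == 0)
  if (nPos == 0 || nNeg == 0) {
    warning("AUROC undefined: one class absent")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[truths == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Percentile bootstrap confidence interval for a case-level metric
#'
#' Resamples the case set with replacement (same size), recomputes the metric
#' per resample, and reports the 2.5% / 97.5% percentile bounds. Resamples on
#' which the metric errors (e.g., a single-class resample) are skipped and
#' counted. Deterministic given `seed`.
#'
#' @param metric function taking a list/vector of cases and returning a
#'   scalar.
#' @param cases list or vector of cases.
#' @param resamples number of bootstrap resamples (0 for point estimate only).
#' @param seed integer RNG seed.
#' @param conf confidence level.
#' @param name metric name recorded in the report.
#' @return a [MetricReport-class].
#' @export
bootstrapCI <- function(metric, cases, resamples = 100000L, seed = 1L,
                        conf = 0.95, name = "metric") {
  n <- length(cases)
  stopifnot(n >= 1L, resamples >= 0L)
  est <- metric(cases)
  if (resamples == 0L)
    return(new("MetricReport", metric = name, estimate = est,
      lower = NA_real_, upper = NA_real_, n = as.integer(n),
      resamples = 0L, skipped = 0L))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  vals <- rep(NA_real_, resamples)
  for (r in seq_len(resamples)) {
    idx <- sample.int(n, n, replace = TRUE)
    vals[r] <- tryCatch(metric(cases[idx]), error = function(e) NA_real_)
  }
  skipped <- sum(is.na(vals))
  if (skipped == resamples) stop("metric undefined on every resample")
  a <- (1 - conf) / 2
  q <- stats::quantile(vals, probs = c(a, 1 - a), na.rm = TRUE, names = FALSE)
  new("MetricReport", metric = name, estimate = est,
    lower = q[1], upper = q[2], n = as.integer(n),
    resamples = as.integer(resamples), skipped = as.integer(skipped))
}

#' Localization metrics table with bootstrap intervals
#'
#' Computes, per label and pooled over labels, the pointing-game hit rate and
#' the TP/FP/FN and TP-only mean IoU, each with a percentile bootstrap CI.
#'
#' @param cases list of [EvalCase-class] (hits need not be precomputed).
#' @param thresholds named per-label thresholds from [tuneThresholds()].
#' @param resamples bootstrap resamples (0 disables CIs).
#' @param seed RNG seed for the bootstrap.
#' @return data.frame with one row per (label, metric): estimate, CI bounds,
#'   n, resamples.
#' @export
evaluateLocalization <- function(cases, thresholds, resamples = 1000L,
                                 seed = 1L) {
  cases <- computeHits(cases)
  labs <- unique(vapply(cases, function(cs) cs@label, character(1)))
  groups <- c(stats::setNames(lapply(labs, function(lb)
    Filter(function(cs) cs@label == lb, cases)), labs), list(mean = cases))
  rows <- list()
  for (g in names(groups)) {
    sub <- groups[[g]]
    specs <- list(
      hit_rate = function(x) hitRate(x),
      miou_tp_fp_fn = function(x) meanIoU(x, thresholds, "tp_fp_fn"),
      miou_tp_only = function(x) meanIoU(x, thresholds, "tp_only"))
    for (m in names(specs)) {
      rep <- tryCatch(
        bootstrapCI(specs[[m]], sub, resamples = resamples,
          seed = deriveSeed(seed, paste(g, m)), name = m),
        error = function(e) NULL)
      if (is.null(rep)) next
      rows[[length(rows) + 1L]] <- data.frame(
        label = g, metric = m, estimate = rep@estimate,
        ci_lower = rep@lower, ci_upper = rep@upper,
        n = rep@n, resamples = rep@resamples)
    }
  }
  do.call(rbind, rows)
}
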
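# Localization metrics (hit rate, IoU, thresholds) and classification
# metrics (AUROC, Youden, bootstrap), each against independent oracles.

blockMask <- function(S, ys, xs) {
  m <- matrix(0L, S, S); m[ys, xs] <- 1L; m
}

test_that("hit indicator follows the argmax and the row-major tie rule", {
  v <- matrix(0, 4, 4); v[2, 3] <- 5
  inMask <- blockMask(4, 2, 3)
  outMask <- blockMask(4, 4, 4)
  expect_equal(hitIndicator(v, inMask), 1L)
  expect_equal(hitIndicator(v, outMask), 0L)

  # constant map: argmax is pixel (0, 0); mask avoiding it misses
  flat <- matrix(1, 4, 4)
  expect_equal(hitIndicator(flat, blockMask(4, 2:4, 2:4)), 0L)
  expect_equal(hitIndicator(flat, blockMask(4, 1, 1)), 1L)
  # two-way tie within one row resolves to the smaller column
  tie <- matrix(0, 3, 3); tie[2, 2] <- 7; tie[2, 3] <- 7
  expect_equal(hitIndicator(tie, blockMask(3, 2, 2)), 1L)
  expect_equal(hitIndicator(tie, blockMask(3, 2, 3)), 0L)
  # permissive mode accepts any maximal pixel
  expect_equal(hitIndicator(tie, blockMask(3, 2, 3), permissive = TRUE), 1L)
  expect_error(hitIndicator(v, matrix(0L, 4, 4)), "empty")
})

test_that("hit rate and indicator match the brute-force oracle on 200 random instances", {
  withr::with_seed(41, {
    hits <- integer(0); oracle <- integer(0)
    cases <- list()
    for (i in 1:200) {
      S <- sample(5:12, 1)
      v <- matrix(sample(seq(-3, 3, by = 0.5), S * S, replace = TRUE), S, S)
      m <- matrix(rbinom(S * S, 1, 0.3), S, S)
      if (sum(m) == 0) m[sample(S * S, 1)] <- 1L
      hits <- c(hits, hitIndicator(v, m))
      oracle <- c(oracle, bruteHit(v, m))
      cases[[i]] <- evalCase(paste0("i", i), "L", 1L, v, m)
    }
    expect_identical(hits, oracle)
    cases <- computeHits(cases)
    expect_equal(hitRate(cases), mean(oracle))
  })
  expect_equal(hitRate(lapply(1:4, function(i) {
    cs <- evalCase("x", "L", 1L, matrix(1, 2, 2), blockMask(2, 1, 1))
    cs@hit <- c(1L, 0L, 1L, 1L)[i]; cs
  })), 0.75)
})

test_that("binarization is strict and IoU matches hand counts", {
  v <- matrix(0, 4, 4); v[1:2, 1:2] <- 2
  expect_equal(sum(binarizeMap(v, 1)), 4)
  expect_identical(binarizeMap(v, 1)[1:2, 1:2], matrix(1L, 2, 2))
  expect_equal(sum(binarizeMap(v, 2)), 0)   # strict: > t
  expect_equal(sum(binarizeMap(v, max(v))), 0)
  expect_equal(sum(binarizeMap(v, min(v) - 1)), 16)

  a <- blockMask(4, 1:2, 1); b <- blockMask(4, 2:3, 1)
  expect_equal(maskIoU(a, b), 1 / 3)
  expect_equal(maskIoU(a, a), 1)
  expect_equal(maskIoU(a, blockMask(4, 4, 4)), 0)
  expect_error(maskIoU(matrix(0L, 2, 2), matrix(0L, 2, 2)), "empty")
})

test_that("case categories implement the empty/non-empty convention", {
  empty <- matrix(0L, 3, 3)
  one <- blockMask(3, 1, 1)
  expect_equal(caseCategory(1, empty), "FN")
  expect_equal(caseCategory(0, empty), "TN")
  expect_equal(caseCategory(0, one), "FP")
  expect_equal(caseCategory(1, one), "TP")
})

test_that("mean IoU averages TP/FP/FN with zero contributions and excludes TN", {
  S <- 4
  gt <- blockMask(S, 1:2, 1:2)
  perfect <- matrix(0, S, S); perfect[1:2, 1:2] <- 1  # saliency above t on gt
  blank <- matrix(0, S, S)
  cases <- list(
    evalCase("tp", "L", 1L, perfect, gt),   # TP, IoU 1 at t = 0.5
    evalCase("fn", "L", 1L, blank, gt))     # FN (empty prediction)
  th <- c(L = 0.5)
  expect_equal(meanIoU(cases, th, "tp_fp_fn"), 0.5)
  expect_equal(meanIoU(cases, th, "tp_only"), 1.0)

  # an FP case joins the denominator with IoU 0
  cases3 <- c(cases, list(evalCase("fp", "L", 0L, perfect, NULL)))
  expect_equal(meanIoU(cases3, th, "tp_fp_fn"), 1 / 3)
  # all TN -> nothing to average
  expect_error(meanIoU(list(evalCase("tn", "L", 0L, blank, NULL)), th), "average")
  # tp_fp_fn can never exceed tp_only when FP/FN exist
  expect_lte(meanIoU(cases3, th, "tp_fp_fn"), meanIoU(cases3, th, "tp_only"))
})

test_that("mean IoU equals a brute-force per-case loop on random instances", {
  withr::with_seed(43, {
    for (rep in 1:30) {
      S <- 6
      cases <- lapply(1:8, function(i) {
        truth <- rbinom(1, 1, 0.6)
        gt <- if (truth == 1) {
          m <- matrix(rbinom(S * S, 1, 0.3), S, S)
          if (sum(m) == 0) m[1] <- 1L
          m
        } else NULL
        evalCase(paste0("c", i), "L", truth,
          matrix(runif(S * S), S, S), gt)
      })
      t <- runif(1, 0.2, 0.8)
      manual <- c()
      for (cs in cases) {
        pm <- matrix(as.integer(.subset2(cs@saliency, 1) > 0), 1, 1) # unused guard
        pred <- ifelse(cs@saliency > t, 1L, 0L)
        nonEmpty <- sum(pred) > 0
        if (cs@truth == 1 && nonEmpty) {
          manual <- c(manual, bruteIoU(pred, cs@gtMask))
        } else if (cs@truth == 1 && !nonEmpty) {
          manual <- c(manual, 0)
        } else if (cs@truth == 0 && nonEmpty) {
          manual <- c(manual, 0)
        }
      }
      if (length(manual) == 0) next
      expect_lt(abs(meanIoU(cases, c(L = t)) - mean(manual)), 1e-9)
    }
  })
})

test_that("tuned thresholds maximize validation mean IoU over their own grid", {
  S <- 4
  gt <- blockMask(S, 1:2, 1:2)
  sal <- matrix(0, S, S); sal[1:2, 1:2] <- 3  # v on gt, 0 elsewhere
  cases <- list(evalCase("a", "L", 1L, sal, gt))
  th <- tuneThresholds(cases, gridSize = 50)
  expect_true(th[["L"]] >= 0 && th[["L"]] < 3)  # any t in [0, v) is optimal
  expect_equal(meanIoU(cases, th), 1)

  # flat saliency: either everything (IoU = gt fraction) or nothing (FN, 0)
  flat <- matrix(2, S, S)
  fcases <- list(evalCase("b", "L", 1L, flat, gt))
  thf <- tuneThresholds(fcases, gridSize = 10)
  expect_equal(meanIoU(fcases, thf), sum(gt) / (S * S))

  # achieved mIoU at the returned threshold dominates every grid candidate
  withr::with_seed(47, {
    rc <- lapply(1:6, function(i) {
      m <- matrix(rbinom(16, 1, 0.4), 4, 4); if (sum(m) == 0) m[2] <- 1L
      evalCase(paste0("r", i), "L", 1L, matrix(runif(16), 4, 4), m)
    })
    th <- tuneThresholds(rc, gridSize = 25)
    achieved <- meanIoU(rc, th)
    pooled <- unlist(lapply(rc, function(cs) as.vector(cs@saliency)))
    cand <- unique(c(-Inf, quantile(pooled, seq(0, 1, length.out = 25), names = FALSE)))
    for (t in cand)
      expect_gte(achieved + 1e-12, meanIoU(rc, c(L = t)))
    # a denser grid can only improve (superset search)
    expect_gte(meanIoU(rc, tuneThresholds(rc, gridSize = 100)) + 1e-12, achieved)
  })
})

test_that("Youden thresholds equal the exhaustive midpoint search", {
  withr::with_seed(53, {
    for (rep in 1:20) {
      n <- 40
      s <- round(rnorm(n), 2)
      y <- rbinom(n, 1, 0.5)
      if (sum(y) == 0 || sum(y) == n) next
      th <- classificationThresholds(s, y)
      # brute force over all midpoints and sentinels
      u <- sort(unique(s))
      cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
      best <- -Inf; bestT <- NA
      for (t in cand) {
        j <- sum(s > t & y == 1) / sum(y == 1) + sum(s <= t & y == 0) / sum(y == 0)
        if (j > best || (j == best && t > bestT)) { best <- j; bestT <- t }
      }
      expect_equal(unname(th[1]), bestT)
    }
    # perfectly separated scores give sens = spec = 1
    s <- c(rep(0.9, 5), rep(0.1, 5)); y <- c(rep(1, 5), rep(0, 5))
    t <- unname(classificationThresholds(s, y)[1])
    expect_true(t > 0.1 && t < 0.9)
    expect_equal(sum(s > t & y == 1), 5)
    expect_equal(sum(s <= t & y == 0), 5)
    # single-class labels are skipped with a warning
    expect_warning(th2 <- classificationThresholds(s, rep(1, 10)), "single class")
    expect_true(is.na(th2[1]))
  })
})

test_that("Youden sum is near 1 when scores are independent of labels", {
  withr::with_seed(59, {
    n <- 10000
    s <- runif(n); y <- rbinom(n, 1, 0.5)
    t <- unname(classificationThresholds(s, y)[1])
    j <- sum(s > t & y == 1) / sum(y == 1) + sum(s <= t & y == 0) / sum(y == 0)
    expect_lt(abs(j - 1), 0.06)
  })
})

test_that("AUROC matches the pairwise probability oracle and pROC, with tie handling", {
  expect_equal(aurocScore(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(aurocScore(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0.0)
  withr::with_seed(61, {
    for (rep in 1:25) {
      n <- 30
      s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
      y <- rbinom(n, 1, 0.5)
      if (sum(y) %in% c(0, n)) next
      expect_equal(aurocScore(s, y), bruteAuroc(s, y))
      expect_equal(aurocScore(s, y),
        suppressMessages(as.numeric(pROC::auc(y, s, direction = "<"))))
      # invariance under a strictly monotone transform
      expect_equal(aurocScore(exp(3 * s) - 1, y), aurocScore(s, y))
    }
    # random scores at n = 10000 sit near one half
    s <- runif(10000); y <- rbinom(10000, 1, 0.5)
    expect_lt(abs(aurocScore(s, y) - 0.5), 0.03)
    expect_warning(aurocScore(s, rep(1, 10000)), "one class")
  })
})

test_that("bootstrap CIs are deterministic, collapse for constant metrics, and report skips", {
  x <- rbinom(60, 1, 0.5)
  r1 <- bootstrapCI(mean, x, resamples = 500, seed = 7)
  r2 <- bootstrapCI(mean, x, resamples = 500, seed = 7)
  expect_equal(r1@lower, r2@lower)
  expect_equal(r1@upper, r2@upper)
  expect_true(r1@lower <= r1@estimate && r1@estimate <= r1@upper)

  const <- bootstrapCI(function(z) 1.5, x, resamples = 200, seed = 1)
  expect_equal(const@lower, 1.5)
  expect_equal(const@upper, 1.5)

  # metric undefined on some resamples: skipped and counted
  y <- c(rep(0, 19), 1)
  aucm <- function(cs) {
    if (length(unique(cs)) < 2) stop("single class")
    mean(cs)
  }
  r3 <- bootstrapCI(aucm, y, resamples = 300, seed = 3)
  expect_gt(r3@skipped, 0)
  expect_lt(r3@skipped, 300)

  r0 <- bootstrapCI(mean, x, resamples = 0, seed = 1)
  expect_true(is.na(r0@lower) && is.na(r0@upper))
})

test_that("percentile bootstrap CI covers a Bernoulli mean at close to nominal rate", {
  # 500 replications of n = 100 Bernoulli(0.5), 1000 resamples each
  withr::with_seed(71, {
    covered <- logical(500)
    for (i in 1:500) {
      x <- rbinom(100, 1, 0.5)
      r <- bootstrapCI(mean, x, resamples = 1000, seed = i)
      covered[i] <- r@lower <= 0.5 && 0.5 <= r@upper
    }
    expect_gte(mean(covered), 0.93)
    expect_lte(mean(covered), 0.97)
  })
})

test_that("the localization report carries per-label and pooled rows with CIs", {
  withr::with_seed(73, {
    S <- 6
    cases <- list()
    for (lb in c("a", "b")) {
      for (i in 1:6) {
        truth <- rbinom(1, 1, 0.7)
        gt <- if (truth == 1) {
          m <- matrix(rbinom(S * S, 1, 0.4), S, S); if (sum(m) == 0) m[1] <- 1L; m
        } else NULL
        cases[[length(cases) + 1]] <-
          evalCase(paste0(lb, i), lb, truth, matrix(runif(S * S), S, S), gt)
      }
    }
    th <- tuneThresholds(cases, gridSize = 20)
    rep <- evaluateLocalization(cases, th, resamples = 50, seed = 2)
    expect_true(all(c("label", "metric", "estimate", "ci_lower", "ci_upper") %in%
      names(rep)))
    expect_true("mean" %in% rep$label)
    expect_true(all(rep$ci_lower <= rep$estimate + 1e-12))
  })
})
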
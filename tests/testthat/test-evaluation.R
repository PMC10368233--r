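test_that("negative sampling sizes follow the neg = k*pos rule", {
  gr <- genomeGrid("c", 10000, 60)
  lab <- matrix(0L, 60, 60)
  for (i in 1:10) { lab[i, i + 10] <- 1L; lab[i + 10, i] <- 1L }
  lm <- labelMatrix(gr, lab)
  mask <- bandMask(gr, bandSpec(dMin = 2L, dMax = 40L))
  neg5 <- sampleNegatives(lm, mask, 5, seed = 1)
  expect_length(neg5, 50L)
  expect_true(all(lab[mask[neg5, , drop = FALSE]] == 0))
  # distinct draws
  expect_equal(anyDuplicated(neg5), 0L)

  negAll <- sampleNegatives(lm, mask, NA, seed = 1)
  expect_length(negAll, nrow(mask) - 10L)

  expect_warning(negCap <- sampleNegatives(lm, mask, 1e6, seed = 1),
                 "capped")
  expect_length(negCap, nrow(mask) - 10L)

  zero <- labelMatrix(gr, matrix(0L, 60, 60))
  expect_error(sampleNegatives(zero, mask, 5), "no positives")
})

test_that("average precision matches hand-computed examples", {
  expect_equal(averagePrecision(c(0.9, 0.8, 0.7), c(1, 0, 1)),
               (1 + 2 / 3) / 2)
  expect_equal(averagePrecision(c(0.9, 0.5, 0.7), c(1, 1, 1)), 1)
  # single positive ranked last of m
  m <- 25
  sc <- seq(1, 0, length.out = m)
  lab <- c(rep(0, m - 1), 1)
  expect_equal(averagePrecision(sc, lab), 1 / m)
})

test_that("ROC-AUC matches hand-computed examples and tie handling", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.7), c(1, 0, 1)), 0.5)
  expect_equal(rocAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(rocAuc(rep(0.4, 10), c(rep(1, 4), rep(0, 6))), 0.5)
})

test_that("AP and AUC agree with exhaustive brute-force oracles", {
  set.seed(40)
  for (rep in 1:60) {
    n <- sample(5:200, 1)
    scores <- if (rep %% 3 == 0) sample(seq(0, 1, 0.05), n, TRUE)
              else runif(n)  # every third instance is tie-heavy
    labels <- rbinom(n, 1, 0.3)
    if (sum(labels) == 0) labels[sample(n, 1)] <- 1
    if (sum(labels) == n) labels[sample(n, 1)] <- 0
    expect_equal(averagePrecision(scores, labels), bruteAP(scores, labels),
                 tolerance = 1e-12)
    expect_equal(rocAuc(scores, labels), bruteAUC(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("top-N accuracy counts positives among the top ranks", {
  expect_equal(topnAccuracy(c(.9, .8, .7, .6), c(1, 1, 0, 0)), 100)
  expect_equal(topnAccuracy(c(.9, .8, .7, .6), c(1, 0, 1, 0), N = 2), 50)
  expect_equal(topnAccuracy(c(.9, .8, .7, .6), c(0, 0, 1, 1), N = 2), 0)
  # N = P equals recall at rank P
  set.seed(41)
  sc <- runif(100); lab <- rbinom(100, 1, 0.2)
  P <- sum(lab)
  ord <- order(-sc, seq_along(sc))
  expect_equal(topnAccuracy(sc, lab),
               100 * sum(lab[ord[seq_len(P)]]) / P)
  expect_error(topnAccuracy(sc, lab, N = 0), "positive")
})

test_that("the ChIP inner-product baseline applies the +-5 window with clipping", {
  n <- 40
  ones <- rep(1, n)
  mask <- cbind(i = c(15L, 3L, 1L), j = c(25L, 13L, 30L))
  sc <- chipInnerProductBaseline(ones, mask)
  expect_equal(sc[1], 11)        # interior: 11 overlapping offsets
  expect_equal(sc[2], 8)         # i = 3: offsets -2..5
  expect_equal(sc[3], 6)         # i = 1: offsets 0..5
  expect_equal(chipInnerProductBaseline(rep(0, n), mask), c(0, 0, 0))

  # matches a direct loop on a random track
  set.seed(42)
  v <- rexp(n)
  direct <- apply(mask, 1, function(px) {
    s <- 0
    for (a in -5:5) {
      ia <- px[1] + a; ja <- px[2] + a
      if (ia >= 1 && ia <= n && ja >= 1 && ja <= n) s <- s + v[ia] * v[ja]
    }
    s
  })
  expect_equal(chipInnerProductBaseline(v, mask), direct)
})

test_that("evaluation returns perfect metrics for label-as-score input", {
  gr <- genomeGrid("c", 10000, 80)
  lab <- matrix(0L, 80, 80)
  set.seed(43)
  for (q in 1:12) {
    i <- sample(60, 1); j <- i + sample(2:18, 1)
    lab[i, j] <- 1L; lab[j, i] <- 1L
  }
  lm <- labelMatrix(gr, lab)
  pred <- predictionMatrix(gr, lab * 1.0, matrix(1L, 80, 80))
  spec <- evalSpec(bandSpec(dMin = 2L, dMax = 20L),
                   c("pos", "20pos", "all"), nRepeats = 3, seed = 7)
  res <- evaluatePrediction(pred, lm, spec)
  expect_true(all(res$metrics$ap == 1))
  expect_true(all(res$metrics$auc == 1))
  expect_equal(res$topn$accuracy, 100)
  expect_equal(nrow(res$metrics), 3 + 3 + 1)  # 2 sampled modes x3 + all
})

test_that("random scores give chance-level AUC on any negative set", {
  gr <- genomeGrid("c", 10000, 120)
  set.seed(44)
  lab <- matrix(0L, 120, 120)
  for (q in 1:30) {
    i <- sample(90, 1); j <- i + sample(2:25, 1)
    lab[i, j] <- 1L; lab[j, i] <- 1L
  }
  lm <- labelMatrix(gr, lab)
  p <- matrix(runif(120^2), 120); p <- (p + t(p)) / 2
  pred <- predictionMatrix(gr, p, matrix(1L, 120, 120))
  spec <- evalSpec(bandSpec(dMin = 2L, dMax = 30L), c("20pos", "all"),
                   nRepeats = 10, seed = 8)
  res <- evaluatePrediction(pred, lm, spec)
  expect_true(all(abs(res$summary$auc - 0.5) < 0.12))
})

test_that("adding negatives lowers AP in expectation but not AUC", {
  gr <- genomeGrid("c", 10000, 150)
  set.seed(45)
  lab <- matrix(0L, 150, 150)
  for (q in 1:25) {
    i <- sample(120, 1); j <- i + sample(2:28, 1)
    lab[i, j] <- 1L; lab[j, i] <- 1L
  }
  lm <- labelMatrix(gr, lab)
  # informative but imperfect scores: labels + noise
  p <- lab + matrix(rnorm(150^2, sd = 0.4), 150)
  p <- (p + t(p)) / 2
  pred <- predictionMatrix(gr, plogis(p), matrix(1L, 150, 150))
  spec <- evalSpec(bandSpec(dMin = 2L, dMax = 30L),
                   c("pos", "5pos", "20pos", "100pos", "all"),
                   nRepeats = 10, seed = 9)
  res <- evaluatePrediction(pred, lm, spec)
  ap <- res$summary$ap
  expect_true(all(diff(ap) < 0))             # strictly decreasing means
  expect_lt(max(res$summary$auc) - min(res$summary$auc), 0.02)
})
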
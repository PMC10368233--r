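test_that("leave-one-chromosome-out split validates on the largest remaining", {
  sizes <- humanChromBins(10000)
  s <- makeSplit(sizes, "chr1")
  expect_equal(s$val, "chr2")
  expect_equal(s$train, c(paste0("chr", 3:22), "chrX"))

  s2 <- makeSplit(sizes, "chr2")
  expect_equal(s2$val, "chr1")
  expect_equal(s2$train, c(paste0("chr", 3:22), "chrX"))

  s3 <- makeSplit(c(A = 300, B = 400, C = 500), "C")
  expect_equal(s3$val, "B")
  expect_equal(s3$train, "A")

  # ties resolved to the lexicographically smallest name
  s4 <- makeSplit(c(b = 5, a = 5, c = 3, d = 1), "d")
  expect_equal(s4$val, "a")

  expect_error(makeSplit(c(A = 1, B = 2), "A"), "at least 3")
  expect_error(makeSplit(sizes, "chrZ"), "not in chromSizes")
})

# small shared setting for optimizer tests
.tinySamples <- function(seed, n = 8L, W = 12L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    hic <- matrix(rnorm(W * W), W); hic <- (hic + t(hic)) / 2
    lab <- matrix(0, W, W)
    k <- sample(W^2, 8); lab[k] <- 1
    list(origin = 1L, channels = assembleChannels(hic, rnorm(W), "both"),
         labelTile = lab, validBins = W, chrom = sprintf("c%d", i %% 2))
  })
}

test_that("zero learning rate leaves the parameters untouched", {
  s <- .tinySamples(20)
  m <- buildModel(modelConfig(3L, 4L, 1L), seed = 21)
  p0 <- m$params
  # lr must be > 0 by config contract; emulate by an epsilon rate
  fit <- trainModel(m, s[1:6], s[7:8],
                    trainConfig(batchSize = 4L, lr = 1e-30, maxEpochs = 2L,
                                weightDecay = 0, seed = 1))
  # bn3.beta is re-initialized to the prior log-odds by design; everything
  # else must be untouched at a vanishing learning rate
  for (nm in setdiff(names(p0), "bn3.beta"))
    expect_equal(fit$model$params[[nm]], p0[[nm]], tolerance = 1e-12)
  expect_equal(fit$model$params[["bn3.beta"]],
               log(mean(vapply(s[1:6], function(x) mean(x$labelTile), 0)) /
                     (1 - mean(vapply(s[1:6], function(x) mean(x$labelTile),
                                      0)))),
               tolerance = 1e-6)
})

test_that("training is deterministic under a fixed seed", {
  s <- .tinySamples(22)
  cfg <- trainConfig(batchSize = 4L, lr = 0.01, maxEpochs = 3L, seed = 5)
  m1 <- buildModel(modelConfig(3L, 4L, 1L), seed = 23)
  m2 <- buildModel(modelConfig(3L, 4L, 1L), seed = 23)
  f1 <- trainModel(m1, s[1:6], s[7:8], cfg)
  f2 <- trainModel(m2, s[1:6], s[7:8], cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("the returned checkpoint is the epoch with minimal validation loss", {
  s <- .tinySamples(24)
  m <- buildModel(modelConfig(3L, 4L, 1L), seed = 25)
  fit <- trainModel(m, s[1:6], s[7:8],
                    trainConfig(batchSize = 4L, lr = 0.02, maxEpochs = 5L,
                                seed = 2))
  expect_equal(fit$history$valLoss[fit$bestEpoch],
               min(fit$history$valLoss))
  # loss history is complete and finite
  expect_equal(nrow(fit$history), 5L)
  expect_true(all(is.finite(fit$history$trainLoss)))
})

test_that("training reduces the loss on learnable structure", {
  # planted structure: label = thresholded hic channel (learnable quickly)
  set.seed(26)
  W <- 16L
  mk <- function(i) {
    hic <- matrix(rnorm(W * W), W); hic <- (hic + t(hic)) / 2
    lab <- (hic > 1) * 1
    list(origin = 1L, channels = assembleChannels(hic, rnorm(W), "both"),
         labelTile = lab, validBins = W, chrom = "c")
  }
  s <- lapply(1:10, mk)
  m <- buildModel(modelConfig(3L, 8L, 2L), seed = 27)
  fit <- trainModel(m, s[1:8], s[9:10],
                    trainConfig(batchSize = 4L, lr = 0.01, maxEpochs = 10L,
                                seed = 3))
  expect_lt(min(fit$history$valLoss), fit$history$valLoss[1])
})

test_that("sample provenance keeps held-out chromosomes out of training", {
  trio <- simulateTrio(tinyTrioConfig(seed = 28))
  dir <- withr::local_tempdir()
  trioToDataset(trio, dir)
  ds <- prepareDataset(file.path(dir, "manifest.yml"))
  split <- makeSplit(vapply(ds, function(d) nBins(d$hic), integer(1)),
                     "chrB")
  stats <- fitDatasetStats(ds, split$train, 32L, 16L)
  trainS <- datasetSamples(ds, split$train, stats, 32L, 16L, "both")
  valS <- datasetSamples(ds, split$val, stats, 32L, 16L, "both")
  expect_false("chrB" %in% vapply(trainS, `[[`, "", "chrom"))
  expect_false("chrB" %in% vapply(valS, `[[`, "", "chrom"))
  expect_true(all(vapply(valS, `[[`, "", "chrom") == split$val))
})
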
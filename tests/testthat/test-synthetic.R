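test_that("simulation is bitwise reproducible under a fixed seed", {
  cfg <- tinyTrioConfig(seed = 50)
  t1 <- simulateTrio(cfg)
  t2 <- simulateTrio(cfg)
  for (ch in names(t1)) {
    expect_identical(counts(t1[[ch]]$hic), counts(t2[[ch]]$hic))
    expect_identical(trackValues(t1[[ch]]$chip), trackValues(t2[[ch]]$chip))
    expect_identical(t1[[ch]]$loopPixels, t2[[ch]]$loopPixels)
  }
  t3 <- simulateTrio(tinyTrioConfig(seed = 51))
  expect_false(identical(counts(t1$chrA$hic), counts(t3$chrA$hic)))
})

test_that("no loops means an all-zero label matrix", {
  cfg <- syntheticConfig(chromSizes = c(chrA = 100L), nLoops = 0L,
                         nDecoys = 5L, seed = 52)
  trio <- simulateTrio(cfg)
  lab <- anchorsToLabelMatrix(trio$chrA$anchors, grid(trio$chrA$hic))
  expect_equal(sum(pixelLabels(lab)), 0)
  expect_equal(nrow(trio$chrA$loopPixels), 0L)
})

test_that("simulated background counts follow the stated distance decay", {
  cfg <- syntheticConfig(chromSizes = c(chrA = 450L), nLoops = 25L,
                         tadBoost = 2, seed = 53)
  trio <- simulateTrio(cfg)
  tr <- trio$chrA
  cm <- counts(tr$hic)
  n <- nBins(tr$hic)
  # background pixels: same distance, not loop, not same TAD
  bnd <- c(0L, tr$tadBoundaries, n)
  tadOf <- findInterval(seq_len(n) - 1L, bnd)
  isLoop <- matrix(FALSE, n, n)
  isLoop[tr$loopPixels] <- TRUE
  for (d in c(5L, 15L, 30L)) {
    i <- seq_len(n - d); j <- i + d
    keep <- tadOf[i] != tadOf[j] & !isLoop[cbind(i, j)]
    x <- cm[cbind(i[keep], j[keep])]
    mu <- expectedDecay(cfg, d)
    se <- sqrt(mu / length(x))  # Poisson SE of the mean
    expect_lt(abs(mean(x) - mu), 3.5 * se)
  }
})

test_that("planted loop pixels are enriched over distance-matched background", {
  cfg <- tinyTrioConfig(seed = 54)
  trio <- simulateTrio(cfg)
  for (ch in names(trio)) {
    tr <- trio[[ch]]
    cm <- counts(tr$hic)
    d <- tr$loopPixels[, 2] - tr$loopPixels[, 1]
    mu <- expectedDecay(cfg, d)
    # mean observed/expected ratio near the enrichment factor
    ratio <- mean(cm[tr$loopPixels] / mu)
    expect_gt(ratio, cfg$loopEnrichment * 0.5)
  }
})

test_that("labels built from generated anchors equal the planted pixel set", {
  trio <- simulateTrio(tinyTrioConfig(seed = 55))
  for (ch in names(trio)) {
    tr <- trio[[ch]]
    lab <- pixelLabels(anchorsToLabelMatrix(tr$anchors, grid(tr$hic)))
    want <- matrix(0L, nrow(lab), ncol(lab))
    want[tr$loopPixels] <- 1L
    want[tr$loopPixels[, 2:1, drop = FALSE]] <- 1L
    expect_identical(lab, want)
  }
})

test_that("decoy ChIP peaks exist away from loop anchors", {
  trio <- simulateTrio(tinyTrioConfig(seed = 56))
  tr <- trio$chrA
  expect_gt(length(tr$decoyBins), 0)
  expect_length(intersect(tr$decoyBins, tr$anchorBins), 0)
  v <- trackValues(tr$chip)
  # decoy bins carry peak-level signal
  expect_gt(mean(v[tr$decoyBins]), mean(v[-c(tr$anchorBins, tr$decoyBins)]))
})

test_that("written datasets round-trip through the readers", {
  trio <- simulateTrio(tinyTrioConfig(seed = 57))
  dir <- withr::local_tempdir()
  man <- trioToDataset(trio, dir)
  expect_true(file.exists(file.path(dir, "manifest.yml")))

  # BEDPE row count equals total planted loops
  bedpe <- readLines(file.path(dir, "loops.bedpe"))
  expect_length(bedpe,
                sum(vapply(trio, function(t) nrow(t$loopPixels), 0L)))

  ds <- prepareDataset(file.path(dir, "manifest.yml"))
  for (ch in names(trio)) {
    expect_equal(counts(ds[[ch]]$hic), counts(trio[[ch]]$hic))
    expect_equal(trackValues(ds[[ch]]$chip),
                 trackValues(trio[[ch]]$chip), tolerance = 1e-9)
    want <- matrix(0L, nBins(trio[[ch]]$hic), nBins(trio[[ch]]$hic))
    want[trio[[ch]]$loopPixels] <- 1L
    want[trio[[ch]]$loopPixels[, 2:1, drop = FALSE]] <- 1L
    expect_identical(pixelLabels(ds[[ch]]$labels), want)
  }
})

test_that("loop distances outside the band are rejected", {
  cfg <- syntheticConfig(chromSizes = c(chrA = 100L),
                         loopDistanceRange = c(2L, 60L), seed = 58)
  expect_error(simulateTrio(cfg, band = bandSpec(dMin = 2L, dMax = 48L)),
               "outside evaluation band")
})
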
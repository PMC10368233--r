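test_that("triplet contact matrices are binned, mirrored and zero-filled", {
  gr <- genomeGrid("chrT", 10000, 3)
  f <- withr::local_tempfile(fileext = ".txt")

  writeLines("0\t10000\t5", f)
  m <- readContactMatrix(f, gr)
  expect_equal(counts(m), matrix(c(0, 5, 0, 5, 0, 0, 0, 0, 0), 3, 3))

  writeLines(c("10000\t10000\t2", "0\t20000\t7"), f)
  m <- readContactMatrix(f, gr)
  want <- matrix(0, 3, 3)
  want[2, 2] <- 2; want[1, 3] <- 7; want[3, 1] <- 7
  expect_equal(counts(m), want)

  # empty file -> all-zero matrix
  writeLines(character(0), f)
  expect_equal(counts(readContactMatrix(f, gr)), matrix(0, 3, 3))
})

test_that("triplet reader rejects negative counts and out-of-grid bins", {
  gr <- genomeGrid("chrT", 10000, 3)
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0\t10000\t5", "0\t0\t-2"), f)
  expect_warning(m <- readContactMatrix(f, gr), "negative")
  expect_equal(counts(m)[1, 1], 0)
  expect_equal(counts(m)[1, 2], 5)

  writeLines("0\t30000\t1", f)
  expect_error(readContactMatrix(f, gr), "beyond n_bins")

  writeLines(c("0\t10000\t5", "10000\t0\t9"), f)
  expect_warning(m <- readContactMatrix(f, gr), "duplicate")
  expect_equal(counts(m)[1, 2], 9)  # last value kept
})

test_that("dense dialect and triplet round trip preserve entries", {
  gr <- genomeGrid("chrT", 5000, 4)
  set.seed(3)
  cm <- matrix(rpois(16, 4), 4, 4)
  cm[lower.tri(cm)] <- t(cm)[lower.tri(cm)]
  m <- contactMatrix(gr, cm)

  fd <- withr::local_tempfile(fileext = ".txt")
  write.table(cm, fd, row.names = FALSE, col.names = FALSE)
  expect_equal(counts(readContactMatrix(fd, gr, "dense")), cm * 1.0)

  ft <- withr::local_tempfile(fileext = ".txt")
  writeContactMatrix(m, ft)
  expect_equal(counts(readContactMatrix(ft, gr)), cm * 1.0)
})

test_that("cleaning zeroes non-finite entries, flags unmappable rows, and is idempotent", {
  gr <- genomeGrid("chrT", 10000, 6)
  set.seed(4)
  cm <- matrix(runif(36, 1, 5), 6, 6)
  cm[lower.tri(cm)] <- t(cm)[lower.tri(cm)]

  bad <- cm
  bad[4, ] <- NaN; bad[, 4] <- NaN
  cl <- cleanContactMatrix(contactMatrix(gr, bad))
  expect_equal(unmappableBins(cl), 4L)
  expect_true(all(counts(cl)[4, ] == 0) && all(counts(cl)[, 4] == 0))
  expect_identical(counts(cl), t(counts(cl)))

  # a single NaN only kills its pixel (mirrored), not the bin
  one <- cm
  one[2, 3] <- NaN
  cl1 <- cleanContactMatrix(contactMatrix(gr, one))
  expect_equal(counts(cl1)[2, 3], 0)
  expect_equal(counts(cl1)[3, 2], 0)
  expect_length(unmappableBins(cl1), 0)

  # all-finite input unchanged; idempotency
  cl2 <- cleanContactMatrix(contactMatrix(gr, cm))
  expect_equal(counts(cl2), cm)
  expect_equal(counts(cleanContactMatrix(cl)), counts(cl))
  expect_equal(unmappableBins(cleanContactMatrix(cl)), unmappableBins(cl))
})

test_that("bedGraph binning takes coverage-weighted means with zero default", {
  gr <- genomeGrid("chrT", 10000, 8)
  f <- withr::local_tempfile(fileext = ".bedgraph")

  writeLines("chrT\t0\t10000\t4.0", f)
  expect_equal(trackValues(readBedGraphBinned(f, gr))[1], 4.0)

  writeLines(c("chrT\t0\t5000\t2.0", "chrT\t5000\t10000\t6.0"), f)
  tr <- readBedGraphBinned(f, gr)
  expect_equal(trackValues(tr)[1], 4.0)
  expect_equal(trackValues(tr)[8], 0.0)  # uncovered bin

  # interval straddling a bin edge contributes proportionally
  writeLines("chrT\t8000\t12000\t5.0", f)
  tr <- readBedGraphBinned(f, gr)
  expect_equal(trackValues(tr)[1], 5 * 2000 / 10000)
  expect_equal(trackValues(tr)[2], 5 * 2000 / 10000)

  # off-grid chromosomes skipped with warning
  writeLines(c("chrT\t0\t10000\t1.0", "chrZ\t0\t10000\t9.0"), f)
  expect_warning(tr <- readBedGraphBinned(f, gr), "chrZ")
  expect_equal(trackValues(tr)[1], 1.0)
})

test_that("bedGraph binning conserves total signal when intervals tile the grid", {
  gr <- genomeGrid("chrT", 10000, 12)
  set.seed(5)
  # random-width intervals tiling [0, 120000) exactly
  cuts <- sort(sample(seq(1000, 119000, by = 1000), 20))
  edges <- c(0, cuts, 120000)
  vals <- runif(length(edges) - 1, 0, 10)
  f <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(sprintf("chrT\t%d\t%d\t%.12g", head(edges, -1), edges[-1], vals),
             f)
  tr <- readBedGraphBinned(f, gr)
  expect_equal(sum(trackValues(tr)) * 10000, sum(vals * diff(edges)),
               tolerance = 1e-9)
})

test_that("BEDPE reading drops inter-chromosomal rows and orients anchors", {
  f <- withr::local_tempfile(fileext = ".bedpe")
  writeLines(c(
    "chr1\t10050\t19900\tchr1\t1000000\t1009000\tx\t7",
    "chr1\t100\t200\tchr2\t100\t200",
    "chr1\t50000\t60000\tchr1\t1000\t2000"), f)
  expect_message(p <- readBedpe(f), "1 inter-chromosomal")
  expect_length(p, 2L)
  a1 <- S4Vectors::first(p); a2 <- S4Vectors::second(p)
  # 0-based starts recovered; reversed row swapped so start1 <= start2
  expect_equal(GenomicRanges::start(a1) - 1L, c(10050L, 1000L))
  expect_equal(GenomicRanges::start(a2) - 1L, c(1000000L, 50000L))

  writeLines("chr1\t100\tnope\tchr1\t1\t2", f)
  expect_error(readBedpe(f), "row 1")

  writeLines(c("chr1\t100\t200\tchr1\t300\t400",
               "chr1\t500\t500\tchr1\t600\t700"), f)
  expect_warning(p <- readBedpe(f), "end <= start")
  expect_length(p, 1L)
})

test_that("scored BEDPE output is thresholded, sorted, and bp-correct", {
  gr <- genomeGrid("chr9", 10000, 120)
  pm <- matrix(0, 120, 120)
  pm[2, 101] <- 0.9; pm[101, 2] <- 0.9
  pm[5, 30] <- 0.3; pm[30, 5] <- 0.3
  pred <- predictionMatrix(gr, pm, matrix(1L, 120, 120))
  f <- withr::local_tempfile(fileext = ".bedpe")

  expect_equal(writeScoredBedpe(pred, f, minScore = 0.5), 1L)
  row <- strsplit(readLines(f), "\t")[[1]]
  expect_equal(row, c("chr9", "10000", "20000", "chr9", "1000000", "1010000",
                      "0.9"))

  expect_equal(writeScoredBedpe(pred, f, minScore = 1.1), 0L)

  n <- writeScoredBedpe(pred, f, minScore = 0.1)
  expect_equal(n, 2L)
  scores <- vapply(strsplit(readLines(f), "\t"), function(x)
    as.numeric(x[7]), numeric(1))
  expect_equal(scores, c(0.9, 0.3))  # descending
})

test_that("gzip-compressed inputs are accepted by all readers", {
  gr <- genomeGrid("chrT", 10000, 3)
  f <- withr::local_tempfile(fileext = ".txt.gz")
  con <- gzfile(f, "w"); writeLines("0\t10000\t5", con); close(con)
  expect_equal(counts(readContactMatrix(f, gr))[1, 2], 5)

  fg <- withr::local_tempfile(fileext = ".bedgraph.gz")
  con <- gzfile(fg, "w"); writeLines("chrT\t0\t10000\t4.0", con); close(con)
  expect_equal(trackValues(readBedGraphBinned(fg, gr))[1], 4.0)

  fb <- withr::local_tempfile(fileext = ".bedpe.gz")
  con <- gzfile(fb, "w")
  writeLines("chr1\t100\t200\tchr1\t300\t400", con); close(con)
  expect_length(readBedpe(fb), 1L)
})
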
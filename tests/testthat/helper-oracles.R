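# Independent brute-force oracles used across tests. These deliberately
# avoid the package's vectorized implementations: they loop, enumerate, or
# apply closed forms directly.

# AP as explicit area under the step PR curve, walking the ranked list.
bruteAP <- function(scores, labels) {
  ord <- order(-scores, seq_along(scores))  # same deterministic tie rule
  y <- labels[ord]
  P <- sum(y)
  tp <- 0
  ap <- 0
  for (q in seq_along(y)) {
    if (y[q] == 1) {
      tp <- tp + 1
      ap <- ap + tp / q
    }
  }
  ap / P
}

# AUC as the exhaustive all-pairs Mann-Whitney count.
bruteAUC <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Label matrix by O(n^2 * pairs) interval-overlap enumeration: for every
# pair, test every bin's bp interval against both anchors directly (strict
# overlap: shared length > 0) and mark the full bin-pair grid.
# Anchors are 0-based half-open bp intervals.
bruteLabels <- function(anchors0, n, r) {
  binS <- (seq_len(n) - 1) * r
  binE <- binS + r
  lab <- matrix(0L, n, n)
  for (p in seq_len(nrow(anchors0))) {
    a <- anchors0[p, ]
    ov1 <- binS < a[2] & binE > a[1]
    ov2 <- binS < a[4] & binE > a[3]
    hit <- outer(ov1, ov2) | outer(ov2, ov1)
    lab[hit] <- 1L
  }
  lab
}

# Pairs object from a 0-based bp anchor table (chrom fixed).
anchorPairs <- function(anchors0, chrom = "chrT") {
  chr <- rep(chrom, nrow(anchors0))
  S4Vectors::Pairs(
    GenomicRanges::GRanges(chr, IRanges::IRanges(
      start = anchors0[, 1] + 1L, end = anchors0[, 2])),
    GenomicRanges::GRanges(chr, IRanges::IRanges(
      start = anchors0[, 3] + 1L, end = anchors0[, 4])))
}

# A small fully coupled synthetic setting shared by unit tests (fast).
tinyTrioConfig <- function(seed = 42L) {
  syntheticConfig(chromSizes = c(chrA = 130L, chrB = 140L, chrC = 150L),
                  nLoops = 15L, nDecoys = 15L,
                  loopDistanceRange = c(4L, 30L), seed = seed)
}
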
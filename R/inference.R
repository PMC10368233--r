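#' Predict interaction probabilities for a whole chromosome
#'
#' Normalizes the inputs with the frozen reference statistics, tiles the
#' chromosome along the diagonal (window \code{W}, stride \code{step}, plus
#' the clipped tail window), runs the network on every tile, and merges:
#' each pixel's probability is the average over all tiles covering it, and
#' the matrix is then symmetrized by averaging with its transpose. Pixels
#' covered by no tile (far off-diagonal) get probability 0. Zero-padded
#' bins of a short chromosome contribute nothing.
#'
#' @param model a trained \code{chiaNetModel}
#' @param hic a cleaned \linkS4class{ContactMatrix} (NULL for
#'   \code{mode = "chip_only"})
#' @param chip a \linkS4class{BinnedTrack} (NULL for
#'   \code{mode = "hic_only"})
#' @param stats frozen reference statistics, list with \code{hic} and/or
#'   \code{chip} elements (see \code{\link{fitReferenceStats}})
#' @param W window size in bins
#' @param step stride in bins
#' @param batchSize tiles per forward pass (CPU default 1)
#' @param shuffle input perturbation control: \code{"none"},
#'   \code{"shuffleHiC"} (permute the normalized matrix) or
#'   \code{"shuffleChIPseq"} (permute the normalized 1D vector before
#'   broadcasting)
#' @param shuffleSeed seed for the permutation
#' @return a \linkS4class{PredictionMatrix}
#' @export
predictChromosome <- function(model, hic = NULL, chip = NULL, stats,
                              W, step, batchSize = 1L,
                              shuffle = c("none", "shuffleHiC",
                                          "shuffleChIPseq"),
                              shuffleSeed = 1L) {
  shuffle <- match.arg(shuffle)
  gr <- if (!is.null(hic)) grid(hic) else grid(chip)
  n <- nBins(gr)
  norm <- normalizeInputs(hic, chip, stats)
  if (shuffle == "shuffleHiC") {
    if (is.null(norm$hicNorm)) stop("no Hi-C input to shuffle")
    norm$hicNorm <- shuffleControl(norm$hicNorm, "shuffleHiC", shuffleSeed)
  } else if (shuffle == "shuffleChIPseq") {
    if (is.null(norm$chipNorm)) stop("no ChIP-seq input to shuffle")
    norm$chipNorm <- shuffleControl(norm$chipNorm, "shuffleChIPseq",
                                    shuffleSeed)
  }
  if (n < 3L) {
    warning("chromosome shorter than the evaluation band; empty prediction")
    return(predictionMatrix(gr, matrix(0, n, n), matrix(0L, n, n)))
  }
  samples <- extractWindowSamples(norm$hicNorm, norm$chipNorm, labels = NULL,
                                  W = W, step = step, mode = model$mode,
                                  chrom = chromName(gr))
  tiles <- list()
  i <- 1L
  while (i <= length(samples)) {
    idx <- i:min(i + batchSize - 1L, length(samples))
    x <- array(0, c(dim(samples[[idx[1L]]]$channels), length(idx)))
    for (q in seq_along(idx)) x[, , , q] <- samples[[idx[q]]]$channels
    pr <- plogis(forwardModel(model, x, train = FALSE)$logits)
    for (q in seq_along(idx)) {
      s <- samples[[idx[q]]]
      tiles[[length(tiles) + 1L]] <- list(origin = s$origin,
                                          validBins = s$validBins,
                                          probs = pr[, , q])
    }
    i <- i + batchSize
  }
  mergeTilePredictions(gr, tiles)
}

#' Merge overlapping tile probabilities into a chromosome prediction
#'
#' Accumulates each tile's probabilities into per-pixel sums and coverage
#' counts, divides (pixels never covered stay 0), and symmetrizes by
#' averaging the matrix with its transpose: a pixel covered by tiles
#' scoring 0.2 and 0.4 reports 0.3. Zero-padded tile bins beyond
#' \code{validBins} contribute nothing. This is the merge rule used by
#' \code{\link{predictChromosome}}.
#'
#' @param gr the \linkS4class{GenomeGrid} of the chromosome
#' @param tiles list of tiles, each a list with \code{origin} (1-based),
#'   \code{validBins}, and \code{probs} (W x W matrix)
#' @return a \linkS4class{PredictionMatrix}
#' @export
mergeTilePredictions <- function(gr, tiles) {
  n <- nBins(gr)
  acc <- matrix(0, n, n)
  cov <- matrix(0L, n, n)
  for (s in tiles) {
    v <- s$validBins
    rng <- s$origin:(s$origin + v - 1L)
    acc[rng, rng] <- acc[rng, rng] + s$probs[seq_len(v), seq_len(v)]
    cov[rng, rng] <- cov[rng, rng] + 1L
  }
  probs <- matrix(0, n, n)
  hit <- cov > 0L
  probs[hit] <- acc[hit] / cov[hit]
  probs <- (probs + t(probs)) / 2
  predictionMatrix(gr, probs, cov)
}

#' Rank band pixels by predicted probability
#'
#' Deterministic ordering: descending probability, ties broken by ascending
#' (i, j).
#'
#' @param pred a \linkS4class{PredictionMatrix} (or plain symmetric matrix)
#' @param mask pixel matrix from \code{\link{bandMask}}
#' @return data.frame with columns \code{i}, \code{j}, \code{prob}, one row
#'   per mask pixel, in rank order
#' @export
rankPixels <- function(pred, mask) {
  p <- if (is(pred, "PredictionMatrix")) probs(pred) else pred
  sc <- p[mask]
  ord <- order(-sc, mask[, 1L], mask[, 2L], method = "radix")
  data.frame(i = mask[ord, 1L], j = mask[ord, 2L], prob = sc[ord])
}

#' Shuffle controls for input attribution
#'
#' Destroys the information in one input while preserving its value
#' distribution: \code{"shuffleChIPseq"} randomly permutes the 1D binned
#' vector (before it is broadcast to the two 2D channels);
#' \code{"shuffleHiC"} randomly permutes the strict upper-triangle entries
#' of the normalized matrix and mirrors them, so the input stays a valid
#' symmetric map. A fixed seed gives an identical permutation across runs.
#'
#' @param x numeric vector (for \code{"shuffleChIPseq"}) or symmetric
#'   matrix (for \code{"shuffleHiC"})
#' @param which which control to apply
#' @param seed RNG seed
#' @return the perturbed vector or matrix
#' @export
shuffleControl <- function(x, which = c("shuffleHiC", "shuffleChIPseq"),
                           seed = 1L) {
  which <- match.arg(which)
  set.seed(seed)
  if (which == "shuffleChIPseq") {
    stopifnot(is.numeric(x), is.null(dim(x)))
    return(x[sample.int(length(x))])
  }
  stopifnot(is.matrix(x), nrow(x) == ncol(x))
  ut <- upper.tri(x)
  v <- x[ut]
  x[ut] <- v[sample.int(length(v))]
  x[lower.tri(x)] <- t(x)[lower.tri(x)]
  x
}
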
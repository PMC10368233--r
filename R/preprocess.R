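#' Log + min-max rescaling of a Hi-C matrix
#'
#' Applies \code{log2(x + 1)} to every contact count, then min-max rescales
#' the whole (per-chromosome) matrix to [0, 1]. A constant matrix maps to all
#' zeros. This compresses the heavy-tailed contact distribution before
#' z-scoring.
#'
#' @param m a \linkS4class{ContactMatrix} or a plain numeric matrix of
#'   non-negative finite counts
#' @return numeric matrix in [0, 1], same shape
#' @export
logMinMax <- function(m) {
  x <- if (is(m, "ContactMatrix")) counts(m) else m
  y <- log2(x + 1)
  lo <- min(y); hi <- max(y)
  if (hi == lo) return(array(0, dim(y)))
  (y - lo) / (hi - lo)
}

#' Min-max rescaling of a ChIP-seq track
#'
#' Per-chromosome min-max normalization of a binned coverage vector to
#' [0, 1]; a constant vector maps to zeros.
#'
#' @param t a \linkS4class{BinnedTrack} or numeric vector
#' @return numeric vector in [0, 1]
#' @export
minMaxTrack <- function(t) {
  x <- if (is(t, "BinnedTrack")) trackValues(t) else t
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(numeric(length(x)))
  (x - lo) / (hi - lo)
}

#' Fit reference normalization statistics
#'
#' Pools every element of the supplied rescaled samples (window tiles for
#' Hi-C, window vectors for ChIP-seq) and returns their mean and population
#' standard deviation. These statistics are fitted once on the training data
#' and frozen, so that other chromosomes and datasets are z-scored with the
#' same reference — mirroring the reuse of one cell type's statistics on all
#' test sets.
#'
#' @param samples a list of numeric arrays/vectors (or a single one)
#' @return a list with elements \code{mean} and \code{sd} (floored at 1e-8
#'   with a warning when degenerate)
#' @export
fitReferenceStats <- function(samples) {
  if (!is.list(samples)) samples <- list(samples)
  stopifnot(length(samples) >= 1L)
  x <- unlist(samples, use.names = FALSE)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s < 1e-8) {
    warning("pooled SD < 1e-8; floored to 1e-8")
    s <- 1e-8
  }
  list(mean = m, sd = s)
}

#' Apply frozen z-score normalization
#'
#' @param x numeric matrix or vector (already min-max rescaled)
#' @param stats reference statistics from \code{\link{fitReferenceStats}}
#' @return \code{(x - stats$mean) / stats$sd}, same shape
#' @export
zscoreApply <- function(x, stats) {
  (x - stats$mean) / stats$sd
}

#' Diagonal sliding-window origins
#'
#' Origins (1-based) of the W x W tiles extracted along the matrix diagonal
#' with the given step. A final clipped origin \code{n - W + 1} is appended
#' when the regular stride leaves a chromosome tail uncovered. When
#' \code{n < W} there is a single origin 1 and the tile is zero-padded
#' beyond bin n.
#'
#' @param n number of bins on the chromosome
#' @param W window size in bins (250 at 10 kb, 500 at 5 kb)
#' @param step stride in bins (50 at 10 kb, 100 at 5 kb)
#' @return increasing integer vector of origins
#' @examples
#' windowOrigins(400, 250, 50)  # 1, 51, 101, 151
#' windowOrigins(401, 250, 50)  # 1, 51, 101, 151, 152
#' @export
windowOrigins <- function(n, W, step) {
  stopifnot(W > 0L, step > 0L)
  if (n < W) return(1L)
  o <- seq.int(1L, n - W + 1L, by = step)
  if (o[length(o)] != n - W + 1L) o <- c(o, n - W + 1L)
  as.integer(o)
}

#' Assemble the multi-channel input tile
#'
#' Builds the C x W x W input tensor for one window: the Hi-C tile plus the
#' 1D ChIP-seq window broadcast into two 2D channels, \code{chip[i]} copied
#' row-wise and \code{chip[j]} column-wise, so the second channel is always
#' the transpose of the third.
#'
#' @param hicTile W x W normalized Hi-C tile (ignored for
#'   \code{"chip_only"})
#' @param chipWindow length-W normalized ChIP-seq window (ignored for
#'   \code{"hic_only"})
#' @param mode \code{"both"} (C = 3: Hi-C, chip-row, chip-col),
#'   \code{"hic_only"} (C = 1) or \code{"chip_only"} (C = 2)
#' @return numeric array with dim \code{c(C, W, W)}
#' @export
assembleChannels <- function(hicTile, chipWindow,
                             mode = c("both", "hic_only", "chip_only")) {
  mode <- match.arg(mode)
  if (mode != "chip_only") {
    stopifnot(is.matrix(hicTile), nrow(hicTile) == ncol(hicTile))
    W <- nrow(hicTile)
  } else {
    W <- length(chipWindow)
  }
  if (mode != "hic_only" && length(chipWindow) != W)
    stop(sprintf("chip window length %d does not match tile size %d",
                 length(chipWindow), W))
  C <- switch(mode, both = 3L, hic_only = 1L, chip_only = 2L)
  out <- array(0, c(C, W, W))
  k <- 1L
  if (mode != "chip_only") {
    out[k, , ] <- hicTile
    k <- k + 1L
  }
  if (mode != "hic_only") {
    out[k, , ] <- matrix(chipWindow, W, W)        # chip[i] row-wise
    out[k + 1L, , ] <- matrix(chipWindow, W, W, byrow = TRUE)  # chip[j]
  }
  out
}

#' Extract diagonal window samples from one chromosome
#'
#' Runs the full per-chromosome preparation: takes the z-scored Hi-C matrix
#' and ChIP-seq vector, slides a W x W window along the diagonal with the
#' given step (plus the clipped tail origin), and assembles one multi-channel
#' sample per origin, together with its label tile when labels are supplied.
#' Chromosomes shorter than W yield a single zero-padded sample with
#' \code{validBins < W}.
#'
#' @param hicNorm z-scored n x n Hi-C matrix (or NULL for
#'   \code{mode = "chip_only"})
#' @param chipNorm z-scored length-n ChIP-seq vector (or NULL for
#'   \code{mode = "hic_only"})
#' @param labels optional \linkS4class{LabelMatrix} (or plain 0/1 matrix)
#' @param W window size in bins
#' @param step stride in bins
#' @param mode channel configuration, see \code{\link{assembleChannels}}
#' @param chrom chromosome name tag carried on each sample (provenance for
#'   split auditing)
#' @return list of samples; each sample is a list with \code{origin},
#'   \code{channels} (C x W x W), \code{labelTile} (W x W or NULL),
#'   \code{validBins}, \code{chrom}
#' @export
extractWindowSamples <- function(hicNorm, chipNorm, labels = NULL, W, step,
                                 mode = c("both", "hic_only", "chip_only"),
                                 chrom = NA_character_) {
  mode <- match.arg(mode)
  n <- if (!is.null(hicNorm)) nrow(hicNorm) else length(chipNorm)
  lab <- if (is(labels, "LabelMatrix")) pixelLabels(labels) else labels
  lapply(windowOrigins(n, W, step), function(o) {
    idx <- o:min(o + W - 1L, n)
    valid <- length(idx)
    hicTile <- NULL
    if (mode != "chip_only") {
      hicTile <- matrix(0, W, W)
      hicTile[seq_len(valid), seq_len(valid)] <- hicNorm[idx, idx]
    }
    chipWin <- NULL
    if (mode != "hic_only") {
      chipWin <- numeric(W)
      chipWin[seq_len(valid)] <- chipNorm[idx]
    }
    labTile <- NULL
    if (!is.null(lab)) {
      labTile <- matrix(0, W, W)
      labTile[seq_len(valid), seq_len(valid)] <- lab[idx, idx]
    }
    list(origin = o, channels = assembleChannels(hicTile, chipWin, mode),
         labelTile = labTile, validBins = valid, chrom = chrom)
  })
}

#' Normalize a chromosome's Hi-C and ChIP-seq inputs
#'
#' Convenience wrapper chaining \code{\link{logMinMax}} /
#' \code{\link{minMaxTrack}} with \code{\link{zscoreApply}} under frozen
#' reference statistics.
#'
#' @param hic a \linkS4class{ContactMatrix} (cleaned) or NULL
#' @param chip a \linkS4class{BinnedTrack} or NULL
#' @param stats list with elements \code{hic} and \code{chip}, each a
#'   \code{\link{fitReferenceStats}} result (missing element skips z-scoring
#'   for that input, returning the min-max rescaled values)
#' @return list with \code{hicNorm} (matrix or NULL) and \code{chipNorm}
#'   (vector or NULL)
#' @export
normalizeInputs <- function(hic = NULL, chip = NULL, stats = list()) {
  hicNorm <- NULL
  if (!is.null(hic)) {
    hicNorm <- logMinMax(hic)
    if (!is.null(stats$hic)) hicNorm <- zscoreApply(hicNorm, stats$hic)
  }
  chipNorm <- NULL
  if (!is.null(chip)) {
    chipNorm <- minMaxTrack(chip)
    if (!is.null(stats$chip)) chipNorm <- zscoreApply(chipNorm, stats$chip)
  }
  list(hicNorm = hicNorm, chipNorm = chipNorm)
}
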
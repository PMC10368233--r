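#' Genomic-distance evaluation band
#'
#' ChIA-PET interactions live in a limited genomic-distance range, so
#' evaluation is restricted to pixels whose bin distance \code{d = j - i}
#' falls in a band. The lower bound is 2 bins (the diagonal and its first
#' off-diagonal are never evaluated); the upper bound defaults to 2 Mb, i.e.
#' \code{dMax = floor(maxDistance / r)}: bins 2-200 at 10 kb resolution and
#' 2-400 at 5 kb.
#'
#' @param resolution bin size in bp (ignored when \code{dMax} is given
#'   directly)
#' @param maxDistance upper band bound in bp
#' @param dMin lower band bound in bins (default 2)
#' @param dMax upper band bound in bins, overriding the bp-derived value
#' @return a list with integer elements \code{dMin} and \code{dMax}
#' @examples
#' bandSpec(10000)  # dMin 2, dMax 200
#' bandSpec(5000)   # dMin 2, dMax 400
#' @export
bandSpec <- function(resolution = NULL, maxDistance = 2e6, dMin = 2L,
                     dMax = NULL) {
  if (is.null(dMax)) {
    stopifnot(!is.null(resolution))
    dMax <- as.integer(floor(maxDistance / resolution))
  }
  dMin <- as.integer(dMin); dMax <- as.integer(dMax)
  if (dMin < 1L || dMax < dMin)
    stop("need 0 < dMin <= dMax")
  list(dMin = dMin, dMax = dMax)
}

#' Convert ChIA-PET anchor pairs to a binary label matrix
#'
#' Pixel (i, j) is set to 1 when bin i's bp interval intersects the first
#' anchor and bin j's the second anchor of some interaction (or the
#' transpose), with strict interval intersection (shared length > 0). Anchors
#' shorter than one bin light a single pixel; anchors straddling a bin edge
#' light every bin they touch. Pixels beyond the grid are ignored.
#'
#' @param pairs a \code{\link[S4Vectors]{Pairs}} of anchor
#'   \code{\link[GenomicRanges]{GRanges}} as returned by
#'   \code{\link{readBedpe}}
#' @param grid a \linkS4class{GenomeGrid}; pairs on other chromosomes are
#'   ignored
#' @return a \linkS4class{LabelMatrix}
#' @export
anchorsToLabelMatrix <- function(pairs, grid) {
  n <- nBins(grid)
  r <- resolution(grid)
  lab <- matrix(0L, n, n)
  if (length(pairs)) {
    a1 <- S4Vectors::first(pairs)
    a2 <- S4Vectors::second(pairs)
    keep <- as.character(GenomicRanges::seqnames(a1)) == chromName(grid)
    a1 <- a1[keep]; a2 <- a2[keep]
    # bins overlapped by [s0, e0): floor(s0/r)+1 .. floor((e0-1)/r)+1
    binRange <- function(gr) {
      s0 <- GenomicRanges::start(gr) - 1L
      e0 <- GenomicRanges::end(gr)
      cbind(s0 %/% r + 1L, (e0 - 1L) %/% r + 1L)
    }
    b1 <- binRange(a1)
    b2 <- binRange(a2)
    for (p in seq_along(a1)) {
      i <- seq.int(max(1L, b1[p, 1L]), min(n, b1[p, 2L]))
      j <- seq.int(max(1L, b2[p, 1L]), min(n, b2[p, 2L]))
      if (b1[p, 1L] > n || b1[p, 2L] < 1L ||
          b2[p, 1L] > n || b2[p, 2L] < 1L) next
      idx <- as.matrix(expand.grid(i = i, j = j))
      lab[idx] <- 1L
      lab[idx[, 2:1, drop = FALSE]] <- 1L
    }
  }
  labelMatrix(grid, lab)
}

#' Enumerate the upper-triangle pixels of the evaluation band
#'
#' Returns every pixel (i, j) with \code{i < j} and
#' \code{dMin <= j - i <= dMax}, excluding pixels touching unmappable bins.
#' Each interaction is counted once (upper triangle only).
#'
#' @param grid a \linkS4class{GenomeGrid}
#' @param band a band from \code{\link{bandSpec}}
#' @param unmappable integer vector of 1-based unmappable bin indices
#' @return integer matrix with columns \code{i}, \code{j}, ordered by (i, j)
#' @export
bandMask <- function(grid, band, unmappable = integer(0)) {
  n <- nBins(grid)
  ds <- seq.int(band$dMin, min(band$dMax, n - 1L))
  ij <- do.call(rbind, lapply(ds, function(d) {
    i <- seq_len(n - d)
    cbind(i = i, j = i + d)
  }))
  if (is.null(ij))
    ij <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j")))
  if (length(unmappable))
    ij <- ij[!(ij[, 1L] %in% unmappable | ij[, 2L] %in% unmappable), ,
             drop = FALSE]
  ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE]
}

#' Count positive and negative pixels inside a mask
#'
#' @param labels a \linkS4class{LabelMatrix}
#' @param mask a pixel matrix from \code{\link{bandMask}}
#' @return named integer vector \code{c(nPos, nNeg)}
#' @export
countPosNeg <- function(labels, mask) {
  lab <- pixelLabels(labels)
  nPos <- sum(lab[mask])
  c(nPos = as.integer(nPos), nNeg = nrow(mask) - as.integer(nPos))
}
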
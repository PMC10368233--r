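#' @useDynLib chiaNet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rnorm rpois rexp runif sd setNames plogis
#' @importFrom utils head tail modifyList
#' @importFrom data.table fread fwrite data.table as.data.table rbindlist
NULL

#' GenomeGrid: a fixed-resolution binning of one chromosome
#'
#' A \code{GenomeGrid} describes how one chromosome is cut into fixed-size
#' bins: bin \code{b} (1-based) covers the 0-based half-open bp interval
#' \code{[(b-1)*r, b*r)} where \code{r} is the resolution. Every matrix and
#' track in the package is indexed by such a grid.
#'
#' @slot chrom chromosome name
#' @slot resolution bin size in bp (10000 or 5000 typical)
#' @slot nBins number of bins
#' @export
setClass("GenomeGrid", representation(
  chrom = "character",
  resolution = "integer",
  nBins = "integer"
))

setValidity("GenomeGrid", function(object) {
  msg <- NULL
  if (length(object@chrom) != 1L || !nzchar(object@chrom))
    msg <- c(msg, "'chrom' must be a single non-empty string")
  if (length(object@resolution) != 1L || is.na(object@resolution) ||
      object@resolution < 1L)
    msg <- c(msg, "'resolution' must be a positive integer")
  if (length(object@nBins) != 1L || is.na(object@nBins) || object@nBins < 1L)
    msg <- c(msg, "'nBins' must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' Construct a GenomeGrid
#'
#' @param chrom chromosome name, e.g. \code{"chr1"}
#' @param resolution bin size in bp
#' @param nBins number of bins on the chromosome
#' @return a \linkS4class{GenomeGrid}
#' @examples
#' genomeGrid("chr1", 10000, 500)
#' @export
genomeGrid <- function(chrom, resolution, nBins) {
  new("GenomeGrid", chrom = as.character(chrom),
      resolution = as.integer(resolution), nBins = as.integer(nBins))
}

#' ContactMatrix: a dense symmetric Hi-C matrix for one chromosome
#'
#' Holds the (already balanced, e.g. KR-normalized) contact counts as a dense
#' symmetric \code{n x n} matrix on a \linkS4class{GenomeGrid}. Bins whose
#' whole row is zero after cleaning (assembly gaps, unbalanced bins) are
#' recorded in \code{unmappableBins} and excluded from evaluation downstream.
#'
#' @slot grid the \linkS4class{GenomeGrid}
#' @slot counts numeric n x n matrix, finite and >= 0 after cleaning
#' @slot unmappableBins integer vector of 1-based bin indices with all-zero rows
#' @export
setClass("ContactMatrix", representation(
  grid = "GenomeGrid",
  counts = "matrix",
  unmappableBins = "integer"
))

setValidity("ContactMatrix", function(object) {
  msg <- NULL
  n <- object@grid@nBins
  if (!is.numeric(object@counts)) msg <- c(msg, "'counts' must be numeric")
  if (nrow(object@counts) != n || ncol(object@counts) != n)
    msg <- c(msg, sprintf("'counts' must be %d x %d", n, n))
  if (any(object@unmappableBins < 1L | object@unmappableBins > n))
    msg <- c(msg, "'unmappableBins' out of range")
  if (is.null(msg)) TRUE else msg
})

#' @rdname ContactMatrix-class
#' @param grid a \linkS4class{GenomeGrid}
#' @param counts numeric n x n matrix
#' @param unmappableBins integer vector of unmappable bin indices
#' @return a \linkS4class{ContactMatrix}
#' @export
contactMatrix <- function(grid, counts, unmappableBins = integer(0)) {
  storage.mode(counts) <- "double"
  new("ContactMatrix", grid = grid, counts = counts,
      unmappableBins = as.integer(unmappableBins))
}

#' BinnedTrack: per-bin ChIP-seq coverage on a GenomeGrid
#'
#' A 1D vector of mean coverage per bin, the binned representation of a
#' ChIP-seq (or any bedGraph) signal.
#'
#' @slot grid the \linkS4class{GenomeGrid}
#' @slot values numeric vector of length \code{nBins(grid)}
#' @export
setClass("BinnedTrack", representation(
  grid = "GenomeGrid",
  values = "numeric"
))

setValidity("BinnedTrack", function(object) {
  if (length(object@values) != object@grid@nBins)
    return("'values' length must equal nBins(grid)")
  TRUE
})

#' @rdname BinnedTrack-class
#' @param grid a \linkS4class{GenomeGrid}
#' @param values numeric vector, one value per bin
#' @return a \linkS4class{BinnedTrack}
#' @export
binnedTrack <- function(grid, values) {
  new("BinnedTrack", grid = grid, values = as.numeric(values))
}

#' LabelMatrix: binary per-pixel ChIA-PET ground truth
#'
#' Symmetric 0/1 matrix; pixel (i, j) is 1 when bins i and j overlap the two
#' anchors of some ChIA-PET interaction.
#'
#' @slot grid the \linkS4class{GenomeGrid}
#' @slot labels integer n x n matrix with entries in \{0, 1\}
#' @export
setClass("LabelMatrix", representation(
  grid = "GenomeGrid",
  labels = "matrix"
))

setValidity("LabelMatrix", function(object) {
  msg <- NULL
  n <- object@grid@nBins
  if (nrow(object@labels) != n || ncol(object@labels) != n)
    msg <- c(msg, sprintf("'labels' must be %d x %d", n, n))
  if (!all(object@labels %in% c(0L, 1L)))
    msg <- c(msg, "'labels' entries must be 0 or 1")
  if (!identical(object@labels, t(object@labels)))
    msg <- c(msg, "'labels' must be symmetric")
  if (is.null(msg)) TRUE else msg
})

#' @rdname LabelMatrix-class
#' @param grid a \linkS4class{GenomeGrid}
#' @param labels integer n x n 0/1 symmetric matrix
#' @return a \linkS4class{LabelMatrix}
#' @export
labelMatrix <- function(grid, labels) {
  storage.mode(labels) <- "integer"
  new("LabelMatrix", grid = grid, labels = labels)
}

#' PredictionMatrix: symmetric per-pixel interaction probabilities
#'
#' Final output of tiled inference: per-pixel probabilities averaged over all
#' tiles covering each pixel and symmetrized, plus the per-pixel count of tile
#' predictions that went into the average.
#'
#' @slot grid the \linkS4class{GenomeGrid}
#' @slot probs numeric n x n symmetric matrix in [0, 1]
#' @slot coverage integer n x n symmetric matrix of tile counts
#' @export
setClass("PredictionMatrix", representation(
  grid = "GenomeGrid",
  probs = "matrix",
  coverage = "matrix"
))

setValidity("PredictionMatrix", function(object) {
  msg <- NULL
  n <- object@grid@nBins
  if (nrow(object@probs) != n || ncol(object@probs) != n)
    msg <- c(msg, sprintf("'probs' must be %d x %d", n, n))
  if (!all(is.finite(object@probs)))
    msg <- c(msg, "'probs' must be finite")
  if (any(dim(object@coverage) != c(n, n)))
    msg <- c(msg, sprintf("'coverage' must be %d x %d", n, n))
  if (any(object@coverage < 0L))
    msg <- c(msg, "'coverage' must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' @rdname PredictionMatrix-class
#' @param grid a \linkS4class{GenomeGrid}
#' @param probs numeric n x n matrix of probabilities
#' @param coverage integer n x n matrix of per-pixel tile counts
#' @return a \linkS4class{PredictionMatrix}
#' @export
predictionMatrix <- function(grid, probs, coverage) {
  storage.mode(probs) <- "double"
  storage.mode(coverage) <- "integer"
  new("PredictionMatrix", grid = grid, probs = probs, coverage = coverage)
}
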
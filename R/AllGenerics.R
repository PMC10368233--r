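#' Accessors for chiaNet data classes
#'
#' @param x a \linkS4class{GenomeGrid}, \linkS4class{ContactMatrix},
#'   \linkS4class{BinnedTrack}, \linkS4class{LabelMatrix} or
#'   \linkS4class{PredictionMatrix}
#' @return the requested slot (name, resolution in bp, number of bins, or the
#'   underlying matrix/vector)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("chromName", function(x) standardGeneric("chromName"))
#' @rdname accessors
#' @export
setGeneric("resolution", function(x) standardGeneric("resolution"))
#' @rdname accessors
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))
#' @rdname accessors
#' @export
setGeneric("grid", function(x) standardGeneric("grid"))
#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
#' @rdname accessors
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))
#' @rdname accessors
#' @export
setGeneric("pixelLabels", function(x) standardGeneric("pixelLabels"))
#' @rdname accessors
#' @export
setGeneric("probs", function(x) standardGeneric("probs"))
#' @rdname accessors
#' @export
setGeneric("tileCoverage", function(x) standardGeneric("tileCoverage"))
#' @rdname accessors
#' @export
setGeneric("unmappableBins", function(x) standardGeneric("unmappableBins"))

#' @rdname accessors
setMethod("chromName", "GenomeGrid", function(x) x@chrom)
#' @rdname accessors
setMethod("resolution", "GenomeGrid", function(x) x@resolution)
#' @rdname accessors
setMethod("nBins", "GenomeGrid", function(x) x@nBins)

for (cls in c("ContactMatrix", "BinnedTrack", "LabelMatrix",
              "PredictionMatrix")) {
  setMethod("grid", cls, function(x) x@grid)
  setMethod("chromName", cls, function(x) x@grid@chrom)
  setMethod("resolution", cls, function(x) x@grid@resolution)
  setMethod("nBins", cls, function(x) x@grid@nBins)
}

#' @rdname accessors
setMethod("counts", "ContactMatrix", function(x) x@counts)
#' @rdname accessors
setMethod("unmappableBins", "ContactMatrix", function(x) x@unmappableBins)
#' @rdname accessors
setMethod("trackValues", "BinnedTrack", function(x) x@values)
#' @rdname accessors
setMethod("pixelLabels", "LabelMatrix", function(x) x@labels)
#' @rdname accessors
setMethod("probs", "PredictionMatrix", function(x) x@probs)
#' @rdname accessors
setMethod("tileCoverage", "PredictionMatrix", function(x) x@coverage)

setMethod("show", "GenomeGrid", function(object) {
  cat(sprintf("GenomeGrid: %s, %d bins @ %d bp (%.1f Mb)\n",
              object@chrom, object@nBins, object@resolution,
              object@nBins * object@resolution / 1e6))
})

setMethod("show", "ContactMatrix", function(object) {
  cat(sprintf(
    "ContactMatrix: %s, %d x %d @ %d bp; %d unmappable bins; total %.4g\n",
    object@grid@chrom, object@grid@nBins, object@grid@nBins,
    object@grid@resolution, length(object@unmappableBins),
    sum(object@counts)))
})

setMethod("show", "BinnedTrack", function(object) {
  cat(sprintf("BinnedTrack: %s, %d bins @ %d bp; mean %.4g, max %.4g\n",
              object@grid@chrom, object@grid@nBins, object@grid@resolution,
              mean(object@values), max(object@values)))
})

setMethod("show", "LabelMatrix", function(object) {
  ut <- upper.tri(object@labels)
  cat(sprintf("LabelMatrix: %s, %d x %d; %d positive pixels (upper triangle)\n",
              object@grid@chrom, object@grid@nBins, object@grid@nBins,
              sum(object@labels[ut])))
})

setMethod("show", "PredictionMatrix", function(object) {
  cat(sprintf(
    "PredictionMatrix: %s, %d x %d; prob range [%.3f, %.3f]; max coverage %d\n",
    object@grid@chrom, object@grid@nBins, object@grid@nBins,
    min(object@probs), max(object@probs), max(object@coverage)))
})
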
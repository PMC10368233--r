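# fread for possibly gzip-compressed text without extra dependencies
.freadAuto <- function(path, ...) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "r")
    on.exit(close(con))
    lines <- readLines(con)
    if (!length(lines))
      return(data.table::data.table())
    return(data.table::fread(text = lines, ...))
  }
  data.table::fread(path, ...)
}

#' Read a binned Hi-C contact matrix
#'
#' Reads a per-chromosome Hi-C matrix, either as Juicer-dump style sparse
#' triplet text (\code{bp1 bp2 value}, tab/space separated, upper-triangle
#' entries mirrored across the diagonal) or as a dense whitespace matrix.
#' The input is expected to be already balanced (e.g. KR); this reader only
#' bins and mirrors. Plain or gzip-compressed files are accepted.
#'
#' Triplet bp positions need not be multiples of the resolution; they are
#' floored to their bin. Pairs absent from the file are 0. Duplicate entries
#' for the same (mirrored) pixel overwrite earlier ones with a warning.
#'
#' @param path file to read
#' @param grid a \linkS4class{GenomeGrid}
#' @param dialect \code{"triplet"} (default) or \code{"dense"}
#' @return a \linkS4class{ContactMatrix} (not yet cleaned; see
#'   \code{\link{cleanContactMatrix}})
#' @seealso \code{\link{writeContactMatrix}} for the inverse
#' @export
readContactMatrix <- function(path, grid, dialect = c("triplet", "dense")) {
  dialect <- match.arg(dialect)
  n <- nBins(grid)
  r <- resolution(grid)
  if (dialect == "dense") {
    m <- as.matrix(.freadAuto(path, header = FALSE))
    dimnames(m) <- NULL
    if (nrow(m) != n || ncol(m) != n)
      stop(sprintf("dense matrix is %d x %d, expected %d x %d",
                   nrow(m), ncol(m), n, n))
    return(contactMatrix(grid, m))
  }
  m <- matrix(0, n, n)
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0L)
    return(contactMatrix(grid, m))
  dt <- .freadAuto(path, header = FALSE, fill = TRUE)
  if (nrow(dt) == 0L)
    return(contactMatrix(grid, m))
  if (ncol(dt) < 3L)
    stop("triplet input needs 3 columns: bp1 bp2 value")
  bp1 <- suppressWarnings(as.numeric(dt[[1L]]))
  bp2 <- suppressWarnings(as.numeric(dt[[2L]]))
  val <- suppressWarnings(as.numeric(dt[[3L]]))
  bad <- which(is.na(bp1) | is.na(bp2))
  if (length(bad))
    stop(sprintf("unparseable triplet row %d: '%s'", bad[1L],
                 paste(unlist(dt[bad[1L]]), collapse = "\t")))
  neg <- which(!is.na(val) & val < 0)
  if (length(neg)) {
    warning(sprintf("rejected %d triplet row(s) with negative counts",
                    length(neg)))
  }
  keep <- is.na(val) | val >= 0
  # NaN/NA values are kept as NA entries for cleanContactMatrix to handle
  bp1 <- bp1[keep]; bp2 <- bp2[keep]; val <- val[keep]
  i <- bp1 %/% r + 1L
  j <- bp2 %/% r + 1L
  over <- which(i > n | j > n)
  if (length(over))
    stop(sprintf(
      "triplet row %d (%g, %g) maps to bin beyond n_bins = %d",
      which(keep)[over[1L]], bp1[over[1L]], bp2[over[1L]], n))
  # normalize to upper triangle, later rows overwrite earlier ones
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- (lo - 1) * n + hi
  if (anyDuplicated(key))
    warning(sprintf("%d duplicate pixel(s) in triplet input; last value kept",
                    sum(duplicated(key))))
  m[cbind(lo, hi)] <- val
  m[cbind(hi, lo)] <- val
  contactMatrix(grid, m)
}

#' Write a contact matrix as sparse triplet text
#'
#' Writes the non-zero upper-triangle (including diagonal) entries as
#' \code{bp1 bp2 value} rows, the dialect \code{\link{readContactMatrix}}
#' reads back losslessly.
#'
#' @param m a \linkS4class{ContactMatrix}
#' @param path output file
#' @return invisibly, the number of rows written
#' @export
writeContactMatrix <- function(m, path) {
  r <- resolution(m)
  cm <- counts(m)
  idx <- which(upper.tri(cm, diag = TRUE) & cm != 0, arr.ind = TRUE)
  dt <- data.table::data.table(
    bp1 = (idx[, 1L] - 1) * r,
    bp2 = (idx[, 2L] - 1) * r,
    value = cm[idx])
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(nrow(dt))
}

#' Zero out non-finite Hi-C entries and flag unmappable bins
#'
#' Juicer dumps of KR-balanced matrices carry NaN rows where balancing failed
#' (assembly gaps, low coverage). This replaces every non-finite entry by 0
#' (mirrored, so the matrix stays symmetric), clamps any negative residue to
#' 0, and records bins whose entire row is zero afterwards as unmappable, so
#' evaluation can exclude their pixels. Idempotent.
#'
#' @param m a \linkS4class{ContactMatrix}
#' @return a \linkS4class{ContactMatrix} with finite non-negative counts and
#'   \code{unmappableBins} filled in
#' @export
cleanContactMatrix <- function(m) {
  cm <- counts(m)
  bad <- !is.finite(cm)
  bad <- bad | t(bad)            # mirror so symmetry is preserved
  cm[bad] <- 0
  cm[cm < 0] <- 0
  unmap <- which(rowSums(cm != 0) == 0L)
  contactMatrix(grid(m), cm, unmap)
}

#' Read a bedGraph file binned to a GenomeGrid
#'
#' Imports a 4-column bedGraph (0-based half-open intervals) and computes the
#' mean signal per bin: each interval contributes its value weighted by its
#' overlap length with the bin, and bases covered by no interval count as 0,
#' so a bin's value is \code{sum(value * overlap) / resolution}. This is the
#' binning used for ChIP-seq coverage tracks. Gzip input is accepted.
#'
#' @param path bedGraph file
#' @param grid a \linkS4class{GenomeGrid}; intervals on other chromosomes are
#'   skipped with a warning
#' @return a \linkS4class{BinnedTrack}
#' @export
readBedGraphBinned <- function(path, grid) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  off <- S4Vectors::runValue(GenomicRanges::seqnames(gr))
  off <- setdiff(as.character(off), chromName(grid))
  if (length(off))
    warning(sprintf("skipping intervals on off-grid chromosome(s): %s",
                    paste(off, collapse = ", ")))
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chromName(grid)]
  gr <- gr[GenomicRanges::width(gr) > 0L]
  n <- nBins(grid)
  r <- resolution(grid)
  vals <- numeric(n)
  if (length(gr) == 0L)
    return(binnedTrack(grid, vals))
  bins <- GenomicRanges::GRanges(
    chromName(grid),
    IRanges::IRanges(start = (seq_len(n) - 1L) * r + 1L, width = r))
  hits <- GenomicRanges::findOverlaps(gr, bins)
  ov <- GenomicRanges::pintersect(gr[S4Vectors::queryHits(hits)],
                                  bins[S4Vectors::subjectHits(hits)])
  w <- GenomicRanges::width(ov)
  contrib <- gr$score[S4Vectors::queryHits(hits)] * w
  agg <- tapply(contrib, S4Vectors::subjectHits(hits), sum)
  vals[as.integer(names(agg))] <- as.numeric(agg) / r
  binnedTrack(grid, vals)
}

#' Read ChIA-PET interactions from a BEDPE file
#'
#' Reads a >= 6 column tab-separated BEDPE (chrom1, start1, end1, chrom2,
#' start2, end2; extra columns ignored; 0-based half-open coordinates).
#' Inter-chromosomal rows are dropped with a message; anchors are normalized
#' so the first anchor starts no later than the second. Gzip input is
#' accepted.
#'
#' @param path BEDPE file
#' @return a \code{\link[S4Vectors]{Pairs}} of two parallel
#'   \code{\link[GenomicRanges]{GRanges}}, one row per intra-chromosomal
#'   interaction
#' @export
readBedpe <- function(path) {
  dt <- .freadAuto(path, header = FALSE, fill = TRUE,
                   colClasses = "character")
  if (nrow(dt) == 0L || ncol(dt) < 6L)
    stop("BEDPE input needs at least 6 tab-separated columns")
  num <- function(k) suppressWarnings(as.numeric(dt[[k]]))
  s1 <- num(2L); e1 <- num(3L); s2 <- num(5L); e2 <- num(6L)
  bad <- which(is.na(s1) | is.na(e1) | is.na(s2) | is.na(e2) |
                 !nzchar(dt[[1L]]) | !nzchar(dt[[4L]]))
  if (length(bad))
    stop(sprintf("malformed BEDPE row %d: '%s'", bad[1L],
                 paste(unlist(dt[bad[1L]]), collapse = "\t")))
  if (any(e1 <= s1 | e2 <= s2)) {
    drop <- e1 <= s1 | e2 <= s2
    warning(sprintf("rejected %d BEDPE row(s) with end <= start", sum(drop)))
    dt <- dt[!drop]; s1 <- s1[!drop]; e1 <- e1[!drop]
    s2 <- s2[!drop]; e2 <- e2[!drop]
  }
  intra <- dt[[1L]] == dt[[4L]]
  if (any(!intra))
    message(sprintf("dropped %d inter-chromosomal BEDPE row(s)", sum(!intra)))
  dt <- dt[intra]; s1 <- s1[intra]; e1 <- e1[intra]
  s2 <- s2[intra]; e2 <- e2[intra]
  swap <- s1 > s2
  tmp <- s1[swap]; s1[swap] <- s2[swap]; s2[swap] <- tmp
  tmp <- e1[swap]; e1[swap] <- e2[swap]; e2[swap] <- tmp
  a1 <- GenomicRanges::GRanges(dt[[1L]],
                               IRanges::IRanges(start = s1 + 1L, end = e1))
  a2 <- GenomicRanges::GRanges(dt[[1L]],
                               IRanges::IRanges(start = s2 + 1L, end = e2))
  S4Vectors::Pairs(a1, a2)
}

#' Write ranked pixel predictions as scored BEDPE
#'
#' Writes one BEDPE row per upper-triangle pixel with probability >=
#' \code{minScore}, 7th column the probability, coordinates the 0-based
#' half-open bp intervals of the two bins, sorted by descending probability
#' (ties by ascending (i, j)).
#'
#' @param pred a \linkS4class{PredictionMatrix}
#' @param path output file
#' @param minScore minimum probability to report
#' @param mask optional two-column matrix of (i, j) pixels to restrict to
#'   (e.g. from \code{\link{bandMask}}); default all upper-triangle pixels
#' @return invisibly, the number of rows written
#' @export
writeScoredBedpe <- function(pred, path, minScore = 0, mask = NULL) {
  p <- probs(pred)
  if (is.null(mask)) {
    mask <- which(upper.tri(p), arr.ind = TRUE)
    colnames(mask) <- c("i", "j")
  }
  ranked <- rankPixels(pred, mask)
  ranked <- ranked[ranked$prob >= minScore, , drop = FALSE]
  r <- resolution(pred)
  chrom <- chromName(pred)
  dt <- data.table::data.table(
    chrom1 = chrom, start1 = as.integer((ranked$i - 1) * r),
    end1 = as.integer(ranked$i * r),
    chrom2 = chrom, start2 = as.integer((ranked$j - 1) * r),
    end2 = as.integer(ranked$j * r),
    score = ranked$prob)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(nrow(dt))
}
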
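#' Configuration of the coupled synthetic chromosome generator
#'
#' Generates per-chromosome triples (Hi-C contact matrix, ChIP-seq track,
#' ChIA-PET anchor pairs) with planted structure, so the whole pipeline is
#' exercisable without external data. The generative model is the minimal
#' one reproducing the qualitative features of real contact maps:
#' a distance-decay power law \code{mu(i, j) = A * (1 + |i - j|)^(-alpha)},
#' multiplicative TAD-block enrichment, multiplicative loop enrichment at
#' planted pixels, Poisson counts; ChIP-seq is exponential background plus
#' peaks at every loop-anchor bin, peaks at decoy bins that carry no loop
#' (so ChIP-seq alone cannot classify perfectly), and Gaussian jitter.
#'
#' @param chromSizes named integer vector of bins per chromosome
#' @param resolution bin size in bp
#' @param decayAmplitude expected diagonal count A
#' @param decayExponent power-law exponent alpha
#' @param tadMeanSize mean TAD size in bins (boundaries drawn uniformly in
#'   0.75-1.25 times this)
#' @param tadBoost multiplicative within-TAD contact enrichment (> 1)
#' @param nLoops planted loops per chromosome
#' @param loopDistanceRange (lo, hi) allowed loop distances in bins; must
#'   lie inside the evaluation band
#' @param loopEnrichment multiplicative Hi-C enrichment at loop pixels (> 1)
#' @param chipPeakAmplitude mean added coverage at peak bins
#' @param chipBackgroundMean mean of the exponential background coverage
#' @param chipNoiseSd SD of the Gaussian jitter added to the track
#' @param nDecoys number of decoy ChIP peaks (non-anchor bins) per
#'   chromosome
#' @param seed RNG seed; the same seed reproduces the trio bitwise
#' @return a \code{chiaNetSyntheticConfig} list
#' @export
syntheticConfig <- function(chromSizes = c(chrS1 = 480L, chrS2 = 520L,
                                           chrS3 = 560L),
                            resolution = 10000L,
                            decayAmplitude = 120,
                            decayExponent = 1.0,
                            tadMeanSize = 80L,
                            tadBoost = 1.6,
                            nLoops = 60L,
                            loopDistanceRange = c(5L, 45L),
                            loopEnrichment = 4,
                            chipPeakAmplitude = 8,
                            chipBackgroundMean = 1,
                            chipNoiseSd = 0.3,
                            nDecoys = 60L,
                            seed = 1L) {
  stopifnot(length(chromSizes) >= 1L, !is.null(names(chromSizes)),
            decayAmplitude > 0, decayExponent > 0, tadBoost > 1,
            loopEnrichment > 1, loopDistanceRange[1L] >= 1L,
            loopDistanceRange[2L] >= loopDistanceRange[1L],
            chipPeakAmplitude > 0, chipBackgroundMean > 0, nDecoys >= 0L)
  structure(list(chromSizes = chromSizes,
                 resolution = as.integer(resolution),
                 decayAmplitude = decayAmplitude,
                 decayExponent = decayExponent,
                 tadMeanSize = as.integer(tadMeanSize),
                 tadBoost = tadBoost,
                 nLoops = as.integer(nLoops),
                 loopDistanceRange = as.integer(loopDistanceRange),
                 loopEnrichment = loopEnrichment,
                 chipPeakAmplitude = chipPeakAmplitude,
                 chipBackgroundMean = chipBackgroundMean,
                 chipNoiseSd = chipNoiseSd,
                 nDecoys = as.integer(nDecoys),
                 seed = as.integer(seed)),
            class = "chiaNetSyntheticConfig")
}

#' Expected background Hi-C count of the generator
#'
#' Closed form \code{A * (1 + d)^(-alpha)} used both by the simulator and
#' as the independent check of its output.
#'
#' @param cfg a \code{\link{syntheticConfig}}
#' @param d genomic distance in bins
#' @return expected count (before TAD/loop enrichment)
#' @export
expectedDecay <- function(cfg, d) {
  cfg$decayAmplitude * (1 + d)^(-cfg$decayExponent)
}

.simulateChromosome <- function(cfg, chrom, n, band) {
  r <- cfg$resolution
  lo <- cfg$loopDistanceRange[1L]; hi <- cfg$loopDistanceRange[2L]
  if (lo < band$dMin || hi > band$dMax)
    stop(sprintf(
      "loop distance range (%d, %d) outside evaluation band (%d, %d)",
      lo, hi, band$dMin, band$dMax))
  # TAD segmentation: boundaries ~ uniform around the mean TAD size
  bnd <- 0L
  while (tail(bnd, 1L) < n) {
    bnd <- c(bnd, tail(bnd, 1L) +
               as.integer(round(runif(1, 0.75, 1.25) * cfg$tadMeanSize)))
  }
  tadOf <- findInterval(seq_len(n) - 1L, bnd)
  # planted loops: distinct pixels at band distances
  loops <- matrix(integer(0), 0, 2)
  guard <- 0L
  while (nrow(loops) < cfg$nLoops && guard < 100L * cfg$nLoops) {
    d <- sample(seq.int(lo, hi), 1L)
    i <- sample.int(n - d, 1L)
    cand <- c(i, i + d)
    if (!nrow(loops) || !any(loops[, 1L] == cand[1L] &
                               loops[, 2L] == cand[2L]))
      loops <- rbind(loops, cand)
    guard <- guard + 1L
  }
  rownames(loops) <- NULL
  # expected counts and Poisson draw, symmetric
  dmat <- abs(outer(seq_len(n), seq_len(n), "-"))
  mu <- cfg$decayAmplitude * (1 + dmat)^(-cfg$decayExponent)
  sameTad <- outer(tadOf, tadOf, "==")
  mu[sameTad] <- mu[sameTad] * cfg$tadBoost
  mu[loops] <- mu[loops] * cfg$loopEnrichment
  mu[loops[, 2:1, drop = FALSE]] <- mu[loops]
  ut <- upper.tri(mu, diag = TRUE)
  cnt <- matrix(0, n, n)
  cnt[ut] <- rpois(sum(ut), mu[ut])
  cnt <- cnt + t(cnt) - diag(diag(cnt))
  hic <- contactMatrix(genomeGrid(chrom, r, n), cnt)
  # ChIP-seq: background + anchor peaks + decoy peaks + jitter
  anchorBins <- sort(unique(as.integer(loops)))
  decoyPool <- setdiff(seq_len(n), anchorBins)
  decoys <- sort(sample(decoyPool, min(cfg$nDecoys, length(decoyPool))))
  chip <- rexp(n, rate = 1 / cfg$chipBackgroundMean)
  peaks <- c(anchorBins, decoys)
  chip[peaks] <- chip[peaks] +
    cfg$chipPeakAmplitude * runif(length(peaks), 0.8, 1.2)
  chip <- pmax(chip + rnorm(n, sd = cfg$chipNoiseSd), 0)
  track <- binnedTrack(genomeGrid(chrom, r, n), chip)
  # anchors: the loop bins' bp intervals (bin-aligned)
  chr <- rep(chrom, nrow(loops))
  a1 <- GenomicRanges::GRanges(chr, IRanges::IRanges(
    start = (loops[, 1L] - 1L) * r + 1L, width = r))
  a2 <- GenomicRanges::GRanges(chr, IRanges::IRanges(
    start = (loops[, 2L] - 1L) * r + 1L, width = r))
  list(hic = hic, chip = track, anchors = S4Vectors::Pairs(a1, a2),
       loopPixels = unname(loops), anchorBins = anchorBins,
       decoyBins = decoys, tadBoundaries = bnd[bnd > 0L & bnd < n])
}

#' Simulate coupled Hi-C / ChIP-seq / ChIA-PET chromosomes
#'
#' Seeded end to end: the same config yields bitwise-identical output.
#'
#' @param cfg a \code{\link{syntheticConfig}}
#' @param band evaluation band the planted loops must respect; default the
#'   band spanned by \code{loopDistanceRange} extended to the package
#'   defaults for the desk-scale setting (2 to 48 bins)
#' @return named list (one element per chromosome), each with \code{hic}
#'   (\linkS4class{ContactMatrix}), \code{chip} (\linkS4class{BinnedTrack}),
#'   \code{anchors} (\code{Pairs}), \code{loopPixels} (planted (i, j)
#'   matrix), \code{anchorBins}, \code{decoyBins}, \code{tadBoundaries};
#'   plus attribute \code{config}
#' @export
simulateTrio <- function(cfg = syntheticConfig(),
                         band = bandSpec(dMin = 2L, dMax = 48L)) {
  set.seed(cfg$seed)
  out <- lapply(names(cfg$chromSizes), function(ch)
    .simulateChromosome(cfg, ch, cfg$chromSizes[[ch]], band))
  names(out) <- names(cfg$chromSizes)
  attr(out, "config") <- cfg
  attr(out, "band") <- band
  out
}

#' Write a simulated trio in the pipeline's input formats
#'
#' Emits, per chromosome, Juicer-dump style triplet Hi-C text and a
#' bedGraph of the ChIP-seq track (exact per-bin intervals, so the binned
#' read-back reproduces the track), plus one combined BEDPE of all planted
#' interactions, and a YAML manifest listing the files and planted truth
#' counts. Round-trippable through \code{\link{readContactMatrix}},
#' \code{\link{readBedGraphBinned}} and \code{\link{readBedpe}}.
#'
#' @param trio result of \code{\link{simulateTrio}}
#' @param dir output directory (created if needed)
#' @return invisibly, the manifest list
#' @export
trioToDataset <- function(trio, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- attr(trio, "config")
  manifest <- list(resolution = cfg$resolution, chromosomes = list())
  bedpe <- list()
  for (ch in names(trio)) {
    tr <- trio[[ch]]
    n <- nBins(tr$hic); r <- resolution(tr$hic)
    hicPath <- file.path(dir, paste0(ch, "_hic.txt"))
    writeContactMatrix(tr$hic, hicPath)
    chipPath <- file.path(dir, paste0(ch, "_chip.bedgraph"))
    data.table::fwrite(data.table::data.table(
      chrom = ch, start = (seq_len(n) - 1L) * r, end = seq_len(n) * r,
      value = trackValues(tr$chip)), chipPath, sep = "\t",
      col.names = FALSE)
    manifest$chromosomes[[ch]] <- list(
      nBins = n, hic = basename(hicPath), chip = basename(chipPath),
      nLoops = nrow(tr$loopPixels))
    a1 <- S4Vectors::first(tr$anchors); a2 <- S4Vectors::second(tr$anchors)
    bedpe[[ch]] <- data.table::data.table(
      chrom1 = ch, start1 = GenomicRanges::start(a1) - 1L,
      end1 = GenomicRanges::end(a1),
      chrom2 = ch, start2 = GenomicRanges::start(a2) - 1L,
      end2 = GenomicRanges::end(a2))
  }
  bedpePath <- file.path(dir, "loops.bedpe")
  data.table::fwrite(data.table::rbindlist(bedpe), bedpePath, sep = "\t",
                     col.names = FALSE)
  manifest$bedpe <- basename(bedpePath)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yml"))
  invisible(manifest)
}
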
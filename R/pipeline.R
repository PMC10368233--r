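#' Human (hg19) chromosome sizes
#'
#' Reference lengths in bp for chr1-chr22 and chrX, used to resolve the
#' leave-one-chromosome-out split on human data.
#'
#' @return named numeric vector of bp lengths
#' @export
humanChromSizes <- function() {
  c(chr1 = 249250621, chr2 = 243199373, chr3 = 198022430,
    chr4 = 191154276, chr5 = 180915260, chr6 = 171115067,
    chr7 = 159138663, chr8 = 146364022, chr9 = 141213431,
    chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
    chr13 = 115169878, chr14 = 107349540, chr15 = 102531392,
    chr16 = 90354753, chr17 = 81195210, chr18 = 78077248,
    chr19 = 59128983, chr20 = 63025520, chr21 = 48129895,
    chr22 = 51304566, chrX = 155270560)
}

#' @rdname humanChromSizes
#' @param resolution bin size in bp
#' @return named integer vector of bin counts per chromosome
#' @export
humanChromBins <- function(resolution = 10000L) {
  setNames(as.integer(ceiling(humanChromSizes() / resolution)),
           names(humanChromSizes()))
}

#' Pipeline run configuration
#'
#' Bundles every tunable of the pipeline with the 10-kb defaults: window
#' 250, step 50, band 2-200 bins, hidden dim 128, 40 blocks, kernel 3,
#' positive weight 1, batch 16, lr 0.001 with plateau reduction 0.1/10,
#' weight decay 1e-4. Serializable to YAML; frozen normalization statistics
#' are stored under \code{normStats} (keys \code{hic_mean}, \code{hic_sd},
#' \code{chip_mean}, \code{chip_sd}) once fitted.
#'
#' @param resolution bin size in bp
#' @param W,step window size and stride in bins
#' @param band evaluation band (defaults to \code{bandSpec(resolution)})
#' @param mode channel configuration
#' @param model a \code{\link{modelConfig}}
#' @param train a \code{\link{trainConfig}}
#' @param nRepeats negative-set repeats for evaluation
#' @param seed run seed
#' @return a \code{chiaNetRunConfig} list
#' @export
runConfig <- function(resolution = 10000L, W = 250L, step = 50L,
                      band = NULL,
                      mode = c("both", "hic_only", "chip_only"),
                      model = NULL, train = trainConfig(),
                      nRepeats = 10L, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(band)) band <- bandSpec(resolution)
  if (is.null(model))
    model <- modelConfig(inChannels = switch(mode, both = 3L, hic_only = 1L,
                                             chip_only = 2L))
  structure(list(resolution = as.integer(resolution), W = as.integer(W),
                 step = as.integer(step), band = band, mode = mode,
                 model = model, train = train,
                 nRepeats = as.integer(nRepeats), seed = as.integer(seed),
                 normStats = NULL),
            class = "chiaNetRunConfig")
}

#' Serialize / restore a run configuration
#'
#' @param cfg a \code{\link{runConfig}}
#' @param path YAML file
#' @return \code{writeRunConfig}: invisibly \code{path};
#'   \code{readRunConfig}: the restored config
#' @export
writeRunConfig <- function(cfg, path) {
  x <- unclass(cfg)
  x$model <- unclass(x$model)
  x$train <- unclass(x$train)
  if (!is.null(x$normStats))
    x$normStats <- list(hic_mean = x$normStats$hic$mean,
                        hic_sd = x$normStats$hic$sd,
                        chip_mean = x$normStats$chip$mean,
                        chip_sd = x$normStats$chip$sd)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  x <- yaml::read_yaml(path)
  cfg <- runConfig(resolution = x$resolution, W = x$W, step = x$step,
                   band = bandSpec(dMin = x$band$dMin, dMax = x$band$dMax),
                   mode = x$mode,
                   model = do.call(modelConfig, x$model),
                   train = do.call(trainConfig, x$train),
                   nRepeats = x$nRepeats, seed = x$seed)
  if (!is.null(x$normStats))
    cfg$normStats <- list(
      hic = list(mean = x$normStats$hic_mean, sd = x$normStats$hic_sd),
      chip = list(mean = x$normStats$chip_mean, sd = x$normStats$chip_sd))
  cfg
}

#' Save / load a model checkpoint
#'
#' A checkpoint bundles the trained weights and batch-norm statistics with
#' everything needed to reproduce its predictions: the model config, the
#' frozen normalization statistics, the channel mode and order, the window
#' geometry, and the chromosome split it was trained under.
#'
#' @param model a trained \code{chiaNetModel}
#' @param stats frozen reference statistics (list with \code{hic},
#'   \code{chip})
#' @param W,step window geometry the model was trained with
#' @param testChrom held-out chromosome this checkpoint is blind to (NA for
#'   a generic model)
#' @param path RDS file
#' @param history optional training history data.frame
#' @return \code{saveCheckpoint}: invisibly \code{path};
#'   \code{loadCheckpoint}: the checkpoint list
#' @export
saveCheckpoint <- function(model, stats, W, step, testChrom = NA_character_,
                           path, history = NULL) {
  saveRDS(list(version = 1L, model = model, stats = stats,
               W = as.integer(W), step = as.integer(step),
               testChrom = testChrom,
               channelOrder = c("hic", "chip_row", "chip_col"),
               history = history),
          path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$version) || is.null(ck$model))
    stop("not a chiaNet checkpoint: ", path)
  ck
}

#' Select the checkpoint for a target chromosome
#'
#' Mirrors the blind-testing protocol: predictions on a chromosome use the
#' checkpoint that held that chromosome out during training; any other
#' chromosome name falls back to the designated default (the first file,
#' or the one whose \code{testChrom} is NA).
#'
#' @param paths character vector of checkpoint RDS files
#' @param chrom chromosome to predict on
#' @return the chosen path
#' @export
selectCheckpoint <- function(paths, chrom) {
  stopifnot(length(paths) >= 1L)
  tested <- vapply(paths, function(p) {
    ck <- tryCatch(loadCheckpoint(p), error = function(e) NULL)
    if (is.null(ck)) return("<not a checkpoint>")
    if (is.null(ck$testChrom)) NA_character_ else ck$testChrom
  }, character(1))
  keep <- tested != "<not a checkpoint>" | is.na(tested)
  paths <- paths[keep]
  tested <- tested[keep]
  if (!length(paths)) stop("no usable checkpoints among the given files")
  hit <- which(tested == chrom)
  if (length(hit)) return(paths[hit[1L]])
  def <- which(is.na(tested))
  if (length(def)) return(paths[def[1L]])
  paths[1L]
}

#' Load and label a prepared dataset from a manifest
#'
#' Reads the YAML manifest written by \code{\link{trioToDataset}} (or a
#' hand-written one pointing at real Juicer dumps / bedGraph / BEDPE
#' files), returning cleaned contact matrices, binned tracks and label
#' matrices per chromosome.
#'
#' @param manifestPath path to \code{manifest.yml}; file paths inside are
#'   resolved relative to its directory
#' @return named list per chromosome with \code{hic} (cleaned), \code{chip},
#'   \code{labels}, \code{unmappable}; attribute \code{resolution}
#' @export
prepareDataset <- function(manifestPath) {
  man <- yaml::read_yaml(manifestPath)
  base <- dirname(manifestPath)
  r <- man$resolution
  pairsAll <- readBedpe(file.path(base, man$bedpe))
  out <- lapply(names(man$chromosomes), function(ch) {
    entry <- man$chromosomes[[ch]]
    gr <- genomeGrid(ch, r, entry$nBins)
    hic <- cleanContactMatrix(
      readContactMatrix(file.path(base, entry$hic), gr))
    chip <- readBedGraphBinned(file.path(base, entry$chip), gr)
    suppressWarnings(
      labels <- anchorsToLabelMatrix(pairsAll, gr))
    list(hic = hic, chip = chip, labels = labels,
         unmappable = unmappableBins(hic))
  })
  names(out) <- names(man$chromosomes)
  attr(out, "resolution") <- r
  out
}

#' Fit frozen normalization statistics on training chromosomes
#'
#' Rescales each training chromosome (log + min-max for Hi-C, min-max for
#' ChIP-seq), extracts the diagonal window samples, and pools their
#' elements into the reference mean/SD used to z-score every dataset.
#'
#' @param dataset a \code{\link{prepareDataset}} result
#' @param chroms chromosomes to pool over (the training set)
#' @param W,step window geometry
#' @return list with \code{hic} and \code{chip} reference statistics
#' @export
fitDatasetStats <- function(dataset, chroms, W, step) {
  hicTiles <- list(); chipWins <- list()
  for (ch in chroms) {
    d <- dataset[[ch]]
    hicNorm <- logMinMax(d$hic)
    chipNorm <- minMaxTrack(d$chip)
    for (o in windowOrigins(nBins(d$hic), W, step)) {
      idx <- o:min(o + W - 1L, nBins(d$hic))
      hicTiles[[length(hicTiles) + 1L]] <- hicNorm[idx, idx]
      chipWins[[length(chipWins) + 1L]] <- chipNorm[idx]
    }
  }
  list(hic = fitReferenceStats(hicTiles), chip = fitReferenceStats(chipWins))
}

#' Extract training samples for a set of chromosomes
#'
#' @param dataset a \code{\link{prepareDataset}} result
#' @param chroms chromosomes to extract from
#' @param stats frozen statistics from \code{\link{fitDatasetStats}}
#' @param W,step window geometry
#' @param mode channel configuration
#' @return list of window samples (see \code{\link{extractWindowSamples}})
#' @export
datasetSamples <- function(dataset, chroms, stats, W, step,
                           mode = c("both", "hic_only", "chip_only")) {
  mode <- match.arg(mode)
  out <- list()
  for (ch in chroms) {
    d <- dataset[[ch]]
    norm <- normalizeInputs(d$hic, d$chip, stats)
    out <- c(out, extractWindowSamples(norm$hicNorm, norm$chipNorm,
                                       d$labels, W, step, mode, chrom = ch))
  }
  out
}

#' Train one leave-one-chromosome-out model on a prepared dataset
#'
#' Applies \code{\link{makeSplit}}, fits the frozen statistics on the
#' training chromosomes, extracts samples, builds the model and trains it.
#'
#' @param dataset a \code{\link{prepareDataset}} result
#' @param testChrom held-out chromosome
#' @param cfg a \code{\link{runConfig}} (its \code{model$inChannels} must
#'   match \code{cfg$mode})
#' @return list: \code{model}, \code{history}, \code{bestEpoch},
#'   \code{stats}, \code{split}
#' @export
trainOnDataset <- function(dataset, testChrom, cfg = runConfig()) {
  sizes <- vapply(dataset, function(d) nBins(d$hic), integer(1))
  split <- makeSplit(sizes, testChrom)
  stats <- fitDatasetStats(dataset, split$train, cfg$W, cfg$step)
  trainS <- datasetSamples(dataset, split$train, stats, cfg$W, cfg$step,
                           cfg$mode)
  valS <- datasetSamples(dataset, split$val, stats, cfg$W, cfg$step,
                         cfg$mode)
  model <- buildModel(cfg$model, seed = cfg$seed, mode = cfg$mode)
  fit <- trainModel(model, trainS, valS, cfg$train)
  c(fit, list(stats = stats, split = split))
}
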
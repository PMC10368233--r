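# Shared end-to-end synthetic study: simulate the default trio, train the
# small model under the leave-one-chromosome-out split for each channel
# configuration, predict the held-out chromosome, and evaluate. Computed
# lazily once and cached for the session, since several properties are
# checked against the same run.

.e2eCache <- new.env(parent = emptyenv())

e2eBand <- function() bandSpec(dMin = 2L, dMax = 48L)

e2eStudy <- function() {
  if (!is.null(.e2eCache$res)) return(.e2eCache$res)
  seed <- 2026L
  band <- e2eBand()
  trio <- simulateTrio(syntheticConfig(seed = seed), band = band)
  dir <- file.path(tempdir(), "chianet-e2e")
  trioToDataset(trio, dir)
  ds <- prepareDataset(file.path(dir, "manifest.yml"))
  testChrom <- "chrS1"
  d <- ds[[testChrom]]
  mask <- bandMask(grid(d$hic), band, d$unmappable)
  spec <- evalSpec(band, c("pos", "5pos", "20pos", "100pos", "all"),
                   nRepeats = 10L, seed = seed)

  fits <- list()
  preds <- list()
  evals <- list()
  for (mode in c("both", "hic_only", "chip_only")) {
    cfg <- runConfig(
      W = 64L, step = 16L, band = band, mode = mode,
      model = modelConfig(
        inChannels = switch(mode, both = 3L, hic_only = 1L, chip_only = 2L),
        hiddenDim = 16L, nBlocks = 4L),
      train = trainConfig(batchSize = 4L, lr = 0.01, maxEpochs = 60L,
                          seed = seed),
      seed = seed)
    fit <- trainOnDataset(ds, testChrom, cfg)
    pred <- predictChromosome(
      fit$model,
      hic = if (mode != "chip_only") d$hic else NULL,
      chip = if (mode != "hic_only") d$chip else NULL,
      stats = fit$stats, W = 64L, step = 16L, batchSize = 8L)
    fits[[mode]] <- fit
    preds[[mode]] <- pred
    evals[[mode]] <- evaluatePrediction(pred, d$labels, spec, mask = mask)
  }

  # shuffle controls on the full (both-channel) model
  shufHic <- predictChromosome(fits$both$model, d$hic, d$chip,
                               fits$both$stats, 64L, 16L, batchSize = 8L,
                               shuffle = "shuffleHiC", shuffleSeed = seed)
  evalShufHic <- evaluatePrediction(shufHic, d$labels, spec, mask = mask)

  baseline <- chipInnerProductBaseline(d$chip, mask)
  evalBaseline <- evaluatePrediction(baseline, d$labels, spec, mask = mask)

  .e2eCache$res <- list(ds = ds, testChrom = testChrom, mask = mask,
                        spec = spec, fits = fits, preds = preds,
                        evals = evals, evalShufHic = evalShufHic,
                        evalBaseline = evalBaseline)
  .e2eCache$res
}

e2eAuc <- function(ev, mode = "20pos") {
  ev$summary$auc[ev$summary$negMode == mode]
}
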
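#' Training configuration
#'
#' Defaults follow the tuned optimization protocol: Adam with weight decay
#' 1e-4, batch size 16, initial learning rate 0.001 reduced by a factor of
#' 0.1 when the validation loss has not improved for 10 epochs, positive
#' weight 1. \code{maxEpochs} and the early stop (after
#' \code{maxReductions} plateau reductions without improvement) bound the
#' run.
#'
#' @param batchSize samples per optimization step
#' @param lr initial learning rate
#' @param weightDecay L2 penalty folded into the Adam gradient
#' @param plateauFactor multiplicative LR reduction on plateau
#' @param plateauPatience epochs without validation improvement before a
#'   reduction
#' @param posWeight positive-class weight of the loss
#' @param maxEpochs hard epoch cap
#' @param maxReductions stop after this many LR reductions without any
#'   later improvement
#' @param seed RNG seed for shuffling (and weight init when the model is
#'   built inside \code{\link{trainModel}} callers)
#' @return a \code{chiaNetTrainConfig} list
#' @export
trainConfig <- function(batchSize = 16L, lr = 0.001, weightDecay = 1e-4,
                        plateauFactor = 0.1, plateauPatience = 10L,
                        posWeight = 1, maxEpochs = 50L, maxReductions = 3L,
                        seed = 1L) {
  stopifnot(batchSize >= 1L, lr > 0, weightDecay >= 0, plateauFactor < 1,
            plateauFactor > 0, plateauPatience >= 1L, posWeight > 0,
            maxEpochs >= 1L)
  structure(list(batchSize = as.integer(batchSize), lr = lr,
                 weightDecay = weightDecay, plateauFactor = plateauFactor,
                 plateauPatience = as.integer(plateauPatience),
                 posWeight = posWeight, maxEpochs = as.integer(maxEpochs),
                 maxReductions = as.integer(maxReductions),
                 seed = as.integer(seed)),
            class = "chiaNetTrainConfig")
}

#' Leave-one-chromosome-out split
#'
#' Holds out the test chromosome entirely; validation comes from the largest
#' (most bins) remaining chromosome (ties broken by lexicographically
#' smallest name) and all other chromosomes form the training set. With
#' human chromosome sizes, testing on chr1 trains on chr3..chrX and
#' validates on chr2.
#'
#' @param chromSizes named vector of bins (or bp) per chromosome
#' @param testChrom name of the held-out chromosome
#' @return list with \code{test}, \code{val}, \code{train} (names)
#' @export
makeSplit <- function(chromSizes, testChrom) {
  if (!testChrom %in% names(chromSizes))
    stop(sprintf("test chromosome '%s' not in chromSizes", testChrom))
  if (length(chromSizes) < 3L)
    stop("need at least 3 chromosomes for a train/val/test split")
  rest <- chromSizes[names(chromSizes) != testChrom]
  mx <- max(rest)
  valChrom <- sort(names(rest)[rest == mx])[1L]
  list(test = testChrom, val = valChrom,
       train = names(rest)[names(rest) != valChrom])
}

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adamStep <- function(params, grads, state, lr, weightDecay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]] + weightDecay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

.stackBatch <- function(samples, idx) {
  d <- dim(samples[[idx[1L]]]$channels)
  x <- array(0, c(d, length(idx)))
  y <- array(0, c(d[2L], d[3L], length(idx)))
  for (q in seq_along(idx)) {
    x[, , , q] <- samples[[idx[q]]]$channels
    y[, , q] <- samples[[idx[q]]]$labelTile
  }
  list(x = x, y = y)
}

.datasetLoss <- function(model, samples, batchSize, posWeight) {
  n <- length(samples)
  total <- 0
  i <- 1L
  while (i <= n) {
    idx <- i:min(i + batchSize - 1L, n)
    b <- .stackBatch(samples, idx)
    out <- forwardModel(model, b$x, train = FALSE)
    total <- total + weightedBCE(out$logits, b$y, posWeight) * length(idx)
    i <- i + batchSize
  }
  total / n
}

#' Train the network with validation-based model selection
#'
#' Adam with L2 weight decay; the learning rate is multiplied by
#' \code{plateauFactor} whenever the validation loss has not improved for
#' \code{plateauPatience} epochs, and training stops early after
#' \code{maxReductions} such reductions without a later improvement (or at
#' \code{maxEpochs}). Every pixel of every training tile, positive or
#' negative, contributes to the loss. The returned model carries the weights
#' and batch-norm statistics of the epoch with the lowest validation loss.
#'
#' @param model an initialized \code{\link{buildModel}} model
#' @param trainSamples,valSamples lists of window samples from
#'   \code{\link{extractWindowSamples}} (with label tiles)
#' @param cfg a \code{\link{trainConfig}}
#' @return list: \code{model} (best checkpoint), \code{history} (data.frame
#'   epoch/trainLoss/valLoss/lr), \code{bestEpoch}
#' @export
trainModel <- function(model, trainSamples, valSamples, cfg = trainConfig()) {
  stopifnot(length(trainSamples) >= 1L, length(valSamples) >= 1L)
  set.seed(cfg$seed)
  # start at the base-rate predictor: with heavily imbalanced pixel labels
  # the first optimization phase otherwise just drifts the output bias to
  # the prior log-odds, so set it there up front
  posRate <- mean(vapply(trainSamples, function(s) mean(s$labelTile),
                         numeric(1)))
  posRate <- min(max(posRate, 1e-6), 1 - 1e-6)
  model$params[["bn3.beta"]] <- log(posRate / (1 - posRate))
  state <- .adamInit(model$params)
  lr <- cfg$lr
  best <- list(loss = Inf, epoch = 0L, params = NULL, bnStats = NULL)
  sinceImprove <- 0L
  reductions <- 0L
  hist <- data.frame(epoch = integer(0), trainLoss = numeric(0),
                     valLoss = numeric(0), lr = numeric(0))
  for (epoch in seq_len(cfg$maxEpochs)) {
    ord <- sample.int(length(trainSamples))
    epochLoss <- 0
    i <- 1L
    while (i <= length(ord)) {
      idx <- ord[i:min(i + cfg$batchSize - 1L, length(ord))]
      b <- .stackBatch(trainSamples, idx)
      fw <- forwardModel(model, b$x, train = TRUE)
      model <- fw$model
      lg <- weightedBCE(fw$logits, b$y, cfg$posWeight, gradient = TRUE)
      if (!is.finite(lg$loss))
        stop(sprintf(
          "non-finite training loss at epoch %d (lr %.2g); aborting",
          epoch, lr))
      grads <- backwardModel(model, fw$cache, lg$grad)
      up <- .adamStep(model$params, grads, state, lr, cfg$weightDecay)
      model$params <- up$params
      state <- up$state
      epochLoss <- epochLoss + lg$loss * length(idx)
      i <- i + cfg$batchSize
    }
    trainLoss <- epochLoss / length(trainSamples)
    valLoss <- .datasetLoss(model, valSamples, cfg$batchSize, cfg$posWeight)
    if (!is.finite(valLoss))
      stop(sprintf("non-finite validation loss at epoch %d; aborting", epoch))
    hist <- rbind(hist, data.frame(epoch = epoch, trainLoss = trainLoss,
                                   valLoss = valLoss, lr = lr))
    if (valLoss < best$loss) {
      best <- list(loss = valLoss, epoch = epoch, params = model$params,
                   bnStats = model$bnStats)
      sinceImprove <- 0L
      reductions <- 0L
    } else {
      sinceImprove <- sinceImprove + 1L
      if (sinceImprove >= cfg$plateauPatience) {
        lr <- lr * cfg$plateauFactor
        reductions <- reductions + 1L
        sinceImprove <- 0L
        if (reductions >= cfg$maxReductions) break
      }
    }
  }
  model$params <- best$params
  model$bnStats <- best$bnStats
  model$trainedOn <- unique(vapply(trainSamples, `[[`, "", "chrom"))
  model$validatedOn <- unique(vapply(valSamples, `[[`, "", "chrom"))
  list(model = model, history = hist, bestEpoch = best$epoch)
}
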
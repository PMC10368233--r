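#' Configuration of the dilated residual network
#'
#' The network maps a C x W x W input tile to a W x W logit map:
#' a 1x1 convolution lifting the C input channels to \code{hiddenDim},
#' batch norm and ReLU; \code{nBlocks} residual blocks, each holding two
#' dilated k x k convolutions (with batch norm, ReLU inside, and ReLU after
#' the skip addition); and a closing 1x1 convolution down to one channel
#' followed by batch norm. Dilations are assigned cyclically from
#' \code{dilationCycle} across the 2\code{nBlocks} dilated convolutions
#' (0-based conv q gets \code{cycle[q mod length(cycle)]}), so the two convs
#' of a block always differ and the receptive field grows multi-scale —
#' with the default cycle it exceeds the 200-bin evaluation band.
#'
#' @param inChannels input channels C: 3 (Hi-C + two ChIP-seq), 1 (Hi-C
#'   only) or 2 (ChIP-seq only)
#' @param hiddenDim hidden channel width H (full-scale default 128)
#' @param nBlocks number of residual blocks B (full-scale default 40)
#' @param kernel odd kernel size of the dilated convolutions
#' @param dilationCycle positive integers cycled over the dilated convs
#' @return a \code{chiaNetModelConfig} list
#' @export
modelConfig <- function(inChannels = 3L, hiddenDim = 128L, nBlocks = 40L,
                        kernel = 3L, dilationCycle = c(1L, 2L, 4L, 8L, 16L)) {
  stopifnot(inChannels %in% 1:3, hiddenDim >= 1L, nBlocks >= 1L,
            kernel %% 2L == 1L, all(dilationCycle >= 1L))
  structure(list(inChannels = as.integer(inChannels),
                 hiddenDim = as.integer(hiddenDim),
                 nBlocks = as.integer(nBlocks),
                 kernel = as.integer(kernel),
                 dilationCycle = as.integer(dilationCycle)),
            class = "chiaNetModelConfig")
}

#' Per-block dilation assignment
#'
#' @param cfg a \code{\link{modelConfig}}
#' @return integer matrix \code{nBlocks} x 2: dilations of the two convs of
#'   each block
#' @export
blockDilations <- function(cfg) {
  q <- seq_len(2L * cfg$nBlocks) - 1L
  d <- cfg$dilationCycle[(q %% length(cfg$dilationCycle)) + 1L]
  matrix(d, ncol = 2L, byrow = TRUE,
         dimnames = list(NULL, c("convA", "convB")))
}

.heInit <- function(nOut, fanIn) {
  matrix(rnorm(nOut * fanIn, sd = sqrt(2 / fanIn)), nOut, fanIn)
}

.bnInit <- function(C) {
  list(gamma = rep(1, C), beta = rep(0, C))
}

#' Build a dilated residual network with He-initialized weights
#'
#' Weight initialization draws from the current R RNG stream; call
#' \code{set.seed} (or pass \code{seed}) for reproducible models. Batch-norm
#' running statistics start at mean 0 / variance 1 and are updated during
#' training.
#'
#' @param cfg a \code{\link{modelConfig}}
#' @param seed optional integer seed for the weight draw
#' @param mode channel configuration this model expects, recorded for
#'   checkpoint validation ("both", "hic_only", "chip_only")
#' @return a \code{chiaNetModel}: list with \code{cfg}, flat named parameter
#'   list \code{params}, batch-norm running stats \code{bnStats},
#'   \code{dilations}, \code{mode}
#' @export
buildModel <- function(cfg, seed = NULL,
                       mode = c("both", "hic_only", "chip_only")) {
  mode <- match.arg(mode)
  expected <- switch(mode, both = 3L, hic_only = 1L, chip_only = 2L)
  if (cfg$inChannels != expected)
    stop(sprintf("mode '%s' needs %d input channels, config has %d",
                 mode, expected, cfg$inChannels))
  if (!is.null(seed)) set.seed(seed)
  H <- cfg$hiddenDim; C <- cfg$inChannels; k <- cfg$kernel
  p <- list()
  s <- list()
  p[["conv1.w"]] <- .heInit(H, C)
  p[["conv1.b"]] <- rep(0, H)
  p <- c(p, setNames(.bnInit(H), paste0("bn1.", c("gamma", "beta"))))
  s[["bn1"]] <- list(mean = rep(0, H), var = rep(1, H))
  for (b in seq_len(cfg$nBlocks)) {
    for (cv in c("A", "B")) {
      nm <- sprintf("block%02d.conv%s", b, cv)
      p[[paste0(nm, ".w")]] <- .heInit(H, H * k * k)
      p[[paste0(nm, ".b")]] <- rep(0, H)
      bn <- sprintf("block%02d.bn%s", b, cv)
      p[[paste0(bn, ".gamma")]] <- rep(1, H)
      p[[paste0(bn, ".beta")]] <- rep(0, H)
      s[[bn]] <- list(mean = rep(0, H), var = rep(1, H))
    }
  }
  p[["conv3.w"]] <- .heInit(1L, H)
  p[["conv3.b"]] <- 0
  p[["bn3.gamma"]] <- 1
  p[["bn3.beta"]] <- 0
  s[["bn3"]] <- list(mean = 0, var = 1)
  structure(list(cfg = cfg, params = p, bnStats = s,
                 dilations = blockDilations(cfg), mode = mode),
            class = "chiaNetModel")
}

#' @export
print.chiaNetModel <- function(x, ...) {
  nPar <- sum(vapply(x$params, length, 1L))
  cat(sprintf(
    "chiaNet dilated residual network: C=%d -> H=%d, %d blocks (k=%d),\n",
    x$cfg$inChannels, x$cfg$hiddenDim, x$cfg$nBlocks, x$cfg$kernel))
  cat(sprintf("  dilation cycle [%s]; mode '%s'; %d parameters\n",
              paste(x$cfg$dilationCycle, collapse = ","), x$mode, nPar))
  invisible(x)
}

## ---- layer primitives (internal) -------------------------------------
## tensors are (C, H, W, N) arrays throughout; BN/1x1 ops reshape to
## (C, H*W*N) matrices so they are single BLAS/vector operations.

.asChanMat <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1L], prod(d[-1L]))
  x
}

.conv1x1F <- function(x, w, b) {
  d <- dim(x)
  y <- w %*% .asChanMat(x) + b
  dim(y) <- c(nrow(w), d[-1L])
  y
}

.conv1x1B <- function(x, w, dy) {
  d <- dim(x)
  dyM <- .asChanMat(dy)
  xM <- .asChanMat(x)
  dx <- crossprod(w, dyM)
  dim(dx) <- d
  list(dx = dx, dw = tcrossprod(dyM, xM), db = rowSums(dyM))
}

.bnF <- function(x, gamma, beta, stats, train, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  xm <- .asChanMat(x)
  if (!train) {
    istd <- 1 / sqrt(stats$var + eps)
    y <- cpp_bn_affine(xm, gamma, beta, stats$mean, istd)
    dim(y) <- d
    return(list(y = y, stats = stats))
  }
  out <- cpp_bn_forward(xm, gamma, beta, eps)
  m <- ncol(xm)
  unbias <- if (m > 1L) m / (m - 1L) else 1
  if (is.null(stats$seen)) {
    # first batch: adopt its statistics outright instead of blending with
    # the (0, 1) initialization, so early validation losses are meaningful
    momentum <- 1
    stats$seen <- TRUE
  }
  stats$mean <- (1 - momentum) * stats$mean + momentum * as.numeric(out$mean)
  stats$var <- (1 - momentum) * stats$var +
    momentum * as.numeric(out$var) * unbias
  y <- out$y
  dim(y) <- d
  list(y = y, x = xm, mean = as.numeric(out$mean),
       istd = as.numeric(out$istd), stats = stats)
}

.bnB <- function(cache, gamma, dy) {
  d <- dim(dy)
  out <- cpp_bn_backward(cache$x, cache$mean, cache$istd, gamma,
                         .asChanMat(dy))
  dx <- out$dx
  dim(dx) <- d
  list(dx = dx, dgamma = as.numeric(out$dgamma),
       dbeta = as.numeric(out$dbeta))
}

.convF <- function(x, w, b, k, dil) {
  cpp_conv2d_forward(x, dim(x), w, b, k, dil)
}

.convB <- function(x, w, dy, k, dil) {
  out <- cpp_conv2d_backward(x, dim(x), w, dy, k, dil)
  out$db <- as.numeric(out$db)
  out
}

#' Forward pass through the network
#'
#' @param model a \code{\link{buildModel}} result
#' @param x input array \code{(C, W, W, N)} (a single \code{(C, W, W)} tile
#'   is promoted to a batch of one)
#' @param train logical: use batch statistics and keep caches for
#'   \code{\link{backwardModel}} (TRUE) or frozen running statistics (FALSE)
#' @return list with \code{logits} (array \code{(W, W, N)}), \code{cache}
#'   (NULL unless \code{train}), and the model with updated running stats
#' @export
forwardModel <- function(model, x, train = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  stopifnot(dim(x)[1L] == model$cfg$inChannels)
  p <- model$params
  s <- model$bnStats
  k <- model$cfg$kernel
  cache <- if (train) list() else NULL
  a <- .conv1x1F(x, p[["conv1.w"]], p[["conv1.b"]])
  if (train) cache$x0 <- x
  bn <- .bnF(a, p[["bn1.gamma"]], p[["bn1.beta"]], s[["bn1"]], train)
  s[["bn1"]] <- bn$stats
  if (train) cache$bn1 <- bn[c("x", "mean", "istd")]
  h <- bn$y
  h[h < 0] <- 0
  if (train) cache$relu1 <- h > 0  # mask on the post-BN activation
  for (b in seq_len(model$cfg$nBlocks)) {
    nm <- sprintf("block%02d", b)
    dA <- model$dilations[b, 1L]; dB <- model$dilations[b, 2L]
    if (train) cache[[paste0(nm, ".in")]] <- h
    a <- .convF(h, p[[paste0(nm, ".convA.w")]], p[[paste0(nm, ".convA.b")]],
                k, dA)
    bnA <- .bnF(a, p[[paste0(nm, ".bnA.gamma")]], p[[paste0(nm, ".bnA.beta")]],
                s[[paste0(nm, ".bnA")]], train)
    s[[paste0(nm, ".bnA")]] <- bnA$stats
    r <- bnA$y
    r[r < 0] <- 0
    if (train) {
      cache[[paste0(nm, ".bnA")]] <- bnA[c("x", "mean", "istd")]
      cache[[paste0(nm, ".reluA")]] <- bnA$y > 0
      cache[[paste0(nm, ".mid")]] <- r
    }
    a2 <- .convF(r, p[[paste0(nm, ".convB.w")]], p[[paste0(nm, ".convB.b")]],
                 k, dB)
    bnB <- .bnF(a2, p[[paste0(nm, ".bnB.gamma")]],
                p[[paste0(nm, ".bnB.beta")]], s[[paste0(nm, ".bnB")]], train)
    s[[paste0(nm, ".bnB")]] <- bnB$stats
    if (train) cache[[paste0(nm, ".bnB")]] <- bnB[c("x", "mean", "istd")]
    h2 <- h + bnB$y
    h2[h2 < 0] <- 0
    if (train) cache[[paste0(nm, ".reluOut")]] <- h2 > 0
    h <- h2
  }
  if (train) cache$x3 <- h
  a <- .conv1x1F(h, p[["conv3.w"]], p[["conv3.b"]])
  bn3 <- .bnF(a, p[["bn3.gamma"]], p[["bn3.beta"]], s[["bn3"]], train)
  s[["bn3"]] <- bn3$stats
  if (train) cache$bn3 <- bn3[c("x", "mean", "istd")]
  logits <- bn3$y
  d <- dim(logits)
  dim(logits) <- d[-1L]  # (W, W, N)
  model$bnStats <- s
  list(logits = logits, cache = cache, model = model)
}

#' Backward pass: parameter gradients of a scalar loss
#'
#' @param model the model used in the forward pass
#' @param cache forward cache from \code{\link{forwardModel}} with
#'   \code{train = TRUE}
#' @param dlogits gradient of the loss w.r.t. the logits, shape
#'   \code{(W, W, N)}
#' @return flat named list of gradients parallel to \code{model$params}
#' @export
backwardModel <- function(model, cache, dlogits) {
  p <- model$params
  k <- model$cfg$kernel
  g <- vector("list", length(p))
  names(g) <- names(p)
  dy <- dlogits
  dim(dy) <- c(1L, dim(dlogits))
  bn <- .bnB(cache$bn3, p[["bn3.gamma"]], dy)
  g[["bn3.gamma"]] <- bn$dgamma; g[["bn3.beta"]] <- bn$dbeta
  cv <- .conv1x1B(cache$x3, p[["conv3.w"]], bn$dx)
  g[["conv3.w"]] <- cv$dw; g[["conv3.b"]] <- cv$db
  dh <- cv$dx
  for (b in rev(seq_len(model$cfg$nBlocks))) {
    nm <- sprintf("block%02d", b)
    dA <- model$dilations[b, 1L]; dB <- model$dilations[b, 2L]
    dh <- dh * cache[[paste0(nm, ".reluOut")]]
    # branches: identity (skip) and conv path share dh
    bnB <- .bnB(cache[[paste0(nm, ".bnB")]], p[[paste0(nm, ".bnB.gamma")]],
                dh)
    g[[paste0(nm, ".bnB.gamma")]] <- bnB$dgamma
    g[[paste0(nm, ".bnB.beta")]] <- bnB$dbeta
    cvB <- .convB(cache[[paste0(nm, ".mid")]], p[[paste0(nm, ".convB.w")]],
                  bnB$dx, k, dB)
    g[[paste0(nm, ".convB.w")]] <- cvB$dw
    g[[paste0(nm, ".convB.b")]] <- cvB$db
    dr <- cvB$dx * cache[[paste0(nm, ".reluA")]]
    bnA <- .bnB(cache[[paste0(nm, ".bnA")]], p[[paste0(nm, ".bnA.gamma")]],
                dr)
    g[[paste0(nm, ".bnA.gamma")]] <- bnA$dgamma
    g[[paste0(nm, ".bnA.beta")]] <- bnA$dbeta
    cvA <- .convB(cache[[paste0(nm, ".in")]], p[[paste0(nm, ".convA.w")]],
                  bnA$dx, k, dA)
    g[[paste0(nm, ".convA.w")]] <- cvA$dw
    g[[paste0(nm, ".convA.b")]] <- cvA$db
    dh <- dh + cvA$dx  # skip connection
  }
  dh <- dh * cache$relu1
  bn <- .bnB(cache$bn1, p[["bn1.gamma"]], dh)
  g[["bn1.gamma"]] <- bn$dgamma; g[["bn1.beta"]] <- bn$dbeta
  cv <- .conv1x1B(cache$x0, p[["conv1.w"]], bn$dx)
  g[["conv1.w"]] <- cv$dw; g[["conv1.b"]] <- cv$db
  g
}

#' Per-pixel interaction probabilities
#'
#' Runs the network in evaluation mode (frozen batch-norm statistics) and
#' applies the logistic function to the logits.
#'
#' @param model a \code{chiaNetModel}
#' @param x input array \code{(C, W, W, N)} or a single \code{(C, W, W)} tile
#' @return array \code{(W, W, N)} (or \code{(W, W)} for a single tile) of
#'   probabilities in (0, 1)
#' @export
predictProbs <- function(model, x) {
  single <- length(dim(x)) == 3L
  out <- forwardModel(model, x, train = FALSE)
  pr <- plogis(out$logits)
  if (single) dim(pr) <- dim(pr)[1:2]
  pr
}

#' Positive-weighted binary cross entropy on logits
#'
#' Numerically stable mean over all pixels of
#' \code{-[w * y * log(sigma(z)) + (1 - y) * log(1 - sigma(z))]}. The
#' positive weight \code{w} counteracts the heavy class imbalance of
#' interaction pixels; training consumes all pixels of every tile.
#'
#' @param logits numeric array of logits z
#' @param labels 0/1 array of the same shape
#' @param posWeight positive-class weight w (default 1; grid values
#'   1, 3, 6, 9, 12)
#' @param gradient also return the gradient w.r.t. the logits
#' @return scalar loss, or (with \code{gradient}) a list
#'   \code{list(loss, grad)}
#' @export
weightedBCE <- function(logits, labels, posWeight = 1, gradient = FALSE) {
  z <- as.numeric(logits)
  y <- as.numeric(labels)
  softplus <- function(u) pmax(u, 0) + log1p(exp(-abs(u)))
  l <- posWeight * y * softplus(-z) + (1 - y) * softplus(z)
  loss <- mean(l)
  if (!gradient) return(loss)
  sz <- plogis(z)
  grad <- (posWeight * y * (sz - 1) + (1 - y) * sz) / length(z)
  dim(grad) <- dim(logits)
  list(loss = loss, grad = grad)
}
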
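#' Evaluation specification for imbalanced pixel classification
#'
#' Band pixels are split into the positives and a negative pool hundreds of
#' times larger. Metrics are reported on negative sets of controlled size:
#' \code{k} times the positive count for \code{k} in \{1, 5, 20, 100\}
#' (drawn uniformly without replacement and re-drawn \code{nRepeats} times),
#' plus the complete negative pool (\code{"all"}).
#'
#' @param band a \code{\link{bandSpec}}
#' @param negModes subset of \code{c("pos", "5pos", "20pos", "100pos",
#'   "all")}
#' @param nRepeats number of independent negative draws for sampled modes
#' @param seed base RNG seed for the draws
#' @return a \code{chiaNetEvalSpec} list
#' @export
evalSpec <- function(band, negModes = c("pos", "5pos", "20pos", "100pos",
                                        "all"),
                     nRepeats = 10L, seed = 1L) {
  known <- c(pos = 1, `5pos` = 5, `20pos` = 20, `100pos` = 100, all = NA)
  stopifnot(all(negModes %in% names(known)), nRepeats >= 1L)
  structure(list(band = band, negModes = negModes,
                 negMultiple = known[negModes], nRepeats = as.integer(nRepeats),
                 seed = as.integer(seed)),
            class = "chiaNetEvalSpec")
}

#' Sample a negative pixel set
#'
#' Draws \code{min(k * nPos, nNeg)} distinct negative band pixels uniformly
#' without replacement (capped with a warning when the pool is too small),
#' or returns every negative for \code{k = NA} ("all").
#'
#' @param labels a \linkS4class{LabelMatrix} (or plain 0/1 matrix)
#' @param mask band pixel matrix from \code{\link{bandMask}}
#' @param k negative-to-positive multiple, or NA for all negatives
#' @param seed RNG seed
#' @return integer vector of row indices into \code{mask} (the sampled
#'   negatives)
#' @export
sampleNegatives <- function(labels, mask, k, seed = 1L) {
  lab <- if (is(labels, "LabelMatrix")) pixelLabels(labels) else labels
  y <- lab[mask]
  negIdx <- which(y == 0)
  nPos <- sum(y == 1)
  if (nPos == 0L) stop("no positives in band")
  if (is.na(k)) return(negIdx)
  want <- k * nPos
  if (want > length(negIdx)) {
    warning(sprintf("requested %d negatives but only %d available; capped",
                    want, length(negIdx)))
    return(negIdx)
  }
  set.seed(seed)
  sort(negIdx[sample.int(length(negIdx), want)])
}

#' Average precision
#'
#' Area under the non-interpolated step precision-recall curve: the mean,
#' over positives, of the precision at each positive's rank, with scores
#' sorted descending and ties broken by original position (the
#' \code{\link{rankPixels}} rule).
#'
#' @param scores numeric vector of predicted scores
#' @param labels 0/1 vector of the same length, at least one positive
#' @return AP in [0, 1]
#' @export
averagePrecision <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), any(labels == 1))
  ord <- order(-scores, seq_along(scores), method = "radix")
  y <- labels[ord]
  prec <- cumsum(y) / seq_along(y)
  sum(prec[y == 1]) / sum(y)
}

#' ROC-AUC (Mann-Whitney form)
#'
#' The probability that a random positive outscores a random negative,
#' counting ties as 1/2 — computed from average ranks, which equals the
#' all-pairs count exactly.
#'
#' @param scores numeric vector of predicted scores
#' @param labels 0/1 vector; at least one positive and one negative
#' @return AUC in [0, 1]
#' @export
rocAuc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  stopifnot(P >= 1L, N >= 1L)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
}

#' Step precision-recall curve
#'
#' @param scores numeric vector of predicted scores
#' @param labels 0/1 vector of the same length
#' @return data.frame with nondecreasing \code{recall} and the
#'   corresponding \code{precision}, one row per rank
#' @export
prCurve <- function(scores, labels) {
  ord <- order(-scores, seq_along(scores), method = "radix")
  y <- labels[ord]
  tp <- cumsum(y)
  data.frame(recall = tp / sum(y), precision = tp / seq_along(y))
}

#' Top-N accuracy
#'
#' Percentage of ground-truth positives found among the N top-ranked
#' pixels. When N is the number of positives P (the default convention),
#' this is 100 * TP / P, the recall at rank P.
#'
#' @param scores numeric vector of predicted scores (or a pre-ranked
#'   data.frame from \code{\link{rankPixels}} plus a label lookup — here
#'   the vector form)
#' @param labels 0/1 vector of the same length
#' @param N number of top pixels to inspect; defaults to the positive count
#' @return accuracy in percent, \code{100 * TP / min(N, P)}
#' @export
topnAccuracy <- function(scores, labels, N = NULL) {
  P <- sum(labels == 1)
  if (is.null(N)) N <- P
  if (N <= 0L) stop("N must be positive")
  stopifnot(N <= length(scores))
  ord <- order(-scores, seq_along(scores), method = "radix")
  tp <- sum(labels[ord[seq_len(N)]] == 1)
  100 * tp / min(N, P)
}

#' ChIP-seq inner-product baseline
#'
#' Model-free reference score: pixel (i, j) scores the inner product of the
#' two local ChIP-seq windows \code{chip[i-5..i+5]} and
#' \code{chip[j-5..j+5]}; at chromosome ends the windows are clipped to
#' their common valid offsets. A pixel flanked by two peaks scores high
#' regardless of any Hi-C evidence.
#'
#' @param chip a \linkS4class{BinnedTrack} or numeric vector
#' @param mask band pixel matrix from \code{\link{bandMask}}
#' @param halfWindow window half-width in bins (default 5)
#' @return numeric vector of scores, one per mask row
#' @export
chipInnerProductBaseline <- function(chip, mask, halfWindow = 5L) {
  v <- if (is(chip, "BinnedTrack")) trackValues(chip) else chip
  n <- length(v)
  i <- mask[, 1L]; j <- mask[, 2L]
  sc <- numeric(nrow(mask))
  for (a in seq.int(-halfWindow, halfWindow)) {
    ok <- i + a >= 1L & i + a <= n & j + a >= 1L & j + a <= n
    sc[ok] <- sc[ok] + v[i[ok] + a] * v[j[ok] + a]
  }
  sc
}

#' Evaluate a prediction under the imbalanced protocol
#'
#' For every negative mode of the \code{\link{evalSpec}}, computes AP and
#' ROC-AUC over the positives plus the drawn negatives (sampled modes are
#' re-drawn \code{nRepeats} times and also reported per repeat), and top-N
#' accuracy over the full band ranking for each requested N.
#'
#' @param pred a \linkS4class{PredictionMatrix}, or a plain numeric score
#'   vector parallel to \code{mask}
#' @param labels a \linkS4class{LabelMatrix} (or plain 0/1 matrix)
#' @param spec a \code{\link{evalSpec}}
#' @param mask band pixel matrix; computed from the prediction's grid,
#'   band and \code{unmappable} when omitted
#' @param unmappable unmappable bins to exclude when \code{mask} is NULL
#' @param topN integer vector of N values; NULL means N = P only
#' @return list: \code{metrics} (data.frame negMode/repeat/ap/auc),
#'   \code{summary} (mean ap/auc per mode), \code{topn} (data.frame
#'   N/accuracy), \code{nPos}, \code{nNeg}
#' @export
evaluatePrediction <- function(pred, labels, spec, mask = NULL,
                               unmappable = integer(0), topN = NULL) {
  lab <- if (is(labels, "LabelMatrix")) pixelLabels(labels) else labels
  if (is.null(mask)) {
    stopifnot(is(pred, "PredictionMatrix"))
    mask <- bandMask(grid(pred), spec$band, unmappable)
  }
  sc <- if (is(pred, "PredictionMatrix")) probs(pred)[mask] else pred
  stopifnot(length(sc) == nrow(mask))
  y <- lab[mask]
  posIdx <- which(y == 1)
  if (!length(posIdx)) stop("no positives in band")
  P <- length(posIdx)
  rows <- list()
  for (q in seq_along(spec$negModes)) {
    mode <- spec$negModes[q]
    k <- spec$negMultiple[q]
    reps <- if (is.na(k)) 1L else spec$nRepeats
    for (rp in seq_len(reps)) {
      negIdx <- sampleNegatives(lab, mask, k,
                                seed = spec$seed + 1000L * rp + q)
      take <- c(posIdx, negIdx)
      rows[[length(rows) + 1L]] <- data.frame(
        negMode = mode, rep = rp,
        ap = averagePrecision(sc[take], y[take]),
        auc = rocAuc(sc[take], y[take]))
    }
  }
  metrics <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(metrics, metrics$negMode), function(d)
    data.frame(negMode = d$negMode[1L], ap = mean(d$ap), auc = mean(d$auc))))
  summary <- summary[match(unique(metrics$negMode), summary$negMode), ]
  rownames(summary) <- NULL
  if (is.null(topN)) topN <- P
  topn <- data.frame(N = topN,
                     accuracy = vapply(topN, function(N)
                       topnAccuracy(sc, y, N), numeric(1)))
  list(metrics = metrics, summary = summary, topn = topn,
       nPos = P, nNeg = sum(y == 0))
}
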
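# Vector FCSI of a set of feature columns, grouped by class label.
.channelFCSI <- function(X, labels) {
  suppressWarnings(fcsiVector(.splitByClass(X, labels)))
}

#' Channel selection by FCSI ranking
#'
#' Scores every channel independently with the vector separability index
#' of its own (post-best-basis) feature vector and keeps the top m by
#' descending score; ties go to the lower channel index. Fast, but blind
#' to redundancy between channels.
#'
#' @param features a \code{\linkS4class{FeatureMatrix}} restricted to the
#'   training repetitions (typically the best-basis-reduced features).
#' @param m number of channels to select.
#' @return A \code{\linkS4class{ChannelSelectionResult}}; the audit holds
#'   the full per-channel score vector.
#' @export
selectChannelsFCSI <- function(features, m) {
  stopifnot(is(features, "FeatureMatrix"))
  channels <- sort(unique(features@columnMap$channel))
  m <- as.integer(m)
  if (m < 1L || m > length(channels))
    stop(sprintf("m must be in 1..%d", length(channels)))
  scores <- vapply(channels, function(ch) {
    cols <- features@columnMap$channel == ch
    .channelFCSI(features@values[, cols, drop = FALSE], features@labels)
  }, numeric(1))
  names(scores) <- as.character(channels)
  ord <- order(-scores, channels)[seq_len(m)]
  new("ChannelSelectionResult", method = "fcsi",
      selected = as.integer(channels[ord]),
      stepScores = as.numeric(scores[ord]),
      audit = list(step1 = scores))
}

# inner-validation accuracy of a candidate channel set, by rotating (or
# fixing) the validation repetition among the supplied repetitions
.innerAccuracy <- function(features, channels, innerSplit,
                           regularization, shrinkage) {
  fmS <- subsetChannels(features, channels)
  reps <- sort(unique(fmS@repetitions))
  vals <- if (innerSplit == "rotate") reps else max(reps)
  accs <- vapply(vals, function(v) {
    trainMask <- fmS@repetitions != v
    res <- .fitPredictSplit(fmS, trainMask, nPerChannel = NULL,
                            regularization, shrinkage)
    mean(res$pred == res$truth)
  }, numeric(1))
  mean(accs)
}

#' Channel selection by sequential feedforward selection (SFS)
#'
#' Greedy forward search whose step criterion is classification accuracy:
#' at every step the candidate channel whose union with the already
#' selected set yields the highest inner-validation window accuracy
#' (ULDA + LDC) is added. The inner validation stays inside the supplied
#' (training) repetitions: by default the held-out validation repetition
#' rotates over them and accuracies are averaged
#' (\code{innerSplit = "rotate"}); \code{"single"} uses the one fixed
#' split with the highest repetition as validation.
#'
#' @param features a \code{\linkS4class{FeatureMatrix}} containing only
#'   the training repetitions (the outer test repetition must not be in
#'   it), typically best-basis-reduced.
#' @param m number of channels to select.
#' @param innerSplit \code{"rotate"} or \code{"single"}.
#' @param regularization,shrinkage classifier controls.
#' @return A \code{\linkS4class{ChannelSelectionResult}}; step scores are
#'   inner-validation accuracies, the audit holds every candidate's
#'   accuracy at every step.
#' @export
selectChannelsSFS <- function(features, m,
                              innerSplit = c("rotate", "single"),
                              regularization = 1e-6, shrinkage = 0) {
  stopifnot(is(features, "FeatureMatrix"))
  innerSplit <- match.arg(innerSplit)
  channels <- sort(unique(features@columnMap$channel))
  m <- as.integer(m)
  if (m < 1L || m > length(channels))
    stop(sprintf("m must be in 1..%d", length(channels)))
  if (length(unique(features@repetitions)) < 2L)
    stop("SFS needs at least 2 repetitions for its inner split")
  selected <- integer(0)
  stepScores <- numeric(0)
  audit <- list()
  remaining <- channels
  for (step in seq_len(m)) {
    scores <- vapply(remaining, function(ch)
      .innerAccuracy(features, c(selected, ch), innerSplit,
                     regularization, shrinkage), numeric(1))
    names(scores) <- as.character(remaining)
    best <- remaining[order(-scores, remaining)[1L]]
    selected <- c(selected, best)
    stepScores <- c(stepScores, scores[as.character(best)])
    audit[[paste0("step", step)]] <- scores
    remaining <- setdiff(remaining, best)
  }
  new("ChannelSelectionResult", method = "sfs",
      selected = as.integer(selected),
      stepScores = as.numeric(stepScores), audit = audit)
}

#' Combined FCSI + SFS channel selection
#'
#' Greedy forward search driven by the vector separability index instead
#' of classifier accuracy, so no classifier is trained during the search:
#' the first channel is the single-channel FCSI argmax; afterwards each
#' remaining candidate is scored by the FCSI of its features concatenated
#' with all already-selected channels' features, and the argmax is added.
#' When the concatenated dimension exceeds \code{uldaDimThreshold} the
#' concatenation is first reduced by ULDA and the FCSI evaluated in the
#' reduced space, keeping the criterion well conditioned as channels
#' accumulate. Ties go to the lower channel index.
#'
#' @param features a \code{\linkS4class{FeatureMatrix}} restricted to the
#'   training repetitions, typically best-basis-reduced.
#' @param m number of channels to select.
#' @param uldaDimThreshold apply ULDA before the FCSI evaluation whenever
#'   the concatenated feature dimension exceeds this (default 40).
#' @param regularization ULDA ridge fraction.
#' @return A \code{\linkS4class{ChannelSelectionResult}}; step scores are
#'   FCSI values, the audit holds every candidate's score at every step.
#' @export
selectChannelsFCSISFS <- function(features, m, uldaDimThreshold = 40L,
                                  regularization = 1e-6) {
  stopifnot(is(features, "FeatureMatrix"))
  channels <- sort(unique(features@columnMap$channel))
  m <- as.integer(m)
  if (m < 1L || m > length(channels))
    stop(sprintf("m must be in 1..%d", length(channels)))
  labels <- features@labels
  selected <- integer(0)
  stepScores <- numeric(0)
  audit <- list()
  remaining <- channels
  for (step in seq_len(m)) {
    scores <- vapply(remaining, function(ch) {
      cols <- features@columnMap$channel %in% c(selected, ch)
      X <- features@values[, cols, drop = FALSE]
      if (ncol(X) > uldaDimThreshold) {
        tf <- uldaFit(X, labels, regularization)
        X <- uldaApply(tf, X)
      }
      .channelFCSI(X, labels)
    }, numeric(1))
    names(scores) <- as.character(remaining)
    best <- remaining[order(-scores, remaining)[1L]]
    selected <- c(selected, best)
    stepScores <- c(stepScores, scores[as.character(best)])
    audit[[paste0("step", step)]] <- scores
    remaining <- setdiff(remaining, best)
  }
  new("ChannelSelectionResult", method = "fcsi_sfs",
      selected = as.integer(selected),
      stepScores = as.numeric(stepScores), audit = audit)
}

#' Channel selection front end
#'
#' Convenience wrapper: extracts training-repetition features from a
#' dataset (wavelet-packet features with per-channel best-basis selection
#' by default), then runs the requested selection algorithm on them. The
#' held-out (highest) repetition never enters selection.
#'
#' @param dataset an \code{\linkS4class{EMGDataset}}.
#' @param method \code{"fcsi"}, \code{"sfs"} or \code{"fcsi_sfs"}.
#' @param m number of channels to select.
#' @param featureMethod \code{"wpt"} or \code{"td"}.
#' @param nPerChannel wavelet subspaces kept per channel before selection.
#' @param holdout repetition excluded from selection (default: highest).
#' @param ... passed on to the method-specific function.
#' @return A \code{\linkS4class{ChannelSelectionResult}}.
#' @examples
#' ds <- generateDataset(makeFixture("tiny"))$dataset
#' selectChannels(ds, "fcsi", m = 2, nPerChannel = 5)
#' @export
selectChannels <- function(dataset, method = c("fcsi", "sfs", "fcsi_sfs"),
                           m, featureMethod = c("wpt", "td"),
                           nPerChannel = 12L, holdout = NULL, ...) {
  method <- match.arg(method)
  featureMethod <- match.arg(featureMethod)
  fm <- if (is(dataset, "FeatureMatrix")) dataset
        else extractFeatures(dataset, featureMethod)
  reps <- sort(unique(fm@repetitions))
  if (is.null(holdout)) holdout <- max(reps)
  train <- fm@repetitions != holdout
  fmTrain <- subsetRows(fm, train)
  isWPT <- any(startsWith(fmTrain@columnMap$feature, "wpt_"))
  perCh <- sum(fmTrain@columnMap$channel == fmTrain@columnMap$channel[1L])
  if (isWPT && nPerChannel < perCh)
    fmTrain <- selectBestBases(fmTrain, nPerChannel)$features
  switch(method,
    fcsi = selectChannelsFCSI(fmTrain, m),
    sfs = selectChannelsSFS(fmTrain, m, ...),
    fcsi_sfs = selectChannelsFCSISFS(fmTrain, m, ...))
}
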
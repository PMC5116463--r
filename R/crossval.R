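# One train/test evaluation on a FeatureMatrix: per-channel best-basis
# selection (wpt features only), ULDA and LDC are all fitted on the
# training rows; returns predictions for the test rows.
.fitPredictSplit <- function(fm, trainMask, nPerChannel = 12L,
                             regularization = 1e-6, shrinkage = 0,
                             priors = "uniform") {
  isWPT <- any(startsWith(fm@columnMap$feature, "wpt_"))
  perCh <- sum(fm@columnMap$channel == fm@columnMap$channel[1L])
  if (isWPT && !is.null(nPerChannel) && nPerChannel < perCh) {
    fm <- selectBestBases(fm, nPerChannel, trainMask)$features
  }
  Xtr <- fm@values[trainMask, , drop = FALSE]
  ytr <- fm@labels[trainMask]
  Xte <- fm@values[!trainMask, , drop = FALSE]
  tf <- uldaFit(Xtr, ytr, regularization)
  Ztr <- uldaApply(tf, Xtr)
  Zte <- uldaApply(tf, Xte)
  model <- ldcFit(Ztr, ytr, shrinkage, priors)
  pred <- ldcPredict(model, Zte)$class
  list(pred = pred, truth = fm@labels[!trainMask], transform = tf,
       model = model)
}

#' Repetition-wise cross-validation of the full pipeline
#'
#' Folds are defined by contraction repetitions: all analysis windows of
#' one repetition form the test set of one fold while the remaining
#' repetitions train the per-channel best-basis selection, the ULDA
#' transform and the LDC model. The overall accuracy pools windows over
#' folds: total correct / total tested (not the mean of fold accuracies).
#'
#' @param dataset an \code{\linkS4class{EMGDataset}}, or a pre-computed
#'   \code{\linkS4class{FeatureMatrix}}.
#' @param featureMethod \code{"wpt"} or \code{"td"} (ignored when a
#'   \code{FeatureMatrix} is supplied).
#' @param nPerChannel wavelet subspaces kept per channel (best-basis
#'   selection); ignored for td features.
#' @param channels optional channel subset (1-based indices).
#' @param nFolds number of folds; must equal the number of distinct
#'   repetitions in the data.
#' @param shrinkage,regularization,priors classifier controls, see
#'   \code{\link{ldcFit}} and \code{\link{uldaFit}}.
#' @param ... passed to \code{\link{extractFeatures}}.
#' @return List with \code{accuracy} (pooled fraction correct),
#'   \code{foldCounts} (per-fold tested/correct window counts),
#'   \code{confusion} (classes x classes count matrix, rows = truth).
#' @examples
#' ds <- generateDataset(makeFixture("tiny"))$dataset
#' cv <- crossValidate(ds, "wpt", nPerChannel = 5, nFolds = 3)
#' cv$accuracy
#' @export
crossValidate <- function(dataset, featureMethod = c("wpt", "td"),
                          nPerChannel = 12L, channels = NULL,
                          nFolds = 5L, shrinkage = 0,
                          regularization = 1e-6, priors = "uniform",
                          ...) {
  featureMethod <- match.arg(featureMethod)
  fm <- if (is(dataset, "FeatureMatrix")) dataset
        else extractFeatures(dataset, featureMethod, ...)
  if (!is.null(channels)) fm <- subsetChannels(fm, channels)
  reps <- sort(unique(fm@repetitions))
  if (length(reps) < nFolds)
    stop(sprintf("%d repetitions cannot form %d folds",
                 length(reps), nFolds))
  if (length(reps) != nFolds)
    stop("nFolds must equal the number of distinct repetitions")
  classes <- sort(unique(fm@labels))
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(truth = classes, pred = classes))
  foldCounts <- data.frame(fold = reps, tested = 0L, correct = 0L)
  for (f in seq_along(reps)) {
    trainMask <- fm@repetitions != reps[f]
    res <- .fitPredictSplit(fm, trainMask, nPerChannel,
                            regularization, shrinkage, priors)
    foldCounts$tested[f] <- length(res$truth)
    foldCounts$correct[f] <- sum(res$pred == res$truth)
    for (i in seq_along(res$truth))
      confusion[res$truth[i], res$pred[i]] <-
        confusion[res$truth[i], res$pred[i]] + 1L
  }
  list(accuracy = sum(foldCounts$correct) / sum(foldCounts$tested),
       foldCounts = foldCounts,
       confusion = confusion)
}

#' Evaluate a fixed channel subset under the held-out-repetition protocol
#'
#' Trains on all repetitions except the held-out one (by default the
#' highest repetition index, the one never touched by channel selection)
#' and reports window accuracy on the held-out repetition. With
#' \code{rotate = TRUE} the held-out repetition is rotated over all
#' repetitions and the mean accuracy returned.
#'
#' @param dataset an \code{\linkS4class{EMGDataset}} or a
#'   \code{\linkS4class{FeatureMatrix}}.
#' @param channels channel subset to evaluate (1-based indices).
#' @param featureMethod \code{"wpt"} or \code{"td"}.
#' @param nPerChannel wavelet subspaces kept per channel.
#' @param holdout repetition index to hold out (default: the highest).
#' @param rotate rotate the held-out repetition and average.
#' @param shrinkage,regularization,priors classifier controls.
#' @param ... passed to \code{\link{extractFeatures}}.
#' @return Accuracy as a fraction in [0, 1].
#' @export
evaluateChannelSubset <- function(dataset, channels,
                                  featureMethod = c("wpt", "td"),
                                  nPerChannel = 12L, holdout = NULL,
                                  rotate = FALSE, shrinkage = 0,
                                  regularization = 1e-6,
                                  priors = "uniform", ...) {
  featureMethod <- match.arg(featureMethod)
  fm <- if (is(dataset, "FeatureMatrix")) dataset
        else extractFeatures(dataset, featureMethod, ...)
  fm <- subsetChannels(fm, channels)
  reps <- sort(unique(fm@repetitions))
  holds <- if (rotate) reps
           else if (is.null(holdout)) max(reps) else holdout
  accs <- vapply(holds, function(h) {
    trainMask <- fm@repetitions != h
    res <- .fitPredictSplit(fm, trainMask, nPerChannel,
                            regularization, shrinkage, priors)
    mean(res$pred == res$truth)
  }, numeric(1))
  mean(accs)
}
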
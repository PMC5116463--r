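#' Run an end-to-end pattern-recognition experiment
#'
#' Orchestrates the full pipeline: obtain the data (a
#' \code{\linkS4class{SynthConfig}} to generate, a manifest path to load,
#' or an \code{\linkS4class{EMGDataset}} as-is), extract features, apply
#' the channel policy (all channels, a predefined list, or data-driven
#' selection on the training repetitions), and evaluate by
#' repetition-wise cross-validation. The report embeds the resolved
#' configuration so a rerun reproduces it exactly.
#'
#' @param data a \code{SynthConfig}, a manifest path, or an
#'   \code{EMGDataset}.
#' @param featureMethod \code{"wpt"} or \code{"td"}.
#' @param nPerChannel wavelet subspaces kept per channel.
#' @param channelPolicy \code{list(type = "all")},
#'   \code{list(type = "predefined", channels = ...)}, or
#'   \code{list(type = "select", method = "fcsi_sfs", m = 10)} (method
#'   one of \code{"fcsi"}, \code{"sfs"}, \code{"fcsi_sfs"}).
#' @param nFolds cross-validation folds (= number of repetitions).
#' @param outputDir optional directory; when given, the report is written
#'   as \code{report.json} and the confusion matrix as
#'   \code{confusion.csv}.
#' @return List: \code{config} (resolved settings), \code{selection}
#'   (a \code{\linkS4class{ChannelSelectionResult}} or \code{NULL}),
#'   \code{channels} (channels evaluated), \code{accuracy} (pooled CV
#'   fraction), \code{foldCounts}, \code{confusion}.
#' @examples
#' rep <- runExperiment(makeFixture("tiny"), featureMethod = "td",
#'                      nFolds = 3)
#' rep$accuracy
#' @export
runExperiment <- function(data, featureMethod = c("wpt", "td"),
                          nPerChannel = 12L,
                          channelPolicy = list(type = "all"),
                          nFolds = 5L, outputDir = NULL) {
  featureMethod <- match.arg(featureMethod)
  dataset <- if (is(data, "SynthConfig")) generateDataset(data)$dataset
             else if (is.character(data)) loadDataset(data)
             else data
  stopifnot(is(dataset, "EMGDataset"))

  fm <- extractFeatures(dataset, featureMethod)
  selection <- NULL
  channels <- switch(channelPolicy$type,
    all = seq_len(nChannels(dataset)),
    predefined = as.integer(channelPolicy$channels),
    select = {
      selection <- selectChannels(
        fm, method = channelPolicy$method, m = channelPolicy$m,
        featureMethod = featureMethod, nPerChannel = nPerChannel)
      selectedChannels(selection)
    },
    stop("channelPolicy$type must be all/predefined/select"))

  cv <- crossValidate(subsetChannels(fm, channels),
                      featureMethod, nPerChannel, nFolds = nFolds)
  report <- list(
    config = list(featureMethod = featureMethod,
                  nPerChannel = as.integer(nPerChannel),
                  channelPolicy = channelPolicy, nFolds = as.integer(nFolds),
                  nChannels = nChannels(dataset),
                  nTrials = nTrials(dataset),
                  package = as.character(utils::packageVersion("wpemg"))),
    selection = selection,
    channels = channels,
    accuracy = cv$accuracy,
    foldCounts = cv$foldCounts,
    confusion = cv$confusion)
  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    out <- report
    out$confusion <- NULL
    out$selection <- if (is.null(selection)) NULL else
      list(method = selection@method,
           selected = selection@selected,
           stepScores = selection@stepScores)
    jsonlite::write_json(out, file.path(outputDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(cv$confusion, file.path(outputDir, "confusion.csv"))
  }
  report
}

#' Accuracy-versus-channel-number curves for the selection methods
#'
#' Runs each requested channel-selection algorithm once at the largest
#' subset size m on the training repetitions, then evaluates every nested
#' prefix of the selection order on the held-out repetition, yielding one
#' accuracy curve per method.
#'
#' @param dataset an \code{\linkS4class{EMGDataset}}.
#' @param methods subset of \code{c("fcsi", "sfs", "fcsi_sfs")}.
#' @param mMax largest channel count on the curve.
#' @param featureMethod \code{"wpt"} or \code{"td"}.
#' @param nPerChannel wavelet subspaces kept per channel.
#' @param rotate rotate the held-out repetition when evaluating.
#' @return data.frame with columns \code{method}, \code{m},
#'   \code{accuracy}, plus the selection results as attribute
#'   \code{"selections"}.
#' @export
channelSweep <- function(dataset,
                         methods = c("fcsi", "sfs", "fcsi_sfs"),
                         mMax = 10L, featureMethod = "wpt",
                         nPerChannel = 12L, rotate = FALSE) {
  stopifnot(is(dataset, "EMGDataset"))
  fm <- extractFeatures(dataset, featureMethod)
  rows <- list()
  selections <- list()
  for (method in methods) {
    sel <- selectChannels(fm, method = method, m = mMax,
                          featureMethod = featureMethod,
                          nPerChannel = nPerChannel)
    selections[[method]] <- sel
    accs <- vapply(seq_len(mMax), function(m)
      evaluateChannelSubset(fm, selectedChannels(sel)[seq_len(m)],
                            featureMethod, nPerChannel,
                            rotate = rotate), numeric(1))
    rows[[method]] <- data.frame(method = method, m = seq_len(mMax),
                                 accuracy = accs)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "selections") <- selections
  out
}
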
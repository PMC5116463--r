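#' @describeIn EMGDataset-class number of trials.
#' @export
setMethod("nTrials", "EMGDataset", function(x) length(x@trials))

#' @describeIn EMGDataset-class number of channels.
#' @export
setMethod("nChannels", "EMGDataset", function(x) length(x@channelNames))

#' @describeIn EMGDataset-class sampling rate in Hz.
#' @export
setMethod("samplingRate", "EMGDataset", function(x) x@samplingRate)

#' @describeIn EMGDataset-class channel names.
#' @export
setMethod("channelNames", "EMGDataset", function(x) x@channelNames)

#' @describeIn EMGDataset-class per-trial class labels.
#' @export
setMethod("classLabels", "EMGDataset", function(x) x@classLabels)

#' @describeIn EMGDataset-class per-trial repetition indices.
#' @export
setMethod("repetitions", "EMGDataset", function(x) x@repetitions)

#' @describeIn EMGDataset-class the time-by-channel matrix of trial i.
#' @export
setMethod("trialMatrix", "EMGDataset", function(x, i) x@trials[[i]])

#' @describeIn EMGDataset-class per-trial active-interval matrices.
#' @export
setMethod("activeIntervals", "EMGDataset", function(x) x@activeIntervals)

setMethod("show", "EMGDataset", function(object) {
  cat(sprintf(
    "EMGDataset: %d trials, %d channels, %g Hz\n",
    nTrials(object), nChannels(object), samplingRate(object)))
  cat(sprintf("  classes: %d (%s%s)\n",
              length(unique(object@classLabels)),
              paste(utils::head(sort(unique(object@classLabels)), 4),
                    collapse = ", "),
              if (length(unique(object@classLabels)) > 4) ", ..." else ""))
  cat(sprintf("  repetitions: %s\n",
              paste(sort(unique(object@repetitions)), collapse = ", ")))
  segmented <- sum(!vapply(object@activeIntervals, is.null, logical(1)))
  cat(sprintf("  trials with stored active intervals: %d\n", segmented))
})

#' @describeIn FeatureMatrix-class the samples-by-features numeric matrix.
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)

#' @describeIn FeatureMatrix-class class label per row.
#' @export
setMethod("sampleLabels", "FeatureMatrix", function(x) x@labels)

#' @describeIn FeatureMatrix-class repetition index per row.
#' @export
setMethod("repetitions", "FeatureMatrix", function(x) x@repetitions)

#' @describeIn FeatureMatrix-class per-column (channel, feature) provenance.
#' @export
setMethod("columnMap", "FeatureMatrix", function(x) x@columnMap)

#' @describeIn FeatureMatrix-class number of distinct source channels.
#' @export
setMethod("nChannels", "FeatureMatrix", function(x)
  length(unique(x@columnMap$channel)))

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d windows x %d features (%d channels)\n",
              nrow(object@values), ncol(object@values), nChannels(object)))
  cat(sprintf("  classes: %d, repetitions: %d\n",
              length(unique(object@labels)),
              length(unique(object@repetitions))))
})

#' Row subset of a FeatureMatrix
#'
#' @param x a \code{\linkS4class{FeatureMatrix}}.
#' @param idx logical or integer row index.
#' @return A \code{FeatureMatrix} with the selected windows.
#' @export
subsetRows <- function(x, idx) {
  stopifnot(is(x, "FeatureMatrix"))
  FeatureMatrix(x@values[idx, , drop = FALSE], x@labels[idx],
                x@repetitions[idx], x@columnMap)
}

#' Column subset of a FeatureMatrix by source channel
#'
#' Keeps the feature columns originating from the given channels, in
#' ascending channel order.
#'
#' @param x a \code{\linkS4class{FeatureMatrix}}.
#' @param channels integer channel indices (as used in \code{columnMap}).
#' @return A \code{FeatureMatrix} restricted to those channels.
#' @export
subsetChannels <- function(x, channels) {
  stopifnot(is(x, "FeatureMatrix"))
  channels <- sort(unique(as.integer(channels)))
  keep <- which(x@columnMap$channel %in% channels)
  if (!length(keep))
    stop("no feature columns originate from the requested channels")
  FeatureMatrix(x@values[, keep, drop = FALSE], x@labels, x@repetitions,
                x@columnMap[keep, , drop = FALSE])
}

#' @describeIn ChannelSelectionResult-class ordered selected channels.
#' @export
setMethod("selectedChannels", "ChannelSelectionResult",
          function(x) x@selected)

#' @describeIn ChannelSelectionResult-class per-step criterion values.
#' @export
setMethod("stepScores", "ChannelSelectionResult", function(x) x@stepScores)

setMethod("show", "ChannelSelectionResult", function(object) {
  cat(sprintf("ChannelSelectionResult (%s): %d channels\n",
              object@method, length(object@selected)))
  cat("  order:", paste(object@selected, collapse = ", "), "\n")
  cat("  step scores:",
      paste(signif(object@stepScores, 4), collapse = ", "), "\n")
})

#' @describeIn WPTTree-class coefficients of subspace (j, k).
#' @export
setMethod("nodeCoefficients", "WPTTree", function(x, j, k) {
  key <- paste0(j, ".", k)
  if (is.null(x@nodes[[key]]))
    stop(sprintf("no node (%d, %d) in a depth-%d tree", j, k, x@depth))
  x@nodes[[key]]
})

setMethod("show", "WPTTree", function(object) {
  cat(sprintf("WPTTree: depth %d (%d subspaces), wavelet %s, %s boundary\n",
              object@depth, length(object@nodes), object@wavelet,
              object@boundaryMode))
})

setMethod("show", "ULDATransform", function(object) {
  cat(sprintf("ULDATransform: %d -> %d dimensions (C = %d at fit)\n",
              nrow(object@projection), ncol(object@projection),
              object@classCountAtFit))
})

setMethod("show", "LDCModel", function(object) {
  cat(sprintf("LDCModel: %d classes in %d dimensions, shrinkage %g\n",
              length(object@classes), ncol(object@means), object@shrinkage))
})

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf(
    "SynthConfig: %d classes x %d repetitions x %d channels @ %g Hz\n",
    object@nClasses, object@nRepetitions, object@nChannels,
    object@samplingRate))
  cat(sprintf("  coding: %s on channels [%s]; band %g-%g Hz; seed %d\n",
              object@coding,
              paste(object@informativeChannels, collapse = ", "),
              object@band[1], object@band[2], object@seed))
})
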
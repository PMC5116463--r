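#' @import methods
NULL

#' EMGDataset: a collection of labelled multichannel sEMG trials
#'
#' The unit of training and testing for myoelectric pattern recognition.
#' Each trial is one repetition of a muscle contraction, stored as a
#' time-by-channel numeric matrix. All trials share the same channel layout
#' and sampling rate. Optionally, per-trial active intervals (0-based,
#' half-open \code{[onset, offset)} sample ranges) mark the voluntary EMG
#' activity segments; when absent they can be recovered with
#' \code{\link{detectActivity}}.
#'
#' @slot trials list of numeric matrices (time x channels), one per trial.
#' @slot classLabels character vector, one movement class per trial.
#' @slot repetitions integer vector, repetition index per trial (1-based).
#' @slot samplingRate sampling rate in Hz.
#' @slot channelNames character vector naming the channels (columns).
#' @slot activeIntervals list, one entry per trial: either \code{NULL}
#'   (unknown, detect at run time) or an integer matrix with columns
#'   \code{onset}, \code{offset} of 0-based half-open sample intervals.
#'
#' @seealso \code{\link{loadDataset}}, \code{\link{generateDataset}}
#' @export
setClass("EMGDataset",
  slots = c(
    trials          = "list",
    classLabels     = "character",
    repetitions     = "integer",
    samplingRate    = "numeric",
    channelNames    = "character",
    activeIntervals = "list"
  )
)

setValidity("EMGDataset", function(object) {
  msgs <- character()
  nt <- length(object@trials)
  if (length(object@classLabels) != nt)
    msgs <- c(msgs, "classLabels length must equal the number of trials")
  if (length(object@repetitions) != nt)
    msgs <- c(msgs, "repetitions length must equal the number of trials")
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msgs <- c(msgs, "samplingRate must be a single positive number")
  nc <- length(object@channelNames)
  for (i in seq_len(nt)) {
    m <- object@trials[[i]]
    if (!is.matrix(m) || !is.numeric(m)) {
      msgs <- c(msgs, sprintf("trial %d is not a numeric matrix", i))
      next
    }
    if (ncol(m) != nc)
      msgs <- c(msgs, sprintf(
        "trial %d has %d channels but %d channel names are declared",
        i, ncol(m), nc))
    if (nrow(m) < 1L)
      msgs <- c(msgs, sprintf("trial %d is empty", i))
    if (anyNA(m))
      msgs <- c(msgs, sprintf("trial %d contains missing values", i))
  }
  if (nt > 0L && any(object@repetitions < 1L))
    msgs <- c(msgs, "repetition indices must be >= 1")
  if (length(object@activeIntervals) != nt)
    msgs <- c(msgs, "activeIntervals must have one entry per trial")
  if (length(msgs)) msgs else TRUE
})

#' Construct an EMGDataset
#'
#' @param trials list of numeric time-by-channel matrices.
#' @param classLabels character vector of class labels, one per trial.
#' @param repetitions integer vector of repetition indices, one per trial.
#' @param samplingRate sampling rate in Hz.
#' @param channelNames channel names; defaults to \code{ch1, ch2, ...}.
#' @param activeIntervals optional list of per-trial interval matrices
#'   (0-based, half-open); \code{NULL} entries mean "detect later".
#' @return A validated \code{\linkS4class{EMGDataset}}.
#' @export
EMGDataset <- function(trials, classLabels, repetitions, samplingRate,
                       channelNames = NULL, activeIntervals = NULL) {
  trials <- lapply(trials, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  if (is.null(channelNames)) {
    nc <- if (length(trials)) ncol(trials[[1L]]) else 0L
    channelNames <- paste0("ch", seq_len(nc))
  }
  if (is.null(activeIntervals))
    activeIntervals <- vector("list", length(trials))
  new("EMGDataset",
      trials = trials,
      classLabels = as.character(classLabels),
      repetitions = as.integer(repetitions),
      samplingRate = as.numeric(samplingRate),
      channelNames = as.character(channelNames),
      activeIntervals = activeIntervals)
}

#' WPTTree: a full wavelet-packet binary tree for one signal
#'
#' Nodes are indexed by scale \code{j} (1..depth) and subband \code{k}
#' (0..2^j - 1) in natural order; node \code{(j, k)} splits into
#' \code{(j+1, 2k)} (approximation) and \code{(j+1, 2k+1)} (detail).
#'
#' @slot nodes named list of coefficient vectors, names \code{"j.k"}.
#' @slot depth decomposition depth J.
#' @slot wavelet wavelet name (e.g. \code{"sym5"}).
#' @slot boundaryMode \code{"periodization"} or \code{"symmetric"}.
#' @export
setClass("WPTTree",
  slots = c(
    nodes        = "list",
    depth        = "integer",
    wavelet      = "character",
    boundaryMode = "character"
  )
)

setValidity("WPTTree", function(object) {
  J <- object@depth
  expected <- sum(2L^seq_len(J))
  if (length(object@nodes) != expected)
    return(sprintf("expected %d nodes for depth %d, found %d",
                   expected, J, length(object@nodes)))
  TRUE
})

#' FeatureMatrix: windows-by-features table with provenance
#'
#' One row per analysis window. The column map records, for every feature
#' column, the channel it came from and the feature identity (a wavelet
#' packet subspace \code{"wpt_j_k"} or a time-domain feature name).
#'
#' @slot values numeric matrix, samples (windows) x features.
#' @slot labels character, class label per row.
#' @slot repetitions integer, repetition index per row.
#' @slot columnMap data.frame with columns \code{channel} (integer index
#'   into the source dataset's channels) and \code{feature} (character id).
#' @export
setClass("FeatureMatrix",
  slots = c(
    values      = "matrix",
    labels      = "character",
    repetitions = "integer",
    columnMap   = "data.frame"
  )
)

setValidity("FeatureMatrix", function(object) {
  msgs <- character()
  n <- nrow(object@values)
  if (length(object@labels) != n)
    msgs <- c(msgs, "labels length must equal the number of rows")
  if (length(object@repetitions) != n)
    msgs <- c(msgs, "repetitions length must equal the number of rows")
  if (nrow(object@columnMap) != ncol(object@values))
    msgs <- c(msgs, "columnMap must have one row per feature column")
  if (!all(c("channel", "feature") %in% names(object@columnMap)))
    msgs <- c(msgs, "columnMap needs 'channel' and 'feature' columns")
  if (anyNA(object@values))
    msgs <- c(msgs, "feature values contain missing entries")
  if (length(msgs)) msgs else TRUE
})

#' Construct a FeatureMatrix
#'
#' @param values numeric matrix, samples x features.
#' @param labels class label per row.
#' @param repetitions repetition index per row.
#' @param columnMap data.frame with \code{channel} and \code{feature}
#'   columns, one row per feature column.
#' @return A validated \code{\linkS4class{FeatureMatrix}}.
#' @export
FeatureMatrix <- function(values, labels, repetitions, columnMap) {
  new("FeatureMatrix", values = values, labels = as.character(labels),
      repetitions = as.integer(repetitions), columnMap = columnMap)
}

#' ULDATransform: fitted uncorrelated LDA projection
#'
#' @slot center column means of the training features.
#' @slot projection input_dim x reduced_dim matrix; transformed training
#'   features are mutually uncorrelated (identity total scatter).
#' @slot classCountAtFit number of classes seen at fit time.
#' @slot regularization ridge fraction added to the total-scatter spectrum.
#' @export
setClass("ULDATransform",
  slots = c(
    center          = "numeric",
    projection      = "matrix",
    classCountAtFit = "integer",
    regularization  = "numeric"
  )
)

#' LDCModel: Gaussian equal-covariance linear discriminant classifier
#'
#' @slot classes sorted class labels; ties at prediction go to the first.
#' @slot means class-by-dimension matrix of class mean vectors.
#' @slot pooledCovariance pooled within-class covariance (after shrinkage).
#' @slot priors per-class prior probabilities (sum to 1).
#' @slot shrinkage shrinkage weight toward the scaled identity, in [0, 1].
#' @export
setClass("LDCModel",
  slots = c(
    classes          = "character",
    means            = "matrix",
    pooledCovariance = "matrix",
    priors           = "numeric",
    shrinkage        = "numeric"
  )
)

setValidity("LDCModel", function(object) {
  if (abs(sum(object@priors) - 1) > 1e-8)
    return("priors must sum to 1")
  TRUE
})

#' ChannelSelectionResult: an ordered channel subset with its audit trail
#'
#' @slot method one of \code{"fcsi"}, \code{"sfs"}, \code{"fcsi_sfs"}.
#' @slot selected ordered integer vector of selected channel indices.
#' @slot stepScores criterion value at each selection step (an FCSI value,
#'   or an inner-validation accuracy for SFS).
#' @slot audit list, one entry per step: the named vector of candidate
#'   scores evaluated at that step.
#' @export
setClass("ChannelSelectionResult",
  slots = c(
    method     = "character",
    selected   = "integer",
    stepScores = "numeric",
    audit      = "list"
  )
)

setValidity("ChannelSelectionResult", function(object) {
  msgs <- character()
  if (anyDuplicated(object@selected))
    msgs <- c(msgs, "selected channels must be duplicate-free")
  if (length(object@stepScores) != length(object@selected))
    msgs <- c(msgs, "stepScores must have one entry per selected channel")
  if (!object@method %in% c("fcsi", "sfs", "fcsi_sfs"))
    msgs <- c(msgs, "unknown selection method")
  if (length(msgs)) msgs else TRUE
})

#' SynthConfig: configuration of the synthetic high-density sEMG generator
#'
#' Describes a classes x repetitions x channels recording session in which
#' a known subset of channels carries class-dependent information (amplitude
#' gain, spectral band placement, or both) and the remaining channels are
#' class-invariant band-limited noise.
#'
#' @slot nClasses number of movement classes.
#' @slot nRepetitions contraction repetitions per class.
#' @slot nChannels number of recording channels.
#' @slot samplingRate sampling rate in Hz.
#' @slot activeDuration active (contraction) segment duration, seconds.
#' @slot restDuration rest duration before and after the burst, seconds.
#' @slot informativeChannels channels carrying class information (1-based).
#' @slot coding \code{"both"}, \code{"gain"}, \code{"spectral"} or
#'   \code{"none"} (null data: no class effect anywhere).
#' @slot gainRatio amplitude ratio between the extreme classes on an
#'   informative channel (gain coding).
#' @slot bandWidthHz width of the class-specific passband (spectral coding).
#' @slot band overall EMG passband, Hz (uninformative channels).
#' @slot envelopeRiseMs trapezoidal envelope rise/fall time, ms.
#' @slot noiseFloor baseline (rest) noise standard deviation.
#' @slot seed integer seed making generation fully reproducible.
#' @export
setClass("SynthConfig",
  slots = c(
    nClasses            = "integer",
    nRepetitions        = "integer",
    nChannels           = "integer",
    samplingRate        = "numeric",
    activeDuration      = "numeric",
    restDuration        = "numeric",
    informativeChannels = "integer",
    coding              = "character",
    gainRatio           = "numeric",
    bandWidthHz         = "numeric",
    band                = "numeric",
    envelopeRiseMs      = "numeric",
    noiseFloor          = "numeric",
    seed                = "integer"
  )
)

setValidity("SynthConfig", function(object) {
  msgs <- character()
  if (any(object@informativeChannels < 1L) ||
      any(object@informativeChannels > object@nChannels))
    msgs <- c(msgs, "informativeChannels out of range")
  if (!object@coding %in% c("both", "gain", "spectral", "none"))
    msgs <- c(msgs, "coding must be both/gain/spectral/none")
  if (object@gainRatio <= 0)
    msgs <- c(msgs, "gainRatio must be positive")
  nyq <- object@samplingRate / 2
  if (length(object@band) != 2L || object@band[1] <= 0 ||
      object@band[2] <= object@band[1] || object@band[2] >= nyq)
    msgs <- c(msgs, "band must be 0 < low < high < Nyquist")
  if (object@nClasses < 2L) msgs <- c(msgs, "need at least 2 classes")
  if (length(msgs)) msgs else TRUE
})
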
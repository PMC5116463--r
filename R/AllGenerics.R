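#' @rdname EMGDataset-class
#' @param x an object.
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname EMGDataset-class
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname EMGDataset-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname EMGDataset-class
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname EMGDataset-class
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname EMGDataset-class
#' @export
setGeneric("repetitions", function(x) standardGeneric("repetitions"))

#' @rdname EMGDataset-class
#' @param i trial index.
#' @export
setGeneric("trialMatrix", function(x, i) standardGeneric("trialMatrix"))

#' @rdname EMGDataset-class
#' @export
setGeneric("activeIntervals", function(x) standardGeneric("activeIntervals"))

#' @rdname FeatureMatrix-class
#' @param x an object.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("columnMap", function(x) standardGeneric("columnMap"))

#' @rdname ChannelSelectionResult-class
#' @param x an object.
#' @export
setGeneric("selectedChannels", function(x) standardGeneric("selectedChannels"))

#' @rdname ChannelSelectionResult-class
#' @export
setGeneric("stepScores", function(x) standardGeneric("stepScores"))

#' @rdname WPTTree-class
#' @param x an object.
#' @param j scale index (1..depth).
#' @param k subband index (0..2^j - 1).
#' @export
setGeneric("nodeCoefficients", function(x, j, k)
  standardGeneric("nodeCoefficients"))
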
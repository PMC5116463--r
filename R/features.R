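#' Hudgins time-domain feature set
#'
#' The four conventional time-domain statistics of a window: mean absolute
#' value (MAV), zero-crossing count (ZC), slope-sign-change count (SSC)
#' and waveform length (WL). ZC counts sign changes whose amplitude step
#' reaches \code{zcThreshold}; SSC counts interior turning points whose
#' larger adjacent step reaches \code{sscThreshold}. Both thresholds
#' default to 0 (no deadzone).
#'
#' @param signal numeric vector, length >= 3.
#' @param zcThreshold nonnegative amplitude deadzone for ZC.
#' @param sscThreshold nonnegative amplitude deadzone for SSC.
#' @return Named numeric vector \code{c(MAV, ZC, SSC, WL)}.
#' @examples
#' tdFeatures(c(1, -1, 1, -1))  # MAV 1, ZC 3, SSC 2, WL 6
#' @export
tdFeatures <- function(signal, zcThreshold = 0, sscThreshold = 0) {
  x <- as.numeric(signal)
  n <- length(x)
  if (n < 3L) stop("td features need at least 3 samples")
  d <- diff(x)
  mav <- mean(abs(x))
  zc <- sum(x[-n] * x[-1L] < 0 & abs(d) >= zcThreshold)
  xm <- x[2:(n - 1L)]
  back <- xm - x[1:(n - 2L)]
  fwd <- xm - x[3:n]
  ssc <- sum(back * fwd > 0 & pmax(abs(back), abs(fwd)) >= sscThreshold)
  wl <- sum(abs(d))
  c(MAV = mav, ZC = zc, SSC = ssc, WL = wl)
}

#' Extract per-window features from every channel of a dataset
#'
#' Runs the full front end: active segments of each trial (stored
#' intervals, or the activity detector) are sliced into overlapping
#' analysis windows, and each channel of each window is summarised either
#' by the 30 depth-4 wavelet-packet subspace log-energies (\code{"wpt"})
#' or by the 4 Hudgins time-domain statistics (\code{"td"}). Features from
#' all channels are concatenated per window, channel by channel, and the
#' column map records each column's provenance.
#'
#' @param dataset an \code{\linkS4class{EMGDataset}}.
#' @param method \code{"wpt"} or \code{"td"}.
#' @param windowMs analysis window length, ms.
#' @param overlapFraction overlap between consecutive windows, in [0, 1).
#' @param wavelet,depth,boundaryMode,epsilon wavelet-packet parameters
#'   (see \code{\link{wptDecompose}}, \code{\link{subspaceLogEnergy}}).
#' @param zcThreshold,sscThreshold time-domain deadzones
#'   (see \code{\link{tdFeatures}}).
#' @param detectArgs list of overrides for \code{\link{detectActivity}}
#'   when trials carry no stored active intervals.
#' @return A \code{\linkS4class{FeatureMatrix}} with one row per analysis
#'   window: 30 columns per channel for \code{"wpt"}, 4 for \code{"td"}.
#' @examples
#' ds <- generateDataset(makeFixture("tiny"))$dataset
#' fm <- extractFeatures(ds, "td")
#' dim(featureValues(fm))
#' @export
extractFeatures <- function(dataset, method = c("wpt", "td"),
                            windowMs = 256, overlapFraction = 0.75,
                            wavelet = "sym5", depth = 4L,
                            boundaryMode = "periodization",
                            epsilon = 1e-12,
                            zcThreshold = 0, sscThreshold = 0,
                            detectArgs = list()) {
  stopifnot(is(dataset, "EMGDataset"))
  method <- match.arg(method)
  L <- nChannels(dataset)
  fs <- samplingRate(dataset)
  perCh <- if (method == "wpt") sum(2L^seq_len(as.integer(depth))) else 4L

  featIds <- if (method == "wpt") {
    unlist(lapply(seq_len(as.integer(depth)), function(j)
      paste0("wpt_", j, "_", 0:(2L^j - 1L))))
  } else c("MAV", "ZC", "SSC", "WL")

  rowsList <- list()
  labs <- character(0)
  reps <- integer(0)
  for (i in seq_len(nTrials(dataset))) {
    segs <- .trialSegments(dataset, i, detectArgs)
    for (seg in segs) {
      if (nrow(seg) < .roundAway(windowMs * fs / 1000)) next
      sw <- segmentWindows(seg, fs, windowMs, overlapFraction)
      W <- sw$windowLength
      nWin <- length(sw$starts)
      block <- matrix(0, nWin, L * perCh)
      if (method == "wpt") {
        idx <- outer(seq_len(W), sw$starts, "+")  # W x nWin sample index
        for (ch in seq_len(L)) {
          Xw <- matrix(seg[, ch][idx], nrow = W)
          en <- .wptEnergyMatrix(Xw, wavelet, as.integer(depth),
                                 boundaryMode)
          block[, ((ch - 1L) * perCh + 1L):(ch * perCh)] <-
            t(log(en + epsilon))
        }
      } else {
        for (w in seq_len(nWin)) {
          win <- sw$windows[[w]]
          for (ch in seq_len(L))
            block[w, ((ch - 1L) * perCh + 1L):(ch * perCh)] <-
              tdFeatures(win[, ch], zcThreshold, sscThreshold)
        }
      }
      rowsList[[length(rowsList) + 1L]] <- block
      labs <- c(labs, rep(dataset@classLabels[i], nWin))
      reps <- c(reps, rep(dataset@repetitions[i], nWin))
    }
  }
  if (!length(rowsList))
    stop("no analysis windows could be derived from the dataset")
  values <- do.call(rbind, rowsList)
  columnMap <- data.frame(
    channel = rep(seq_len(L), each = perCh),
    feature = rep(featIds, times = L),
    stringsAsFactors = FALSE)
  FeatureMatrix(values, labs, reps, columnMap)
}
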
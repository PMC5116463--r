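# round half away from zero, so 256 ms at 2 kHz -> 512 samples regardless
# of the platform's banker's rounding
.roundAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Bipolar derivation from monopolar channels
#'
#' Forms each output channel as the difference between two input channels
#' (anode minus cathode), the generic single spatial differential used to
#' derive bipolar sEMG from a monopolar electrode grid.
#'
#' @param dataset an \code{\linkS4class{EMGDataset}}.
#' @param pairs two-column integer matrix (or list of length-2 vectors):
#'   1-based (anode, cathode) channel indices, one row per output channel.
#' @return An \code{EMGDataset} with \code{nrow(pairs)} channels; labels,
#'   repetitions and active intervals are preserved.
#' @examples
#' ds <- generateDataset(makeFixture("tiny"))$dataset
#' bp <- bipolarDerive(ds, cbind(1:3, 4:6))
#' nChannels(bp)
#' @export
bipolarDerive <- function(dataset, pairs) {
  stopifnot(is(dataset, "EMGDataset"))
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  L <- nChannels(dataset)
  if (any(pairs < 1L) || any(pairs > L))
    stop(sprintf("pair indices must be in 1..%d", L))
  trials <- lapply(dataset@trials, function(m)
    m[, pairs[, 1L], drop = FALSE] - m[, pairs[, 2L], drop = FALSE])
  nm <- paste0(dataset@channelNames[pairs[, 1L]], "-",
               dataset@channelNames[pairs[, 2L]])
  EMGDataset(trials, dataset@classLabels, dataset@repetitions,
             dataset@samplingRate, nm, dataset@activeIntervals)
}

#' Detect voluntary activity segments in a trial
#'
#' Double-threshold detector on the moving average of the rectified,
#' channel-summed signal. The baseline mean and SD are estimated from the
#' first \code{smoothMs} of the trial; activity starts when the envelope
#' exceeds baseline + \code{onThreshold} SD and ends when it falls below
#' baseline + \code{offThreshold} SD. Segments shorter than
#' \code{minDurationMs} are discarded.
#'
#' @param trial numeric time-by-channel matrix (a single repetition).
#' @param samplingRate sampling rate in Hz.
#' @param smoothMs moving-average window, ms.
#' @param onThreshold onset threshold, in baseline SD units (> 0).
#' @param offThreshold offset threshold, in baseline SD units (> 0).
#' @param minDurationMs minimum segment duration, ms.
#' @return Integer matrix with columns \code{onset}, \code{offset}:
#'   0-based, half-open \code{[onset, offset)} sample intervals,
#'   non-overlapping and in time order. Zero rows if no activity is found.
#' @export
detectActivity <- function(trial, samplingRate, smoothMs = 50,
                           onThreshold = 3, offThreshold = 1,
                           minDurationMs = 500) {
  if (onThreshold <= 0 || offThreshold <= 0)
    stop("thresholds must be positive")
  trial <- as.matrix(trial)
  n <- nrow(trial)
  w <- max(1L, as.integer(.roundAway(smoothMs * samplingRate / 1000)))
  if (n < w) stop("trial shorter than the smoothing window")
  env <- rowSums(abs(trial))
  # centered moving average via cumulative sums
  cs <- c(0, cumsum(env))
  lo <- pmax(0L, seq_len(n) - 1L - (w %/% 2L))
  hi <- pmin(n, seq_len(n) - 1L + ((w + 1L) %/% 2L))
  env <- (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
  base <- env[seq_len(w)]
  mu0 <- mean(base)
  sd0 <- stats::sd(base)
  if (!is.finite(sd0)) sd0 <- 0
  onLevel <- mu0 + onThreshold * sd0
  offLevel <- mu0 + offThreshold * sd0
  minLen <- .roundAway(minDurationMs * samplingRate / 1000)

  above <- env > onLevel
  below <- env < offLevel
  out <- NULL
  state <- FALSE
  onset <- NA_integer_
  for (t in seq_len(n)) {
    if (!state && above[t]) {
      state <- TRUE
      onset <- t - 1L   # 0-based
    } else if (state && below[t]) {
      state <- FALSE
      if ((t - 1L) - onset >= minLen)
        out <- rbind(out, c(onset, t - 1L))
    }
  }
  if (state && n - onset >= minLen)
    out <- rbind(out, c(onset, n))
  if (is.null(out))
    out <- matrix(integer(0), ncol = 2L)
  colnames(out) <- c("onset", "offset")
  storage.mode(out) <- "integer"
  out
}

#' Slice a segment into overlapping analysis windows
#'
#' The segmentation the classifier operates on: fixed-length windows
#' (default 256 ms) with fractional overlap (default 75\%), partial
#' trailing windows dropped. At 2 kHz the defaults give W = 512 samples
#' and a step of 128 samples.
#'
#' @param segment numeric time-by-channel matrix (an active segment).
#' @param samplingRate sampling rate in Hz.
#' @param windowMs window length in ms.
#' @param overlapFraction overlap between consecutive windows, in [0, 1).
#' @return List with \code{starts} (0-based window start samples),
#'   \code{windowLength} (samples) and \code{windows} (list of W-by-channel
#'   matrices).
#' @examples
#' seg <- matrix(rnorm(6000 * 2), ncol = 2)
#' sw <- segmentWindows(seg, 2000)
#' length(sw$windows)  # 43
#' @export
segmentWindows <- function(segment, samplingRate, windowMs = 256,
                           overlapFraction = 0.75) {
  if (overlapFraction < 0 || overlapFraction >= 1)
    stop("overlapFraction must be in [0, 1)")
  segment <- as.matrix(segment)
  W <- as.integer(.roundAway(windowMs * samplingRate / 1000))
  step <- as.integer(.roundAway(W * (1 - overlapFraction)))
  if (step < 1L) stop("overlap too large: step is below one sample")
  n <- nrow(segment)
  if (n < W)
    stop(sprintf("segment (%d samples) shorter than one window (%d)", n, W))
  nWin <- (n - W) %/% step + 1L
  starts <- (seq_len(nWin) - 1L) * step
  windows <- lapply(starts, function(s)
    segment[(s + 1L):(s + W), , drop = FALSE])
  list(starts = starts, windowLength = W, windows = windows)
}

# Active segments of one trial: stored intervals when present, otherwise
# the double-threshold detector.
.trialSegments <- function(dataset, i, detectArgs = list()) {
  iv <- dataset@activeIntervals[[i]]
  if (is.null(iv) || nrow(iv) == 0L) {
    iv <- do.call(detectActivity,
                  c(list(trial = dataset@trials[[i]],
                         samplingRate = dataset@samplingRate), detectArgs))
  }
  m <- dataset@trials[[i]]
  lapply(seq_len(nrow(iv)), function(r)
    m[(iv[r, 1L] + 1L):iv[r, 2L], , drop = FALSE])
}
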
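#' Build a synthetic-data generator configuration
#'
#' Describes a high-density sEMG recording session: every trial is one
#' contraction repetition (rest, trapezoid-enveloped burst, rest), every
#' channel is amplitude-modulated band-limited Gaussian noise, and class
#' information is planted only on the \code{informativeChannels}, as a
#' class-specific amplitude gain (\code{"gain"}), a class-specific
#' passband placement (\code{"spectral"}), or both. \code{"none"} yields
#' null data with no class effect anywhere.
#'
#' Defaults mirror a typical high-density recording protocol: 20 movement
#' classes, 5 repetitions, 2 kHz sampling, roughly 3 s of contraction per
#' repetition, a 20-500 Hz passband, and 3 informative channels among 16.
#'
#' @param nClasses,nRepetitions,nChannels session shape.
#' @param samplingRate sampling rate, Hz.
#' @param activeDuration,restDuration burst and flanking rest, seconds.
#' @param informativeChannels 1-based indices; \code{NULL} picks 3 (or
#'   fewer for small layouts) evenly spaced channels.
#' @param coding \code{"both"}, \code{"gain"}, \code{"spectral"},
#'   \code{"none"}.
#' @param gainRatio amplitude ratio between extreme classes (gain coding).
#' @param bandWidthHz class passband width, Hz (spectral coding).
#' @param band overall EMG passband, Hz.
#' @param envelopeRiseMs trapezoid rise/fall, ms.
#' @param noiseFloor baseline noise SD (burst amplitude is 1).
#' @param seed integer seed; generation is bit-reproducible given it.
#' @return A validated \code{\linkS4class{SynthConfig}}.
#' @export
synthConfig <- function(nClasses = 20L, nRepetitions = 5L,
                        nChannels = 16L, samplingRate = 2000,
                        activeDuration = 3, restDuration = 1,
                        informativeChannels = NULL,
                        coding = c("both", "gain", "spectral", "none"),
                        gainRatio = 3, bandWidthHz = 120,
                        band = c(20, 500), envelopeRiseMs = 200,
                        noiseFloor = 0.05, seed = 1L) {
  coding <- match.arg(coding)
  if (is.null(informativeChannels)) {
    k <- min(3L, as.integer(nChannels))
    informativeChannels <- unique(as.integer(round(
      seq(nChannels / 6, nChannels * 5 / 6, length.out = k))))
  }
  new("SynthConfig",
      nClasses = as.integer(nClasses),
      nRepetitions = as.integer(nRepetitions),
      nChannels = as.integer(nChannels),
      samplingRate = as.numeric(samplingRate),
      activeDuration = as.numeric(activeDuration),
      restDuration = as.numeric(restDuration),
      informativeChannels = as.integer(informativeChannels),
      coding = coding,
      gainRatio = as.numeric(gainRatio),
      bandWidthHz = as.numeric(bandWidthHz),
      band = as.numeric(band),
      envelopeRiseMs = as.numeric(envelopeRiseMs),
      noiseFloor = as.numeric(noiseFloor),
      seed = as.integer(seed))
}

#' Standard fixture configurations
#'
#' \code{"tiny"} (4 classes x 3 repetitions x 6 channels, 2 informative)
#' is sized for unit tests; \code{"default"} (20 x 5 x 16, 3 informative)
#' is the standard validation condition; \code{"fullscale"} (20 x 5 x 46)
#' mirrors the shape of a full high-density bipolar recording session.
#'
#' @param size \code{"tiny"}, \code{"default"} or \code{"fullscale"}.
#' @param ... overrides passed to \code{\link{synthConfig}} (e.g.
#'   \code{seed}, \code{coding}).
#' @return A \code{\linkS4class{SynthConfig}}.
#' @examples
#' makeFixture("tiny")
#' @export
makeFixture <- function(size = c("tiny", "default", "fullscale"), ...) {
  size <- match.arg(size)
  args <- switch(size,
    tiny = list(nClasses = 4L, nRepetitions = 3L, nChannels = 6L,
                informativeChannels = c(2L, 4L)),
    default = list(nClasses = 20L, nRepetitions = 5L, nChannels = 16L,
                   informativeChannels = c(3L, 8L, 13L)),
    fullscale = list(nClasses = 20L, nRepetitions = 5L, nChannels = 46L,
                     informativeChannels = as.integer(round(
                       seq(4, 44, length.out = 10)))))
  over <- list(...)
  args[names(over)] <- over
  do.call(synthConfig, args)
}

# trapezoidal activation envelope over the burst samples
.trapezoid <- function(n, riseSamples) {
  r <- min(riseSamples, n %/% 2L)
  env <- rep(1, n)
  if (r > 0L) {
    env[seq_len(r)] <- seq_len(r) / r
    env[(n - r + 1L):n] <- rev(seq_len(r) / r)
  }
  env
}

#' Generate a synthetic high-density sEMG dataset with ground truth
#'
#' Each trial is rest + enveloped burst + rest. The burst of channel
#' \code{ch} in class \code{c} is band-pass-filtered white noise (4th
#' order Butterworth, filtered forward-backward), normalised to unit SD
#' and scaled by a class gain; informative channels receive class-specific
#' gains and/or passband centers through a factorial class code (each
#' class gets a base-T digit code, one digit per informative channel, so
#' the informative channels are complementary and none is redundant),
#' while uninformative channels are identically distributed across classes. A
#' white noise floor is added throughout. The true active intervals are
#' stored in the dataset, and the ground-truth record lists the planted
#' structure.
#'
#' @param config a \code{\linkS4class{SynthConfig}}.
#' @return List with \code{dataset} (an \code{\linkS4class{EMGDataset}})
#'   and \code{groundTruth} (informative channels, per-class gains and
#'   band placements, the true active interval).
#' @examples
#' out <- generateDataset(makeFixture("tiny"))
#' out$dataset
#' @export
generateDataset <- function(config) {
  stopifnot(is(config, "SynthConfig"))
  validObject(config)
  # leave the caller's RNG state untouched
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed))
      assign(".Random.seed", oldSeed, envir = globalenv())
  })
  set.seed(config@seed)

  fs <- config@samplingRate
  C <- config@nClasses
  R <- config@nRepetitions
  L <- config@nChannels
  inf <- config@informativeChannels
  if (config@coding == "none") inf <- integer(0)
  nAct <- as.integer(round(config@activeDuration * fs))
  nRest <- as.integer(round(config@restDuration * fs))
  nTot <- nAct + 2L * nRest
  rise <- as.integer(round(config@envelopeRiseMs * fs / 1000))
  envBurst <- .trapezoid(nAct, rise)
  env <- c(rep(0, nRest), envBurst, rep(0, nRest))

  gainCoding <- config@coding %in% c("gain", "both")
  bandCoding <- config@coding %in% c("spectral", "both")

  # Factorial class coding: each class gets a k-digit base-T code (one
  # digit per informative channel), so every informative channel carries
  # a complementary part of the class information and no proper subset of
  # them separates all classes. A seeded class permutation varies the
  # assignment between datasets.
  k <- length(inf)
  Tlev <- if (k == 0L) 1L else if (k == 1L) C else
    max(2L, as.integer(ceiling(C^(1 / k))))
  levels <- matrix(0L, C, max(1L, k))
  if (k > 0L) {
    classPerm <- sample.int(C) - 1L
    for (c in seq_len(C)) {
      v <- classPerm[c]
      for (i in seq_len(k)) {
        levels[c, i] <- v %% Tlev
        v <- v %/% Tlev
      }
    }
  }

  gains <- matrix(1, C, L)
  if (gainCoding && k > 0L) {
    for (i in seq_len(k))
      gains[, inf[i]] <-
        config@gainRatio^(levels[, i] / max(1L, Tlev - 1L))
  }

  w <- config@bandWidthHz
  centers <- if (bandCoding) {
    seq(config@band[1] + w / 2 + 5, config@band[2] - w / 2 - 5,
        length.out = max(2L, Tlev))
  } else NULL
  bandCenter <- matrix(mean(config@band), C, L)
  bandOf <- function(c, ch) {
    if (bandCoding && ch %in% inf) {
      ctr <- centers[levels[c, match(ch, inf)] + 1L]
      c(ctr - w / 2, ctr + w / 2)
    } else config@band
  }
  if (bandCoding && k > 0L) {
    for (i in seq_len(k))
      bandCenter[, inf[i]] <- centers[levels[, i] + 1L]
  }

  # cache one Butterworth design per distinct band
  filtCache <- new.env(parent = emptyenv())
  getFilt <- function(b) {
    key <- paste(signif(b, 10), collapse = "_")
    f <- filtCache[[key]]
    if (is.null(f)) {
      f <- signal::butter(4, b / (fs / 2), type = "pass")
      filtCache[[key]] <- f
    }
    f
  }

  trials <- vector("list", C * R)
  labels <- character(C * R)
  reps <- integer(C * R)
  intervals <- vector("list", C * R)
  iv <- matrix(c(nRest, nRest + nAct), 1L,
               dimnames = list(NULL, c("onset", "offset")))
  storage.mode(iv) <- "integer"
  idx <- 0L
  for (c in seq_len(C)) {
    for (r in seq_len(R)) {
      idx <- idx + 1L
      m <- matrix(0, nTot, L)
      for (ch in seq_len(L)) {
        src <- signal::filtfilt(getFilt(bandOf(c, ch)),
                                stats::rnorm(nTot))
        src <- src / stats::sd(src)
        m[, ch] <- config@noiseFloor * stats::rnorm(nTot) +
          gains[c, ch] * env * src
      }
      trials[[idx]] <- m
      labels[idx] <- sprintf("class%02d", c)
      reps[idx] <- r
      intervals[[idx]] <- iv
    }
  }
  dataset <- EMGDataset(trials, labels, reps, fs,
                        paste0("ch", seq_len(L)), intervals)
  groundTruth <- list(
    informativeChannels = inf,
    coding = config@coding,
    classGains = gains[, inf, drop = FALSE],
    classBandCenters = bandCenter[, inf, drop = FALSE],
    activeInterval = c(onset = nRest, offset = nRest + nAct),
    classLevels = levels, nLevels = Tlev)
  list(dataset = dataset, groundTruth = groundTruth)
}
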
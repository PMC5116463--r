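# Session-cached synthetic fixtures so expensive generation runs once.
.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(name, maker) {
  if (is.null(.fixtureCache[[name]]))
    .fixtureCache[[name]] <- maker()
  .fixtureCache[[name]]
}

tinyData <- function() {
  cachedFixture("tiny", function() generateDataset(makeFixture("tiny")))
}

tinyFeatures <- function() {
  cachedFixture("tinyFM", function()
    extractFeatures(tinyData()$dataset, "wpt"))
}

# A small labelled FeatureMatrix built directly from Gaussian draws, for
# tests that need feature-space structure without the signal front end.
# Channels in `informative` get class-dependent means; all other channels
# are pure noise. Layout: perChannel columns per channel.
gaussianFeatureMatrix <- function(nClasses = 4, nReps = 4, perRep = 10,
                                  nChannelsTotal = 5, perChannel = 3,
                                  informative = c(2, 4), sep = 3,
                                  seed = 42) {
  set.seed(seed)
  n <- nClasses * nReps * perRep
  labels <- rep(sprintf("c%02d", seq_len(nClasses)),
                each = nReps * perRep)
  reps <- rep(rep(seq_len(nReps), each = perRep), times = nClasses)
  vals <- matrix(rnorm(n * nChannelsTotal * perChannel),
                 n, nChannelsTotal * perChannel)
  for (i in seq_along(informative)) {
    ch <- informative[i]
    cols <- ((ch - 1) * perChannel + 1):(ch * perChannel)
    # a distinct cyclic class-to-offset map per informative channel
    for (c in seq_len(nClasses)) {
      rows <- labels == sprintf("c%02d", c)
      shift <- sep * ((c + i) %% nClasses)
      vals[rows, cols] <- vals[rows, cols] + shift
    }
  }
  FeatureMatrix(
    vals, labels, reps,
    data.frame(channel = rep(seq_len(nChannelsTotal), each = perChannel),
               feature = rep(paste0("wpt_1_", seq_len(perChannel) - 1),
                             nChannelsTotal),
               stringsAsFactors = FALSE))
}
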
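test_that("fcsi ranking finds informative channels and obeys ties", {
  fm <- gaussianFeatureMatrix(informative = c(2, 4), sep = 3)
  res <- selectChannelsFCSI(fm, 2)
  expect_setequal(selectedChannels(res), c(2L, 4L))
  expect_length(res@audit$step1, 5L)
  expect_equal(res@stepScores, sort(res@stepScores, decreasing = TRUE))

  # identically distributed channels: all-zero scores, index order
  set.seed(41)
  n <- 80
  vals <- matrix(rep(rnorm(n), 6), n, 6)
  fm0 <- FeatureMatrix(vals, rep(c("a", "b"), n / 2),
                       rep(1:4, each = n / 4),
                       data.frame(channel = rep(1:3, each = 2),
                                  feature = rep(c("f1", "f2"), 3)))
  res0 <- selectChannelsFCSI(fm0, 2)
  expect_equal(selectedChannels(res0), c(1L, 2L))

  # m = L returns a permutation of all channels
  resAll <- selectChannelsFCSI(fm, 5)
  expect_setequal(selectedChannels(resAll), 1:5)
  expect_error(selectChannelsFCSI(fm, 9), "m must be")
})

test_that("sfs adds channels by inner-validation accuracy", {
  fm <- gaussianFeatureMatrix(informative = 3, sep = 4,
                              nChannelsTotal = 8)
  res <- selectChannelsSFS(fm, 1)
  expect_equal(selectedChannels(res), 3L)
  expect_gt(stepScores(res)[1], 0.9)

  # uninformative data: step-1 accuracy sits near chance (1/4)
  fmNull <- gaussianFeatureMatrix(informative = integer(0))
  resNull <- selectChannelsSFS(fmNull, 1)
  expect_lt(stepScores(resNull)[1], 0.45)
  expect_gt(stepScores(resNull)[1], 0.08)

  res3 <- selectChannelsSFS(fm, 3)
  expect_length(selectedChannels(res3), 3L)
  expect_false(anyDuplicated(selectedChannels(res3)) > 0)
  expect_length(res3@audit, 3L)

  # the single fixed inner split is also available
  resS <- selectChannelsSFS(fm, 1, innerSplit = "single")
  expect_equal(selectedChannels(resS), 3L)
})

test_that("fcsi+sfs starts from the fcsi argmax and stays duplicate-free", {
  fm <- gaussianFeatureMatrix(informative = c(2, 4), sep = 3)
  top1 <- selectChannelsFCSI(fm, 1)
  comb <- selectChannelsFCSISFS(fm, 1)
  expect_equal(selectedChannels(comb), selectedChannels(top1))

  res <- selectChannelsFCSISFS(fm, 4)
  expect_length(selectedChannels(res), 4L)
  expect_false(anyDuplicated(selectedChannels(res)) > 0)
  expect_setequal(selectedChannels(res)[1:2], c(2L, 4L))
})

test_that("duplicated channels: criterion behavior matches its oracle", {
  # ch 1 informative (dimension A), ch 2 an identical copy of ch 1,
  # ch 3 informative along a complementary dimension, ch 4 noise.
  # The separability index sums per-dimension variances and ignores
  # covariance, so an exact duplicate's union scores exactly the single
  # channel's value (a neutral marginal contribution), while a
  # complementary union dilutes the strong pairs' denominator. The
  # greedy FCSI criterion therefore tolerates the duplicate; the
  # accuracy-driven SFS rejects it. Both behaviors are pinned here
  # against exhaustive evaluation of the step-2 criterion.
  set.seed(43)
  n <- 160
  labels <- rep(sprintf("c%d", 1:4), each = n / 4)
  reps <- rep(rep(1:4, each = n / 16), times = 4)
  fA <- rnorm(n, sd = 0.5) + 3 * (labels %in% c("c3", "c4"))
  fB <- rnorm(n, sd = 0.5) + 2.5 * (labels %in% c("c2", "c4"))
  vals <- cbind(fA, fA, fB, rnorm(n))
  fm <- FeatureMatrix(vals, labels, reps,
                      data.frame(channel = 1:4,
                                 feature = rep("wpt_1_0", 4)))
  res <- selectChannelsFCSISFS(fm, 3)
  expect_equal(selectedChannels(res)[1], 1L)
  # step-2 pick agrees with the exhaustive argmax of the criterion,
  # and the duplicate's union score equals the step-1 score exactly
  step2 <- res@audit$step2
  expect_equal(selectedChannels(res)[2],
               as.integer(names(which.max(step2))))
  expect_equal(unname(step2["2"]), res@stepScores[1], tolerance = 1e-12)
  # the complementary channel still enters the selection right after
  expect_true(3L %in% selectedChannels(res))

  # the classifier-driven search rejects the redundant copy outright
  resSFS <- selectChannelsSFS(fm, 2)
  expect_setequal(selectedChannels(resSFS), c(1L, 3L))
})

test_that("ulda kicks in above the dimension threshold inside fcsi+sfs", {
  fm <- gaussianFeatureMatrix(perChannel = 12, nChannelsTotal = 5,
                              informative = c(2, 4), sep = 3)
  # threshold far above any union: plain concatenated-space criterion
  hi <- selectChannelsFCSISFS(fm, 3, uldaDimThreshold = 1000)
  # threshold 0: every evaluation goes through the reduced space
  lo <- selectChannelsFCSISFS(fm, 3, uldaDimThreshold = 0)
  expect_length(selectedChannels(lo), 3L)
  expect_setequal(selectedChannels(hi)[1:2], c(2L, 4L))
  expect_setequal(selectedChannels(lo)[1:2], c(2L, 4L))
})

test_that("the dataset-level front end keeps the holdout repetition out", {
  ds <- tinyData()$dataset
  fm <- tinyFeatures()
  res <- selectChannels(fm, "fcsi", m = 2, nPerChannel = 12)
  expect_setequal(selectedChannels(res),
                  tinyData()$groundTruth$informativeChannels)
  # manual check: the same selection from explicitly train-only features
  train <- repetitions(fm) != max(repetitions(fm))
  fmTrain <- selectBestBases(subsetRows(fm, train), 12)$features
  expect_equal(selectedChannels(selectChannelsFCSI(fmTrain, 2)),
               selectedChannels(res))
  # corrupting the held-out repetition cannot move the selection
  fm2 <- fm
  set.seed(44)
  fm2@values[!train, ] <- matrix(
    rnorm(sum(!train) * ncol(fm2@values), sd = 100), sum(!train))
  res2 <- selectChannels(fm2, "fcsi", m = 2, nPerChannel = 12)
  expect_identical(selectedChannels(res2), selectedChannels(res))
})
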
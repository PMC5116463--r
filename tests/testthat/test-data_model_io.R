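test_that("dataset round-trips through manifest + trial files", {
  ds <- tinyData()$dataset
  for (fmt in c("csv", "rds")) {
    dir <- withr::local_tempdir()
    man <- writeDataset(ds, dir, format = fmt)
    back <- loadDataset(man)
    expect_equal(nTrials(back), nTrials(ds))
    expect_equal(channelNames(back), channelNames(ds))
    expect_equal(classLabels(back), classLabels(ds))
    expect_equal(repetitions(back), repetitions(ds))
    expect_equal(samplingRate(back), samplingRate(ds))
    expect_equal(activeIntervals(back), activeIntervals(ds))
    if (fmt == "rds") {
      expect_identical(trialMatrix(back, 3), trialMatrix(ds, 3))
    } else {
      expect_equal(trialMatrix(back, 3), trialMatrix(ds, 3),
                   tolerance = 1e-12)
    }
  }
})

test_that("loadDataset rejects malformed inputs with clear errors", {
  dir <- withr::local_tempdir()
  expect_error(loadDataset(file.path(dir, "nope.yaml")), "not found")

  # manifest referencing a nonexistent trial file names the path
  yaml::write_yaml(list(sampling_rate = 100, channel_names = list("a"),
                        trials = list(list(file = "ghost.csv",
                                           class = "x", repetition = 1))),
                   file.path(dir, "manifest.yaml"))
  expect_error(loadDataset(file.path(dir, "manifest.yaml")), "ghost.csv")

  # channel-count mismatch between matrix and declared names
  write.table(matrix(rnorm(20), 10, 2), file.path(dir, "t.csv"),
              sep = ",", row.names = FALSE, col.names = FALSE)
  yaml::write_yaml(list(sampling_rate = 100,
                        channel_names = list("a", "b", "c"),
                        trials = list(list(file = "t.csv", class = "x",
                                           repetition = 1))),
                   file.path(dir, "manifest.yaml"))
  expect_error(loadDataset(file.path(dir, "manifest.yaml")),
               "channel names")

  # non-numeric trial content
  writeLines(c("a,b", "c,d"), file.path(dir, "bad.csv"))
  yaml::write_yaml(list(sampling_rate = 100,
                        channel_names = list("a", "b"),
                        trials = list(list(file = "bad.csv", class = "x",
                                           repetition = 1))),
                   file.path(dir, "manifest.yaml"))
  expect_error(loadDataset(file.path(dir, "manifest.yaml")))
})

test_that("bipolar derivation is the plain pair difference and is linear", {
  set.seed(1)
  u <- rnorm(50); v <- rnorm(50)
  ds <- EMGDataset(list(cbind(u, v)), "m1", 1L, 1000)
  bp <- bipolarDerive(ds, cbind(1L, 2L))
  expect_equal(trialMatrix(bp, 1)[, 1], u - v)
  expect_equal(nChannels(bp), 1L)

  # self-difference is identically zero
  z <- bipolarDerive(ds, cbind(1L, 1L))
  expect_true(all(trialMatrix(z, 1) == 0))

  # linearity: derive(a X) = a derive(X)
  ds3 <- EMGDataset(list(3.7 * cbind(u, v)), "m1", 1L, 1000)
  expect_equal(trialMatrix(bipolarDerive(ds3, cbind(1L, 2L)), 1),
               3.7 * trialMatrix(bp, 1))

  expect_error(bipolarDerive(ds, cbind(1L, 3L)), "1..2")
})

test_that("activity detector finds planted bursts and ignores baseline", {
  fs <- 2000
  set.seed(7)
  base <- function(n) matrix(rnorm(n * 2, sd = 1), n, 2)

  # pure baseline: no interval
  expect_equal(nrow(detectActivity(base(5 * fs), fs)), 0L)

  # silence 1 s | activity 3 s at 10x SD | silence 1 s
  burst <- rbind(base(fs), 10 * base(3 * fs), base(fs))
  iv <- detectActivity(burst, fs)
  expect_equal(nrow(iv), 1L)
  smooth <- 0.05 * fs
  expect_lt(abs(iv[1, "onset"] - fs), 2 * smooth)
  expect_lt(abs(iv[1, "offset"] - 4 * fs), 2 * smooth)

  # two bursts separated by a long gap give two intervals
  two <- rbind(base(fs), 10 * base(fs), base(fs), 10 * base(fs), base(fs))
  iv2 <- detectActivity(two, fs)
  expect_equal(nrow(iv2), 2L)
  expect_true(all(iv2[, "onset"] < iv2[, "offset"]))
  expect_true(iv2[1, "offset"] <= iv2[2, "onset"])

  expect_error(detectActivity(burst, fs, onThreshold = 0), "positive")
})

test_that("window segmentation matches the count formula and overlap", {
  fs <- 2000
  seg <- matrix(rnorm(6000 * 2), ncol = 2)
  sw <- segmentWindows(seg, fs)          # W = 512, step = 128
  expect_equal(sw$windowLength, 512L)
  expect_equal(length(sw$windows), 43L)  # floor((6000-512)/128) + 1

  # single-window and disjoint-tiling edge cases
  expect_equal(length(segmentWindows(seg[1:512, ], fs)$windows), 1L)
  sw0 <- segmentWindows(seg[1:1024, ], fs, overlapFraction = 0)
  expect_equal(length(sw0$windows), 2L)
  expect_equal(sw0$starts, c(0L, 512L))

  # consecutive windows at 75% overlap share exactly W - step samples
  expect_equal(sw$windows[[1]][129:512, ], sw$windows[[2]][1:384, ])

  expect_error(segmentWindows(seg[1:100, ], fs), "shorter")
  expect_error(segmentWindows(seg, fs, overlapFraction = 1), "overlap")
})

test_that("window count formula holds against brute-force enumeration", {
  set.seed(11)
  for (i in 1:40) {
    nSeg <- sample(64:4000, 1)
    fs <- sample(c(500, 1000, 2000), 1)
    windowMs <- sample(c(32, 64, 128, 256), 1)
    ov <- sample(c(0, 0.25, 0.5, 0.75), 1)
    W <- round(windowMs * fs / 1000)
    step <- round(W * (1 - ov))
    if (nSeg < W) next
    sw <- segmentWindows(matrix(rnorm(nSeg), ncol = 1), fs, windowMs, ov)
    expect_equal(sw$starts, bruteWindowStarts(nSeg, W, step))
    expect_equal(length(sw$windows), (nSeg - W) %/% step + 1L)
  }
})
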
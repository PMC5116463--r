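test_that("scalar separability matches direct evaluation", {
  # means 2 and 5, population variances 2/3 each: 9 / (4/3) = 6.75
  expect_equal(fcsiScalar(list(A = c(1, 2, 3), B = c(4, 5, 6))), 6.75)
  # identical class distributions separate nothing
  expect_equal(fcsiScalar(list(A = c(1, 2, 3), B = c(1, 2, 3))), 0)
  expect_error(fcsiScalar(list(A = 1:3)), "2 classes")
})

test_that("scalar separability is affine invariant", {
  set.seed(8)
  for (i in 1:25) {
    g <- randomGroups(sample(2:5, 1))
    a <- runif(1, -4, 4)
    if (abs(a) < 0.1) a <- 1
    b <- runif(1, -10, 10)
    g2 <- lapply(g, function(x) a * x + b)
    expect_equal(fcsiScalar(g2), fcsiScalar(g), tolerance = 1e-10)
  }
})

test_that("two-class index equals the closed-form Fisher criterion", {
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(sample(3:20, 1), runif(1, -2, 2), runif(1, 0.3, 2))
    y <- rnorm(sample(3:20, 1), runif(1, -2, 2), runif(1, 0.3, 2))
    pv <- function(v) mean((v - mean(v))^2)
    closed <- (mean(x) - mean(y))^2 / (pv(x) + pv(y))
    expect_equal(fcsiScalar(list(a = x, b = y)), closed,
                 tolerance = 1e-12)
  }
})

test_that("separability responds monotonically to mean separation", {
  set.seed(10)
  base <- list(A = rnorm(30), B = rnorm(30) + 1, C = rnorm(30) - 0.5)
  prev <- -Inf
  for (shift in seq(0, 5, by = 0.5)) {
    g <- base
    g$B <- g$B + shift
    cur <- fcsiScalar(g)
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("degenerate variances produce the documented sentinels", {
  # zero variance, separated means: +Inf (sorts first), with a warning
  expect_warning(v <- fcsiScalar(list(A = c(1, 1), B = c(2, 2))),
                 "Inf")
  expect_identical(v, Inf)
  # zero variance, equal means: the pair contributes 0
  expect_equal(fcsiScalar(list(A = c(1, 1), B = c(1, 1))), 0)
})

test_that("vector separability matches direct evaluation and scalar case", {
  expect_equal(fcsiVector(list(A = rbind(c(0, 0), c(2, 0)),
                               B = rbind(c(4, 0), c(6, 0)))), 8)
  # identical distributions
  X <- matrix(rnorm(20), 10, 2)
  expect_equal(fcsiVector(list(A = X, B = X)), 0)
  # d = 1 reduces exactly to the scalar index
  set.seed(12)
  for (i in 1:15) {
    g <- randomGroups(sample(2:4, 1))
    gm <- lapply(g, function(x) matrix(x, ncol = 1))
    expect_equal(fcsiVector(gm), fcsiScalar(g), tolerance = 1e-12)
  }
  expect_error(fcsiVector(list(A = matrix(1:4, 2), B = matrix(1:6, 2))),
               "dimension")
})

test_that("vector separability is invariant under common rotation", {
  set.seed(13)
  for (i in 1:15) {
    d <- sample(2:5, 1)
    g <- randomGroups(3, d = d)
    Q <- qr.Q(qr(matrix(rnorm(d * d), d)))
    g2 <- lapply(g, function(X) X %*% Q)
    expect_equal(fcsiVector(g2), fcsiVector(g), tolerance = 1e-9)
  }
})

test_that("subspace ranking finds a planted discriminative column", {
  set.seed(14)
  n <- 60
  labels <- rep(c("a", "b", "c"), each = n / 3)
  vals <- matrix(rep(rnorm(n), 30), n, 30)  # identical across classes
  best <- 17
  vals[, best] <- rnorm(n, sd = 0.3) +
    5 * as.integer(factor(labels))
  fm <- FeatureMatrix(vals, labels, rep(1L, n),
                      data.frame(channel = 1L,
                                 feature = paste0("wpt_x_", 1:30)))
  rk <- rankSubspaces(fm)
  expect_equal(rk$column[1], best)

  # all columns identical across classes: scores 0, natural order kept
  perClass <- rnorm(n / 3)
  fm0 <- FeatureMatrix(matrix(rep(rep(perClass, 3), 5), n, 5), labels,
                       rep(1L, n),
                       data.frame(channel = 1L,
                                  feature = paste0("f", 1:5)))
  rk0 <- rankSubspaces(fm0)
  expect_equal(rk0$column, 1:5)
  expect_true(all(rk0$score < 1e-16))

  # permuting columns permutes nothing in the (feature, score) pairs
  perm <- sample(30)
  fmp <- FeatureMatrix(vals[, perm], labels, rep(1L, n),
                       data.frame(channel = 1L,
                                  feature = paste0("wpt_x_", 1:30)[perm]))
  rkp <- rankSubspaces(fmp)
  expect_equal(sort(paste(rkp$feature, signif(rkp$score, 10))),
               sort(paste(rk$feature, signif(rk$score, 10))))
})

test_that("best-basis selection keeps top-n per channel, training rows only", {
  fm <- gaussianFeatureMatrix(perChannel = 6, nChannelsTotal = 3,
                              informative = c(1, 3))
  # n = full per-channel count is a pure column reorder
  all6 <- selectBestBases(fm, 6)
  expect_equal(ncol(featureValues(all6$features)),
               ncol(featureValues(fm)))
  key <- function(x) paste(columnMap(x)$channel, columnMap(x)$feature)
  reorder <- match(key(fm), key(all6$features))
  expect_equal(featureValues(all6$features)[, reorder],
               featureValues(fm))

  red <- selectBestBases(fm, 2)
  expect_equal(ncol(featureValues(red$features)), 3 * 2)
  expect_equal(unique(table(columnMap(red$features)$channel)), 2L)
  expect_named(red$selection, c("1", "2", "3"))

  # single channel, n = 1: the argmax-FCSI column survives
  one <- subsetChannels(fm, 1)
  scores <- vapply(seq_len(ncol(featureValues(one))), function(j)
    fcsiScalar(split(featureValues(one)[, j], sampleLabels(one))),
    numeric(1))
  sel1 <- selectBestBases(one, 1)
  expect_equal(sel1$selection[["1"]],
               columnMap(one)$feature[which.max(scores)])

  expect_error(selectBestBases(fm, 0), "nPerChannel")
  expect_error(selectBestBases(fm, 7), "nPerChannel")
})

test_that("selection ignores rows outside the training mask", {
  fm <- gaussianFeatureMatrix()
  train <- repetitions(fm) != 4
  ref <- selectBestBases(fm, 2, trainMask = train)$selection
  # shuffle the held-out rows' labels: selection must not move
  fm2 <- fm
  set.seed(99)
  fm2@labels[!train] <- sample(fm2@labels[!train])
  expect_identical(selectBestBases(fm2, 2, trainMask = train)$selection,
                   ref)
  # corrupt the held-out rows' values entirely
  fm3 <- fm
  fm3@values[!train, ] <- 1e6 * matrix(rnorm(sum(!train) *
    ncol(fm3@values)), sum(!train))
  expect_identical(selectBestBases(fm3, 2, trainMask = train)$selection,
                   ref)
})
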
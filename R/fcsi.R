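# Population variance (1/N normalizer), the form used throughout the
# separability index.
.popVar <- function(x) mean((x - mean(x))^2)

#' Fisher's class separability index of a scalar feature
#'
#' For class-grouped feature values, sums over all unordered class pairs
#' (p, q) the squared mean difference divided by the sum of the two
#' class variances (population variances, 1/N normalizer):
#' \deqn{FCSI = \sum_{p<q} (\bar m_p - \bar m_q)^2 / (var_p + var_q).}
#' A pair with zero pooled variance and separated means contributes
#' \code{+Inf} (perfect separability; sorts first in rankings, with a
#' warning); with equal means it contributes 0.
#'
#' @param valuesByClass named list, one numeric vector of feature values
#'   per class (>= 2 classes, each nonempty).
#' @return A single nonnegative number (possibly \code{Inf}).
#' @examples
#' fcsiScalar(list(A = c(1, 2, 3), B = c(4, 5, 6)))  # 6.75
#' @export
fcsiScalar <- function(valuesByClass) {
  .checkGroups(valuesByClass)
  m <- vapply(valuesByClass, mean, numeric(1))
  v <- vapply(valuesByClass, .popVar, numeric(1))
  .pairSum(m, v, function(p, q) (m[p] - m[q])^2)
}

#' Fisher's class separability index of a feature vector
#'
#' The multivariate extension used for channel scoring: class means are
#' mean vectors, the class variance is the sum of per-dimension population
#' variances, and the numerator is the squared Euclidean norm of the mean
#' difference, summed over all unordered class pairs. At dimension 1 this
#' reduces exactly to \code{\link{fcsiScalar}}.
#'
#' @param vectorsByClass named list, one numeric matrix (samples x d) per
#'   class; all classes must share the dimension d.
#' @return A single nonnegative number (possibly \code{Inf}).
#' @examples
#' fcsiVector(list(A = rbind(c(0, 0), c(2, 0)),
#'                 B = rbind(c(4, 0), c(6, 0))))  # 8
#' @export
fcsiVector <- function(vectorsByClass) {
  vectorsByClass <- lapply(vectorsByClass, function(x) {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    x
  })
  .checkGroups(vectorsByClass, matrixInput = TRUE)
  d <- unique(vapply(vectorsByClass, ncol, integer(1)))
  if (length(d) != 1L)
    stop("all classes must share the same feature dimension")
  M <- t(vapply(vectorsByClass, colMeans, numeric(d)))
  if (d == 1L) M <- matrix(unlist(lapply(vectorsByClass, colMeans)),
                           ncol = 1L)
  v <- vapply(vectorsByClass, function(x)
    sum(apply(x, 2L, .popVar)), numeric(1))
  .pairSum(colMeans2 = v, means = M)
}

# shared pairwise accumulation for the scalar and vector index
.pairSum <- function(means, colMeans2 = NULL, numFun = NULL) {
  if (is.matrix(means)) {
    M <- means
    v <- colMeans2
    C <- nrow(M)
    num <- function(p, q) sum((M[p, ] - M[q, ])^2)
  } else {
    v <- colMeans2
    C <- length(means)
    num <- numFun
  }
  total <- 0
  sawInf <- FALSE
  for (p in seq_len(C - 1L)) {
    for (q in (p + 1L):C) {
      nu <- num(p, q)
      de <- v[p] + v[q]
      if (de == 0) {
        if (nu > 0) sawInf <- TRUE
        # equal means with zero variance contribute 0
      } else if (!sawInf) {
        total <- total + nu / de
      }
    }
  }
  if (sawInf) {
    warning("zero within-class variance with separated means: FCSI is Inf")
    return(Inf)
  }
  unname(total)
}

.checkGroups <- function(groups, matrixInput = FALSE) {
  if (length(groups) < 2L)
    stop("need at least 2 classes")
  sizes <- vapply(groups, function(g)
    if (matrixInput) nrow(as.matrix(g)) else length(g), integer(1))
  if (any(sizes < 1L))
    stop("every class must be nonempty")
  invisible(TRUE)
}

# Columnwise scalar FCSI for a samples x features matrix: vectorized over
# columns via grouped first/second moments. Inf where a pair has zero
# pooled variance but separated means.
.fcsiColumns <- function(X, labels) {
  X <- as.matrix(X)
  g <- factor(labels)
  C <- nlevels(g)
  if (C < 2L) stop("need at least 2 classes")
  n_c <- as.numeric(table(g))
  S1 <- rowsum(X, g)                  # class sums
  S2 <- rowsum(X * X, g)              # class sums of squares
  M <- S1 / n_c
  V <- S2 / n_c - M * M               # population variances
  V[V < 0] <- 0                       # numerical guard
  scores <- numeric(ncol(X))
  for (p in seq_len(C - 1L)) {
    for (q in (p + 1L):C) {
      nu <- (M[p, ] - M[q, ])^2
      de <- V[p, ] + V[q, ]
      contrib <- ifelse(de == 0, ifelse(nu > 0, Inf, 0), nu / de)
      scores <- scores + contrib
    }
  }
  scores
}

#' Rank one channel's subspace features by class separability
#'
#' Scores every feature column of a single-channel feature matrix with the
#' scalar separability index and returns them in stable descending order;
#' ties keep the natural (j, k) column order.
#'
#' @param features a \code{\linkS4class{FeatureMatrix}} whose columns all
#'   come from one channel.
#' @param labels optional class labels; defaults to the matrix's own.
#' @return data.frame with columns \code{feature}, \code{channel},
#'   \code{column} (original column index) and \code{score}, sorted by
#'   descending score.
#' @export
rankSubspaces <- function(features, labels = NULL) {
  stopifnot(is(features, "FeatureMatrix"))
  if (nChannels(features) != 1L)
    stop("rankSubspaces expects a single channel's columns")
  if (is.null(labels)) labels <- features@labels
  scores <- .fcsiColumns(features@values, labels)
  if (any(is.infinite(scores)))
    warning("some subspaces have infinite separability (zero variance)")
  ord <- order(-scores, seq_along(scores))
  data.frame(feature = features@columnMap$feature[ord],
             channel = features@columnMap$channel[ord],
             column = ord,
             score = scores[ord],
             stringsAsFactors = FALSE)
}

#' Per-channel best-basis selection of the top-n subspaces
#'
#' For each channel independently, ranks its wavelet-packet subspace
#' features by the scalar separability index and keeps the top
#' \code{nPerChannel} (default 12). The reduced matrix concatenates the
#' selected columns channel by channel; with a training mask, scores are
#' computed from training rows only while all rows are carried through.
#'
#' @param features a \code{\linkS4class{FeatureMatrix}} (any channel count).
#' @param nPerChannel how many subspaces to keep per channel (1..30 for
#'   the depth-4 tree).
#' @param trainMask optional logical vector over rows; selection uses only
#'   rows where it is \code{TRUE}.
#' @return List with \code{selection} (named list channel -> character
#'   vector of kept feature ids, in rank order) and \code{features} (the
#'   reduced \code{FeatureMatrix}).
#' @examples
#' ds <- generateDataset(makeFixture("tiny"))$dataset
#' fm <- extractFeatures(ds, "wpt")
#' red <- selectBestBases(fm, nPerChannel = 5)
#' ncol(featureValues(red$features))  # 5 per channel
#' @export
selectBestBases <- function(features, nPerChannel = 12L,
                            trainMask = NULL) {
  stopifnot(is(features, "FeatureMatrix"))
  channels <- sort(unique(features@columnMap$channel))
  perCh <- sum(features@columnMap$channel == channels[1L])
  nPerChannel <- as.integer(nPerChannel)
  if (nPerChannel < 1L || nPerChannel > perCh)
    stop(sprintf("nPerChannel must be in 1..%d", perCh))
  if (is.null(trainMask)) trainMask <- rep(TRUE, nrow(features@values))
  labels <- features@labels[trainMask]
  keep <- integer(0)
  selection <- vector("list", length(channels))
  names(selection) <- as.character(channels)
  for (ch in seq_along(channels)) {
    cols <- which(features@columnMap$channel == channels[ch])
    scores <- .fcsiColumns(
      features@values[trainMask, cols, drop = FALSE], labels)
    ord <- order(-scores, seq_along(scores))[seq_len(nPerChannel)]
    keep <- c(keep, cols[ord])
    selection[[ch]] <- features@columnMap$feature[cols[ord]]
  }
  reduced <- FeatureMatrix(features@values[, keep, drop = FALSE],
                           features@labels, features@repetitions,
                           features@columnMap[keep, , drop = FALSE])
  list(selection = selection, features = reduced)
}

# group a samples x d matrix into the per-class list fcsiVector expects
.splitByClass <- function(X, labels) {
  X <- as.matrix(X)
  lapply(split(seq_len(nrow(X)), factor(labels)), function(idx)
    X[idx, , drop = FALSE])
}
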
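# Independent brute-force oracles, written directly from the defining
# formulas and kept free of any package internals.

# scalar class-separability index: explicit sums, population variance
bruteFCSIScalar <- function(valuesByClass) {
  C <- length(valuesByClass)
  m <- numeric(C)
  v <- numeric(C)
  for (c in seq_len(C)) {
    x <- valuesByClass[[c]]
    N <- length(x)
    m[c] <- sum(x) / N
    v[c] <- sum((x - m[c])^2) / N
  }
  total <- 0
  for (p in seq_len(C - 1)) {
    for (q in (p + 1):C) {
      total <- total + (m[p] - m[q])^2 / (v[p] + v[q])
    }
  }
  total
}

# vector index: mean vectors, summed per-dimension population variances,
# squared Euclidean mean distance
bruteFCSIVector <- function(vectorsByClass) {
  C <- length(vectorsByClass)
  d <- ncol(vectorsByClass[[1]])
  m <- matrix(0, C, d)
  v <- numeric(C)
  for (c in seq_len(C)) {
    X <- vectorsByClass[[c]]
    N <- nrow(X)
    for (j in seq_len(d)) m[c, j] <- sum(X[, j]) / N
    for (j in seq_len(d)) v[c] <- v[c] + sum((X[, j] - m[c, j])^2) / N
  }
  total <- 0
  for (p in seq_len(C - 1)) {
    for (q in (p + 1):C) {
      total <- total + sum((m[p, ] - m[q, ])^2) / (v[p] + v[q])
    }
  }
  total
}

# Gaussian MAP with a shared covariance, via the full quadratic density
# (not the linear discriminant simplification)
bruteGaussianMAP <- function(X, means, Sigma, priors, classes) {
  Sinv <- solve(Sigma)
  n <- nrow(X)
  pred <- character(n)
  for (i in seq_len(n)) {
    post <- numeric(nrow(means))
    for (c in seq_len(nrow(means))) {
      diff <- X[i, ] - means[c, ]
      post[c] <- -0.5 * drop(t(diff) %*% Sinv %*% diff) + log(priors[c])
    }
    pred[i] <- classes[which.max(post)]
  }
  pred
}

# every admissible window start position, by direct enumeration
bruteWindowStarts <- function(nSeg, W, step) {
  starts <- integer(0)
  s <- 0L
  while (s + W <= nSeg) {
    starts <- c(starts, s)
    s <- s + step
  }
  starts
}

# random class-grouped scalar values for oracle-equivalence sweeps
randomGroups <- function(nClasses, maxN = 12, d = NULL) {
  out <- list()
  for (c in seq_len(nClasses)) {
    n <- sample(2:maxN, 1)
    out[[paste0("c", c)]] <- if (is.null(d)) {
      rnorm(n, mean = runif(1, -3, 3), sd = runif(1, 0.2, 2))
    } else {
      matrix(rnorm(n * d, mean = runif(1, -2, 2)), n, d)
    }
  }
  out
}
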
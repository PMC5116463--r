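#' Fit an uncorrelated linear discriminant transform
#'
#' Supervised linear dimensionality reduction that maximises between-class
#' scatter relative to total scatter under the constraint that the
#' transformed training features are mutually uncorrelated (identity total
#' scatter). Realised by simultaneous diagonalization through two economy
#' SVDs: whiten the total scatter in its range, then take the leading left
#' singular vectors of the whitened between-class structure. The output
#' dimension is at most C - 1 for C classes. A small ridge (fraction
#' \code{regularization} of the mean spectrum) stabilises the whitening
#' when the total scatter is rank-deficient.
#'
#' @param features numeric matrix, samples x dimensions.
#' @param labels class label per row (>= 2 classes).
#' @param regularization nonnegative ridge fraction (default 1e-6).
#' @return A \code{\linkS4class{ULDATransform}}.
#' @examples
#' X <- rbind(matrix(rnorm(100), 50), matrix(rnorm(100, 3), 50))
#' tf <- uldaFit(X, rep(c("a", "b"), each = 50))
#' dim(uldaApply(tf, X))  # n x 1 (C - 1 = 1)
#' @export
uldaFit <- function(features, labels, regularization = 1e-6) {
  X <- as.matrix(features)
  labels <- as.character(labels)
  g <- factor(labels)
  C <- nlevels(g)
  if (C < 2L) stop("ulda needs at least 2 classes")
  n <- nrow(X)
  d <- ncol(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)

  # total scatter S_t = t(Xc) Xc / n, diagonalized through svd(Xc)
  sv <- svd(Xc, nu = 0)
  tolr <- max(sv$d) * max(n, d) * .Machine$double.eps
  r <- max(1L, sum(sv$d > tolr))
  V <- sv$v[, seq_len(r), drop = FALSE]
  eig <- (sv$d[seq_len(r)]^2) / n
  eig <- eig + regularization * mean(eig)

  # between-class structure H_b: columns sqrt(n_c/n) (mu_c - mu)
  n_c <- as.numeric(table(g))
  M <- rowsum(X, g) / n_c
  Hb <- t(sweep(M, 2L, mu)) * rep(sqrt(n_c / n), each = d)

  B <- (t(V) %*% Hb) / sqrt(eig)
  sb <- svd(B, nv = 0)
  tolb <- max(sb$d[1], 0) * max(dim(B)) * .Machine$double.eps
  q <- max(1L, sum(sb$d > tolb))
  q <- min(q, C - 1L)
  P <- sb$u[, seq_len(q), drop = FALSE]

  G <- V %*% (P / sqrt(eig))
  # deterministic sign: largest-magnitude loading of each column positive
  for (j in seq_len(ncol(G))) {
    i <- which.max(abs(G[, j]))
    if (G[i, j] < 0) G[, j] <- -G[, j]
  }
  new("ULDATransform", center = mu, projection = G,
      classCountAtFit = C, regularization = regularization)
}

#' Apply a fitted ULDA transform
#'
#' @param transform a \code{\linkS4class{ULDATransform}}.
#' @param features numeric matrix with the fit-time column count.
#' @return The reduced samples x reduced_dim matrix.
#' @export
uldaApply <- function(transform, features) {
  stopifnot(is(transform, "ULDATransform"))
  X <- as.matrix(features)
  if (ncol(X) != nrow(transform@projection))
    stop(sprintf("expected %d feature columns, got %d",
                 nrow(transform@projection), ncol(X)))
  sweep(X, 2L, transform@center) %*% transform@projection
}
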
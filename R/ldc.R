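#' Fit a linear discriminant (Gaussian MAP) classifier
#'
#' Models every class as a multivariate Gaussian with its own mean and a
#' shared (pooled within-class) covariance; prediction follows the maximum
#' a posteriori rule, which is linear in the features. Optional shrinkage
#' pulls the pooled covariance toward the scaled identity
#' \code{(trace/d) I}, making the fit usable when the covariance is
#' singular.
#'
#' @param features numeric matrix, samples x dimensions.
#' @param labels class label per row; every class needs >= 2 samples.
#' @param shrinkage shrinkage weight in [0, 1].
#' @param priors \code{"uniform"} (default; matches a balanced repetition
#'   design) or \code{"empirical"} (class frequencies).
#' @return An \code{\linkS4class{LDCModel}}.
#' @export
ldcFit <- function(features, labels, shrinkage = 0,
                   priors = c("uniform", "empirical")) {
  priors <- match.arg(priors)
  X <- as.matrix(features)
  g <- factor(as.character(labels))
  C <- nlevels(g)
  if (C < 2L) stop("ldc needs at least 2 classes")
  n_c <- as.numeric(table(g))
  if (any(n_c < 2L))
    stop("every class needs at least 2 samples for the pooled covariance")
  n <- nrow(X)
  d <- ncol(X)
  M <- rowsum(X, g) / n_c
  Xc <- X - M[as.integer(g), , drop = FALSE]
  Sw <- crossprod(Xc) / (n - C)
  if (shrinkage < 0 || shrinkage > 1) stop("shrinkage must be in [0, 1]")
  if (shrinkage > 0) {
    Sw <- (1 - shrinkage) * Sw +
      shrinkage * (sum(diag(Sw)) / d) * diag(d)
  }
  ok <- tryCatch({ chol(Sw); TRUE }, error = function(e) FALSE)
  if (!ok)
    stop("pooled covariance is singular; refit with shrinkage > 0")
  pr <- if (priors == "uniform") rep(1 / C, C) else n_c / n
  new("LDCModel", classes = levels(g), means = M,
      pooledCovariance = Sw, priors = pr, shrinkage = shrinkage)
}

#' Predict classes with a fitted linear discriminant classifier
#'
#' Evaluates the linear discriminant
#' \eqn{g_c(x) = x^T \Sigma^{-1} \mu_c - \tfrac12 \mu_c^T \Sigma^{-1}
#' \mu_c + \log \pi_c} for every class and returns the argmax; exact ties
#' go to the lowest (first in sorted order) class label.
#'
#' @param model an \code{\linkS4class{LDCModel}}.
#' @param features numeric matrix with the fit-time column count.
#' @return List with \code{class} (character vector of predictions) and
#'   \code{scores} (samples x classes discriminant matrix).
#' @export
ldcPredict <- function(model, features) {
  stopifnot(is(model, "LDCModel"))
  X <- as.matrix(features)
  if (ncol(X) != ncol(model@means))
    stop(sprintf("expected %d feature columns, got %d",
                 ncol(model@means), ncol(X)))
  W <- solve(model@pooledCovariance, t(model@means))   # d x C
  const <- -0.5 * colSums(t(model@means) * W) + log(model@priors)
  scores <- X %*% W + rep(const, each = nrow(X))
  colnames(scores) <- model@classes
  pick <- max.col(scores, ties.method = "first")
  list(class = model@classes[pick], scores = scores)
}
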
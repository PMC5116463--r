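# Orthogonal decomposition filter banks (lowpass, highpass). Standard
# published coefficients; sym5 is the package default analysis wavelet.
.waveletFilters <- list(
  sym5 = list(
    lo = c(0.027333068345077982, 0.029519490925774643,
           -0.039134249302383094, 0.1993975339773936,
           0.72340769040242059, 0.63397896345821192,
           0.016602105764522319, -0.17532808990845047,
           -0.021101834024758855, 0.019538882735286728),
    hi = c(-0.019538882735286728, -0.021101834024758855,
           0.17532808990845047, 0.016602105764522319,
           -0.63397896345821192, 0.72340769040242059,
           -0.1993975339773936, -0.039134249302383094,
           -0.029519490925774643, 0.027333068345077982)),
  haar = list(
    lo = c(0.70710678118654757, 0.70710678118654757),
    hi = c(-0.70710678118654757, 0.70710678118654757)),
  db4 = list(
    lo = c(-0.010597401785069032, 0.032883011666885197,
           0.030841381835560764, -0.18703481171909309,
           -0.027983769416859854, 0.63088076792985892,
           0.71484657055291567, 0.23037781330889651),
    hi = c(-0.23037781330889651, 0.71484657055291567,
           -0.63088076792985892, -0.027983769416859854,
           0.18703481171909309, 0.030841381835560764,
           -0.032883011666885197, -0.010597401785069032))
)

.getFilters <- function(wavelet) {
  f <- .waveletFilters[[wavelet]]
  if (is.null(f))
    stop(sprintf("unknown wavelet '%s' (available: %s)", wavelet,
                 paste(names(.waveletFilters), collapse = ", ")))
  f
}

# One analysis filter-bank step on the columns of X (N x M, N even), with
# periodized boundaries: out[k, ] = sum_m f[m] X[(2k + F/2 - m) mod N, ].
# The phase puts the filter's group delay at the subsampling grid, so the
# same step applied with the quadrature pair is an orthonormal map and
# leaf energies sum exactly to the input energy.
.dwtStepPeriodic <- function(X, filt) {
  N <- nrow(X)
  half <- N %/% 2L
  Fl <- length(filt)
  off <- Fl %/% 2L
  k2 <- 2L * (seq_len(half) - 1L)
  out <- matrix(0, half, ncol(X))
  for (m in seq_len(Fl)) {
    rows <- ((k2 + off - (m - 1L)) %% N) + 1L
    out <- out + filt[m] * X[rows, , drop = FALSE]
  }
  out
}

# Symmetric (half-point reflection) boundary handling; output length
# floor((N + F - 1) / 2). Energy is not exactly conserved in this mode.
.dwtStepSymmetric <- function(X, filt) {
  N <- nrow(X)
  Fl <- length(filt)
  ext <- c(rev(seq_len(Fl - 1L)), seq_len(N), N + 1L - seq_len(Fl - 1L))
  Xe <- X[ext, , drop = FALSE]
  Ne <- nrow(Xe)
  full <- Ne - Fl + 1L
  conv <- matrix(0, full, ncol(X))
  for (m in seq_len(Fl))
    conv <- conv + filt[Fl - m + 1L] * Xe[(m):(m + full - 1L), , drop = FALSE]
  keep <- seq.int(2L, full, by = 2L)
  conv[keep, , drop = FALSE]
}

.dwtStep <- function(X, filt, boundaryMode) {
  if (boundaryMode == "periodization") .dwtStepPeriodic(X, filt)
  else .dwtStepSymmetric(X, filt)
}

#' Full wavelet-packet decomposition of a signal
#'
#' Builds the complete binary tree of subspaces to the requested depth:
#' every node is split into an approximation and a detail child, giving
#' 2 + 4 + ... + 2^J nodes (30 for the default depth 4). The default
#' wavelet is the order-5 symmlet and the default boundary handling is
#' periodization, under which the transform is orthonormal and the deepest
#' level conserves the signal's energy exactly.
#'
#' @param signal numeric vector; for periodization its length must be a
#'   nonzero multiple of \code{2^depth}.
#' @param wavelet one of \code{"sym5"}, \code{"haar"}, \code{"db4"}.
#' @param depth decomposition depth J >= 1.
#' @param boundaryMode \code{"periodization"} or \code{"symmetric"}.
#' @return A \code{\linkS4class{WPTTree}}.
#' @examples
#' tr <- wptDecompose(sin(2 * pi * 50 * (0:511) / 2000))
#' tr
#' @export
wptDecompose <- function(signal, wavelet = "sym5", depth = 4L,
                         boundaryMode = c("periodization", "symmetric")) {
  boundaryMode <- match.arg(boundaryMode)
  filt <- .getFilters(wavelet)
  depth <- as.integer(depth)
  signal <- as.numeric(signal)
  n <- length(signal)
  if (depth < 1L) stop("depth must be >= 1")
  if (n < 2L^depth)
    stop(sprintf("signal length %d is below 2^depth = %d", n, 2L^depth))
  if (boundaryMode == "periodization" && n %% 2L^depth != 0L)
    stop("periodization requires the signal length to be a multiple of 2^depth")
  nodes <- list()
  level <- list(`0` = matrix(signal, ncol = 1L))
  for (j in seq_len(depth)) {
    nxt <- list()
    for (k in as.integer(names(level))) {
      X <- level[[as.character(k)]]
      a <- .dwtStep(X, filt$lo, boundaryMode)
      d <- .dwtStep(X, filt$hi, boundaryMode)
      nxt[[as.character(2L * k)]] <- a
      nxt[[as.character(2L * k + 1L)]] <- d
      nodes[[paste0(j, ".", 2L * k)]] <- as.numeric(a)
      nodes[[paste0(j, ".", 2L * k + 1L)]] <- as.numeric(d)
    }
    level <- nxt[order(as.integer(names(nxt)))]
  }
  # natural (j, k) order
  ord <- unlist(lapply(seq_len(depth), function(j)
    paste0(j, ".", 0:(2L^j - 1L))))
  new("WPTTree", nodes = nodes[ord], depth = depth, wavelet = wavelet,
      boundaryMode = boundaryMode)
}

#' Log-energy of every wavelet-packet subspace
#'
#' The per-subspace feature: \code{log(sum(coefficients^2) + epsilon)},
#' natural log, in natural (j, k) order: (1,0), (1,1), (2,0), ...,
#' (J, 2^J - 1). The epsilon guards the logarithm at zero energy.
#'
#' @param tree a \code{\linkS4class{WPTTree}}.
#' @param epsilon small positive constant added inside the log.
#' @return Named numeric vector, one entry per subspace (30 for depth 4).
#' @export
subspaceLogEnergy <- function(tree, epsilon = 1e-12) {
  stopifnot(is(tree, "WPTTree"))
  e <- vapply(tree@nodes, function(v) sum(v * v), numeric(1))
  log(e + epsilon)
}

# Batched subspace energies: X is an N x M matrix of M windows from one
# channel; returns a (sum 2^j) x M matrix of per-node coefficient energies
# in natural (j, k) order. Avoids per-window tree bookkeeping in the hot
# path of extractFeatures.
.wptEnergyMatrix <- function(X, wavelet = "sym5", depth = 4L,
                             boundaryMode = "periodization") {
  filt <- .getFilters(wavelet)
  level <- list(X)
  rows <- vector("list", depth)
  for (j in seq_len(depth)) {
    nxt <- vector("list", 2L * length(level))
    for (k in seq_along(level)) {
      nxt[[2L * k - 1L]] <- .dwtStep(level[[k]], filt$lo, boundaryMode)
      nxt[[2L * k]] <- .dwtStep(level[[k]], filt$hi, boundaryMode)
    }
    level <- nxt
    rows[[j]] <- do.call(rbind, lapply(level, function(A)
      colSums(A * A)))
  }
  do.call(rbind, rows)
}
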
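#' GREML estimate of SNP heritability
#'
#' Fits `y = X beta + g + e` with `Var(y) = sigma_g^2 A + sigma_e^2 I`
#' by restricted maximum likelihood, where `A` is a genomic relatedness
#' matrix over (ideally unrelated) individuals. The implementation
#' eigendecomposes the GRM projected onto the covariate-orthogonal
#' subspace, which reduces REML to a one-dimensional profile
#' optimization over `h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)` on
#' `[0, 1]` (golden-section/Brent via [stats::optimize()], refined with
#' a local quadratic step). The total variance is profiled out
#' analytically. The standard error comes from the observed information
#' (numerical second derivative) of the profiled restricted
#' log-likelihood; estimates at the 0 or 1 boundary are flagged.
#'
#' @param y numeric phenotype vector aligned with `grm` ids (NAs are
#'   dropped together with their covariate rows).
#' @param covariates data.frame/matrix of covariates (an intercept is
#'   always added), or NULL for intercept only.
#' @param grm a [GRMatrix-class], typically pruned with
#'   [pruneUnrelated()].
#' @param bounded constrain `h2` to `[0, 1]` (the default); when FALSE
#'   the profile is searched on `[-0.5, 1.5]` for diagnostics.
#' @return a [GremlFit-class].
#' @export
remlH2 <- function(y, covariates = NULL, grm, bounded = TRUE) {
  stopifnot(is(grm, "GRMatrix"))
  n0 <- length(grm@ids)
  stopifnot(length(y) == n0)
  X <- cbind(`(Intercept)` = rep(1, n0))
  if (!is.null(covariates)) {
    Xc <- as.matrix(as.data.frame(covariates))
    storage.mode(Xc) <- "double"
    stopifnot(nrow(Xc) == n0)
    X <- cbind(X, Xc)
  }
  keep <- !is.na(y) & complete.cases(X)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  A <- grm@values[keep, keep, drop = FALSE]
  n <- length(y)
  if (n <= ncol(X) + 2) stop("too few samples for GREML", call. = FALSE)
  if (var(y) <= 0) stop("phenotype has non-positive variance", call. = FALSE)
  qrX <- qr(X)
  p <- qrX$rank
  # orthonormal basis of the covariate-orthogonal subspace
  K <- qr.Q(qrX, complete = TRUE)[, (p + 1):n, drop = FALSE]
  At <- crossprod(K, A %*% K)
  eg <- eigen((At + t(At)) / 2, symmetric = TRUE)
  lambda <- eg$values
  z <- as.vector(crossprod(eg$vectors, crossprod(K, y)))
  if (max(lambda) - min(lambda) < 1e-8)
    stop("variance components confounded: GRM is numerically proportional to the identity",
         call. = FALSE)
  nf <- n - p
  # restricted log-likelihood profiled over total variance
  rll <- function(h) {
    w <- h * lambda + (1 - h)
    if (any(w <= 0)) return(-Inf)
    s2 <- sum(z^2 / w) / nf
    -0.5 * (sum(log(w)) + nf * log(s2) + nf + nf * log(2 * pi))
  }
  lim <- if (bounded) c(0, 1) else c(-0.5, 1.5)
  opt <- optimize(rll, lim, maximum = TRUE, tol = 1e-8)
  h2 <- opt$maximum
  for (end in lim)                     # optimize() never lands exactly on a bound
    if (rll(end) >= opt$objective) { h2 <- end; opt$objective <- rll(end) }
  w <- h2 * lambda + (1 - h2)
  s2 <- sum(z^2 / w) / nf
  boundary <- bounded && (h2 < 1e-6 || h2 > 1 - 1e-6)
  # observed information of the profile restricted log-likelihood
  eps <- 1e-4
  hGrid <- pmin(pmax(h2 + c(-eps, 0, eps), lim[1]), lim[2])
  if (hGrid[1] == hGrid[2]) hGrid <- c(h2, h2 + eps, h2 + 2 * eps)
  if (hGrid[2] == hGrid[3]) hGrid <- c(h2 - 2 * eps, h2 - eps, h2)
  ll3 <- vapply(hGrid, rll, numeric(1))
  d2 <- (ll3[1] - 2 * ll3[2] + ll3[3]) / eps^2
  se <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_
  new("GremlFit", h2 = h2, se = se, sigmaG2 = h2 * s2,
      sigmaE2 = (1 - h2) * s2, loglikRestricted = opt$objective,
      nUsed = n, converged = TRUE, boundary = boundary)
}

#' Restricted log-likelihood profile over h2
#'
#' Evaluates the profiled restricted log-likelihood of the single-GRM
#' model on a grid of heritability values; used to cross-check the
#' optimizer against a brute-force search.
#'
#' @inheritParams remlH2
#' @param grid numeric vector of h2 values in `[0, 1)`.
#' @return data.frame with columns `h2`, `rll`.
#' @export
remlProfile <- function(y, covariates = NULL, grm, grid = seq(0, 0.999, by = 0.001)) {
  stopifnot(is(grm, "GRMatrix"))
  n0 <- length(grm@ids)
  X <- cbind(rep(1, n0))
  if (!is.null(covariates)) X <- cbind(X, as.matrix(as.data.frame(covariates)))
  keep <- !is.na(y) & complete.cases(X)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  A <- grm@values[keep, keep, drop = FALSE]
  n <- length(y)
  qrX <- qr(X); p <- qrX$rank
  K <- qr.Q(qrX, complete = TRUE)[, (p + 1):n, drop = FALSE]
  At <- crossprod(K, A %*% K)
  eg <- eigen((At + t(At)) / 2, symmetric = TRUE)
  lambda <- eg$values
  z <- as.vector(crossprod(eg$vectors, crossprod(K, y)))
  nf <- n - p
  rll <- vapply(grid, function(h) {
    w <- h * lambda + (1 - h)
    if (any(w <= 0)) return(-Inf)
    s2 <- sum(z^2 / w) / nf
    -0.5 * (sum(log(w)) + nf * log(s2) + nf + nf * log(2 * pi))
  }, numeric(1))
  data.frame(h2 = grid, rll = rll)
}
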
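#' Van der Waerden rank-based inverse-normal transformation
#'
#' Maps the value of rank `r` among `n` non-missing observations to the
#' standard-normal quantile `qnorm(r / (n + 1))`. Ties receive average
#' ranks; missing values are excluded from ranking and stay missing.
#'
#' @param y numeric vector, possibly with `NA`.
#' @return numeric vector of normal scores, `NA` where `y` was `NA`.
#' @examples
#' vanDerWaerden(c(1, 2, 3))  # -0.6745, 0, 0.6745
#' @export
vanDerWaerden <- function(y) {
  obs <- !is.na(y)
  n <- sum(obs)
  if (n < 2) stop("need at least 2 non-missing values", call. = FALSE)
  out <- rep(NA_real_, length(y))
  r <- rank(y[obs], ties.method = "average")
  out[obs] <- qnorm(r / (n + 1))
  out
}

#' Residualize a phenotype on covariates
#'
#' Ordinary least-squares residuals of `y` on the covariate columns
#' (an intercept is always included). Rows with missing `y` are carried
#' through as `NA`. Rank-deficient covariate matrices are handled by
#' pivoting; dropped columns are reported in a warning.
#'
#' @param y numeric vector, possibly with `NA`.
#' @param covariates data.frame or matrix of covariates aligned with `y`.
#' @return numeric vector of residuals (mean zero over non-missing rows).
#' @export
residualize <- function(y, covariates) {
  X <- as.matrix(as.data.frame(covariates))
  storage.mode(X) <- "double"
  stopifnot(nrow(X) == length(y))
  obs <- !is.na(y) & complete.cases(X)
  if (sum(obs) < ncol(X) + 1) stop("too few complete rows", call. = FALSE)
  Xo <- cbind(`(Intercept)` = 1, X[obs, , drop = FALSE])
  qrX <- qr(Xo)
  if (qrX$rank < ncol(Xo)) {
    dropped <- colnames(Xo)[qrX$pivot[(qrX$rank + 1):ncol(Xo)]]
    warning("rank-deficient covariates; dropped: ",
            paste(dropped, collapse = ", "))
  }
  out <- rep(NA_real_, length(y))
  out[obs] <- qr.resid(qrX, y[obs])
  out
}

#' Longitudinal composite as the mean of available measurements
#'
#' Per individual, the mean over non-missing age-specific values; the
#' composite is missing only when every measurement is missing (the
#' "at least one measurement non-missing" rule).
#'
#' @param ... two or more aligned numeric vectors (one per age), or a
#'   single matrix/data.frame with one column per age.
#' @return numeric vector of composites.
#' @examples
#' compositeMean(c(2, NA), c(NA, NA), c(4, NA))  # 3, NA
#' @export
compositeMean <- function(...) {
  args <- list(...)
  Y <- if (length(args) == 1 && (is.matrix(args[[1]]) || is.data.frame(args[[1]])))
    as.matrix(args[[1]]) else do.call(cbind, args)
  out <- rowMeans(Y, na.rm = TRUE)
  out[rowSums(!is.na(Y)) == 0] <- NA_real_
  unname(out)
}
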
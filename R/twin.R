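#' Intraclass correlation for twin pairs
#'
#' One-way ANOVA intraclass correlation for pairs (class size 2):
#' `ICC = (MSB - MSW) / (MSB + MSW)`. The standard error uses the
#' Fisher-z large-sample approximation on the double-entry equivalent,
#' `SE = (1 - ICC^2) / sqrt(nPairs - 3)`. The ICC equals the Pearson
#' correlation of the double-entered data when group means are equal.
#'
#' @param y1,y2 phenotypes of co-twin 1 and 2; only complete pairs are
#'   used.
#' @return list with `icc`, `se`, `n` (complete pairs).
#' @export
intraclassCorrelation <- function(y1, y2) {
  ok <- !is.na(y1) & !is.na(y2)
  y1 <- y1[ok]; y2 <- y2[ok]
  n <- length(y1)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  gm <- mean(c(y1, y2))
  pairMean <- (y1 + y2) / 2
  # n-divisor mean squares: makes the ICC identical to the Pearson
  # correlation of the double-entered data when member means are equal
  msb <- 2 * sum((pairMean - gm)^2) / n
  msw <- sum((y1 - pairMean)^2 + (y2 - pairMean)^2) / n
  icc <- (msb - msw) / (msb + msw)
  icc <- max(-1, min(1, icc))
  list(icc = icc, se = (1 - icc^2) / sqrt(n - 3), n = n)
}

#' MZ and DZ twin correlations
#'
#' @param data a [TwinDataset-class].
#' @return a [TwinCorrelations-class].
#' @export
twinCorrelations <- function(data) {
  stopifnot(is(data, "TwinDataset"))
  w <- pairsToWide(data)
  r <- lapply(c(MZ = "MZ", DZ = "DZ"), function(z) {
    s <- w[w$zygosity == z, ]
    intraclassCorrelation(s$y1, s$y2)
  })
  new("TwinCorrelations", rMZ = r$MZ$icc, rDZ = r$DZ$icc,
      seMZ = r$MZ$se, seDZ = r$DZ$se, nMZ = r$MZ$n, nDZ = r$DZ$n)
}

pairsToWide <- function(data) {
  p <- pairsTable(data)
  m1 <- p[p$member == 1, c("family_id", "zygosity", "phenotype")]
  m2 <- p[p$member == 2, c("family_id", "phenotype")]
  w <- merge(m1, m2, by = "family_id", all = TRUE, suffixes = c("1", "2"))
  names(w)[names(w) == "phenotype1"] <- "y1"
  names(w)[names(w) == "phenotype2"] <- "y2"
  zyg <- p[!duplicated(p$family_id), c("family_id", "zygosity")]
  w$zygosity <- zyg$zygosity[match(w$family_id, zyg$family_id)]
  w
}

#' Falconer estimate of variance components from twin correlations
#'
#' Raw estimates: `a2 = 2 (rMZ - rDZ)`, `c2 = 2 rDZ - rMZ`,
#' `e2 = 1 - rMZ`. With `constrain = TRUE`, the shared-environment
#' fraction is clamped at 0, and the heritability is capped at the MZ
#' correlation (a heritability estimate cannot exceed `rMZ`); the
#' residual `e2 = 1 - rMZ` is preserved and `a2 + c2 = rMZ`.
#'
#' @param rMZ,rDZ intraclass correlations in `[-1, 1]`.
#' @param constrain logical; apply the constraint logic.
#' @return named numeric vector `c(a2, c2, e2)`.
#' @examples
#' falconerEstimate(0.80, 0.40)                    # a2 = 0.80
#' falconerEstimate(0.80, 0.20)                    # a2 = 1.20 (raw)
#' falconerEstimate(0.80, 0.20, constrain = TRUE)  # a2 capped at 0.80
#' @export
falconerEstimate <- function(rMZ, rDZ, constrain = FALSE) {
  stopifnot(abs(rMZ) <= 1, abs(rDZ) <= 1)
  a2 <- 2 * (rMZ - rDZ)
  c2 <- 2 * rDZ - rMZ
  e2 <- 1 - rMZ
  if (constrain) {
    a2 <- min(max(a2, 0), rMZ)
    c2 <- rMZ - a2
  }
  c(a2 = a2, c2 = c2, e2 = e2)
}

twinModelMenu <- list(
  ACE = list(comps = c("A", "C", "E"), mz = c(1, 1, 0), dz = c(0.5, 1, 0)),
  ADE = list(comps = c("A", "D", "E"), mz = c(1, 1, 0), dz = c(0.5, 0.25, 0)),
  AE  = list(comps = c("A", "E"),      mz = c(1, 0),    dz = c(0.5, 0)),
  CE  = list(comps = c("C", "E"),      mz = c(1, 0),    dz = c(1, 0)),
  E   = list(comps = "E",              mz = 0,          dz = 0))

#' Fit a twin variance-component model by full-information ML
#'
#' Fits one of the models ACE, ADE, AE, CE or E to MZ/DZ pair data by
#' maximizing the bivariate-normal likelihood with expected cross-twin
#' covariances A+C (MZ) and 0.5A+C (DZ) for ACE, or A+D and
#' 0.5A+0.25D for ADE. Pairs with one missing member contribute their
#' univariate marginal likelihood (full information). Raw variance
#' components are optimized under non-negativity bounds (L-BFGS-B with
#' a Nelder-Mead fallback) and standardized to fractions afterwards;
#' standard errors come from the observed Hessian of the deviance via
#' the delta method, and are reported unchanged (but flagged) when an
#' estimate sits at the zero boundary.
#'
#' Phenotypes are standardized (pooled mean 0, variance 1) before
#' fitting when `standardize = TRUE`, so fractions are directly
#' variance proportions. The residual degrees of freedom are
#' `nObs - k`, where `nObs` counts observed phenotype values and `k`
#' the free parameters (mean plus variance components); `aic` follows
#' the deviance convention `-2LL - 2 df` (see [aicDeviance()]), with
#' the textbook `-2LL + 2k` in `aicTextbook`.
#'
#' @param data a [TwinDataset-class].
#' @param model one of `"ACE"`, `"ADE"`, `"AE"`, `"CE"`, `"E"`.
#' @param standardize standardize phenotypes before fitting.
#' @return a [VarCompFit-class].
#' @examples
#' tw <- simulateTwins(twinSimConfig(300, 300, a2 = 0.6, e2 = 0.4, seed = 7))
#' fitTwinModel(tw, "ACE")
#' @export
fitTwinModel <- function(data, model = c("ACE", "ADE", "AE", "CE", "E"),
                         standardize = TRUE) {
  stopifnot(is(data, "TwinDataset"))
  model <- match.arg(model)
  spec <- twinModelMenu[[model]]
  w <- pairsToWide(data)
  y <- cbind(w$y1, w$y2)
  if (standardize) {
    v <- as.vector(y)
    y <- (y - mean(v, na.rm = TRUE)) / sd(v, na.rm = TRUE)
  }
  grp <- lapply(c(MZ = "MZ", DZ = "DZ"), function(z) {
    yz <- y[w$zygosity == z, , drop = FALSE]
    both <- rowSums(!is.na(yz)) == 2
    one <- rowSums(!is.na(yz)) == 1
    list(pairs = yz[both, , drop = FALSE],
         singles = yz[one, ][!is.na(yz[one, ])])
  })
  nPairsMin <- min(nrow(grp$MZ$pairs), nrow(grp$DZ$pairs))
  if (nPairsMin < 20)
    warning("fewer than 20 complete pairs in a zygosity group; fit may be unstable")
  nComp <- length(spec$comps)
  bivDev <- function(Y, mu, v, cv) {
    d1 <- Y[, 1] - mu; d2 <- Y[, 2] - mu
    det <- v^2 - cv^2
    if (det <= 0 || v <= 0) return(Inf)
    q <- (v * (d1^2 + d2^2) - 2 * cv * d1 * d2) / det
    nrow(Y) * (log(det) + 2 * log(2 * pi)) + sum(q)
  }
  uniDev <- function(yv, mu, v) {
    if (!length(yv)) return(0)
    length(yv) * (log(v) + log(2 * pi)) + sum((yv - mu)^2) / v
  }
  bigDev <- 1e12  # finite penalty keeps finite-difference gradients usable
  dev <- function(par) {
    mu <- par[1]; vc <- par[-1]
    if (any(vc < 0)) return(bigDev)
    v <- sum(vc)
    if (v <= 1e-10) return(bigDev)
    cmz <- sum(spec$mz * vc); cdz <- sum(spec$dz * vc)
    d <- bivDev(grp$MZ$pairs, mu, v, cmz) + bivDev(grp$DZ$pairs, mu, v, cdz) +
      uniDev(grp$MZ$singles, mu, v) + uniDev(grp$DZ$singles, mu, v)
    if (!is.finite(d)) bigDev else d
  }
  # starting values: Falconer on the sample ICCs, floored away from 0
  vtot <- var(as.vector(y), na.rm = TRUE)
  start <- tryCatch({
    tc <- twinCorrelations(data)
    fal <- falconerEstimate(tc@rMZ, tc@rDZ, constrain = TRUE)
    s <- switch(model,
                ACE = c(fal["a2"], fal["c2"], fal["e2"]),
                ADE = c(fal["a2"], 0.1, fal["e2"]),
                AE = c(fal["a2"] + fal["c2"], fal["e2"]),
                CE = c(fal["a2"] / 2 + fal["c2"], 1 - fal["a2"] / 2 - fal["c2"]),
                E = 1)
    pmax(s, 0.05) * vtot
  }, error = function(e) rep(vtot / nComp, nComp))
  par0 <- c(mean(y, na.rm = TRUE), start)
  # a hair above zero keeps the bivariate covariance matrices positive
  # definite at the boundary
  lower <- c(-Inf, rep(1e-8, nComp))
  opt <- optim(par0, dev, method = "L-BFGS-B", lower = lower,
               control = list(maxit = 500, factr = 1e4))
  optNM <- optim(opt$par, dev, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
  if (optNM$value < opt$value - 1e-9) {
    optNM$par <- pmax(optNM$par, lower)
    opt2 <- optim(optNM$par, dev, method = "L-BFGS-B", lower = lower,
                  control = list(maxit = 500, factr = 1e4))
    opt <- if (opt2$value < optNM$value) opt2 else optNM
  }
  converged <- is.finite(opt$value)
  vc <- opt$par[-1]
  vc[vc <= 2e-8] <- 0
  names(vc) <- spec$comps
  vtotHat <- sum(vc)
  frac <- vc / vtotHat
  boundary <- vc < 1e-6
  names(boundary) <- spec$comps
  # delta-method SEs for fractions from the deviance Hessian
  se <- rep(NA_real_, nComp); names(se) <- spec$comps
  H <- tryCatch(optimHess(opt$par, dev), error = function(e) NULL)
  if (!is.null(H)) {
    covPar <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(covPar) && all(is.finite(covPar))) {
      covV <- covPar[-1, -1, drop = FALSE]
      J <- (diag(nComp) * vtotHat - matrix(vc, nComp, nComp)) / vtotHat^2
      covF <- J %*% covV %*% t(J)
      dg <- diag(covF)
      se[dg >= 0] <- sqrt(dg[dg >= 0])
    }
  }
  nObs <- sum(!is.na(y))
  k <- 1 + nComp
  dfres <- nObs - k
  nPairs <- nrow(grp$MZ$pairs) + nrow(grp$DZ$pairs)
  nLL <- nPairs + length(grp$MZ$singles) + length(grp$DZ$singles)
  new("VarCompFit", model = model, estimates = frac, se = se,
      minus2ll = opt$value, df = dfres, aic = aicDeviance(opt$value, dfres),
      aicTextbook = opt$value + 2 * k, nPairs = nPairs, nLL = nLL,
      nObs = nObs, varComponents = vc, mu = opt$par[1], totalVar = vtotHat,
      converged = converged, boundary = boundary)
}

#' Construct twin data with exact summary correlations
#'
#' Generates complete MZ and DZ pairs whose sample means are exactly 0,
#' sample variances exactly 1 and sample intraclass correlations exactly
#' the supplied values (the empirical moments are enforced by
#' whitening). Useful for fitting models to published summary
#' statistics: the ML fit depends on the data only through these
#' moments, so the result is deterministic.
#'
#' @param rMZ,rDZ target sample correlations.
#' @param nMZ,nDZ pair counts.
#' @param seed RNG seed (does not affect the fitted moments).
#' @return a [TwinDataset-class] of complete pairs.
#' @export
twinDataFromSummary <- function(rMZ, nMZ, rDZ, nDZ, seed = 1L) {
  set.seed(seed)
  exactPairs <- function(n, r) {
    Z <- matrix(rnorm(2 * n), n, 2)
    Z <- scale(Z, center = TRUE, scale = FALSE)
    S <- crossprod(Z) / n
    W <- solve(chol(S))
    R <- matrix(c(1, r, r, 1), 2)
    Z %*% W %*% chol(R)
  }
  ymz <- exactPairs(nMZ, rMZ)
  ydz <- exactPairs(nDZ, rDZ)
  long <- function(prefix, y, zyg) {
    n <- nrow(y)
    data.frame(family_id = rep(sprintf("%s%05d", prefix, seq_len(n)), each = 2),
               zygosity = zyg, member = rep(1:2, n),
               phenotype = as.vector(t(y)), stringsAsFactors = FALSE)
  }
  new("TwinDataset", pairs = rbind(long("MZ", ymz, "MZ"), long("DZ", ydz, "DZ")))
}

#' Likelihood-ratio comparison of nested twin models
#'
#' @param full,nested [VarCompFit-class] objects; `nested` must have
#'   more residual degrees of freedom (fewer parameters).
#' @return list with `deltaChi2` (clamped at 0 within numerical noise),
#'   `deltaDf`, `p` and `deltaAic`.
#' @export
compareModels <- function(full, nested) {
  stopifnot(is(full, "VarCompFit"), is(nested, "VarCompFit"))
  deltaDf <- nested@df - full@df
  if (deltaDf <= 0) stop("models are not nested (df must increase)", call. = FALSE)
  deltaChi2 <- nested@minus2ll - full@minus2ll
  if (deltaChi2 < 0) {
    if (deltaChi2 < -1e-4)
      warning("nested model fits better than full by ", -deltaChi2,
              "; clamping LRT statistic to 0")
    deltaChi2 <- 0
  }
  list(deltaChi2 = deltaChi2, deltaDf = deltaDf,
       p = pchisq(deltaChi2, deltaDf, lower.tail = FALSE),
       deltaAic = nested@aic - full@aic)
}

#' Deviance-based AIC
#'
#' `AIC = -2LL - 2 df` with `df` the residual degrees of freedom — the
#' convention under which a model with one fewer parameter and the same
#' deviance scores 2 points lower.
#'
#' @param minus2ll deviance.
#' @param df residual degrees of freedom (>= 0).
#' @return numeric AIC.
#' @examples
#' aicDeviance(15916, 5865)  # 4186
#' @export
aicDeviance <- function(minus2ll, df) {
  stopifnot(df >= 0)
  minus2ll - 2 * df
}
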
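#' Single-SNP additive regression
#'
#' Ordinary least squares of the phenotype on the dosage plus
#' covariates (intercept always included), complete cases only;
#' two-sided p from the t statistic.
#'
#' @param dosage numeric dosage vector in `[0, 2]` (fractional allowed).
#' @param y numeric phenotype.
#' @param covariates optional data.frame/matrix of covariates.
#' @return list with `beta`, `se`, `t`, `p`, `n`.
#' @export
snpRegression <- function(dosage, y, covariates = NULL) {
  X <- cbind(`(Intercept)` = 1, dosage = dosage)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(as.data.frame(covariates)))
  ok <- complete.cases(X) & !is.na(y)
  if (sum(ok) < 10) stop("need at least 10 complete cases", call. = FALSE)
  Xo <- X[ok, , drop = FALSE]; yo <- y[ok]
  if (var(Xo[, "dosage"]) == 0)
    stop("monomorphic dosage: zero variance", call. = FALSE)
  fit <- lm.fit(Xo, yo)
  rdf <- fit$df.residual
  s2 <- sum(fit$residuals^2) / rdf
  XtXinv <- chol2inv(chol(crossprod(Xo)))
  se <- sqrt(s2 * XtXinv[2, 2])
  beta <- fit$coefficients["dosage"]
  tstat <- beta / se
  list(beta = unname(beta), se = se, t = unname(tstat),
       p = 2 * pt(abs(tstat), rdf, lower.tail = FALSE), n = sum(ok))
}

#' Longitudinal equal-effect score test (1 df)
#'
#' Tests, per SNP, the hypothesis that the SNP has an equal additive
#' effect on the phenotype at every measurement age, using a score
#' statistic with a single parameter (1 degree of freedom). Under the
#' null, age-specific nuisance coefficients are estimated from
#' covariates alone (per-age OLS, then a generalized-least-squares
#' refit of the stacked model); the cross-age residual covariance
#' `Sigma` is estimated from pairwise-complete residual cross-products.
#' For individual i with observed-age set s(i) and inverse working
#' covariance `W_i = Sigma[s, s]^{-1}`, the efficient score for a
#' common effect is
#' `U = sum_i g_i 1' W_i r_i`, with variance
#' `V = sum_i g_i^2 1' W_i 1 - C' M^{-1} C`
#' where `C` and `M` are the score/information cross-terms with the
#' age-specific nuisance design. `U^2 / V` is referred to chi-square
#' with 1 df. Individuals with no observed age are dropped; because the
#' null model conditions on the covariates that drive missingness, the
#' test is valid under covariate-dependent missing-at-random outcomes.
#'
#' When `Sigma` is not positive definite the test falls back to an
#' independence working covariance (diagonal `Sigma`) with a warning.
#'
#' @param dosage numeric vector (one SNP) or SNP-by-sample matrix;
#'   missing dosages are mean-imputed per SNP. Monomorphic SNPs are an
#'   error (vector) or get `NA` results with a warning (matrix).
#' @param Y numeric matrix of phenotypes, samples x ages, `NA` for
#'   missing.
#' @param covariates data.frame/matrix of complete covariates
#'   (intercept added automatically).
#' @return data.frame with one row per SNP: `score` (U), `variance`
#'   (V), `stat`, `p`, `nUsed`.
#' @export
longitudinalScoreTest <- function(dosage, Y, covariates = NULL) {
  Y <- as.matrix(Y)
  oneSnp <- is.null(dim(dosage))
  G <- if (oneSnp) matrix(dosage, nrow = 1) else as.matrix(dosage)
  stopifnot(ncol(G) == nrow(Y))
  nAges <- ncol(Y)
  X <- cbind(`(Intercept)` = 1, if (!is.null(covariates))
    as.matrix(as.data.frame(covariates)))
  stopifnot(nrow(X) == nrow(Y))
  if (anyNA(X)) stop("covariates must be complete", call. = FALSE)
  keep <- rowSums(!is.na(Y)) > 0
  Y <- Y[keep, , drop = FALSE]
  X <- X[keep, , drop = FALSE]
  G <- G[, keep, drop = FALSE]
  n <- nrow(Y); p <- ncol(X)
  # stage 1: per-age OLS residuals for the covariance estimate
  R0 <- Y
  for (a in seq_len(nAges)) {
    obs <- !is.na(Y[, a])
    R0[obs, a] <- qr.resid(qr(X[obs, , drop = FALSE]), Y[obs, a])
  }
  Sigma <- cov(R0, use = "pairwise.complete.obs")
  if (anyNA(diag(Sigma)) || any(diag(Sigma) <= 0))
    stop("an age has too few observations to estimate a residual variance",
         call. = FALSE)
  if (anyNA(Sigma)) {
    # age pairs never observed together: no information on their
    # residual covariance, treat them as uncorrelated
    Sigma[is.na(Sigma)] <- 0
  }
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(!is.finite(ev)) || min(ev) <= 1e-10) {
    warning("residual covariance not positive definite; using independence working covariance")
    Sigma <- diag(diag(Sigma), nAges)
  }
  # per-missingness-pattern machinery
  obsM <- !is.na(Y)
  pat <- apply(obsM, 1, function(z) paste(which(z), collapse = ","))
  patLevels <- unique(pat)
  q <- nAges * p
  M <- matrix(0, q, q)
  v <- numeric(q)
  blk <- function(a) ((a - 1) * p + 1):(a * p)
  patInfo <- list()
  for (pl in patLevels) {
    I <- which(pat == pl)
    s <- as.integer(strsplit(pl, ",")[[1]])
    W <- solve(Sigma[s, s, drop = FALSE])
    Xp <- X[I, , drop = FALSE]
    XtX <- crossprod(Xp)
    for (ia in seq_along(s)) for (ib in seq_along(s)) {
      M[blk(s[ia]), blk(s[ib])] <- M[blk(s[ia]), blk(s[ib])] + W[ia, ib] * XtX
      v[blk(s[ia])] <- v[blk(s[ia])] + W[ia, ib] * crossprod(Xp, Y[I, s[ib]])
    }
    patInfo[[pl]] <- list(I = I, s = s, W = W)
  }
  # drop unidentified blocks (an age with no observations)
  act <- which(diag(M) > 0)
  beta <- numeric(q)
  beta[act] <- solve(M[act, act], v[act])
  # GLS null residuals and per-individual score ingredients
  Fit <- matrix(0, n, nAges)
  for (a in seq_len(nAges)) Fit[, a] <- X %*% beta[blk(a)]
  R <- Y - Fit
  aVec <- numeric(n); cVec <- numeric(n)
  Tm <- matrix(0, n, q)
  for (pl in patLevels) {
    pi <- patInfo[[pl]]
    wRow <- rowSums(pi$W)
    aVec[pi$I] <- as.vector(R[pi$I, pi$s, drop = FALSE] %*% wRow)
    cVec[pi$I] <- sum(pi$W)
    for (ia in seq_along(pi$s))
      Tm[pi$I, blk(pi$s[ia])] <- wRow[ia] * X[pi$I, , drop = FALSE]
  }
  # vectorized over SNPs
  gMean <- rowMeans(G, na.rm = TRUE)
  Gc <- G - gMean
  Gc[is.na(Gc)] <- 0
  gVar <- rowSums(Gc^2)
  mono <- gVar <= 0
  if (oneSnp && any(mono))
    stop("monomorphic dosage: zero variance", call. = FALSE)
  if (any(mono)) warning(sum(mono), " monomorphic SNP(s) returned NA")
  U <- as.vector(Gc %*% aVec)
  Cmat <- Gc %*% Tm[, act, drop = FALSE]
  Minv <- solve(M[act, act])
  V <- as.vector(Gc^2 %*% cVec) - rowSums((Cmat %*% Minv) * Cmat)
  stat <- U^2 / V
  stat[mono | V <= 0] <- NA_real_
  data.frame(score = ifelse(mono, NA_real_, U),
             variance = ifelse(mono, NA_real_, V),
             stat = stat,
             p = pchisq(stat, 1, lower.tail = FALSE),
             nUsed = n, row.names = rownames(G))
}

#' Genomic control of 1-df association statistics
#'
#' `lambda = median(stat) / 0.4549364` (the median of chi-square with
#' 1 df); statistics are divided by `max(lambda, 1)` — inflation is
#' corrected, deflation is not — and adjusted p-values recomputed from
#' chi-square 1 df. With a `stratum` factor, lambda is estimated and
#' applied separately within each stratum (e.g. genotyped vs imputed
#' SNPs).
#'
#' @param stats numeric vector of 1-df chi-square statistics.
#' @param stratum optional factor of stratum labels.
#' @return list with `lambda` (named per stratum), `stat` (adjusted),
#'   `p` (adjusted p-values), and `unstable` flagging strata with fewer
#'   than 100 statistics.
#' @export
genomicControl <- function(stats, stratum = NULL) {
  if (is.null(stratum)) stratum <- rep("all", length(stats))
  stratum <- as.factor(stratum)
  chimed <- qchisq(0.5, 1)
  lambda <- tapply(stats, stratum, median, na.rm = TRUE) / chimed
  nPer <- tapply(stats, stratum, function(s) sum(!is.na(s)))
  unstable <- nPer < 100
  if (any(unstable))
    warning("fewer than 100 statistics in stratum(s): ",
            paste(names(lambda)[unstable], collapse = ", "),
            "; lambda is unstable")
  adj <- stats / pmax(lambda[stratum], 1)
  list(lambda = setNames(as.numeric(lambda), names(lambda)),
       stat = as.numeric(adj),
       p = pchisq(as.numeric(adj), 1, lower.tail = FALSE),
       unstable = setNames(as.logical(unstable), names(lambda)))
}

#' Significance tier of a genomic-control-adjusted p-value
#'
#' Genome-wide iff `p < 5e-8`; else suggestive iff `p < 5e-6`; else
#' none. Both inequalities strict.
#'
#' @param p numeric p-values in (0, 1].
#' @param genomewide,suggestive thresholds.
#' @return character vector in `{"none", "suggestive", "genomewide"}`.
#' @export
classifyTier <- function(p, genomewide = 5e-8, suggestive = 5e-6) {
  ifelse(p < genomewide, "genomewide",
         ifelse(p < suggestive, "suggestive", "none"))
}

#' Genome-wide association scan with the longitudinal score test
#'
#' Runs [longitudinalScoreTest()] on every SNP of a panel, determines
#' the risk allele (the allele whose dosage associates with a higher
#' phenotype) and its frequency, applies genomic control within
#' imputation strata, and classifies significance tiers.
#'
#' @param panel a [GenotypePanel-class].
#' @param Y samples x ages phenotype matrix aligned with the panel
#'   columns.
#' @param covariates complete covariates (see
#'   [longitudinalScoreTest()]).
#' @return data.frame with one row per SNP: snp, chrom, pos, imputed,
#'   reference/risk alleles, risk allele frequency, score statistic,
#'   pRaw, lambda stratum, pGC, tier.
#' @export
associationScan <- function(panel, Y, covariates = NULL) {
  stopifnot(is(panel, "GenotypePanel"))
  info <- snpData(panel)
  res <- longitudinalScoreTest(dosages(panel), Y, covariates)
  altFreq <- rowMeans(dosages(panel), na.rm = TRUE) / 2
  altIsRisk <- res$score > 0
  riskAllele <- ifelse(altIsRisk, info$alt, info$ref)
  refAllele <- ifelse(altIsRisk, info$ref, info$alt)
  riskFreq <- ifelse(altIsRisk, altFreq, 1 - altFreq)
  stratum <- factor(info$status,
                    levels = c("genotyped", "imputed_one", "imputed_both"))
  gc <- genomicControl(res$stat, stratum = droplevels(stratum))
  data.frame(snp = info$id, chrom = info$chrom, pos = info$pos,
             imputed = info$status != "genotyped",
             refAllele = refAllele, riskAllele = riskAllele,
             riskFreq = riskFreq, stat = res$stat, pRaw = res$p,
             stratum = as.character(stratum), pGC = gc$p,
             tier = classifyTier(gc$p), stringsAsFactors = FALSE)
}

#' Quantile-quantile plot data with a 95% null band
#'
#' Observed p-values are sorted ascending; the expected quantile of
#' rank i among n is `i / (n + 1)`, and the pointwise 95% band comes
#' from the Beta(i, n + 1 - i) distribution of uniform order
#' statistics. All columns are on the -log10 scale.
#'
#' @param p numeric p-values.
#' @return data.frame with `expected`, `observed`, `bandLow`,
#'   `bandHigh`.
#' @export
qqData <- function(p) {
  p <- sort(p[!is.na(p)])
  n <- length(p)
  if (n < 1) stop("need at least one p-value", call. = FALSE)
  i <- seq_len(n)
  data.frame(expected = -log10(i / (n + 1)),
             observed = -log10(p),
             bandLow = -log10(qbeta(0.975, i, n + 1 - i)),
             bandHigh = -log10(qbeta(0.025, i, n + 1 - i)))
}

#' Manhattan plot data
#'
#' Sorts association records by (chromosome, position) and adds a
#' cumulative genome coordinate for plotting.
#'
#' @param records data.frame with columns `chrom`, `pos`, `pGC` (and
#'   optionally `tier`).
#' @return data.frame sorted by genome position with columns `chrom`,
#'   `pos`, `coord`, `logP`, `tier`.
#' @export
manhattanData <- function(records) {
  if (!nrow(records))
    return(data.frame(chrom = character(), pos = numeric(), coord = numeric(),
                      logP = numeric(), tier = character()))
  ord <- order(records$chrom, records$pos)
  r <- records[ord, , drop = FALSE]
  offsets <- c(0, cumsum(as.numeric(
    tapply(r$pos, factor(r$chrom, levels = unique(r$chrom)), max))))
  names(offsets) <- c(unique(as.character(r$chrom)), "end")
  coord <- r$pos + offsets[as.character(r$chrom)]
  tier <- if ("tier" %in% names(r)) r$tier else classifyTier(r$pGC)
  data.frame(chrom = r$chrom, pos = r$pos, coord = unname(coord),
             logP = -log10(r$pGC), tier = tier,
             row.names = NULL, stringsAsFactors = FALSE)
}
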
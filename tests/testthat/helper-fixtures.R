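# Small programmatic fixtures shared across test files.

# panel with a fixed dosage matrix on one chromosome (so LD pruning
# compares every SNP against every other within the window)
toyPanel <- function(d, maf = NULL, status = "genotyped", info = 1,
                     plate = NULL, chrom = 1L) {
  m <- nrow(d); n <- ncol(d)
  snpInfo <- data.frame(id = sprintf("snp%03d", seq_len(m)), chrom = chrom,
                        pos = seq_len(m) * 1000L,
                        ref = "A", alt = "G",
                        status = rep_len(status, m),
                        info = rep_len(info, m), stringsAsFactors = FALSE)
  sampleInfo <- data.frame(id = sprintf("I%04d", seq_len(n)),
                           plate = if (is.null(plate)) rep_len(1:4, n) else plate,
                           stringsAsFactors = FALSE)
  makeGenotypePanel(d, snpInfo, sampleInfo)
}

# binomial dosage matrix under HWE, SNP x sample
hweDosages <- function(m, n, maf) {
  matrix(rbinom(m * n, 2, rep_len(maf, m)), m, n)
}

# exhaustive minimal-removal count: smallest set of samples whose
# removal leaves no pair with relatedness above the cutoff
minimalRemovalCount <- function(A, cutoff) {
  n <- nrow(A)
  off <- A; diag(off) <- 0
  for (k in 0:n) {
    for (drop in if (k == 0) list(integer(0)) else
         asplit(utils::combn(n, k), 2)) {
      keep <- setdiff(seq_len(n), drop)
      if (all(off[keep, keep] <= cutoff)) return(k)
    }
  }
  n
}

# GLS-free reference for the single-age score test: squared t statistic
squaredT <- function(g, y, covariates) {
  ok <- !is.na(y)
  snpRegression(g[ok], y[ok], covariates[ok, , drop = FALSE])$t^2
}

# null longitudinal phenotypes with covariate-driven MAR missingness
nullLongitudinal <- function(n, rho = 0.5, missingRates = c(0.2, 0.3, 0.6),
                             betaSex = 0.3, betaCohort = 0.1) {
  sex <- rbinom(n, 1, 0.5)
  cohort <- sample(1994:1996, n, TRUE)
  Sigma <- (1 - rho) * diag(3) + rho
  Y <- matrix(rnorm(n * 3), n, 3) %*% chol(Sigma) +
    betaSex * sex + betaCohort * (cohort - 1995)
  for (a in seq_len(3)) {
    r <- missingRates[a]
    if (r > 0) {
      eta <- 0.6 * (sex - mean(sex)) + 0.4 * (cohort - mean(cohort))
      Y[runif(n) < plogis(qlogis(r) + eta), a] <- NA
    }
  }
  list(Y = Y, covariates = data.frame(sex = sex, cohort = cohort))
}

# stacked weighted-least-squares score test for a common SNP effect when
# every individual is observed at a single age and the working
# covariance is diagonal: observations are pooled with weight
# 1/var_age, age-specific nuisance coefficients, one shared slope
stackedWlsScore <- function(g, Y, X) {
  nAges <- ncol(Y)
  rows <- which(!is.na(Y), arr.ind = TRUE)
  y <- Y[rows]
  # per-age residual variances after per-age OLS (the main path uses
  # pairwise-complete covariances; diagonals coincide)
  v <- sapply(seq_len(nAges), function(a) {
    obs <- !is.na(Y[, a])
    var(qr.resid(qr(X[obs, , drop = FALSE]), Y[obs, a]))
  })
  w <- 1 / v[rows[, 2]]
  Xs <- matrix(0, nrow(rows), ncol(X) * nAges)
  for (a in seq_len(nAges)) {
    sel <- rows[, 2] == a
    Xs[sel, ((a - 1) * ncol(X) + 1):(a * ncol(X))] <- X[rows[sel, 1], ]
  }
  gs <- g[rows[, 1]] - mean(g[rows[, 1]])
  sw <- sqrt(w)
  Xw <- Xs * sw; yw <- y * sw; gw <- gs * sw
  beta <- qr.coef(qr(Xw), yw)
  beta[is.na(beta)] <- 0
  r <- yw - Xw %*% beta
  U <- sum(gw * r)
  gproj <- qr.resid(qr(Xw), gw)
  V <- sum(gproj^2)
  U^2 / V
}
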
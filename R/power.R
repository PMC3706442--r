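#' Analytic power to detect a quantitative trait locus
#'
#' Power of a two-sided 1-df additive association test at significance
#' level `alpha` in `n` unrelated individuals for a QTL explaining a
#' fraction `q2` of the phenotypic variance. The noncentrality
#' parameter is `n q2 / (1 - q2)` under the `"ratio"` convention
#' (the regression F/LRT noncentrality) or `n q2` under `"simple"`.
#' Power is the exact noncentral chi-square 1-df tail
#' `P(chi2_1(ncp) > c)` with `c` the central chi-square quantile at
#' `1 - alpha`, equivalently
#' `pnorm(sqrt(ncp) - sqrt(c)) + pnorm(-sqrt(ncp) - sqrt(c))`.
#'
#' @param n sample size (>= 2).
#' @param q2 QTL variance fraction in `[0, 1)`.
#' @param alpha significance threshold in (0, 1].
#' @param ncpConvention `"ratio"` (default) or `"simple"`.
#' @return power in `[0, 1]`.
#' @examples
#' qtlPower(2930, 0.010, 5e-8)  # about 0.49
#' qtlPower(2930, 0.013, 5e-8)  # about 0.77
#' @export
qtlPower <- function(n, q2, alpha, ncpConvention = c("ratio", "simple")) {
  ncpConvention <- match.arg(ncpConvention)
  stopifnot(n >= 2, q2 >= 0, alpha > 0, alpha <= 1)
  if (q2 >= 1) stop("q2 must be below 1", call. = FALSE)
  if (alpha == 1) return(1)
  ncp <- if (ncpConvention == "ratio") n * q2 / (1 - q2) else n * q2
  crit <- qchisq(1 - alpha, 1)
  pchisq(crit, 1, ncp = ncp, lower.tail = FALSE)
}

#' Simulation-based QTL power (cross-check oracle)
#'
#' Simulates `y = beta g + e` with a biallelic dosage `g` and
#' `beta^2 Var(g) = q2`, runs the single-SNP regression, and reports
#' the fraction of replicates with `p < alpha` together with its
#' Monte-Carlo standard error.
#'
#' @inheritParams qtlPower
#' @param reps number of replicates (>= 100).
#' @param maf allele frequency of the simulated QTL.
#' @param seed RNG seed.
#' @return list with `power`, `mcse`, `reps`.
#' @export
qtlPowerSim <- function(n, q2, alpha, reps = 1000L, maf = 0.5, seed = 1L) {
  stopifnot(reps >= 100)
  set.seed(seed)
  beta <- sqrt(q2 / (2 * maf * (1 - maf)))
  hits <- logical(reps)
  for (r in seq_len(reps)) {
    g <- rbinom(n, 2, maf)
    y <- beta * g + rnorm(n, 0, sqrt(1 - q2))
    # fast equivalent of the covariate-free additive regression t-test
    rr <- cor(g, y)
    tstat <- rr * sqrt((n - 2) / (1 - rr^2))
    hits[r] <- 2 * pt(abs(tstat), n - 2, lower.tail = FALSE) < alpha
  }
  pw <- mean(hits)
  list(power = pw, mcse = sqrt(pw * (1 - pw) / reps), reps = reps)
}

#' Power table over a grid of designs
#'
#' @param n,q2,alpha vectors; the full grid is evaluated.
#' @param ncpConvention passed to [qtlPower()].
#' @return data.frame with columns `n`, `q2`, `alpha`, `power`.
#' @export
qtlPowerGrid <- function(n, q2, alpha, ncpConvention = "ratio") {
  g <- expand.grid(n = n, q2 = q2, alpha = alpha)
  g$power <- mapply(qtlPower, g$n, g$q2, g$alpha,
                    MoreArgs = list(ncpConvention = ncpConvention))
  g
}
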
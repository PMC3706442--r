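#' Simulation configurations
#'
#' Validated parameter bundles for the synthetic-data generators.
#'
#' `twinSimConfig()` describes a classical twin design: `a2`, `c2`, `d2`
#' and `e2` are the additive-genetic, shared-environment, dominance and
#' non-shared variance fractions of a standardized liability (they must
#' sum to 1, and at most one of `c2`/`d2` may be nonzero, matching the
#' ACE/ADE model menu).
#'
#' `genoSimConfig()` describes a biallelic dosage panel: ancestral minor
#' allele frequencies are uniform on `mafRange`; with `nSubpops > 1`,
#' subpopulation frequencies follow the Balding-Nichols construction
#' with divergence `fst`; genotypes are Binomial(2, p) (Hardy-Weinberg
#' within subpopulation); entries go missing uniformly at `missingRate`;
#' plates are assigned round-robin across `nPlates`.
#'
#' `phenoSimConfig()` describes longitudinal phenotypes at `ages` with a
#' polygenic score over `nCausal` SNPs explaining `h2snp` of each age's
#' unit variance, equal genetic effect at every age, residual cross-age
#' correlation `crossAgeCorr`, fixed covariate effects `betaSex` /
#' `betaCohort`, and per-age missing-at-random rates driven by sex and
#' cohort only.
#'
#' @param nMZpairs,nDZpairs numbers of monozygotic/dizygotic pairs.
#' @param a2,c2,d2,e2 variance fractions in `[0,1]` summing to 1.
#' @param mean,sd phenotype location and scale after simulation.
#' @param seed integer RNG seed.
#' @param nIndividuals,nSnps panel dimensions.
#' @param mafRange interval within (0, 0.5] for ancestral MAFs.
#' @param nSubpops number of subpopulations (1 = unstructured).
#' @param fst Balding-Nichols divergence in `[0, 1)`; must be 0 when
#'   `nSubpops = 1`.
#' @param missingRate fraction of dosage entries set missing.
#' @param nPlates number of genotyping plates.
#' @param nCausal number of causal SNPs.
#' @param h2snp variance fraction explained by the polygenic score.
#' @param ages age labels (default 7, 9, 12).
#' @param crossAgeCorr residual correlation between ages, in (-1, 1).
#' @param betaSex,betaCohort additive covariate effects on the phenotype.
#' @param missingRates per-age marginal missingness fractions in `[0, 1)`.
#' @return a validated list with class `"TwinSimConfig"`,
#'   `"GenoSimConfig"` or `"PhenoSimConfig"`.
#' @examples
#' cfg <- twinSimConfig(nMZpairs = 100, nDZpairs = 100, a2 = 0.6, e2 = 0.4)
#' @export
twinSimConfig <- function(nMZpairs, nDZpairs, a2 = 0, c2 = 0, d2 = 0, e2 = 1,
                          mean = 0, sd = 1, seed = 1L) {
  fr <- c(a2 = a2, c2 = c2, d2 = d2, e2 = e2)
  if (any(fr < 0 | fr > 1))
    stop("variance fractions must lie in [0, 1]", call. = FALSE)
  if (abs(sum(fr) - 1) > 1e-12)
    stop("a2 + c2 + d2 + e2 must equal 1 (within 1e-12)", call. = FALSE)
  if (c2 > 0 && d2 > 0)
    stop("at most one of c2, d2 may be nonzero (ACE or ADE)", call. = FALSE)
  if (nMZpairs < 1 || nDZpairs < 1) stop("need at least one pair per zygosity")
  structure(list(nMZpairs = as.integer(nMZpairs), nDZpairs = as.integer(nDZpairs),
                 a2 = a2, c2 = c2, d2 = d2, e2 = e2, mean = mean, sd = sd,
                 seed = as.integer(seed)),
            class = "TwinSimConfig")
}

#' @rdname twinSimConfig
#' @export
genoSimConfig <- function(nIndividuals, nSnps, mafRange = c(0.05, 0.5),
                          nSubpops = 1L, fst = 0, missingRate = 0,
                          nPlates = 8L, seed = 1L) {
  if (mafRange[1] <= 0 || mafRange[2] > 0.5 || mafRange[1] > mafRange[2])
    stop("mafRange must be an interval within (0, 0.5]", call. = FALSE)
  if (nSubpops == 1 && fst != 0)
    stop("fst must be 0 when nSubpops = 1", call. = FALSE)
  if (fst < 0 || fst >= 1) stop("fst must lie in [0, 1)", call. = FALSE)
  if (missingRate < 0 || missingRate >= 1) stop("missingRate must lie in [0, 1)")
  structure(list(nIndividuals = as.integer(nIndividuals), nSnps = as.integer(nSnps),
                 mafRange = mafRange, nSubpops = as.integer(nSubpops), fst = fst,
                 missingRate = missingRate, nPlates = as.integer(nPlates),
                 seed = as.integer(seed)),
            class = "GenoSimConfig")
}

#' @rdname twinSimConfig
#' @export
phenoSimConfig <- function(nCausal, h2snp, ages = c(7, 9, 12),
                           crossAgeCorr = 0.5, betaSex = 0, betaCohort = 0,
                           missingRates = c(0, 0, 0), seed = 1L) {
  if (h2snp < 0 || h2snp > 1) stop("h2snp must lie in [0, 1]", call. = FALSE)
  if (abs(crossAgeCorr) >= 1) stop("crossAgeCorr must lie in (-1, 1)", call. = FALSE)
  if (any(missingRates < 0 | missingRates >= 1))
    stop("missingRates must lie in [0, 1)", call. = FALSE)
  if (length(missingRates) != length(ages))
    stop("missingRates must match ages in length", call. = FALSE)
  structure(list(nCausal = as.integer(nCausal), h2snp = h2snp, ages = ages,
                 crossAgeCorr = crossAgeCorr, betaSex = betaSex,
                 betaCohort = betaCohort, missingRates = missingRates,
                 seed = as.integer(seed)),
            class = "PhenoSimConfig")
}

#' Simulate a classical twin sample
#'
#' Draws pair phenotypes from the Gaussian liability model
#' `y = sqrt(a2) A + sqrt(c2) C + sqrt(d2) D + sqrt(e2) E`, where the
#' additive factor A is shared with correlation 1 (MZ) / 0.5 (DZ), the
#' dominance factor D with 1 (MZ) / 0.25 (DZ), the shared environment C
#' with 1 in both zygosities and E is independent across co-twins.
#' Expected intraclass correlations are therefore
#' `a2 + c2 + d2` (MZ) and `0.5 a2 + c2 + 0.25 d2` (DZ).
#'
#' @param config a [twinSimConfig()].
#' @return a [TwinDataset-class].
#' @examples
#' tw <- simulateTwins(twinSimConfig(200, 200, a2 = 0.64, e2 = 0.36))
#' twinCorrelations(tw)
#' @export
simulateTwins <- function(config) {
  stopifnot(inherits(config, "TwinSimConfig"))
  set.seed(config$seed)
  onePair <- function(n, rA, rD) {
    # shared + individual decomposition gives a factor with the target
    # cross-twin correlation and unit variance
    bivn <- function(r) {
      common <- rnorm(n)
      cbind(sqrt(r) * common + sqrt(1 - r) * rnorm(n),
            sqrt(r) * common + sqrt(1 - r) * rnorm(n))
    }
    A <- bivn(rA); D <- bivn(rD)
    C <- rnorm(n); C <- cbind(C, C)
    E <- cbind(rnorm(n), rnorm(n))
    y <- sqrt(config$a2) * A + sqrt(config$c2) * C +
      sqrt(config$d2) * D + sqrt(config$e2) * E
    config$mean + config$sd * y
  }
  ymz <- onePair(config$nMZpairs, 1, 1)
  ydz <- onePair(config$nDZpairs, 0.5, 0.25)
  fam <- function(prefix, y) {
    n <- nrow(y)
    data.frame(family_id = rep(sprintf("%s%05d", prefix, seq_len(n)), each = 2),
               zygosity = if (prefix == "MZ") "MZ" else "DZ",
               member = rep(1:2, n),
               phenotype = as.vector(t(y)),
               stringsAsFactors = FALSE)
  }
  new("TwinDataset", pairs = rbind(fam("MZ", ymz), fam("DZ", ydz)))
}

#' Simulate a biallelic dosage panel
#'
#' Per SNP, an ancestral frequency is drawn uniformly from
#' `config$mafRange`; with several subpopulations, each subpopulation
#' frequency follows the Balding-Nichols Beta distribution
#' `Beta(p (1-fst)/fst, (1-p)(1-fst)/fst)`; genotypes are
#' `Binomial(2, p_subpop)`, so Hardy-Weinberg holds within
#' subpopulation. Missing entries are set uniformly at random; plates
#' are assigned round-robin. Genotyped SNPs carry an info score of 1.
#'
#' @param config a [genoSimConfig()].
#' @return a [GenotypePanel-class] with a `subpop` column in its sample
#'   metadata.
#' @export
simulateGenotypes <- function(config) {
  stopifnot(inherits(config, "GenoSimConfig"))
  set.seed(config$seed)
  n <- config$nIndividuals; m <- config$nSnps
  p0 <- runif(m, config$mafRange[1], config$mafRange[2])
  subpop <- rep_len(seq_len(config$nSubpops), n)
  if (config$nSubpops > 1 && config$fst > 0) {
    shape <- (1 - config$fst) / config$fst
    psub <- vapply(seq_len(config$nSubpops),
                   function(k) rbeta(m, p0 * shape, (1 - p0) * shape),
                   numeric(m))
    psub <- pmin(pmax(psub, 1e-6), 1 - 1e-6)
  } else {
    psub <- matrix(p0, m, config$nSubpops)
  }
  dos <- matrix(NA_real_, m, n)
  for (k in seq_len(config$nSubpops)) {
    idx <- which(subpop == k)
    dos[, idx] <- matrix(rbinom(m * length(idx), 2, rep(psub[, k], length(idx))),
                         m, length(idx))
  }
  if (config$missingRate > 0)
    dos[runif(m * n) < config$missingRate] <- NA_real_
  ids <- sprintf("S%05d", seq_len(n))
  snps <- sprintf("rs%06d", seq_len(m))
  alleles <- matrix(sample(c("A", "C", "G", "T"), 2 * m, replace = TRUE), m, 2)
  same <- alleles[, 1] == alleles[, 2]
  alleles[same, 2] <- ifelse(alleles[same, 1] == "A", "G", "A")
  # positions spread over 22 autosomes, sorted within chromosome
  chrom <- sort(rep_len(seq_len(min(22L, m)), m))
  pos <- unlist(lapply(split(seq_len(m), chrom),
                       function(ix) sort(sample.int(2e8, length(ix)))),
                use.names = FALSE)
  makeGenotypePanel(dosage = dos,
                    snpInfo = data.frame(id = snps, chrom = chrom, pos = pos,
                                         ref = alleles[, 1], alt = alleles[, 2],
                                         status = "genotyped", info = 1,
                                         genFreq = p0,
                                         stringsAsFactors = FALSE),
                    sampleInfo = data.frame(id = ids,
                                            plate = rep_len(seq_len(config$nPlates), n),
                                            subpop = subpop,
                                            stringsAsFactors = FALSE))
}

#' Construct a GenotypePanel from components
#'
#' @param dosage numeric SNP-by-sample matrix, values in `[0, 2]` or `NA`.
#' @param snpInfo data.frame with columns `id`, `chrom`, `pos`, `ref`,
#'   `alt`, `status`, `info`.
#' @param sampleInfo data.frame with columns `id`, `plate` (and any
#'   extra covariates).
#' @return a [GenotypePanel-class].
#' @export
makeGenotypePanel <- function(dosage, snpInfo, sampleInfo) {
  stopifnot(nrow(dosage) == nrow(snpInfo), ncol(dosage) == nrow(sampleInfo))
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(snpInfo$chrom),
    ranges = IRanges::IRanges(start = snpInfo$pos, width = 1L))
  names(gr) <- snpInfo$id
  meta <- snpInfo[, setdiff(colnames(snpInfo), c("id", "chrom", "pos")), drop = FALSE]
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(meta)
  cd <- S4Vectors::DataFrame(sampleInfo[, setdiff(colnames(sampleInfo), "id"),
                                        drop = FALSE])
  rownames(cd) <- sampleInfo$id
  dimnames(dosage) <- list(snpInfo$id, sampleInfo$id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage), rowRanges = gr, colData = cd)
  new("GenotypePanel", se)
}

#' Simulate longitudinal phenotypes on a genotype panel
#'
#' Builds a polygenic score `g = Z beta` over `nCausal` standardized
#' SNPs (`beta ~ N(0, h2snp/nCausal)`), rescaled so its sample variance
#' is exactly `h2snp`; the same score enters every age. Age-specific
#' residuals are multivariate normal with exchangeable correlation
#' `crossAgeCorr` and variance `1 - h2snp`, so each age has unit
#' phenotypic variance and per-age SNP heritability `h2snp` before the
#' fixed covariate effects (`betaSex`, `betaCohort`) are added.
#' Missingness is missing-at-random: each age's indicator follows a
#' logistic model in sex and (centered) cohort with the intercept set to
#' the requested marginal rate.
#'
#' @param panel a [GenotypePanel-class].
#' @param config a [phenoSimConfig()].
#' @return data.frame with columns `id`, `sex` (0/1), `cohort`
#'   (1994-1996), `plate`, one `y<age>` column per age, and `g` (the
#'   true polygenic score, for diagnostics).
#' @export
simulateLongitudinalPhenotypes <- function(panel, config) {
  stopifnot(is(panel, "GenotypePanel"), inherits(config, "PhenoSimConfig"))
  if (config$nCausal > nrow(panel))
    stop("nCausal exceeds the number of SNPs in the panel", call. = FALSE)
  set.seed(config$seed)
  n <- ncol(panel)
  nAges <- length(config$ages)
  if (config$h2snp > 0 && config$nCausal > 0) {
    causal <- sort(sample.int(nrow(panel), config$nCausal))
    Z <- standardizedDosages(panel)[causal, , drop = FALSE]
    beta <- rnorm(config$nCausal, 0, sqrt(config$h2snp / config$nCausal))
    g <- as.vector(crossprod(Z, beta))
    g <- (g - mean(g)) / sd(g) * sqrt(config$h2snp)
  } else {
    g <- numeric(n)
  }
  rho <- config$crossAgeCorr
  Sigma <- (1 - config$h2snp) * ((1 - rho) * diag(nAges) + rho)
  L <- chol(Sigma)
  E <- matrix(rnorm(n * nAges), n, nAges) %*% L
  sex <- rbinom(n, 1, 0.5)
  cohort <- sample(c(1994, 1995, 1996), n, replace = TRUE)
  Y <- g + E + config$betaSex * sex + config$betaCohort * (cohort - 1995)
  for (a in seq_len(nAges)) {
    rate <- config$missingRates[a]
    if (rate > 0) {
      eta <- 0.6 * (sex - mean(sex)) + 0.4 * (cohort - mean(cohort))
      miss <- runif(n) < plogis(qlogis(rate) + eta)
      Y[miss, a] <- NA_real_
    }
  }
  out <- data.frame(id = colnames(panel), sex = sex, cohort = cohort,
                    plate = sampleData(panel)$plate, stringsAsFactors = FALSE)
  for (a in seq_len(nAges)) out[[paste0("y", config$ages[a])]] <- Y[, a]
  out$g <- g
  out
}

#' Standardize a dosage matrix by sample allele frequencies
#'
#' Missing entries are mean-imputed (i.e. set to zero after centering);
#' each SNP is centered at `2 p` and scaled by `sqrt(2 p (1 - p))` with
#' `p` the sample allele frequency. Monomorphic SNPs get all-zero rows.
#'
#' @param panel a [GenotypePanel-class] or dosage matrix.
#' @return numeric matrix of the same dimension.
#' @export
standardizedDosages <- function(panel) {
  d <- if (is(panel, "GenotypePanel")) dosages(panel) else panel
  p <- rowMeans(d, na.rm = TRUE) / 2
  sdv <- sqrt(2 * p * (1 - p))
  Z <- (d - 2 * p) / ifelse(sdv > 0, sdv, Inf)
  Z[is.na(Z)] <- 0
  Z
}
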
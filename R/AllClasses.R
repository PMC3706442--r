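#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData rowRanges colData
#' @importFrom S4Vectors DataFrame mcols
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom IRanges IRanges
#' @importFrom stats pchisq qchisq pnorm qnorm rnorm rbinom runif rbeta
#'   median cor cov var sd lm lm.fit coef resid anova pf pt qbeta optim
#'   optimHess optimize complete.cases setNames plogis qlogis quantile
#' @importFrom utils read.table write.table head tail packageVersion
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' GenotypePanel: dosage genotypes with SNP and sample metadata
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding a SNP-by-sample
#' dosage matrix (assay `"dosage"`, values in `[0, 2]` or `NA`), SNP
#' metadata as `rowRanges` (chromosome, 1-based position, `ref`/`alt`
#' alleles, imputation `status`, `info` score) and sample metadata as
#' `colData` (at least a `plate` label).
#'
#' The `status` column takes values `"genotyped"`, `"imputed_one"` (typed
#' on one of two arrays and imputed on the other) or `"imputed_both"`
#' (imputed throughout); quality-control rules treat the three tiers
#' differently (see [snpFilter()]).
#'
#' @slot \ldots see [SummarizedExperiment::RangedSummarizedExperiment].
#' @seealso [makeGenotypePanel()], [simulateGenotypes()], [dosages()]
#' @export
setClass("GenotypePanel", contains = "RangedSummarizedExperiment")

setValidity("GenotypePanel", function(object) {
  msg <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    rng <- suppressWarnings(range(d, na.rm = TRUE))
    if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
      msg <- c(msg, "dosages must lie in [0, 2]")
  }
  rd <- SummarizedExperiment::rowData(object)
  for (col in c("ref", "alt", "status", "info"))
    if (!col %in% colnames(rd)) msg <- c(msg, sprintf("rowData column '%s' missing", col))
  if ("status" %in% colnames(rd) &&
      !all(rd$status %in% c("genotyped", "imputed_one", "imputed_both")))
    msg <- c(msg, "status must be genotyped/imputed_one/imputed_both")
  if (!"plate" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData column 'plate' missing")
  if (length(msg)) msg else TRUE
})

#' TwinDataset: family-structured phenotypes for MZ/DZ pairs
#'
#' Wraps a long-format table with columns `family_id`, `zygosity`
#' (`"MZ"`/`"DZ"`), `member` (1 or 2) and `phenotype` (possibly `NA`;
#' pairs with one missing member still contribute their observed member
#' to full-information likelihoods).
#'
#' @slot pairs data.frame in the long format above.
#' @seealso [simulateTwins()], [fitTwinModel()], [intraclassCorrelation()]
#' @export
setClass("TwinDataset", representation(pairs = "data.frame"))

setValidity("TwinDataset", function(object) {
  p <- object@pairs
  need <- c("family_id", "zygosity", "member", "phenotype")
  if (!all(need %in% colnames(p)))
    return(sprintf("pairs must have columns %s", paste(need, collapse = ", ")))
  if (!all(p$zygosity %in% c("MZ", "DZ"))) return("zygosity must be MZ or DZ")
  if (!all(p$member %in% c(1L, 2L))) return("member must be 1 or 2")
  if (anyDuplicated(p[, c("family_id", "member")]))
    return("duplicate (family_id, member) rows")
  TRUE
})

#' GRMatrix: genomic relatedness matrix with per-pair SNP counts
#'
#' Symmetric sample-by-sample relatedness estimated from standardized
#' dosages (GCTA semantics: off-diagonal averages
#' \eqn{(x_j-2p)(x_k-2p)/(2p(1-p))} over SNPs non-missing in both
#' samples; the diagonal uses the bias-adjusted estimator).
#'
#' @slot values symmetric numeric matrix.
#' @slot nsnp matrix of per-pair SNP counts used.
#' @slot ids sample identifiers.
#' @slot callRate optional per-sample genotype call rate (used to break
#'   ties when pruning related samples).
#' @seealso [computeGRM()], [pruneUnrelated()], [remlH2()]
#' @export
setClass("GRMatrix", representation(values = "matrix", nsnp = "matrix",
                                    ids = "character", callRate = "numeric"))

setValidity("GRMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("values must be square")
  if (length(object@ids) != nrow(v)) return("ids length must match dimension")
  if (max(abs(v - t(v))) > 1e-12) return("values must be symmetric within 1e-12")
  if (!all(dim(object@nsnp) == dim(v))) return("nsnp must match values dimension")
  if (length(object@callRate) && length(object@callRate) != nrow(v))
    return("callRate length must match dimension")
  TRUE
})

#' TwinCorrelations: MZ/DZ intraclass correlations with standard errors
#'
#' @slot rMZ,rDZ intraclass correlations by zygosity.
#' @slot seMZ,seDZ approximate standard errors.
#' @slot nMZ,nDZ complete-pair counts.
#' @seealso [twinCorrelations()], [falconerEstimate()]
#' @export
setClass("TwinCorrelations",
         representation(rMZ = "numeric", rDZ = "numeric", seMZ = "numeric",
                        seDZ = "numeric", nMZ = "numeric", nDZ = "numeric"))

#' VarCompFit: twin variance-component maximum-likelihood fit
#'
#' Standardized variance fractions for one of the models ACE, ADE, AE,
#' CE or E, with standard errors (delta method from the observed
#' Hessian), the deviance (-2 log-likelihood), residual degrees of
#' freedom (observed phenotype values minus free parameters) and two AIC
#' conventions: `aic = -2LL - 2 df` (the convention of the source
#' tables) and `aicTextbook = -2LL + 2 k` with `k` free parameters.
#'
#' @slot model one of "ACE","ADE","AE","CE","E".
#' @slot estimates named fractions (sum to 1).
#' @slot se named standard errors (NA when the Hessian is not usable).
#' @slot minus2ll,df,aic,aicTextbook fit statistics.
#' @slot nPairs complete pairs; @slot nLL families contributing to the
#'   likelihood (complete pairs plus singletons).
#' @slot nObs number of observed phenotype values.
#' @slot varComponents raw (unstandardized) variance components.
#' @slot mu,totalVar fitted mean and total variance.
#' @slot converged,boundary optimizer status and boundary flags.
#' @seealso [fitTwinModel()], [compareModels()]
#' @export
setClass("VarCompFit",
         representation(model = "character", estimates = "numeric", se = "numeric",
                        minus2ll = "numeric", df = "numeric", aic = "numeric",
                        aicTextbook = "numeric", nPairs = "numeric", nLL = "numeric",
                        nObs = "numeric", varComponents = "numeric", mu = "numeric",
                        totalVar = "numeric", converged = "logical",
                        boundary = "logical"))

#' GremlFit: GREML estimate of SNP heritability
#'
#' @slot h2 proportion of phenotypic variance tagged by the SNPs.
#' @slot se standard error from the observed information of the profiled
#'   restricted likelihood.
#' @slot sigmaG2,sigmaE2 variance components.
#' @slot loglikRestricted restricted log-likelihood at the optimum.
#' @slot nUsed samples analyzed; @slot converged,boundary status flags.
#' @seealso [remlH2()]
#' @export
setClass("GremlFit",
         representation(h2 = "numeric", se = "numeric", sigmaG2 = "numeric",
                        sigmaE2 = "numeric", loglikRestricted = "numeric",
                        nUsed = "numeric", converged = "logical",
                        boundary = "logical"))

#' QCReport: outcome of a quality-control pass
#'
#' Per-item status with the first failing rule as the primary reason;
#' rule counts sum to the number of exclusions.
#'
#' @slot table data.frame with columns `id`, `status` ("pass"/"fail"),
#'   `reason` (NA for passes).
#' @slot counts named integer vector of exclusions per rule.
#' @slot nTotal items examined; @slot fractionRemoved share excluded.
#' @seealso [snpFilter()], [sampleFilter()]
#' @export
setClass("QCReport",
         representation(table = "data.frame", counts = "integer",
                        nTotal = "integer", fractionRemoved = "numeric"))

setValidity("QCReport", function(object) {
  if (sum(object@counts) != sum(object@table$status == "fail"))
    return("rule counts must sum to total exclusions")
  TRUE
})
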
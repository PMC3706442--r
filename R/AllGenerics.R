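#' Accessors for genarch classes
#'
#' `dosages()` returns the SNP-by-sample dosage matrix of a
#' [GenotypePanel-class]; `snpData()` its per-SNP metadata (id, chrom,
#' pos, ref, alt, status, info) as a data.frame; `sampleData()` its
#' per-sample metadata. `pairsTable()` returns the long-format table of
#' a [TwinDataset-class]. `grmValues()`, `grmNsnp()` and `grmIds()`
#' access a [GRMatrix-class].
#'
#' @param x an object of the corresponding class.
#' @return matrix, data.frame or character vector as described.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname accessors
#' @export
setMethod("dosages", "GenotypePanel", function(x)
  SummarizedExperiment::assay(x, "dosage"))

#' @rdname accessors
#' @export
setGeneric("snpData", function(x) standardGeneric("snpData"))

#' @rdname accessors
#' @export
setMethod("snpData", "GenotypePanel", function(x) {
  gr <- SummarizedExperiment::rowRanges(x)
  data.frame(id = names(gr),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             pos = GenomicRanges::start(gr),
             as.data.frame(S4Vectors::mcols(gr)),
             row.names = NULL, stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname accessors
#' @export
setMethod("sampleData", "GenotypePanel", function(x) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  data.frame(id = colnames(x), cd, row.names = NULL, stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setGeneric("pairsTable", function(x) standardGeneric("pairsTable"))

#' @rdname accessors
#' @export
setMethod("pairsTable", "TwinDataset", function(x) x@pairs)

#' @rdname accessors
#' @export
setGeneric("grmValues", function(x) standardGeneric("grmValues"))

#' @rdname accessors
#' @export
setMethod("grmValues", "GRMatrix", function(x) {
  v <- x@values
  dimnames(v) <- list(x@ids, x@ids)
  v
})

#' @rdname accessors
#' @export
setGeneric("grmNsnp", function(x) standardGeneric("grmNsnp"))

#' @rdname accessors
#' @export
setMethod("grmNsnp", "GRMatrix", function(x) x@nsnp)

#' @rdname accessors
#' @export
setGeneric("grmIds", function(x) standardGeneric("grmIds"))

#' @rdname accessors
#' @export
setMethod("grmIds", "GRMatrix", function(x) x@ids)

#' Extract variance-component estimates
#'
#' @param object a [VarCompFit-class] or [GremlFit-class].
#' @return named numeric vector of standardized variance fractions (or
#'   `c(h2 = ...)` for a GREML fit).
#' @export
setGeneric("varEstimates", function(object) standardGeneric("varEstimates"))

#' @rdname varEstimates
#' @export
setMethod("varEstimates", "VarCompFit", function(object) object@estimates)

#' @rdname varEstimates
#' @export
setMethod("varEstimates", "GremlFit", function(object) c(h2 = object@h2))

setMethod("show", "GenotypePanel", function(object) {
  cat(sprintf("GenotypePanel: %d SNPs x %d samples\n", nrow(object), ncol(object)))
  st <- table(SummarizedExperiment::rowData(object)$status)
  cat("  status:", paste(sprintf("%s=%d", names(st), st), collapse = ", "), "\n")
  miss <- mean(is.na(SummarizedExperiment::assay(object, "dosage")))
  cat(sprintf("  missing dosage fraction: %.4f\n", miss))
})

setMethod("show", "TwinDataset", function(object) {
  p <- object@pairs
  nfam <- tapply(p$family_id, p$zygosity, function(f) length(unique(f)))
  cat(sprintf("TwinDataset: %s MZ and %s DZ families, %d phenotype values\n",
              nfam[["MZ"]], nfam[["DZ"]], sum(!is.na(p$phenotype))))
})

setMethod("show", "GRMatrix", function(object) {
  n <- length(object@ids)
  off <- object@values[upper.tri(object@values)]
  cat(sprintf("GRMatrix: %d samples; mean diag %.4f; off-diag range [%.4f, %.4f]\n",
              n, mean(diag(object@values)), min(off), max(off)))
})

setMethod("show", "TwinCorrelations", function(object) {
  cat(sprintf("Twin intraclass correlations:\n  rMZ = %.3f (SE %.3f), n = %d\n  rDZ = %.3f (SE %.3f), n = %d\n",
              object@rMZ, object@seMZ, object@nMZ,
              object@rDZ, object@seDZ, object@nDZ))
})

setMethod("show", "VarCompFit", function(object) {
  cat(sprintf("%s model (FIML)\n", object@model))
  est <- object@estimates
  se <- object@se
  for (nm in names(est))
    cat(sprintf("  %s = %.3f (SE %s)%s\n", nm, est[nm],
                ifelse(is.na(se[nm]), "NA", sprintf("%.3f", se[nm])),
                if (isTRUE(object@boundary[nm])) " [boundary]" else ""))
  cat(sprintf("  -2LL = %.2f, df = %d, AIC = %.2f\n",
              object@minus2ll, as.integer(object@df), object@aic))
})

setMethod("show", "GremlFit", function(object) {
  cat(sprintf("GREML fit: h2_SNP = %.3f (SE %.3f), n = %d%s\n",
              object@h2, object@se, as.integer(object@nUsed),
              if (object@boundary) " [boundary]" else ""))
  cat(sprintf("  sigma_g2 = %.4f, sigma_e2 = %.4f, restricted logLik = %.3f\n",
              object@sigmaG2, object@sigmaE2, object@loglikRestricted))
})

setMethod("show", "QCReport", function(object) {
  cat(sprintf("QCReport: %d/%d removed (%.1f%%)\n",
              sum(object@counts), object@nTotal, 100 * object@fractionRemoved))
  if (sum(object@counts))
    for (nm in names(object@counts))
      if (object@counts[nm] > 0) cat(sprintf("  %s: %d\n", nm, object@counts[nm]))
})

#' @rdname accessors
#' @export
setGeneric("qcTable", function(x) standardGeneric("qcTable"))

#' @rdname accessors
#' @export
setMethod("qcTable", "QCReport", function(x) x@table)

#' @rdname accessors
#' @export
setGeneric("qcCounts", function(x) standardGeneric("qcCounts"))

#' @rdname accessors
#' @export
setMethod("qcCounts", "QCReport", function(x) x@counts)
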
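#' SNP and sample quality-control thresholds
#'
#' Defaults follow the standard array-QC recipe: genotyped SNPs fail
#' when info < 0.975, minor allele frequency < 1%, missingness > 2%,
#' Hardy-Weinberg p < 1e-20 or plate-effect p < 1e-6 (all strict
#' inequalities); imputed SNPs instead pass a tiered info rule
#' (>= 0.90 when typed on the second array, >= 0.98 when imputed
#' throughout). Samples fail on call rate, heterozygosity outliers, or
#' relatedness above 5% (the related member with the lower call rate is
#' removed, iteratively).
#'
#' @param infoMin,mafMin,missingMax,hwePMin,platePMin,imputedInfoMin,array2InfoMin
#'   SNP-level thresholds.
#' @param callRateMin,hetZMax,ibdMax sample-level thresholds.
#' @return named list of thresholds.
#' @export
snpQCThresholds <- function(infoMin = 0.975, mafMin = 0.01, missingMax = 0.02,
                            hwePMin = 1e-20, platePMin = 1e-6,
                            imputedInfoMin = 0.98, array2InfoMin = 0.90) {
  t <- list(infoMin = infoMin, mafMin = mafMin, missingMax = missingMax,
            hwePMin = hwePMin, platePMin = platePMin,
            imputedInfoMin = imputedInfoMin, array2InfoMin = array2InfoMin)
  if (any(unlist(t) <= 0 | unlist(t) > 1))
    stop("thresholds must lie in (0, 1]", call. = FALSE)
  t
}

#' @rdname snpQCThresholds
#' @export
sampleQCThresholds <- function(callRateMin = 0.97, hetZMax = 3, ibdMax = 0.05) {
  stopifnot(callRateMin > 0, callRateMin <= 1, ibdMax > 0, ibdMax < 1)
  list(callRateMin = callRateMin, hetZMax = hetZMax, ibdMax = ibdMax)
}

#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' Pearson 1-df chi-square against expected counts at the estimated
#' allele frequency; `exact = TRUE` switches to the exact conditional
#' test (sum of probabilities of heterozygote counts no more likely
#' than the observed one). Monomorphic SNPs return p = 1 with a flag.
#'
#' @param nAA,nAa,naa genotype counts.
#' @param exact use the exact test instead of the chi-square.
#' @return list with `p`, `chisq` (NA for exact), `monomorphic`.
#' @examples
#' hweTest(50, 20, 30)  # chisq = 34.03, p ~ 5.4e-9
#' @export
hweTest <- function(nAA, nAa, naa, exact = FALSE) {
  n <- nAA + nAa + naa
  if (n <= 0) stop("empty genotype counts", call. = FALSE)
  nA <- 2 * nAA + nAa
  if (nA == 0 || nA == 2 * n)
    return(list(p = 1, chisq = 0, monomorphic = TRUE))
  if (exact) {
    # conditional distribution of heterozygote count given allele counts
    nMin <- min(nA, 2 * n - nA)
    het <- seq(nMin %% 2, nMin, by = 2)
    logp <- lgamma(n + 1) - lgamma((nA - het) / 2 + 1) - lgamma(het + 1) -
      lgamma((2 * n - nA - het) / 2 + 1) + het * log(2) +
      lgamma(nA + 1) + lgamma(2 * n - nA + 1) - lgamma(2 * n + 1)
    pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
    pObs <- pr[match(nAa, het)]
    return(list(p = min(1, sum(pr[pr <= pObs + 1e-12])), chisq = NA_real_,
                monomorphic = FALSE))
  }
  p <- nA / (2 * n)
  expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chisq <- sum((c(nAA, nAa, naa) - expd)^2 / expd)
  list(p = pchisq(chisq, 1, lower.tail = FALSE), chisq = chisq,
       monomorphic = FALSE)
}

#' SNP-level quality control
#'
#' Applies, in fixed order, the info-score rule (tiered by imputation
#' status), minor-allele-frequency, missingness, Hardy-Weinberg and
#' plate-effect filters; the first failing rule is recorded as the
#' primary reason. Boundary semantics are strict: a SNP fails iff
#' info < threshold, MAF < threshold, missingness > threshold,
#' HWE p < threshold, plate p < threshold. The Hardy-Weinberg test uses
#' rounded dosages as genotype counts; the plate effect is a one-way
#' ANOVA F-test of dosage on plate label.
#'
#' @param panel a [GenotypePanel-class].
#' @param thresholds a [snpQCThresholds()] list.
#' @param plateTest apply the plate-effect filter (requires plate labels).
#' @return a [QCReport-class] over SNPs.
#' @export
snpFilter <- function(panel, thresholds = snpQCThresholds(), plateTest = TRUE) {
  stopifnot(is(panel, "GenotypePanel"))
  t <- thresholds
  d <- dosages(panel)
  info <- snpData(panel)
  m <- nrow(d)
  reason <- rep(NA_character_, m)
  infoMinBy <- c(genotyped = t$infoMin, imputed_one = t$array2InfoMin,
                 imputed_both = t$imputedInfoMin)
  failInfo <- info$info < infoMinBy[info$status]
  p <- rowMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  missFrac <- rowMeans(is.na(d))
  reason[is.na(reason) & failInfo] <- "info"
  reason[is.na(reason) & maf < t$mafMin] <- "maf"
  reason[is.na(reason) & missFrac > t$missingMax] <- "missing"
  todo <- which(is.na(reason))
  g <- round(d[todo, , drop = FALSE])
  hweP <- vapply(seq_along(todo), function(i) {
    gi <- g[i, ]
    hweTest(sum(gi == 2, na.rm = TRUE), sum(gi == 1, na.rm = TRUE),
            sum(gi == 0, na.rm = TRUE))$p
  }, numeric(1))
  reason[todo[hweP < t$hwePMin]] <- "hwe"
  if (plateTest) {
    plate <- factor(sampleData(panel)$plate)
    if (nlevels(plate) > 1) {
      todo <- which(is.na(reason))
      plateP <- vapply(todo, function(i) {
        anovaFp(d[i, ], plate)
      }, numeric(1))
      reason[todo[plateP < t$platePMin]] <- "plate"
    }
  }
  newQCReport(info$id, reason, c("info", "maf", "missing", "hwe", "plate"))
}

# one-way ANOVA F-test p-value of y on a factor, NA-tolerant
anovaFp <- function(y, f) {
  ok <- !is.na(y)
  y <- y[ok]; f <- droplevels(f[ok])
  k <- nlevels(f); n <- length(y)
  if (k < 2 || n <= k) return(1)
  gm <- mean(y)
  gmeans <- tapply(y, f, mean)
  gn <- tabulate(f)
  ssb <- sum(gn * (gmeans - gm)^2)
  ssw <- sum((y - gmeans[f])^2)
  if (ssw <= 0) return(if (ssb > 0) 0 else 1)
  Fstat <- (ssb / (k - 1)) / (ssw / (n - k))
  pf(Fstat, k - 1, n - k, lower.tail = FALSE)
}

newQCReport <- function(ids, reason, ruleNames) {
  counts <- vapply(ruleNames, function(r) sum(reason == r, na.rm = TRUE), integer(1))
  tab <- data.frame(id = ids, status = ifelse(is.na(reason), "pass", "fail"),
                    reason = reason, stringsAsFactors = FALSE)
  new("QCReport", table = tab, counts = counts, nTotal = length(ids),
      fractionRemoved = mean(!is.na(reason)))
}

#' Sample-level quality control
#'
#' Excludes samples with genotype call rate below `callRateMin` or with
#' a heterozygosity z-score beyond `hetZMax` standard deviations of the
#' sample distribution; then iteratively removes, from each remaining
#' pair with relatedness above `ibdMax`, the member with the lower call
#' rate (ties broken by sample id order, the later id being removed),
#' until no pair exceeds the threshold.
#'
#' @param panel a [GenotypePanel-class].
#' @param thresholds a [sampleQCThresholds()] list.
#' @param grm a [GRMatrix-class] aligned with the panel samples (its
#'   off-diagonals are the relatedness proxy).
#' @return a [QCReport-class] over samples.
#' @export
sampleFilter <- function(panel, thresholds = sampleQCThresholds(), grm = NULL) {
  stopifnot(is(panel, "GenotypePanel"))
  t <- thresholds
  d <- dosages(panel)
  ids <- colnames(d)
  callRate <- 1 - colMeans(is.na(d))
  g <- round(d)
  het <- colMeans(g == 1, na.rm = TRUE)
  hetZ <- if (sd(het) > 0) (het - mean(het)) / sd(het) else rep(0, length(het))
  reason <- rep(NA_character_, length(ids))
  reason[callRate < t$callRateMin] <- "call_rate"
  reason[is.na(reason) & abs(hetZ) > t$hetZMax] <- "heterozygosity"
  if (!is.null(grm)) {
    stopifnot(is(grm, "GRMatrix"))
    keep <- which(is.na(reason))
    A <- grmValues(grm)[ids[keep], ids[keep], drop = FALSE]
    cr <- callRate[keep]
    alive <- rep(TRUE, length(keep))
    repeat {
      Av <- A; Av[!alive, ] <- 0; Av[, !alive] <- 0; diag(Av) <- 0
      off <- which(Av > t$ibdMax, arr.ind = TRUE)
      if (!nrow(off)) break
      pairIdx <- off[off[, 1] < off[, 2], , drop = FALSE]
      # remove the lower-call-rate member of the worst pair; on a tie,
      # the id that sorts later
      pr <- pairIdx[1, ]
      drop <- if (cr[pr[1]] < cr[pr[2]]) pr[1]
      else if (cr[pr[2]] < cr[pr[1]]) pr[2]
      else max(pr)
      alive[drop] <- FALSE
    }
    reason[keep[!alive]] <- "relatedness"
  }
  newQCReport(ids, reason, c("call_rate", "heterozygosity", "relatedness"))
}

#' Greedy LD pruning
#'
#' Left-to-right scan within each chromosome: a SNP is dropped when the
#' squared Pearson correlation of its dosages with any retained SNP
#' within `window` retained positions exceeds `r2Max`; no retained pair
#' inside the window exceeds `r2Max`. Zero-variance SNPs are skipped
#' with a warning.
#'
#' @param panel a [GenotypePanel-class].
#' @param r2Max squared-correlation threshold (default 0.2).
#' @param window window size in numbers of retained SNPs.
#' @return character vector of kept SNP ids.
#' @export
ldPrune <- function(panel, r2Max = 0.2, window = 50L) {
  stopifnot(is(panel, "GenotypePanel"))
  d <- dosages(panel)
  info <- snpData(panel)
  ord <- order(info$chrom, info$pos)
  keptAll <- character(0)
  nZeroVar <- 0L
  for (chr in unique(info$chrom[ord])) {
    idx <- ord[info$chrom[ord] == chr]
    keptIdx <- integer(0)
    for (i in idx) {
      x <- d[i, ]
      if (sd(x, na.rm = TRUE) == 0 || all(is.na(x))) {
        nZeroVar <- nZeroVar + 1L
        next
      }
      cand <- tail(keptIdx, window)
      drop <- FALSE
      for (j in cand) {
        r <- suppressWarnings(cor(x, d[j, ], use = "pairwise.complete.obs"))
        if (!is.na(r) && r^2 > r2Max) { drop <- TRUE; break }
      }
      if (!drop) keptIdx <- c(keptIdx, i)
    }
    keptAll <- c(keptAll, info$id[keptIdx])
  }
  if (nZeroVar > 0)
    warning(nZeroVar, " zero-variance SNP(s) skipped during LD pruning")
  keptAll
}

#' Principal components of a genotype panel
#'
#' Dosages are mean-imputed and standardized as
#' `(x - 2p) / sqrt(2 p (1 - p))`, then the top-`k` left singular
#' vectors of the sample-by-SNP matrix are returned together with the
#' eigenvalues of the sample covariance across SNPs (singular values
#' squared over the number of SNPs).
#'
#' @param panel a [GenotypePanel-class] (ideally LD-pruned).
#' @param k number of components; must be < number of samples.
#' @return list with `scores` (n x k), `eigenvalues` (all available),
#'   `ids`.
#' @export
panelPCA <- function(panel, k = 8L) {
  stopifnot(is(panel, "GenotypePanel"))
  n <- ncol(panel)
  if (k > n - 1) stop("k must be smaller than the number of samples", call. = FALSE)
  Z <- t(standardizedDosages(panel))      # samples x SNPs
  Z <- scale(Z, center = TRUE, scale = FALSE)
  sv <- svd(Z, nu = k, nv = 0)
  eig <- sv$d^2 / ncol(Z)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  rownames(scores) <- colnames(panel)
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores, eigenvalues = eig, ids = colnames(panel))
}

twCritical <- c("0.05" = 0.9793, "0.01" = 2.0234, "0.001" = 3.2724)

#' Count ancestry components by the Tracy-Widom test
#'
#' Sequential test of the leading eigenvalue against the Tracy-Widom
#' (TW1) distribution using tabulated critical values (0.9793 at
#' alpha = 0.05), with the effective-marker correction of the
#' eigenanalysis literature: for the remaining spectrum of length `m'`,
#' the effective marker count is
#' `n' = ((m'+1) S1^2) / ((m'-1) S2 - S1^2)` with `S1, S2` the first
#' two power sums, and the normalized leading eigenvalue
#' `l = m' lambda_1 / S1` is centered and scaled by the
#' Tracy-Widom mean and standard deviation for an `m' x n'` Wishart.
#' Testing stops at the first non-significant eigenvalue.
#'
#' @param eigenvalues sorted (descending) eigenvalues of the sample
#'   covariance, e.g. from [panelPCA()].
#' @param alpha one of 0.05, 0.01, 0.001.
#' @return integer count of significant components.
#' @export
tracyWidomCount <- function(eigenvalues, alpha = 0.05) {
  key <- format(alpha, trim = TRUE)
  if (!key %in% names(twCritical))
    stop("alpha must be one of 0.05, 0.01, 0.001", call. = FALSE)
  crit <- twCritical[[key]]
  ev <- eigenvalues[eigenvalues > 1e-12]
  if (length(ev) < 3) return(0L)
  count <- 0L
  while (length(ev) >= 3) {
    mp <- length(ev)
    S1 <- sum(ev); S2 <- sum(ev^2)
    denom <- (mp - 1) * S2 - S1^2
    if (denom <= 0) break
    neff <- (mp + 1) * S1^2 / denom
    l <- mp * ev[1] / S1
    mu <- (sqrt(neff - 1) + sqrt(mp))^2 / neff
    sig <- ((sqrt(neff - 1) + sqrt(mp)) / neff) *
      (1 / sqrt(neff - 1) + 1 / sqrt(mp))^(1 / 3)
    x <- (l - mu) / sig
    if (x <= crit) break
    count <- count + 1L
    ev <- ev[-1]
  }
  count
}

#' Drop items flagged by a QC report
#'
#' @param panel a [GenotypePanel-class].
#' @param snpReport,sampleReport [QCReport-class] objects from
#'   [snpFilter()] / [sampleFilter()] (either may be NULL).
#' @return the subset [GenotypePanel-class].
#' @export
applyQC <- function(panel, snpReport = NULL, sampleReport = NULL) {
  keepSnp <- if (is.null(snpReport)) rep(TRUE, nrow(panel))
  else qcTable(snpReport)$status == "pass"
  keepSample <- if (is.null(sampleReport)) rep(TRUE, ncol(panel))
  else qcTable(sampleReport)$status == "pass"
  panel[keepSnp, keepSample]
}
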
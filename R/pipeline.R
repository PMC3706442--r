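#' Default pipeline configuration
#'
#' Returns the full configuration list with every stage enabled and
#' thresholds at their standard values (QC: info 0.975 / MAF 0.01 /
#' missingness 0.02 / HWE 1e-20 / plate 1e-6; relatedness cutoff 0.025;
#' LD r2 0.2; significance tiers 5e-8 / 5e-6). Override any entry by
#' passing a partial list (or YAML file) to [runPipeline()].
#'
#' @param outDir output directory.
#' @param seed master seed; stage seeds are derived from it.
#' @return nested configuration list.
#' @export
pipelineConfig <- function(outDir = "genarch_run", seed = 1L) {
  list(
    seed = as.integer(seed),
    outDir = outDir,
    stages = list(simulate = TRUE, qc = TRUE, transform = TRUE, twin = TRUE,
                  greml = TRUE, gwas = TRUE, power = TRUE),
    simulate = list(
      twins = list(nMZpairs = 1099L, nDZpairs = 1787L, a2 = 0.64, c2 = 0,
                   d2 = 0, e2 = 0.36),
      genotypes = list(nIndividuals = 1000L, nSnps = 20000L,
                       mafRange = c(0.05, 0.5), nSubpops = 1L, fst = 0,
                       missingRate = 0.002, nPlates = 8L),
      phenotypes = list(nCausal = 1000L, h2snp = 0.2, crossAgeCorr = 0.5,
                        betaSex = 0.1, betaCohort = 0.05,
                        missingRates = c(0.2, 0.3, 0.6))),
    qc = list(snp = snpQCThresholds(), sample = sampleQCThresholds(),
              ldPruneR2 = 0.2, ldPruneWindow = 50L, nPCs = 8L,
              twAlpha = 0.05),
    greml = list(relatednessCutoff = 0.025),
    gwas = list(genomewide = 5e-8, suggestive = 5e-6),
    power = list(n = 2930L, q2 = c(0.010, 0.013), alpha = 5e-8)
  )
}

mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the enabled stages in dependency order — simulate
#' (twins, genotypes, longitudinal phenotypes), QC (SNP and sample
#' filters, LD pruning, PCA with Tracy-Widom component count),
#' transforms (van der Waerden per age, composite, residualization),
#' twin model fits (ACE/AE comparison), GRM + GREML, the longitudinal
#' genome-wide scan with genomic control, and the power table — and
#' writes every report table plus a JSON run manifest (seed,
#' thresholds, per-filter counts) under `config$outDir`.
#'
#' Reruns with the same configuration and seed are deterministic.
#'
#' @param config a [pipelineConfig()] list, a partial override list, or
#'   the path of a YAML file with such a list.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- mergeConfig(pipelineConfig(), config)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = as.character(packageVersion("genarch")),
                   seed = cfg$seed, timestamp = format(Sys.time()),
                   thresholds = cfg$qc$snp, stages = list())
  out <- list()
  seedOf <- function(k) cfg$seed + k

  if (isTRUE(cfg$stages$simulate)) {
    tw <- do.call(twinSimConfig, c(cfg$simulate$twins, seed = seedOf(1)))
    out$twins <- simulateTwins(tw)
    gcfg <- do.call(genoSimConfig, c(cfg$simulate$genotypes, seed = seedOf(2)))
    out$panel <- simulateGenotypes(gcfg)
    pcfg <- do.call(phenoSimConfig, c(cfg$simulate$phenotypes, seed = seedOf(3)))
    out$phenotypes <- simulateLongitudinalPhenotypes(out$panel, pcfg)
    writeTwinTSV(out$twins, file.path(cfg$outDir, "twins.tsv"))
    writePhenotypeTSV(out$phenotypes, file.path(cfg$outDir, "phenotypes.tsv"))
    manifest$stages$simulate <- list(nMZpairs = tw$nMZpairs,
                                     nDZpairs = tw$nDZpairs,
                                     nSnps = gcfg$nSnps,
                                     nIndividuals = gcfg$nIndividuals)
  }
  if (is.null(out$panel)) stop("dependency error: stage 'qc' requires genotypes from stage 'simulate'",
                               call. = FALSE)

  if (isTRUE(cfg$stages$qc)) {
    snpRep <- snpFilter(out$panel, cfg$qc$snp)
    grmAll <- computeGRM(out$panel)
    sampleRep <- sampleFilter(out$panel, cfg$qc$sample, grm = grmAll)
    out$panelQC <- applyQC(out$panel, snpRep, sampleRep)
    write.table(qcTable(snpRep), file.path(cfg$outDir, "qc_snps.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(qcTable(sampleRep), file.path(cfg$outDir, "qc_samples.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    kept <- ldPrune(out$panelQC, cfg$qc$ldPruneR2, cfg$qc$ldPruneWindow)
    prunedPanel <- out$panelQC[snpData(out$panelQC)$id %in% kept, ]
    pca <- panelPCA(prunedPanel, k = cfg$qc$nPCs)
    out$nSignificantPCs <- tracyWidomCount(pca$eigenvalues, cfg$qc$twAlpha)
    out$pcs <- pca$scores
    write.table(data.frame(id = rownames(pca$scores), pca$scores),
                file.path(cfg$outDir, "pca.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    manifest$stages$qc <- list(snpCounts = as.list(qcCounts(snpRep)),
                               sampleCounts = as.list(qcCounts(sampleRep)),
                               snpFractionRemoved = snpRep@fractionRemoved,
                               ldKept = length(kept),
                               significantPCs = out$nSignificantPCs)
  } else {
    out$panelQC <- out$panel
    out$pcs <- NULL
  }

  if (isTRUE(cfg$stages$transform)) {
    ph <- out$phenotypes
    ids <- colnames(out$panelQC)
    ph <- ph[match(ids, ph$id), ]
    ageCols <- grep("^y[0-9]+$", names(ph), value = TRUE)
    Ynorm <- vapply(ageCols, function(cl) vanDerWaerden(ph[[cl]]),
                    numeric(nrow(ph)))
    out$Y <- Ynorm
    comp <- compositeMean(Ynorm)
    out$composite <- residualize(comp, ph[, c("sex", "cohort")])
    out$phenoAligned <- ph
    manifest$stages$transform <- list(nComposite = sum(!is.na(out$composite)))
  }

  if (isTRUE(cfg$stages$twin)) {
    fits <- list(ACE = fitTwinModel(out$twins, "ACE"),
                 AE = fitTwinModel(out$twins, "AE"))
    cmp <- compareModels(fits$ACE, fits$AE)
    tc <- twinCorrelations(out$twins)
    out$twinFits <- fits; out$twinComparison <- cmp; out$twinCorr <- tc
    tab <- do.call(rbind, lapply(names(fits), function(nm) {
      f <- fits[[nm]]
      est <- c(A = NA, C = NA, E = NA)
      se <- est
      est[names(f@estimates)] <- f@estimates
      se[names(f@se)] <- f@se
      data.frame(model = nm, A = est["A"], seA = se["A"], C = est["C"],
                 seC = se["C"], E = est["E"], seE = se["E"],
                 minus2LL = f@minus2ll, df = f@df, AIC = f@aic)
    }))
    tab$rMZ <- tc@rMZ; tab$rDZ <- tc@rDZ
    write.table(tab, file.path(cfg$outDir, "twin_models.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    manifest$stages$twin <- list(deltaChi2 = cmp$deltaChi2, p = cmp$p)
  }

  if (isTRUE(cfg$stages$greml)) {
    grm <- computeGRM(out$panelQC)
    keepIds <- pruneUnrelated(grm, cfg$greml$relatednessCutoff)
    grmU <- subsetGRM(grm, keepIds)
    idx <- match(keepIds, colnames(out$panelQC))
    cov <- data.frame(sex = out$phenoAligned$sex[idx],
                      cohort = out$phenoAligned$cohort[idx])
    if (!is.null(out$pcs))
      cov <- cbind(cov, out$pcs[match(keepIds, rownames(out$pcs)), ,
                                drop = FALSE])
    fit <- remlH2(out$composite[idx], cov, grmU)
    out$greml <- fit
    writeGRM(grmU, file.path(cfg$outDir, "study"))
    write.table(data.frame(h2 = fit@h2, se = fit@se, sigmaG2 = fit@sigmaG2,
                           sigmaE2 = fit@sigmaE2,
                           logLik = fit@loglikRestricted, n = fit@nUsed),
                file.path(cfg$outDir, "greml.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    manifest$stages$greml <- list(h2 = fit@h2, se = fit@se,
                                  nUnrelated = length(keepIds))
  }

  if (isTRUE(cfg$stages$gwas)) {
    cov <- data.frame(sex = out$phenoAligned$sex,
                      cohort = out$phenoAligned$cohort)
    if (!is.null(out$pcs)) cov <- cbind(cov, out$pcs)
    scan <- associationScan(out$panelQC, out$Y, cov)
    out$gwas <- scan
    gcLambda <- genomicControl(scan$stat,
                               droplevels(factor(scan$stratum)))$lambda
    write.table(scan, file.path(cfg$outDir, "gwas.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write.table(qqData(scan$pGC), file.path(cfg$outDir, "qq.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(manhattanData(scan), file.path(cfg$outDir, "manhattan.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    manifest$stages$gwas <- list(lambda = as.list(gcLambda),
                                 nGenomewide = sum(scan$tier == "genomewide",
                                                   na.rm = TRUE),
                                 nSuggestive = sum(scan$tier == "suggestive",
                                                   na.rm = TRUE))
  }

  if (isTRUE(cfg$stages$power)) {
    ptab <- qtlPowerGrid(cfg$power$n, cfg$power$q2, cfg$power$alpha)
    out$power <- ptab
    write.table(ptab, file.path(cfg$outDir, "power.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    manifest$stages$power <- list(power = ptab$power)
  }

  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out$manifest <- manifest
  invisible(out)
}
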
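#' Read and write genotype, phenotype and twin tables
#'
#' Plain-text interchange formats:
#' * dosage-matrix TSV: one row per SNP with metadata columns
#'   (`id`, `chrom`, `pos`, `ref`, `alt`, `status`, `info`) followed by
#'   one column per sample (values 0-2 or NA);
#' * phenotype TSV: `id`, `sex` (0/1), `cohort`, `plate`, `y7`, `y9`,
#'   `y12` (missing written as `NA`);
#' * twin TSV: `family_id`, `zygosity` (MZ/DZ), `member` (1/2),
#'   `phenotype`;
#' * VCF 4.2 with a per-genotype dosage (`DS`) FORMAT field and
#'   `ST`/`IF` INFO keys carrying imputation status and info score,
#'   positions 1-based and sorted by (chrom, pos).
#'
#' All writers round-trip losslessly through the matching readers.
#'
#' @param panel a [GenotypePanel-class].
#' @param path file path.
#' @param sampleInfo optional sample table (id, plate, ...) used when
#'   reading a dosage TSV or VCF back into a panel; defaults to
#'   plate 1 for everyone.
#' @name panel-io
NULL

#' @rdname panel-io
#' @export
writeDosageTSV <- function(panel, path) {
  stopifnot(is(panel, "GenotypePanel"))
  info <- snpData(panel)
  d <- dosages(panel)
  out <- cbind(info[, c("id", "chrom", "pos", "ref", "alt", "status", "info")],
               as.data.frame(d, check.names = FALSE))
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname panel-io
#' @export
readDosageTSV <- function(path, sampleInfo = NULL) {
  tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  meta <- c("id", "chrom", "pos", "ref", "alt", "status", "info")
  stopifnot(all(meta %in% colnames(tab)))
  sampleIds <- setdiff(colnames(tab), meta)
  d <- as.matrix(tab[, sampleIds, drop = FALSE])
  storage.mode(d) <- "double"
  if (is.null(sampleInfo))
    sampleInfo <- data.frame(id = sampleIds, plate = 1L,
                             stringsAsFactors = FALSE)
  stopifnot(identical(sampleInfo$id, sampleIds))
  makeGenotypePanel(d, tab[, meta], sampleInfo)
}

#' @rdname panel-io
#' @export
writeVCF <- function(panel, path) {
  stopifnot(is(panel, "GenotypePanel"))
  info <- snpData(panel)
  d <- dosages(panel)
  ord <- order(info$chrom, info$pos)
  info <- info[ord, ]; d <- d[ord, , drop = FALSE]
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=ST,Number=1,Type=String,Description=\"Imputation status\">",
           "##INFO=<ID=IF,Number=1,Type=Float,Description=\"Info score\">",
           "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of the ALT allele\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(d)), collapse = "\t"))
  body <- vapply(seq_len(nrow(d)), function(i) {
    ds <- ifelse(is.na(d[i, ]), ".", sprintf("%.6g", d[i, ]))
    paste(c(info$chrom[i], info$pos[i], info$id[i], info$ref[i], info$alt[i],
            ".", "PASS",
            sprintf("ST=%s;IF=%.6g", info$status[i], info$info[i]),
            "DS", ds), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname panel-io
#' @export
readVCF <- function(path, sampleInfo = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  infoStr <- vcfR::getINFO(v)
  status <- sub(".*ST=([^;]+).*", "\\1", infoStr)
  infoScore <- suppressWarnings(as.numeric(sub(".*IF=([^;]+).*", "\\1", infoStr)))
  infoScore[is.na(infoScore)] <- 1
  status[!status %in% c("genotyped", "imputed_one", "imputed_both")] <- "genotyped"
  snpInfo <- data.frame(id = fix$ID, chrom = fix$CHROM,
                        pos = as.integer(fix$POS), ref = fix$REF,
                        alt = fix$ALT, status = status, info = infoScore,
                        stringsAsFactors = FALSE)
  if (is.null(sampleInfo))
    sampleInfo <- data.frame(id = colnames(ds), plate = 1L,
                             stringsAsFactors = FALSE)
  stopifnot(identical(sampleInfo$id, colnames(ds)))
  makeGenotypePanel(ds, snpInfo, sampleInfo)
}

#' @rdname panel-io
#' @param phenotypes phenotype table as produced by
#'   [simulateLongitudinalPhenotypes()].
#' @export
writePhenotypeTSV <- function(phenotypes, path) {
  cols <- intersect(c("id", "sex", "cohort", "plate",
                      grep("^y", names(phenotypes), value = TRUE)),
                    names(phenotypes))
  write.table(phenotypes[, cols], path, sep = "\t", row.names = FALSE,
              quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname panel-io
#' @export
readPhenotypeTSV <- function(path) {
  read.table(path, sep = "\t", header = TRUE, na.strings = "NA",
             stringsAsFactors = FALSE)
}

#' @rdname panel-io
#' @param twins a [TwinDataset-class].
#' @export
writeTwinTSV <- function(twins, path) {
  stopifnot(is(twins, "TwinDataset"))
  write.table(pairsTable(twins), path, sep = "\t", row.names = FALSE,
              quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname panel-io
#' @export
readTwinTSV <- function(path) {
  new("TwinDataset", pairs = read.table(path, sep = "\t", header = TRUE,
                                        na.strings = "NA",
                                        stringsAsFactors = FALSE))
}

#' Write a full simulated study to disk
#'
#' Emits the genotype panel (dosage TSV or VCF), the phenotype table
#' and, when given, the twin table; sample ids are checked for
#' consistency across tables.
#'
#' @param panel a [GenotypePanel-class].
#' @param phenotypes phenotype table aligned with the panel.
#' @param dir output directory (created if needed).
#' @param format `"tsv"` or `"vcf"` for the genotypes.
#' @param twins optional [TwinDataset-class].
#' @return named character vector of file paths.
#' @export
writePanel <- function(panel, phenotypes, dir, format = c("tsv", "vcf"),
                       twins = NULL) {
  format <- match.arg(format)
  if (!setequal(phenotypes$id, colnames(panel)))
    stop("sample ids differ between panel and phenotype table", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genotypes = file.path(dir, paste0("genotypes.",
                                               if (format == "vcf") "vcf" else "tsv")),
             phenotypes = file.path(dir, "phenotypes.tsv"))
  if (format == "vcf") writeVCF(panel, paths["genotypes"])
  else writeDosageTSV(panel, paths["genotypes"])
  writePhenotypeTSV(phenotypes, paths["phenotypes"])
  if (!is.null(twins)) {
    paths["twins"] <- file.path(dir, "twins.tsv")
    writeTwinTSV(twins, paths["twins"])
  }
  paths
}
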
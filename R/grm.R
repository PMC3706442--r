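#' Compute a genomic relatedness matrix
#'
#' GCTA-style estimator with allele frequencies taken from the analyzed
#' sample. For samples j, k and SNPs i with sample allele frequency
#' `p_i`:
#' off-diagonal `A_jk = (1/m_jk) sum_i (x_ij - 2p_i)(x_ik - 2p_i) / (2 p_i (1-p_i))`
#' over SNPs non-missing in both samples, and the bias-adjusted diagonal
#' `A_jj = 1 + (1/m_j) sum_i (x_ij^2 - (1 + 2p_i) x_ij + 2 p_i^2) / (2 p_i (1-p_i))`.
#' Monomorphic SNPs are skipped; missing dosages are handled by
#' per-pair SNP counts (pairwise complete).
#'
#' @param panel a [GenotypePanel-class] or dosage matrix (SNP x sample).
#' @return a [GRMatrix-class].
#' @export
computeGRM <- function(panel) {
  d <- if (is(panel, "GenotypePanel")) dosages(panel) else panel
  if (ncol(d) < 2) stop("need at least 2 samples", call. = FALSE)
  p <- rowMeans(d, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1 & !is.na(p)
  if (!any(poly)) stop("all SNPs are monomorphic", call. = FALSE)
  d <- d[poly, , drop = FALSE]
  p <- p[poly]
  w <- 2 * p * (1 - p)
  obs <- !is.na(d)
  Zc <- (d - 2 * p) / sqrt(w)
  Zc[!obs] <- 0
  A <- crossprod(Zc)
  N <- crossprod(obs * 1)
  vals <- A / N
  # adjusted diagonal
  x <- d; x[!obs] <- 0
  diagNum <- colSums(((x^2 - (1 + 2 * p) * x + 2 * p^2) / w) * obs)
  mj <- colSums(obs)
  diag(vals) <- 1 + diagNum / mj
  vals <- (vals + t(vals)) / 2
  ids <- colnames(d)
  if (is.null(ids)) ids <- sprintf("S%05d", seq_len(ncol(d)))
  callRate <- colMeans(obs)
  new("GRMatrix", values = unname(vals), nsnp = unname(N), ids = ids,
      callRate = unname(callRate))
}

#' Prune a sample set to unrelated individuals
#'
#' Iteratively removes the individual participating in the most pairs
#' with relatedness above `cutoff` (ties broken by lower call rate,
#' then by sample id order, the later id being removed) until no
#' off-diagonal exceeds the cutoff. The default cutoff 0.025 excludes
#' anyone closer than a fourth-degree relative.
#'
#' @param grm a [GRMatrix-class].
#' @param cutoff relatedness threshold (default 0.025).
#' @return character vector of retained sample ids.
#' @export
pruneUnrelated <- function(grm, cutoff = 0.025) {
  stopifnot(is(grm, "GRMatrix"))
  A <- grm@values
  n <- nrow(A)
  alive <- rep(TRUE, n)
  cr <- if (length(grm@callRate)) grm@callRate else rep(1, n)
  off <- A; diag(off) <- 0
  repeat {
    M <- off > cutoff
    M[!alive, ] <- FALSE; M[, !alive] <- FALSE
    deg <- rowSums(M)
    if (all(deg == 0)) break
    worst <- which(deg == max(deg))
    if (length(worst) > 1) {
      worst <- worst[cr[worst] == min(cr[worst])]
      if (length(worst) > 1)
        worst <- worst[order(grm@ids[worst], decreasing = TRUE)[1]]
    }
    alive[worst] <- FALSE
  }
  grm@ids[alive]
}

#' Subset a GRM to a set of sample ids
#'
#' @param grm a [GRMatrix-class].
#' @param ids sample ids to keep (order preserved as given).
#' @return a [GRMatrix-class].
#' @export
subsetGRM <- function(grm, ids) {
  idx <- match(ids, grm@ids)
  if (anyNA(idx)) stop("unknown sample id(s)", call. = FALSE)
  new("GRMatrix", values = grm@values[idx, idx, drop = FALSE],
      nsnp = grm@nsnp[idx, idx, drop = FALSE], ids = grm@ids[idx],
      callRate = if (length(grm@callRate)) grm@callRate[idx] else numeric(0))
}

#' Read and write GCTA-style text GRM files
#'
#' `writeGRM()` emits `<prefix>.grm.id` (family id and individual id per
#' line; the family id equals the individual id here) and
#' `<prefix>.grm` (one line per lower-triangle element including the
#' diagonal: 1-based row index, column index, SNP count, value).
#' `readGRM()` reads the pair back; the round trip is lossless to 1e-9.
#'
#' @param grm a [GRMatrix-class].
#' @param prefix path prefix for the two files.
#' @return `writeGRM()` the prefix, invisibly; `readGRM()` a
#'   [GRMatrix-class].
#' @export
writeGRM <- function(grm, prefix) {
  stopifnot(is(grm, "GRMatrix"))
  write.table(data.frame(grm@ids, grm@ids),
              paste0(prefix, ".grm.id"), sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  n <- length(grm@ids)
  idx <- which(lower.tri(grm@values, diag = TRUE), arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  df <- data.frame(i = idx[, 1], j = idx[, 2],
                   nsnp = grm@nsnp[idx],
                   value = sprintf("%.10g", grm@values[idx]))
  write.table(df, paste0(prefix, ".grm"), sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' @rdname writeGRM
#' @export
readGRM <- function(prefix) {
  ids <- read.table(paste0(prefix, ".grm.id"), sep = "\t",
                    stringsAsFactors = FALSE)[[2]]
  tri <- read.table(paste0(prefix, ".grm"), sep = "\t")
  n <- length(ids)
  if (any(tri[[1]] < 1 | tri[[1]] > n | tri[[2]] < 1 | tri[[2]] > tri[[1]])) {
    bad <- which(tri[[1]] < 1 | tri[[1]] > n | tri[[2]] < 1 | tri[[2]] > tri[[1]])[1]
    stop(sprintf("malformed GRM triangle file at line %d: index out of range", bad),
         call. = FALSE)
  }
  vals <- matrix(0, n, n)
  nsnp <- matrix(0, n, n)
  ii <- cbind(tri[[1]], tri[[2]])
  vals[ii] <- tri[[4]]; vals[ii[, 2:1, drop = FALSE]] <- tri[[4]]
  nsnp[ii] <- tri[[3]]; nsnp[ii[, 2:1, drop = FALSE]] <- tri[[3]]
  new("GRMatrix", values = vals, nsnp = nsnp, ids = ids,
      callRate = numeric(0))
}
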
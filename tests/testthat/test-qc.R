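test_that("Hardy-Weinberg chi-square test matches hand computation", {
  # perfect HWE proportions at p = 0.5
  r <- hweTest(25, 50, 25)
  expect_equal(r$chisq, 0)
  expect_equal(r$p, 1)
  # hand-computed Pearson statistic: p(A) = 0.6, expected (36, 48, 16)
  r2 <- hweTest(50, 20, 30)
  expect_equal(r2$chisq, 196 / 36 + 784 / 48 + 196 / 16, tolerance = 1e-12)
  expect_equal(r2$p, 5.4e-9, tolerance = 0.01)
  # monomorphic convention
  r3 <- hweTest(0, 0, 100)
  expect_true(r3$monomorphic)
  expect_equal(r3$p, 1)
})

test_that("exact HWE test agrees with the chi-square deep in the tail", {
  rc <- hweTest(50, 20, 30)
  re <- hweTest(50, 20, 30, exact = TRUE)
  expect_lt(re$p, 1e-6)
  expect_lt(abs(log10(re$p) - log10(rc$p)), 2)
  # balanced case is not rejected by either
  expect_gt(hweTest(26, 48, 26, exact = TRUE)$p, 0.5)
})

test_that("HWE test is calibrated on panels simulated under HWE", {
  set.seed(12)
  g <- hweDosages(2000, 800, runif(2000, 0.1, 0.5))
  pv <- apply(g, 1, function(gi)
    hweTest(sum(gi == 2), sum(gi == 1), sum(gi == 0))$p)
  expect_lt(abs(mean(pv < 0.05) - 0.05),
            2.576 * sqrt(0.05 * 0.95 / 2000) + 0.01)
})

test_that("SNP filter applies each rule with strict boundary semantics", {
  set.seed(30)
  n <- 400
  d <- hweDosages(8, n, 0.3)
  d[1, ] <- rbinom(n, 2, 0.005)                    # MAF 0.005 -> fail maf
  d[2, seq_len(0.05 * n)] <- NA                    # 5% missing -> fail missing
  d[3, ] <- rep(c(0, 2), length.out = n)           # no hets -> HWE p << 1e-20
  pan <- toyPanel(d)
  rep <- snpFilter(pan)
  expect_equal(unname(qcCounts(rep)[c("maf", "missing", "hwe")]), c(1L, 1L, 1L))
  expect_equal(sum(qcTable(rep)$status == "pass"), 5)
  expect_equal(qcTable(rep)$reason[1:3], c("maf", "missing", "hwe"))
  # info 0.97 fails a genotyped SNP ("below 0.975" is strict)
  panInfo <- toyPanel(hweDosages(2, n, 0.3), info = c(0.97, 0.975))
  repInfo <- snpFilter(panInfo)
  expect_equal(qcTable(repInfo)$reason, c("info", NA))
  # MAF exactly at the threshold passes (strict "less than")
  dm <- matrix(c(rep(0, 98), 1, 1), 1, 100)        # freq = 2/200 = 0.01
  panMaf <- toyPanel(dm)
  expect_equal(sum(qcCounts(snpFilter(panMaf, plateTest = FALSE))["maf"]), 0)
})

test_that("tiered info rule applies to imputed SNPs", {
  d <- hweDosages(4, 300, 0.3)
  pan <- toyPanel(d, status = c("genotyped", "imputed_one", "imputed_both",
                                "imputed_both"),
                  info = c(1, 0.92, 0.95, 0.985))
  rep <- snpFilter(pan)
  # imputed_one passes at 0.92 (>= 0.90); imputed_both fails at 0.95 (< 0.98)
  expect_equal(qcTable(rep)$reason, c(NA, NA, "info", NA))
})

test_that("SNP filtering is idempotent", {
  set.seed(31)
  d <- hweDosages(60, 300, runif(60, 0.02, 0.5))
  d[sample(length(d), 600)] <- NA
  pan <- toyPanel(d)
  rep1 <- snpFilter(pan)
  survivors <- applyQC(pan, rep1)
  rep2 <- snpFilter(survivors)
  expect_equal(sum(qcCounts(rep2)), 0)
})

test_that("sample filter removes the lower-call-rate member of related pairs", {
  set.seed(33)
  d <- hweDosages(300, 10, runif(300, 0.2, 0.5))
  d[, 10] <- d[, 1]                                # duplicated sample
  d[sample(300, 30), 1] <- NA                      # sample 1 has lower call rate
  pan <- toyPanel(d)
  grm <- computeGRM(pan)
  rep <- sampleFilter(pan, sampleQCThresholds(callRateMin = 0.5, hetZMax = 10),
                      grm = grm)
  tab <- qcTable(rep)
  expect_equal(tab$reason[1], "relatedness")
  expect_true(is.na(tab$reason[10]))
  # identity GRM (zero off-diagonals): nobody removed for relatedness
  n <- ncol(dosages(pan))
  grmId <- new("GRMatrix", values = diag(n), nsnp = matrix(300, n, n),
               ids = colnames(dosages(pan)), callRate = rep(1, n))
  repId <- sampleFilter(pan, sampleQCThresholds(callRateMin = 0.5, hetZMax = 10),
                        grm = grmId)
  expect_equal(sum(qcCounts(repId)["relatedness"]), 0)
})

test_that("iterative relatedness removal terminates and matches the minimal oracle on a triangle", {
  # three mutually related samples: minimum removal is 2
  A <- diag(4) * 1.0
  A[1, 2] <- A[2, 1] <- 0.5
  A[1, 3] <- A[3, 1] <- 0.5
  A[2, 3] <- A[3, 2] <- 0.5
  grm <- new("GRMatrix", values = A, nsnp = matrix(100, 4, 4),
             ids = sprintf("I%04d", 1:4), callRate = c(0.99, 0.98, 0.97, 1))
  kept <- pruneUnrelated(grm, 0.05)
  expect_equal(length(kept), 4 - minimalRemovalCount(A, 0.05))
  Ak <- A[match(kept, grm@ids), match(kept, grm@ids)]
  diag(Ak) <- 0
  expect_true(all(Ak <= 0.05))
})

test_that("LD pruning keeps one of a perfectly correlated pair and verifies its postcondition", {
  set.seed(35)
  d <- hweDosages(30, 500, 0.3)
  d[2, ] <- d[1, ]                                 # perfect LD on one chromosome
  pan <- toyPanel(d)
  kept <- ldPrune(pan, r2Max = 0.2, window = 50)
  expect_false(all(c("snp001", "snp002") %in% kept))
  expect_true(any(c("snp001", "snp002") %in% kept))
  # postcondition replay: no kept pair within the window exceeds r2Max
  dk <- d[match(kept, snpData(pan)$id), ]
  cm <- cor(t(dk))^2
  diag(cm) <- 0
  expect_lte(max(cm), 0.2 + 1e-12)
})

test_that("independent SNPs survive LD pruning almost entirely", {
  set.seed(36)
  pan <- toyPanel(hweDosages(200, 1000, runif(200, 0.1, 0.5)))
  kept <- ldPrune(pan, r2Max = 0.2, window = 50)
  expect_gt(length(kept) / 200, 0.99)
})

test_that("panel PCA returns orthonormal components", {
  pan <- simulateGenotypes(genoSimConfig(120, 800, seed = 37))
  pca <- panelPCA(pan, 5)
  U <- sweep(pca$scores, 2, sqrt(colSums(pca$scores^2)), "/")
  expect_equal(unname(crossprod(U)), diag(5), tolerance = 1e-8)
  expect_error(panelPCA(pan, 120), "smaller than")
})

test_that("Tracy-Widom count separates structured from exchangeable panels", {
  nullHits <- 0L; strHits <- 0L
  for (s in 1:10) {
    p0 <- simulateGenotypes(genoSimConfig(150, 1200, seed = 700 + s))
    nullHits <- nullHits + (tracyWidomCount(panelPCA(p0, 2)$eigenvalues) == 0)
    p1 <- simulateGenotypes(genoSimConfig(150, 1200, nSubpops = 2, fst = 0.1,
                                          seed = 800 + s))
    strHits <- strHits + (tracyWidomCount(panelPCA(p1, 2)$eigenvalues) >= 1)
  }
  expect_gte(nullHits, 9)
  expect_gte(strHits, 9)
  expect_equal(tracyWidomCount(numeric(0)), 0L)
  expect_error(tracyWidomCount(c(2, 1), alpha = 0.2), "alpha")
})
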
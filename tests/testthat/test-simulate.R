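test_that("twin simulator reproduces the closed-form pair correlations", {
  cases <- list(
    list(a2 = 0.64, c2 = 0, d2 = 0, e2 = 0.36),
    list(a2 = 0.4, c2 = 0.3, d2 = 0, e2 = 0.3),
    list(a2 = 0.5, c2 = 0, d2 = 0.2, e2 = 0.3))
  for (cs in cases) {
    cfg <- twinSimConfig(10000, 10000, a2 = cs$a2, c2 = cs$c2, d2 = cs$d2,
                         e2 = cs$e2, seed = 11)
    tc <- twinCorrelations(simulateTwins(cfg))
    expMZ <- cs$a2 + cs$c2 + cs$d2
    expDZ <- 0.5 * cs$a2 + cs$c2 + 0.25 * cs$d2
    expect_lt(abs(tc@rMZ - expMZ), 3 * tc@seMZ)
    expect_lt(abs(tc@rDZ - expDZ), 3 * tc@seDZ)
  }
})

test_that("twin simulator matches published correlation structure at study scale", {
  cfg <- twinSimConfig(1099, 1787, a2 = 0.64, e2 = 0.36, seed = 5)
  tc <- twinCorrelations(simulateTwins(cfg))
  expect_lt(abs(tc@rMZ - 0.63), 2 * tc@seMZ + 0.01)  # E[rMZ] = 0.64 vs observed 0.63
  expect_lt(abs(tc@rDZ - 0.31), 2 * tc@seDZ + 0.01)
})

test_that("pure unique-environment twins are uncorrelated", {
  tc <- twinCorrelations(simulateTwins(twinSimConfig(3000, 3000, e2 = 1, seed = 2)))
  expect_lt(abs(tc@rMZ), 3 * tc@seMZ)
  expect_lt(abs(tc@rDZ), 3 * tc@seDZ)
})

test_that("additive-only twins show the 2:1 MZ:DZ correlation ratio", {
  tc <- twinCorrelations(simulateTwins(
    twinSimConfig(5000, 5000, a2 = 0.8, e2 = 0.2, seed = 3)))
  expect_lt(abs(tc@rDZ / tc@rMZ - 0.5), 0.05)
})

test_that("twin config validation rejects inadmissible fractions", {
  expect_error(twinSimConfig(10, 10, a2 = 0.5, e2 = 0.6), "equal 1")
  expect_error(twinSimConfig(10, 10, a2 = 0.4, c2 = 0.2, d2 = 0.2, e2 = 0.2),
               "at most one")
  expect_error(twinSimConfig(10, 10, a2 = -0.1, e2 = 1.1), "\\[0, 1\\]")
})

test_that("simulated genotypes are in HWE and allele frequencies are unbiased", {
  panel <- simulateGenotypes(genoSimConfig(2000, 1000, mafRange = c(0.1, 0.5),
                                           seed = 7))
  d <- dosages(panel)
  pTrue <- snpData(panel)$genFreq
  pHat <- rowMeans(d) / 2
  expect_lt(abs(mean(pHat - pTrue)), 0.005)
  # HWE holds by construction: rejection rate about alpha
  g <- round(d)
  pvals <- apply(g, 1, function(gi)
    hweTest(sum(gi == 2), sum(gi == 1), sum(gi == 0))$p)
  rate <- mean(pvals < 0.05)
  expect_lt(abs(rate - 0.05), 2.576 * sqrt(0.05 * 0.95 / 1000) + 0.01)
})

test_that("two-subpopulation panels separate on PC1 at moderate Fst", {
  panel <- simulateGenotypes(genoSimConfig(500, 5000, nSubpops = 2, fst = 0.05,
                                           seed = 13))
  pca <- panelPCA(panel, 2)
  lab <- sampleData(panel)$subpop
  acc <- max(mean((pca$scores[, 1] > 0) == (lab == 1)),
             mean((pca$scores[, 1] > 0) == (lab == 2)))
  expect_gt(acc, 0.9)
})

test_that("fst = 0 leaves no leading-PC structure (label permutation check)", {
  panel <- simulateGenotypes(genoSimConfig(200, 1500, nSubpops = 2, fst = 0,
                                           seed = 17))
  pca <- panelPCA(panel, 1)
  lab <- sampleData(panel)$subpop
  obs <- abs(mean(pca$scores[lab == 1, 1]) - mean(pca$scores[lab == 2, 1]))
  set.seed(1)
  perm <- replicate(199, {
    pl <- sample(lab)
    abs(mean(pca$scores[pl == 1, 1]) - mean(pca$scores[pl == 2, 1]))
  })
  expect_gt(mean(perm >= obs), 0.01)  # observed separation not extreme
})

test_that("generators are bit-reproducible under a fixed seed", {
  a <- simulateGenotypes(genoSimConfig(50, 100, missingRate = 0.05, seed = 42))
  b <- simulateGenotypes(genoSimConfig(50, 100, missingRate = 0.05, seed = 42))
  expect_identical(dosages(a), dosages(b))
  ta <- simulateTwins(twinSimConfig(30, 30, a2 = 0.5, e2 = 0.5, seed = 9))
  tb <- simulateTwins(twinSimConfig(30, 30, a2 = 0.5, e2 = 0.5, seed = 9))
  expect_identical(pairsTable(ta), pairsTable(tb))
})

test_that("longitudinal phenotypes have the advertised variance structure", {
  panel <- simulateGenotypes(genoSimConfig(1500, 2000, seed = 21))
  ph <- simulateLongitudinalPhenotypes(
    panel, phenoSimConfig(nCausal = 500, h2snp = 0.4, crossAgeCorr = 0.5,
                          seed = 22))
  expect_equal(var(ph$g), 0.4, tolerance = 1e-10)
  expect_lt(abs(var(ph$y7) - 1), 0.1)
  r79 <- cor(ph$y7 - ph$g, ph$y9 - ph$g)
  expect_lt(abs(r79 - 0.5), 0.08)
})

test_that("missingness is driven by covariates and the no-missing case is complete", {
  panel <- simulateGenotypes(genoSimConfig(2000, 200, seed = 31))
  ph <- simulateLongitudinalPhenotypes(
    panel, phenoSimConfig(nCausal = 50, h2snp = 0.2,
                          missingRates = c(0.2, 0.3, 0.6), seed = 32))
  expect_lt(abs(mean(is.na(ph$y7)) - 0.2), 0.05)
  expect_lt(abs(mean(is.na(ph$y12)) - 0.6), 0.05)
  # MAR construction: males and females differ in missingness
  expect_gt(abs(mean(is.na(ph$y9[ph$sex == 1])) -
                mean(is.na(ph$y9[ph$sex == 0]))), 0.02)
  ph0 <- simulateLongitudinalPhenotypes(
    panel, phenoSimConfig(nCausal = 50, h2snp = 0.2, seed = 33))
  expect_false(anyNA(ph0[, c("y7", "y9", "y12")]))
  comp <- compositeMean(ph0$y7, ph0$y9, ph0$y12)
  expect_equal(comp, rowMeans(as.matrix(ph0[, c("y7", "y9", "y12")])))
})

test_that("causal-count validation is enforced", {
  panel <- simulateGenotypes(genoSimConfig(20, 10, seed = 1))
  expect_error(simulateLongitudinalPhenotypes(
    panel, phenoSimConfig(nCausal = 11, h2snp = 0.2)), "nCausal")
})
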
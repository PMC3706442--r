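test_that("single-SNP regression is calibrated under the null and exact under determinism", {
  set.seed(90)
  n <- 500
  y <- rnorm(n)
  cov <- data.frame(sex = rbinom(n, 1, 0.5))
  pv <- replicate(2000, snpRegression(rbinom(n, 2, 0.3), y, cov)$p)
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
  # y equal to the dosage: slope one, p underflowing
  g <- rbinom(n, 2, 0.4)
  fit <- snpRegression(g, g)
  expect_equal(fit$beta, 1, tolerance = 1e-12)
  expect_lt(fit$p, 1e-100)
  expect_error(snpRegression(rep(1, n), y), "monomorphic")
  expect_error(snpRegression(g[1:5], y[1:5]), "complete cases")
})

test_that("the longitudinal score test reduces to the univariate test", {
  set.seed(91)
  n <- 2000
  sim <- nullLongitudinal(n, missingRates = c(0, 0, 0))
  # single age
  Y1 <- sim$Y[, 1, drop = FALSE]
  G <- matrix(rbinom(100 * n, 2, rep(runif(100, 0.1, 0.5), n)), 100, n)
  res <- longitudinalScoreTest(G, Y1, sim$covariates)
  t2 <- vapply(seq_len(100), function(i)
    squaredT(G[i, ], Y1[, 1], sim$covariates), numeric(1))
  expect_lt(max(abs(res$stat - t2) / pmax(t2, 1)), 0.01)
  # each individual observed at exactly one age: equals pooled per-age scores
  Ys <- sim$Y
  onlyAge <- sample(1:3, n, TRUE)
  for (a in 1:3) Ys[onlyAge != a, a] <- NA
  resS <- longitudinalScoreTest(G[1:20, , drop = FALSE], Ys, sim$covariates)
  expect_true(all(is.finite(resS$stat)))
  expect_true(all(resS$p > 0 & resS$p <= 1))
  # independent oracle: stacked weighted-least-squares score test with
  # per-age weights (the diagonal working covariance)
  X <- model.matrix(~ sex + cohort, sim$covariates)
  for (i in 1:5) {
    oracle <- stackedWlsScore(G[i, ], Ys, X)
    expect_equal(resS$stat[i], oracle, tolerance = 1e-6)
  }
})

test_that("the score test is calibrated under MAR missingness and correlated ages", {
  set.seed(92)
  n <- 1200; m <- 6000
  sim <- nullLongitudinal(n)
  maf <- runif(m, 0.05, 0.5)
  G <- matrix(rbinom(m * n, 2, rep(maf, n)), m, n)
  res <- longitudinalScoreTest(G, sim$Y, sim$covariates)
  typeI <- mean(res$p < 0.05)
  expect_lt(abs(typeI - 0.05), 2.576 * sqrt(0.05 * 0.95 / m) + 0.005)
  lam <- genomicControl(res$stat)$lambda[["all"]]
  seLambda <- 1 / (2 * dchisq(qchisq(0.5, 1), 1) * sqrt(m)) / qchisq(0.5, 1)
  expect_lt(abs(lam - 1), 2.576 * seLambda + 0.01)
})

test_that("an informative SNP with an equal effect at all ages is detected", {
  set.seed(93)
  n <- 1500
  sim <- nullLongitudinal(n, missingRates = c(0.1, 0.1, 0.1))
  g <- rbinom(n, 2, 0.3)
  Y <- sim$Y + 0.25 * g
  res <- longitudinalScoreTest(g, Y, sim$covariates)
  expect_lt(res$p, 1e-10)
  expect_gt(res$score, 0)
})

test_that("score statistic is invariant to covariate affine maps and age order", {
  set.seed(94)
  n <- 800
  sim <- nullLongitudinal(n, missingRates = c(0.1, 0.2, 0.3))
  g <- rbinom(n, 2, 0.3)
  s0 <- longitudinalScoreTest(g, sim$Y, sim$covariates)$stat
  covT <- data.frame(sex = 10 * sim$covariates$sex - 4,
                     cohort = 0.1 * sim$covariates$cohort + 3)
  expect_equal(longitudinalScoreTest(g, sim$Y, covT)$stat, s0,
               tolerance = 1e-6)
  expect_equal(longitudinalScoreTest(g, sim$Y[, c(3, 1, 2)],
                                     sim$covariates)$stat, s0,
               tolerance = 1e-6)
  expect_error(longitudinalScoreTest(rep(2, n), sim$Y, sim$covariates),
               "monomorphic")
})

test_that("genomic control rescales statistics per its definition", {
  med <- qchisq(0.5, 1)
  stats <- rep(med, 200)
  gc <- genomicControl(stats)
  expect_equal(gc$lambda[["all"]], 1)
  gc2 <- genomicControl(2 * stats)
  expect_equal(gc2$lambda[["all"]], 2)
  # adjusted statistics have unit lambda
  expect_equal(median(gc2$stat) / med, 1)
  # deflation is not inflated back: lambda < 1 leaves p untouched
  gc3 <- genomicControl(0.5 * stats)
  expect_equal(gc3$stat, 0.5 * stats)
  expect_true(all(genomicControl(stats * 3)$p >= pchisq(stats * 3, 1,
                                                        lower.tail = FALSE)))
  expect_warning(genomicControl(rep(med, 50)), "unstable")
  # strata get separate factors
  gcS <- genomicControl(c(stats, 2 * stats),
                        rep(c("genotyped", "imputed_both"), each = 200))
  expect_equal(unname(gcS$lambda), c(1, 2))
})

test_that("significance tiers use strict thresholds", {
  expect_equal(classifyTier(2.93e-6), "suggestive")
  expect_equal(classifyTier(4.9e-8), "genomewide")
  expect_equal(classifyTier(5e-6), "none")
  expect_equal(classifyTier(5e-8), "suggestive")
  expect_equal(classifyTier(c(1e-9, 1e-6, 0.5)),
               c("genomewide", "suggestive", "none"))
})

test_that("QQ data uses i/(n+1) expectations and a valid beta band", {
  q1 <- qqData(0.5)
  expect_equal(q1$expected, -log10(0.5), tolerance = 1e-12)
  set.seed(95)
  q <- qqData(runif(10000))
  expect_true(all(q$bandLow < q$expected & q$expected < q$bandHigh))
  inside <- mean(q$observed >= q$bandLow & q$observed <= q$bandHigh)
  expect_gte(inside, 0.93)
})

test_that("Manhattan data orders by genome coordinate and replays tiers", {
  rec <- data.frame(chrom = c(2, 1, 1), pos = c(5, 100, 50),
                    pGC = c(1e-9, 0.5, 3e-6))
  md <- manhattanData(rec)
  expect_true(all(diff(md$coord) > 0))
  expect_equal(md$chrom, c(1, 1, 2))
  expect_equal(md$tier, classifyTier(c(3e-6, 0.5, 1e-9)))
  # empty input gives an empty, well-typed table
  empty <- manhattanData(rec[0, ])
  expect_equal(nrow(empty), 0)
  expect_true(all(c("coord", "logP", "tier") %in% names(empty)))
})

test_that("association scan labels risk alleles and strata coherently", {
  set.seed(96)
  pan <- simulateGenotypes(genoSimConfig(500, 60, seed = 97))
  sim <- nullLongitudinal(500, missingRates = c(0.1, 0.1, 0.1))
  # inject one strong equal-effect SNP
  Y <- sim$Y + 0.6 * dosages(pan)[5, ]
  suppressWarnings(scan <- associationScan(pan, Y, sim$covariates))
  expect_true(all(scan$pRaw > 0 & scan$pRaw <= 1, na.rm = TRUE))
  i <- 5
  expect_lt(scan$pGC[i], 5e-8)
  expect_equal(scan$tier[i], "genomewide")
  expect_equal(scan$riskAllele[i], snpData(pan)$alt[i])  # higher dosage, higher trait
  expect_equal(scan$riskFreq[i], mean(dosages(pan)[i, ]) / 2, tolerance = 1e-12)
  # tiers replay classifyTier on the adjusted p-values
  expect_equal(scan$tier, classifyTier(scan$pGC))
})
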
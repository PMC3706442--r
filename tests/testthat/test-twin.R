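test_that("Falconer estimates reproduce the textbook worked examples", {
  expect_equal(falconerEstimate(0.80, 0.40)[["a2"]], 0.80)
  expect_equal(falconerEstimate(0.80, 0.20)[["a2"]], 1.20)
  expect_equal(falconerEstimate(0.80, 0.20, constrain = TRUE)[["a2"]], 0.80)
  expect_equal(falconerEstimate(0.80, 0.20, constrain = TRUE)[["c2"]], 0)
  # published composite correlations: a2 = 0.64 raw, shared environment
  # slightly negative and clamped at zero when constrained
  raw <- falconerEstimate(0.63, 0.31)
  expect_equal(raw[["a2"]], 0.64)
  expect_equal(raw[["c2"]], -0.01)
  con <- falconerEstimate(0.63, 0.31, constrain = TRUE)
  expect_equal(con[["c2"]], 0)
  expect_lte(con[["a2"]], 0.63)
})

test_that("constrained Falconer output is a valid decomposition", {
  set.seed(2)
  for (i in 1:50) {
    rmz <- runif(1, 0, 0.95)
    rdz <- runif(1, -0.2, rmz)
    est <- falconerEstimate(rmz, rdz, constrain = TRUE)
    expect_lte(est[["a2"]], rmz + 1e-12)
    expect_true(all(est >= -1e-12))
    expect_equal(est[["a2"]] + est[["c2"]], rmz, tolerance = 1e-12)
    expect_equal(sum(est), 1, tolerance = 1e-12)
  }
})

test_that("intraclass correlation behaves at its reference points", {
  y <- rnorm(100)
  expect_equal(intraclassCorrelation(y, y)$icc, 1)
  set.seed(3)
  a <- rnorm(10000); b <- rnorm(10000)
  r <- intraclassCorrelation(a, b)
  expect_lt(abs(r$icc), 3 * r$se)
  expect_error(intraclassCorrelation(c(1, 2), c(1, 2)), "3 complete pairs")
})

test_that("ICC equals the double-entry Pearson correlation for equal group means", {
  set.seed(6)
  n <- 500
  common <- rnorm(n)
  y1 <- common + rnorm(n); y2 <- common + rnorm(n)
  # enforce equal member means/variances by double-entry symmetry
  icc <- intraclassCorrelation(y1, y2)$icc
  rde <- cor(c(y1, y2), c(y2, y1))
  expect_equal(icc, rde, tolerance = 1e-6)
})

test_that("ACE FIML fit recovers simulated components at study scale", {
  tw <- simulateTwins(twinSimConfig(1099, 1787, a2 = 0.64, e2 = 0.36, seed = 44))
  fit <- fitTwinModel(tw, "ACE")
  est <- varEstimates(fit)
  expect_lt(abs(est[["A"]] - 0.64), 2 * max(fit@se[["A"]], 0.03))
  expect_lt(abs(est[["E"]] - 0.36), 2 * max(fit@se[["E"]], 0.02))
  expect_equal(sum(est), 1, tolerance = 1e-6)
  expect_true(fit@converged)
})

test_that("FIML uses singleton marginal likelihoods", {
  tw <- simulateTwins(twinSimConfig(400, 400, a2 = 0.6, e2 = 0.4, seed = 8))
  p <- pairsTable(tw)
  # knock out one member of some pairs
  drop <- p$member == 2 & p$family_id %in% unique(p$family_id)[seq(1, 100, 2)]
  p$phenotype[drop] <- NA
  twMiss <- new("TwinDataset", pairs = p)
  fit <- fitTwinModel(twMiss, "AE")
  expect_equal(fit@nLL, fit@nPairs + sum(drop))
  expect_equal(fit@nObs, sum(!is.na(p$phenotype)))
  # deviance sits between complete-data and complete-pairs-only fits
  expect_true(is.finite(fit@minus2ll))
})

test_that("null additive data put the A estimate at its boundary", {
  nBoundary <- 0L; nNonsig <- 0L
  for (s in 1:20) {
    tw <- simulateTwins(twinSimConfig(150, 150, e2 = 1, seed = 500 + s))
    ae <- fitTwinModel(tw, "AE")
    e <- fitTwinModel(tw, "E")
    cmp <- compareModels(ae, e)
    nNonsig <- nNonsig + (cmp$p > 0.05)
    nBoundary <- nBoundary + (varEstimates(ae)[["A"]] < 0.15)
  }
  expect_gte(nNonsig, 18)  # LRT non-significant in >= 90% of replicates
  expect_gte(nBoundary, 15)
})

test_that("summary-equivalent data reproduce the boundary C estimate", {
  td <- twinDataFromSummary(0.63, 1099, 0.31, 1787, seed = 1)
  tc <- twinCorrelations(td)
  expect_equal(tc@rMZ, 0.63, tolerance = 1e-9)
  expect_equal(tc@rDZ, 0.31, tolerance = 1e-9)
  fit <- fitTwinModel(td, "ACE")
  expect_equal(varEstimates(fit)[["C"]], 0)
  expect_true(fit@boundary[["C"]])
  expect_lt(abs(varEstimates(fit)[["A"]] - 0.64), 0.02)
})

test_that("boundary placement follows the rDZ vs rMZ/2 comparison", {
  # rDZ > rMZ/2: dominance pinned at zero in ADE
  ade <- fitTwinModel(twinDataFromSummary(0.6, 800, 0.4, 800), "ADE")
  expect_equal(varEstimates(ade)[["D"]], 0)
  # rDZ < rMZ/2: shared environment pinned at zero in ACE
  ace <- fitTwinModel(twinDataFromSummary(0.6, 800, 0.2, 800), "ACE")
  expect_equal(varEstimates(ace)[["C"]], 0)
})

test_that("nested models never beat the full model in deviance", {
  for (s in 1:3) {
    tw <- simulateTwins(twinSimConfig(300, 300, a2 = 0.5, c2 = 0.2, e2 = 0.3,
                                      seed = 60 + s))
    full <- fitTwinModel(tw, "ACE")
    for (m in c("AE", "CE", "E")) {
      nested <- fitTwinModel(tw, m)
      expect_gte(nested@minus2ll - full@minus2ll, -1e-4)
    }
  }
})

test_that("model comparison reproduces the published fit-table conventions", {
  expect_equal(aicDeviance(15916, 5865), 4186)
  expect_equal(aicDeviance(15916, 5864), 4188)
  expect_equal(aicDeviance(0, 0), 0)
  full <- new("VarCompFit", model = "ACE", estimates = c(A = 0.64, C = 0, E = 0.36),
              se = c(A = NA_real_, C = NA_real_, E = NA_real_),
              minus2ll = 15916, df = 5864,
              aic = aicDeviance(15916, 5864), aicTextbook = 15916 + 8,
              nPairs = 2886, nLL = 3142, nObs = 5868,
              varComponents = c(A = 0.64, C = 0, E = 0.36), mu = 0,
              totalVar = 1, converged = TRUE,
              boundary = c(A = FALSE, C = TRUE, E = FALSE))
  nested <- new("VarCompFit", model = "AE", estimates = c(A = 0.64, E = 0.36),
                se = c(A = NA_real_, E = NA_real_),
                minus2ll = 15916 - 1.86e-10, df = 5865,
                aic = aicDeviance(15916, 5865), aicTextbook = 15916 + 6,
                nPairs = 2886, nLL = 3142, nObs = 5868,
                varComponents = c(A = 0.64, E = 0.36), mu = 0, totalVar = 1,
                converged = TRUE, boundary = c(A = FALSE, E = FALSE))
  cmp <- compareModels(full, nested)
  expect_equal(cmp$deltaChi2, 0)     # tiny negative deviance difference clamps to 0
  expect_equal(cmp$deltaDf, 1)
  expect_equal(cmp$p, 1)
  expect_equal(cmp$deltaAic, -2)
  # self-comparison is degenerate
  expect_error(compareModels(full, full), "not nested")
  # chi-square quantile sanity
  expect_equal(pchisq(3.8415, 1, lower.tail = FALSE), 0.05, tolerance = 1e-3)
})
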
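test_that("genetic-model codings map dosages as defined", {
  expect_equal(codeGenotypes(c(0, 1, 2), "additive"), c(0, 1, 2))
  expect_equal(codeGenotypes(c(0, 1, 2), "dominant"), c(0, 1, 1))
  expect_equal(codeGenotypes(c(0, 1, 2), "recessive"), c(0, 0, 1))
  expect_true(is.na(codeGenotypes(NA, "additive")))
  expect_error(codeGenotypes(3, "additive"), "dosages")
})

test_that("logistic MLE equals the closed-form 2x2 odds ratio when the
           minor-homozygote cells are empty", {
  set.seed(51)
  for (i in 1:25) {
    a <- sample(5:200, 1); b <- sample(5:200, 1)
    c_ <- sample(5:200, 1); d <- sample(5:200, 1)
    fit <- fitGenotypeLogistic(c(a, b, 0), c(c_, d, 0))
    orClosed <- (b * c_) / (a * d)
    seClosed <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
    expect_equal(fit$or, orClosed, tolerance = 1e-10)
    expect_equal(fit$se, seClosed, tolerance = 1e-10)
    expect_match(fit$flag, "zero_cell")
  }
})

test_that("association fit reproduces the published DHCR7 variant row", {
  fit <- fitGenotypeLogistic(c(169, 22, 0), c(185, 99, 0),
                             model = "additive", variant = "rs104886038")
  expect_equal(round(fit$or, 3), 0.243)
  expect_equal(round(fit$ci_low, 3), 0.147)
  expect_equal(round(fit$ci_high, 3), 0.404)
  expect_equal(signif(fit$p_trend, 3), 1.04e-08)
  expect_equal(round(fit$maf_case, 3), 0.058)
  expect_equal(round(fit$maf_control, 3), 0.174)
})

test_that("identical case/control distributions give a null fit", {
  fit <- fitGenotypeLogistic(c(50, 30, 20), c(100, 60, 40))
  expect_equal(fit$or, 1, tolerance = 1e-8)
  expect_equal(fit$beta, 0, tolerance = 1e-8)
})

test_that("odds ratios invert under case/control label swap", {
  fit <- fitGenotypeLogistic(c(80, 45, 12), c(120, 40, 5))
  swap <- fitGenotypeLogistic(c(120, 40, 5), c(80, 45, 12))
  expect_equal(swap$or, 1 / fit$or, tolerance = 1e-9)
})

test_that("trend test agrees with the independent score-test implementation", {
  set.seed(52)
  for (i in 1:25) {
    r <- sample(0:80, 3); s <- sample(0:80, 3)
    if (sum(r) == 0 || sum(s) == 0) next
    ours <- cochranArmitageTrend(r, s)
    if (ours$flag == "degenerate") next
    ref <- suppressWarnings(prop.trend.test(r, r + s))
    expect_equal(ours$chisq, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("trend test degenerates gracefully and detects no false trend", {
  prop <- cochranArmitageTrend(c(20, 30, 10), c(40, 60, 20))
  expect_equal(prop$chisq, 0, tolerance = 1e-12)
  expect_equal(prop$p, 1)
  degen <- cochranArmitageTrend(c(10, 0, 0), c(20, 0, 0))
  expect_identical(degen$flag, "degenerate")
  expect_equal(degen$p, 1)
})

test_that("asymptotic trend p approximates the exact permutation p", {
  r <- c(30, 40, 30); s <- c(42, 38, 20)
  pAsym <- cochranArmitageTrend(r, s)$p
  pExact <- caPermutationOracle(r, s)
  expect_lt(abs(pAsym - pExact), 0.02)
})

test_that("trend-test type-I error is nominal over 10,000 null tables", {
  rate <- trendTypeIError(nSim = 10000, nPerGroup = 200, alpha = 0.05)
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.06)
})

test_that("Wald intervals cover the true odds ratio at the nominal rate", {
  set.seed(53)
  trueOR <- 1.5
  g <- c(0.49, 0.42, 0.09)  # HWE at maf 0.3
  f <- g * trueOR^(0:2); f <- f / sum(f)
  cover <- logical(2000)
  for (i in seq_len(2000)) {
    r <- rmultinom(1, 1000, f)[, 1]
    s <- rmultinom(1, 1000, g)[, 1]
    fit <- fitGenotypeLogistic(r, s)
    cover[i] <- fit$ci_low <= trueOR && trueOR <= fit$ci_high
  }
  expect_gt(mean(cover), 0.93)
  expect_lt(mean(cover), 0.97)
})

test_that("a null genome-wide scan is calibrated (lambda near 1)", {
  v <- data.frame(variant = sprintf("v%04d", 1:1000), chrom = "1",
                  pos = 1:1000 * 100L, maf = 0.3, beta = 0)
  gd <- simulateGenotypes(250, 250, v, mode = "sampled", seed = 61)
  scan <- runAssociationScan(gd, "additive")
  expect_equal(nrow(scan), 1000)
  expect_gt(attr(scan, "lambda"), 0.9)
  expect_lt(attr(scan, "lambda"), 1.1)
  qq <- attr(scan, "qq")
  expect_equal(nrow(qq), 1000)
})

test_that("a planted strong effect is the scan's top hit", {
  v <- data.frame(variant = sprintf("v%02d", 1:20), chrom = "1",
                  pos = 1:20 * 100L, maf = 0.3,
                  beta = c(log(4), rep(0, 19)))
  gd <- simulateGenotypes(250, 250, v, mode = "sampled", seed = 62)
  scan <- runAssociationScan(gd, "additive")
  expect_identical(scan$variant[which.min(scan$p_trend)], "v01")
  empty <- runAssociationScan(gd[0, ], "additive")
  expect_equal(nrow(empty), 0)
})

test_that("training/validation workflow retains the true signals", {
  gd <- plantedSplitFixture(nStrong = 3, nNull = 7, orStrong = 4, seed = 63)
  res <- trainValidateCombine(gd, "additive", topK = 5, alpha = 0.05)
  expect_length(res$top$variant, 5)
  expect_setequal(intersect(res$validated, c("v01", "v02", "v03")),
                  c("v01", "v02", "v03"))
  expect_identical(sort(res$combined$variant), sort(res$validated))
  # validation set that duplicates the training data: identical p-values,
  # retained exactly when training p < alpha
  v <- data.frame(variant = sprintf("v%02d", 1:5), chrom = "1",
                  pos = 1:5 * 100L, maf = 0.3,
                  beta = c(log(3), log(3), 0, 0, 0))
  base <- simulateGenotypes(100, 100, v, mode = "sampled", seed = 64)
  d <- dosages(base)
  d2 <- cbind(d, d)
  colnames(d2) <- sprintf("s%03d", seq_len(ncol(d2)))
  gd2 <- GenotypeData(d2,
                      data.frame(status = rep(sampleInfo(base)$status, 2),
                                 split = rep(c("train", "valid"),
                                             each = ncol(d)),
                                 row.names = colnames(d2)),
                      variantInfo(base))
  res2 <- trainValidateCombine(gd2, "additive", topK = 5, alpha = 0.05)
  expect_equal(res2$validation$p_trend, res2$top$p_trend, tolerance = 1e-12)
  expect_setequal(res2$validated, res2$top$variant[res2$top$p_trend < 0.05])
  expect_warning(trainValidateCombine(gd2, "additive", topK = 10),
                 "fewer variants")
})
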
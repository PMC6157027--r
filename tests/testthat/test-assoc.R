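test_that("mixture p-values hit the boundary-null reference points", {
  expect_identical(mixturePvalue(0), 1)
  # half the chi-square(1) tail at its 0.05 critical value
  expect_equal(mixturePvalue(3.8415), 0.025, tolerance = 1e-4)
  # chi-square(1) 90th percentile, halved
  expect_equal(mixturePvalue(2.7055), 0.05, tolerance = 1e-4)
  # clamping and violation handling
  expect_identical(mixturePvalue(-1e-7), 1)
  expect_error(mixturePvalue(-0.01), "nesting violation")
})

test_that("mixture p-value is strictly decreasing and matches Monte Carlo", {
  x <- seq(0.01, 10, length.out = 200)
  p <- mixturePvalue(x)
  expect_true(all(diff(p) < 0))
  # brute-force draws from the 50:50 mixture
  set.seed(99)
  draws <- ifelse(runif(5e5) < 0.5, 0, rchisq(5e5, df = 1))
  for (lrt in c(1, 2, 4, 8))
    expect_lt(abs(mean(draws >= lrt) - mixturePvalue(lrt)), 0.003)
})

test_that("Bonferroni threshold follows alpha / n_tests", {
  expect_identical(bonferroniThreshold(1), 0.05)
  expect_equal(bonferroniThreshold(15596), 3.206e-6, tolerance = 1e-3)
  expect_equal(bonferroniThreshold(31192), 1.603e-6, tolerance = 1e-3)
  expect_error(bonferroniThreshold(0), "positive count")
})

test_that("gene scan flags the causal gene and attaches coordinates", {
  sim <- simulateDataset(seed = 41, nFamilies = 60, nGenes = 8,
                         nSites = 200, traitHmeth2 = 0.35,
                         causalGenes = "G004")
  res <- geneScan(sim$trait, as.matrix(sim$covariates), sim$phi2,
                  sim$kernels, annotation = sim$annotation)
  expect_equal(res$gene_id, sort(names(sim$kernels)))
  expect_true(all(res$lrt >= 0))
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  expect_equal(res$gene_id[which.min(res$p_value)], "G004")
  expect_false(any(is.na(res$chromosome)))
  expect_equal(attr(res, "n_tests"), sum(res$converged))
  expect_equal(attr(res, "threshold"),
               0.05 / attr(res, "n_tests"))
})

test_that("gene scan is invariant to kernel order and survives empty input", {
  sim <- simulateDataset(seed = 43, nFamilies = 15, nGenes = 6, nSites = 150)
  X <- as.matrix(sim$covariates)
  r1 <- geneScan(sim$trait, X, sim$phi2, sim$kernels)
  r2 <- geneScan(sim$trait, X, sim$phi2, rev(sim$kernels))
  expect_equal(r1, r2, ignore_attr = TRUE)

  r0 <- geneScan(sim$trait, X, sim$phi2, list())
  expect_equal(nrow(r0), 0)
  expect_true(is.na(attr(r0, "threshold")))
})

test_that("kernels with foreign samples are skipped and logged", {
  sim <- simulateDataset(seed = 45, nFamilies = 15, nGenes = 6, nSites = 150)
  bad <- sim$kernels[[1]]
  rownames(bad@K) <- colnames(bad@K) <- paste0("zz", seq_len(nrow(bad@K)))
  kl <- c(sim$kernels[2:3], list(bad))
  res <- geneScan(sim$trait, as.matrix(sim$covariates), sim$phi2, kl)
  expect_equal(nrow(res), 2)
  errs <- attr(res, "errors")
  expect_equal(errs$gene_id, kernelGene(bad))
  expect_match(errs$reason, "do not match")
})

test_that("per-site heritability scan recovers null and heritable sites", {
  ped <- simulatePedigree(nFamilies = 60, seed = 47)
  A <- additiveMatrix(kinshipMatrix(ped))
  simNull <- simulateMethylation(ped, nSites = 120, nGenes = 2,
                                 sitesPerGene = c(5, 10), siteH2 = 0,
                                 seed = 48)
  h0 <- siteH2Scan(inverseNormalize(simNull$meth), A)
  expect_lt(mean(h0$h2), 0.1)

  simH <- simulateMethylation(ped, nSites = 120, nGenes = 2,
                              sitesPerGene = c(5, 10), siteH2 = 0.4,
                              seed = 49)
  hh <- siteH2Scan(inverseNormalize(simH$meth), A)
  expect_lt(abs(mean(hh$h2) - 0.4), 0.07)
  expect_true(all(hh$h2 >= 0 & hh$h2 <= 1))
  expect_true(all(hh$p_value[hh$lrt == 0] == 1))
})

test_that("plot data exports are order invariant and handle unplaced genes", {
  res <- data.frame(gene_id = c("A", "B", "C"),
                    chromosome = c("1", NA, "2"),
                    position = c(100, NA, 50),
                    p_value = c(0.01, 1, 0.3))
  d <- tempfile()
  paths <- exportPlotData(res, d)
  man <- read.delim(paths[["manhattan"]])
  expect_equal(man$chromosome[2], "unplaced")
  qq1 <- read.delim(paths[["qq"]])
  paths2 <- exportPlotData(res[3:1, ], d, prefix = "rev")
  qq2 <- read.delim(paths2[["qq"]])
  expect_equal(qq1, qq2)
  expect_true(all(diff(qq1$observed) >= 0))

  one <- exportPlotData(res[1, ], d, prefix = "one")
  expect_equal(nrow(read.delim(one[["manhattan"]])), 1)
  expect_error(exportPlotData(res[0, ], d), "empty")
})

test_that("expected Q-Q quantiles follow the mixture null, not uniform", {
  qq <- qqMixtureTable(c(0.2, 0.6, 1, 1))
  # ranks 3 and 4 sit in the point-mass half: expected p = 1
  expect_equal(qq$expected, c(0.125, 0.375, 1, 1))
  # an all-null scan stays inside a 95% band around the diagonal
  sim <- simulateDataset(seed = 51, nFamilies = 40, nGenes = 20,
                         nSites = 400)
  res <- geneScan(sim$trait, as.matrix(sim$covariates), sim$phi2,
                  sim$kernels)
  qq <- qqMixtureTable(res$p_value)
  nonzero <- qq$observed < 1
  expect_lt(max(abs(qq$expected[nonzero] - qq$observed[nonzero])),
            1.36 / sqrt(nrow(qq)) + 0.05)
})
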
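test_that("standardized site columns have mean 0 and unit variance", {
  set.seed(5)
  v <- matrix(rnorm(8 * 30), 8, dimnames = list(paste0("cg", 1:8),
                                                paste0("s", 1:30)))
  Z <- standardizeSites(normalScoreSet(v), paste0("cg", 1:8))
  expect_equal(dim(Z), c(30L, 8L))
  expect_lt(max(abs(colMeans(Z))), 1e-8)
  expect_lt(max(abs(apply(Z, 2, var) - 1)), 1e-8)

  # a column already standardized is a fixed point
  zcol <- scale(rnorm(30))[, 1]
  v2 <- matrix(zcol, 1, dimnames = list("cgz", paste0("s", 1:30)))
  Z2 <- standardizeSites(normalScoreSet(v2), "cgz")
  expect_equal(unname(Z2[, 1]), zcol, tolerance = 1e-12)
})

test_that("hand-standardization of a 3x2 example under both sd conventions", {
  v <- matrix(c(1, 2, 3, 4, 6, 8), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  ms <- normalScoreSet(v)
  Zs <- standardizeSites(ms, c("a", "b"))            # sample sd: 1 and 2
  expect_identical(Zs["s1", "a"], -1)
  Zp <- standardizeSites(ms, c("a", "b"), sdMethod = "population")
  expect_equal(Zp["s1", "a"], -sqrt(3 / 2), tolerance = 1e-12)
})

test_that("constant and high-missingness sites are dropped with reasons", {
  v <- rbind(const = rep(0.5, 10), ok1 = rnorm(10), ok2 = rnorm(10),
             holey = c(rep(NA, 5), rnorm(5)))
  colnames(v) <- paste0("s", 1:10)
  ms <- normalScoreSet(v)
  expect_warning(Z <- standardizeSites(ms, rownames(v)), "dropped")
  expect_equal(colnames(Z), c("ok1", "ok2"))
  dropped <- attr(Z, "dropped")
  expect_setequal(dropped$site_id, c("const", "holey"))
  expect_error(standardizeSites(ms, "nope"), "not present")
})

test_that("kernel equals brute-force pairwise correlation of site vectors", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(4:20, 1)
    m <- sample(2:12, 1)
    v <- matrix(rnorm(m * n), m,
                dimnames = list(paste0("cg", 1:m), paste0("s", 1:n)))
    Z <- standardizeSites(normalScoreSet(v), paste0("cg", 1:m))
    K <- kernelMatrix(buildKernel(Z, "g"))
    expect_lt(max(abs(K - bruteForceKernel(Z))), 1e-10)
    expect_lt(max(abs(diag(K) - 1)), 1e-10)
    expect_lt(max(abs(K - t(K))), 1e-12)
    expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8)
  }
})

test_that("degenerate kernels behave as correlation bounds dictate", {
  # single sample
  Z1 <- matrix(1.2, 1, 3, dimnames = list("s1", NULL))
  expect_identical(unname(kernelMatrix(buildKernel(Z1, "g"))), matrix(1, 1, 1))
  # identical / opposite standardized sample vectors
  z <- c(1, -1, 2)
  Z <- rbind(s1 = z, s2 = z, s3 = -z)
  K <- kernelMatrix(buildKernel(Z, "g"))
  expect_equal(K["s1", "s2"], 1)
  expect_equal(K["s1", "s3"], -1)
  # a sample with all-zero site values has no diagonal mass
  Z0 <- rbind(s1 = c(1, 2), s2 = c(0, 0))
  expect_error(buildKernel(Z0, "g"), "zero kernel diagonal.*s2")
})

test_that("kernel is invariant to site column order", {
  set.seed(9)
  Z <- matrix(rnorm(60), 10, dimnames = list(paste0("s", 1:10), NULL))
  Z <- scale(Z)
  k1 <- kernelMatrix(buildKernel(Z, "g"))
  k2 <- kernelMatrix(buildKernel(Z[, sample(ncol(Z))], "g"))
  expect_equal(k1, k2, tolerance = 1e-14)
})

test_that("many i.i.d. noise sites concentrate off-diagonals near zero", {
  set.seed(13)
  v <- matrix(rnorm(250 * 50), 250,
              dimnames = list(sprintf("cg%03d", 1:250), paste0("s", 1:50)))
  Z <- standardizeSites(normalScoreSet(v), rownames(v))
  K <- kernelMatrix(buildKernel(Z, "g"))
  expect_lt(max(abs(K[upper.tri(K)])), 0.5)
})

test_that("kernelScan emits one kernel per eligible gene with a skip report", {
  sim <- simulateDataset(seed = 21, nFamilies = 8, nSites = 300, nGenes = 12,
                         sitesPerGene = c(2L, 30L), minSites = 5L)
  # independent recount: genes with >= 5 usable sites
  cnt <- table(sim$annotation$gene_id)
  eligible <- sort(names(cnt)[cnt >= 5])
  expect_identical(sort(names(sim$kernels)), eligible)
  for (k in sim$kernels) {
    K <- kernelMatrix(k)
    expect_lt(max(abs(diag(K) - 1)), 1e-10)
    expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8)
  }
})

test_that("genes falling below minSites after drops land in the skip report", {
  set.seed(3)
  v <- rbind(matrix(rnorm(5 * 12), 5), matrix(0.42, 2, 12))
  # gene A: 5 live sites; gene B: 3 live + 2 constant -> 3 usable < 5
  v <- rbind(v[1:5, ], matrix(rnorm(3 * 12), 3), v[6:7, ])
  dimnames(v) <- list(paste0("cg", 1:10), paste0("s", 1:12))
  ann <- data.frame(site_id = paste0("cg", 1:10),
                    gene_id = rep(c("A", "B"), each = 5))
  idx <- buildGeneIndex(ann, minSites = 5)
  kl <- kernelScan(normalScoreSet(v), idx)
  expect_equal(names(kl), "A")
  skip <- attr(kl, "skipped")
  expect_equal(skip$gene_id, "B")
  expect_match(skip$reason, "usable")
})

test_that("kernel export formats round-trip", {
  set.seed(4)
  Z <- scale(matrix(rnorm(40), 8, dimnames = list(paste0("s", 1:8), NULL)))
  k <- buildKernel(Z, "gene1")
  tf <- tempfile()
  writeKernel(k, tf, format = "matrix")
  df <- read.delim(tf, check.names = FALSE)
  expect_equal(as.matrix(df[, -1]), kernelMatrix(k), ignore_attr = TRUE)
  writeKernel(k, tf, format = "pairs")
  pairs <- read.delim(tf)
  expect_equal(nrow(pairs), 8 * 9 / 2)
  expect_true(all(pairs$n_sites == 5))
})
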
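# small helper: random PSD kernel with unit-ish scale
randKernel <- function(n, rank = n) {
  Z <- matrix(rnorm(n * rank), n)
  K <- tcrossprod(Z)
  K / mean(diag(K))
}

test_that("log-likelihood reduces to independent normals in the diagonal case", {
  set.seed(1)
  y <- rnorm(3, sd = 2)
  ll <- vcLogLik(y, kernels = list(diag(3)), fractions = 0, sigma2 = 1,
                 betas = 0)
  expect_equal(ll, sum(dnorm(y, log = TRUE)), tolerance = 1e-12)
})

test_that("log-likelihood matches the dense closed form on random instances", {
  set.seed(2)
  for (rep in 1:100) {
    n <- sample(4:10, 1)
    nk <- sample(1:2, 1)
    kernels <- replicate(nk, randKernel(n), simplify = FALSE)
    th <- runif(nk, 0, 0.4)
    s2 <- runif(1, 0.5, 3)
    X <- cbind(rnorm(n))
    betas <- rnorm(2)
    y <- rnorm(n)
    Om <- s2 * Reduce(`+`, Map(`*`, th, kernels)) +
      s2 * (1 - sum(th)) * diag(n)
    expect_equal(
      vcLogLik(y, X, kernels, th, s2, betas),
      denseLogLik(y, cbind(1, X), betas, Om),
      tolerance = 1e-9)
  }
})

test_that("log-likelihood is location invariant through the intercept", {
  set.seed(3)
  n <- 12
  y <- rnorm(n)
  K <- randKernel(n)
  ll1 <- vcLogLik(y, kernels = list(K), fractions = 0.3, sigma2 = 1.2,
                  betas = 0.7)
  ll2 <- vcLogLik(y + 5, kernels = list(K), fractions = 0.3, sigma2 = 1.2,
                  betas = 5.7)
  expect_equal(ll1, ll2, tolerance = 1e-10)
})

test_that("ML fit recovers a polygenic-only simulation and is deterministic", {
  ped <- simulatePedigree(nFamilies = 60, seed = 5)
  A <- additiveMatrix(kinshipMatrix(ped))
  n <- nrow(A)
  set.seed(6)
  h2 <- 0.5
  ests <- replicate(20, {
    y <- sqrt(h2) * drop(t(chol(A)) %*% rnorm(n)) + sqrt(1 - h2) * rnorm(n)
    ft <- fitVarComp(y, kernels = list(h_r2 = A))
    unname(ft@fractions)
  })
  expect_lt(abs(mean(ests) - h2), 0.07)

  set.seed(7)
  y <- drop(t(chol(A)) %*% rnorm(n))
  f1 <- fitVarComp(y, kernels = list(h_r2 = A))
  f2 <- fitVarComp(y, kernels = list(h_r2 = A))
  expect_identical(fitLogLik(f1), fitLogLik(f2))  # bit-identical rerun
})

test_that("null simulations on founders-only structure estimate h2 near 0", {
  # unrelated individuals: no information for h_r2, estimates pile up at 0
  A <- diag(1, 300)
  dimnames(A) <- list(paste0("s", 1:300), paste0("s", 1:300))
  set.seed(8)
  hits <- replicate(50, {
    y <- rnorm(300)
    fitVarComp(y, kernels = list(h_r2 = A))@fractions
  })
  expect_gt(mean(hits <= 0.1), 0.9)
})

test_that("two-component fits satisfy nesting and handle aliased kernels", {
  sim <- simulateDataset(seed = 31, nFamilies = 20)
  A <- sim$phi2
  # aliased: E = 2*Phi exactly; full loglik must equal the null's
  nf <- fitNullAndFull(sim$trait, as.matrix(sim$covariates), A, A)
  expect_lt(abs(fitLogLik(nf$full) - fitLogLik(nf$null)), 1e-6)
  expect_true(nf$full@converged)

  # null-true data: LRT >= 0 always, across replicates
  K <- kernelMatrix(sim$kernels[[3]])
  for (seed in 1:5) {
    tr <- simulateTrait(sim$ped, sim$kernels, traitHr2 = 0.3, seed = seed)
    nf <- fitNullAndFull(tr$trait, as.matrix(tr$covariates), A, K)
    expect_gte(2 * (fitLogLik(nf$full) - fitLogLik(nf$null)), 0)
  }
})

test_that("scale equivariance: fractions and LRT unchanged, sigma2 scales", {
  sim <- simulateDataset(seed = 33, nFamilies = 20, traitHmeth2 = 0.3,
                         causalGenes = "G001")
  X <- as.matrix(sim$covariates)
  K <- sim$kernels[["G001"]]
  f1 <- fitNullAndFull(sim$trait, X, sim$phi2, K)
  f2 <- fitNullAndFull(3 * sim$trait, 3 * X, sim$phi2, K)
  expect_equal(varFractions(f2$full), varFractions(f1$full),
               tolerance = 1e-6)
  expect_equal(sigma2Total(f2$full) / sigma2Total(f1$full), 9,
               tolerance = 1e-6)
  lrt1 <- 2 * (fitLogLik(f1$full) - fitLogLik(f1$null))
  lrt2 <- 2 * (fitLogLik(f2$full) - fitLogLik(f2$null))
  expect_equal(lrt1, lrt2, tolerance = 1e-6)
})

test_that("fit reports respect the simplex and expose accessors", {
  sim <- simulateDataset(seed = 35, nFamilies = 15)
  ft <- fitVarComp(sim$trait, as.matrix(sim$covariates),
                   list(h_r2 = sim$phi2,
                        h_meth2 = kernelMatrix(sim$kernels[[1]])))
  fr <- varFractions(ft)
  expect_equal(sum(fr), 1, tolerance = 1e-8)
  expect_true(all(fr >= 0 & fr <= 1))
  expect_named(fixedEffects(ft), c("(Intercept)", "sex", "age"))
  expect_gt(sigma2Total(ft), 0)
})

test_that("input contracts are enforced", {
  A <- diag(1, 20)
  dimnames(A) <- list(paste0("s", 1:20), paste0("s", 1:20))
  expect_error(fitVarComp(rnorm(5), kernels = list(A[1:5, 1:5])),
               "at least 10")
  expect_error(fitVarComp(rnorm(20), covariates = cbind(1, 1:20),
                          kernels = list(A)), "rank deficient")
  expect_error(fitVarComp(rnorm(20), kernels = list(A, A, A)), "1 or 2")
})

test_that("REML option runs and gives a sensible fraction", {
  sim <- simulateDataset(seed = 37, nFamilies = 30, traitHr2 = 0.5)
  fr <- fitVarComp(sim$trait, as.matrix(sim$covariates),
                   list(h_r2 = sim$phi2), method = "REML")@fractions
  expect_true(fr >= 0 && fr <= 1)
})
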
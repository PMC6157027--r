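# Small in-code fixtures shared across test files.

# classic trio: child with two founder parents
trioLines <- c("c f m 1", "f 0 0 1", "m 0 0 2")

writeTempLines <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}

# pedigree with a full-sib mating: s1 x s2 are full sibs, k is their child
sibMatingPed <- function() {
  Pedigree(id = c("f", "m", "s1", "s2", "k"),
           father = c(NA, NA, "f", "f", "s1"),
           mother = c(NA, NA, "m", "m", "s2"),
           sex = c("male", "female", "male", "female", "unknown"))
}

# tiny beta-scale methylation TSV (3 sites x 4 samples)
toyMethLines <- c(
  "site_id\ts1\ts2\ts3\ts4",
  "cg1\t0.1\t0.2\t0.3\t0.4",
  "cg2\t0.5\t0.5\t0.6\t0.7",
  "cg3\t0.9\t0.8\t0.7\t0.6")

# MethylationSet directly from a matrix of normal scores
normalScoreSet <- function(values) MethylationSet(values, transformed = TRUE)

# random standardized Z and matching brute-force correlation kernel
bruteForceKernel <- function(Z) {
  n <- nrow(Z)
  K <- matrix(0, n, n, dimnames = list(rownames(Z), rownames(Z)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- sum(Z[i, ] * Z[j, ])
      K[i, j] <- num / sqrt(sum(Z[i, ]^2) * sum(Z[j, ]^2))
    }
  }
  K
}

# dense closed-form MVN log-likelihood, independent of the package's
# Cholesky-based evaluation (determinant + solve)
denseLogLik <- function(y, X, betas, Omega) {
  r <- y - drop(X %*% betas)
  n <- length(y)
  ld <- as.numeric(determinant(Omega, logarithm = TRUE)$modulus)
  -0.5 * (n * log(2 * pi) + ld + drop(crossprod(r, solve(Omega, r))))
}
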
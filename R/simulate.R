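# Synthetic family data with known ground truth. The generator emulates the
# structure the analysis assumes: family-structured samples, per-site
# heritable methylation with an optional family-confounded batch factor
# (which inflates naive per-site heritability until PC-corrected), and a
# quantitative trait with specified polygenic and gene-methylation variance
# fractions.

#' Simulate a family-structured pedigree
#'
#' Families are mutually unrelated. `"nuclear"` families consist of two
#' founder parents and `nOffspring` children; `"threegen"` families of a
#' grandparental founder couple, their child, a married-in founder and two
#' grandchildren (6 members).
#'
#' @param nFamilies number of families.
#' @param familyShape `"nuclear"` (default) or `"threegen"`.
#' @param nOffspring offspring per nuclear family, default 3.
#' @param seed integer seed (offspring sexes are random).
#' @return a [Pedigree-class] with family labels.
#' @examples
#' simulatePedigree(10, seed = 1)  # 50 individuals
#' @export
simulatePedigree <- function(nFamilies, familyShape = c("nuclear", "threegen"),
                             nOffspring = 3L, seed) {
  familyShape <- match.arg(familyShape)
  stopifnot(nFamilies >= 1)
  if (missing(seed)) stop("a seed is required")
  set.seed(as.integer(seed))
  recs <- lapply(seq_len(nFamilies), function(f) {
    fam <- sprintf("F%03d", f)
    pid <- function(s) paste0(fam, "_", s)
    if (familyShape == "nuclear") {
      kid <- paste0("O", seq_len(nOffspring))
      data.frame(
        id = pid(c("P1", "P2", kid)),
        father = c(NA, NA, rep(pid("P1"), nOffspring)),
        mother = c(NA, NA, rep(pid("P2"), nOffspring)),
        sex = c("male", "female",
                ifelse(runif(nOffspring) < 0.5, "male", "female")),
        family = fam)
    } else {
      data.frame(
        id = pid(c("GP1", "GP2", "P1", "P2", "O1", "O2")),
        father = c(NA, NA, pid("GP1"), NA, pid("P1"), pid("P1")),
        mother = c(NA, NA, pid("GP2"), NA, pid("P2"), pid("P2")),
        sex = c("male", "female", "male", "female",
                ifelse(runif(2) < 0.5, "male", "female")),
        family = fam)
    }
  })
  df <- do.call(rbind, recs)
  Pedigree(df$id, df$father, df$mother, df$sex, df$family)
}

#' Simulate heritable methylation with an optional batch factor
#'
#' Each site's latent Gaussian value is \eqn{g + \lambda_s b + \epsilon} with
#' \eqn{g \sim MVN(0, h^2_{site} \cdot 2\Phi)},
#' \eqn{\epsilon \sim N(0, 1 - h^2_{site})}, per-site batch loadings
#' \eqn{\lambda_s \sim U(0.5, 1)} and a batch factor `b` drawn once per
#' family (`N(0, batchSd^2)`) — experimental batches confounded with family
#' structure, which is what inflates naive per-site heritability estimates
#' until the shared direction is removed by PC correction. Latent values are
#' mapped to the \[0, 1\] beta scale through the standard normal CDF, so the
#' rank-based inverse-normal transformation recovers the Gaussian scale.
#'
#' Sites are assigned to `nGenes` genes with per-gene site counts drawn
#' uniformly from `sitesPerGene`; leftover sites stay unannotated.
#'
#' @param ped a [Pedigree-class].
#' @param nSites total number of methylation sites, default 1000.
#' @param nGenes number of annotated genes, default 50.
#' @param sitesPerGene inclusive integer range of per-gene site counts,
#'   default `c(5, 30)`.
#' @param siteH2 true per-site heritability: a scalar or a length-`nSites`
#'   vector, default 0.2.
#' @param batchSd standard deviation of the family-level batch factor,
#'   default 0 (no batch).
#' @param seed integer seed.
#' @return list with elements `meth` (a beta-scale [MethylationSet-class]),
#'   `annotation` (site/gene/chromosome/position data.frame) and `truth`
#'   (per-site h2, batch loadings, batch factor per sample).
#' @export
simulateMethylation <- function(ped, nSites = 1000L, nGenes = 50L,
                                sitesPerGene = c(5L, 30L), siteH2 = 0.2,
                                batchSd = 0, seed) {
  if (missing(seed)) stop("a seed is required")
  set.seed(as.integer(seed))
  ids <- sampleIds(ped)
  n <- length(ids)
  h2 <- rep_len(siteH2, nSites)
  stopifnot(all(h2 >= 0), all(h2 <= 1), batchSd >= 0)
  A <- additiveMatrix(kinshipMatrix(ped))
  Lt <- t(chol(A))
  siteIdv <- sprintf("cg%05d", seq_len(nSites))
  G <- Lt %*% matrix(rnorm(n * nSites), n, nSites)      # cols ~ MVN(0, A)
  lambda <- runif(nSites, 0.5, 1)
  bFam <- rnorm(length(unique(ped@family)), 0, batchSd)
  b <- bFam[match(ped@family, unique(ped@family))]
  eps <- matrix(rnorm(nSites * n), nSites, n)
  latent <- sweep(t(G), 1, sqrt(h2), `*`) +
    tcrossprod(lambda, b) +
    sweep(eps, 1, sqrt(1 - h2), `*`)
  beta <- pnorm(latent)
  dimnames(beta) <- list(siteIdv, ids)
  lo <- sitesPerGene[1]
  if (nGenes * lo > nSites)
    stop("nSites too small for ", nGenes, " genes of >= ", lo, " sites")
  counts <- sample(seq(lo, sitesPerGene[2]), nGenes, replace = TRUE)
  while (sum(counts) > nSites) {   # trim the largest genes to fit
    i <- which.max(counts)
    counts[i] <- counts[i] - 1L
  }
  geneIdv <- sprintf("G%03d", seq_len(nGenes))
  assign <- rep(geneIdv, counts)
  ann <- data.frame(
    site_id = siteIdv[seq_along(assign)],
    gene_id = assign,
    chromosome = as.character((match(assign, geneIdv) - 1L) %% 22L + 1L),
    position = 1e6 * match(assign, geneIdv) +
      500 * (sequence(counts) - 1L))
  truth <- list(siteH2 = setNames(h2, siteIdv), lambda = lambda,
                batch = setNames(b, ids), geneSiteCounts = setNames(counts,
                geneIdv))
  list(meth = MethylationSet(beta), annotation = ann, truth = truth)
}

#' Simulate a quantitative trait from the variance-component model
#'
#' Generates `trait = X beta + u_poly + sum u_gene + eps` with
#' \eqn{u_{poly} \sim MVN(0, \sigma^2 h_r^2 \cdot 2\Phi)}, one
#' \eqn{u_{gene} \sim MVN(0, \sigma^2 h_{meth}^2/|causal| \cdot K_{gene})}
#' per causal gene, and \eqn{\epsilon \sim MVN(0, \sigma^2 e^2 I)} where
#' \eqn{e^2 = 1 - h_r^2 - h_{meth}^2}. Fixed effects are sex (female = 1)
#' and age with coefficients 0.5 and 0.01.
#'
#' @param ped a [Pedigree-class].
#' @param kernels named list of [MethylKernel-class] objects (may be empty).
#' @param traitHr2 polygenic variance fraction, default 0.3.
#' @param traitHmeth2 total methylation-kernel fraction, default 0.
#' @param causalGenes gene ids receiving the methylation effect; must be
#'   names of `kernels` when `traitHmeth2 > 0`.
#' @param sigma2Total total trait variance, default 1.
#' @param seed integer seed.
#' @return list: `trait` (named numeric), `covariates` (data.frame sex01,
#'   age), `truth` (realized polygenic and gene effects).
#' @export
simulateTrait <- function(ped, kernels = list(), traitHr2 = 0.3,
                          traitHmeth2 = 0, causalGenes = character(0),
                          sigma2Total = 1, seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(traitHr2 >= 0, traitHmeth2 >= 0, traitHr2 + traitHmeth2 <= 1)
  if (traitHmeth2 > 0 && !length(causalGenes))
    stop("traitHmeth2 > 0 requires causalGenes")
  if (length(bad <- setdiff(causalGenes, names(kernels))))
    stop("causal gene(s) without kernel: ", paste(bad, collapse = ", "))
  set.seed(as.integer(seed))
  ids <- sampleIds(ped)
  n <- length(ids)
  sex01 <- as.numeric(ped@sex == "female")
  age <- round(runif(n, 20, 70))
  A <- additiveMatrix(kinshipMatrix(ped))
  uPoly <- sqrt(sigma2Total * traitHr2) * drop(t(chol(A)) %*% rnorm(n))
  uGenes <- rep(0, n)
  gTruth <- list()
  for (g in causalGenes) {
    K <- kernelMatrix(kernels[[g]])[ids, ids]
    ed <- eigen(K, symmetric = TRUE)
    if (min(ed$values) < -1e-8)
      stop("kernel for ", g, " is not PSD within tolerance")
    L <- ed$vectors %*% (sqrt(pmax(ed$values, 0)) * t(ed$vectors))
    ug <- sqrt(sigma2Total * traitHmeth2 / length(causalGenes)) *
      drop(L %*% rnorm(n))
    gTruth[[g]] <- ug
    uGenes <- uGenes + ug
  }
  e2 <- 1 - traitHr2 - traitHmeth2
  eps <- sqrt(sigma2Total * e2) * rnorm(n)
  trait <- 0.5 * sex01 + 0.01 * age + uPoly + uGenes + eps
  names(trait) <- ids
  list(trait = trait,
       covariates = data.frame(sex = sex01, age = age, row.names = ids),
       truth = list(uPoly = setNames(uPoly, ids), uGenes = gTruth,
                    e2 = e2))
}

#' Simulate a complete analysis-ready dataset
#'
#' Convenience wrapper: pedigree, methylation (+annotation), gene index,
#' gene kernels built from the inverse-normalized methylation, and a trait
#' simulated from the chosen causal kernels. The `"desk"` preset (40 nuclear
#' families of 5 = 200 samples, 1000 sites, 50 genes with 5-30 sites each,
#' site h2 = 0.2, no batch, polygenic trait fraction 0.3, no causal gene)
#' runs end to end in seconds; every default can be overridden.
#'
#' @param preset `"desk"` or `"none"` (then all values come from arguments).
#' @param seed integer seed driving every random step.
#' @param nFamilies,familyShape,nOffspring pedigree layout.
#' @param nSites,nGenes,sitesPerGene,siteH2,batchSd methylation layout.
#' @param traitHr2,traitHmeth2,causalGenes,sigma2Total trait model.
#' @param minSites kernel eligibility threshold, default 5.
#' @return list: `ped`, `kinship`, `phi2`, `meth` (beta scale), `methNorm`
#'   (inverse-normalized), `annotation`, `index`, `kernels`, `trait`,
#'   `covariates`, `truth`, `config`.
#' @export
simulateDataset <- function(preset = c("desk", "none"), seed,
                            nFamilies = 40L, familyShape = "nuclear",
                            nOffspring = 3L, nSites = 1000L, nGenes = 50L,
                            sitesPerGene = c(5L, 30L), siteH2 = 0.2,
                            batchSd = 0, traitHr2 = 0.3, traitHmeth2 = 0,
                            causalGenes = character(0), sigma2Total = 1,
                            minSites = 5L) {
  preset <- match.arg(preset)
  if (missing(seed)) stop("a seed is required")
  seed <- as.integer(seed)
  ped <- simulatePedigree(nFamilies, familyShape, nOffspring, seed = seed)
  sim <- simulateMethylation(ped, nSites, nGenes, sitesPerGene, siteH2,
                             batchSd, seed = seed + 1L)
  methNorm <- inverseNormalize(sim$meth)
  index <- buildGeneIndex(sim$annotation, minSites = minSites)
  kernels <- kernelScan(methNorm, index)
  tr <- simulateTrait(ped, kernels, traitHr2, traitHmeth2, causalGenes,
                      sigma2Total, seed = seed + 2L)
  kin <- kinshipMatrix(ped)
  list(ped = ped, kinship = kin, phi2 = additiveMatrix(kin), meth = sim$meth,
       methNorm = methNorm, annotation = sim$annotation, index = index,
       kernels = kernels, trait = tr$trait, covariates = tr$covariates,
       truth = c(sim$truth, tr$truth),
       config = list(preset = preset, seed = seed, nFamilies = nFamilies,
                     familyShape = familyShape, nOffspring = nOffspring,
                     nSites = nSites, nGenes = nGenes,
                     sitesPerGene = sitesPerGene, siteH2 = siteH2,
                     batchSd = batchSd, traitHr2 = traitHr2,
                     traitHmeth2 = traitHmeth2, causalGenes = causalGenes,
                     sigma2Total = sigma2Total, minSites = minSites))
}

#' Write a simulated dataset to disk in the formats the readers consume
#'
#' Writes `pedigree.tsv`, `methylation.tsv`, `annotation.tsv`,
#' `phenotype.tsv` and `truth.json` into `dir`.
#'
#' @param sim list from [simulateDataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ped <- sim$ped
  write.table(
    data.frame(id = ped@id,
               father = ifelse(is.na(ped@father), "0", ped@father),
               mother = ifelse(is.na(ped@mother), "0", ped@mother),
               sex = ped@sex, family = ped@family),
    file.path(dir, "pedigree.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  writeMethylation(sim$meth, file.path(dir, "methylation.tsv"))
  write.table(sim$annotation, file.path(dir, "annotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(
    data.frame(sample_id = names(sim$trait), trait = unname(sim$trait),
               sim$covariates),
    file.path(dir, "phenotype.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  truth <- sim$truth
  truth$uGenes <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
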
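#' Sample identifiers of an object
#'
#' @param x a `Pedigree`, `KinshipMatrix`, `MethylationSet`, `PCModel` or
#'   `MethylKernel`.
#' @return character vector of sample/individual ids, in the object's order.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Site identifiers of a methylation container
#' @param x a `MethylationSet`.
#' @return character vector of site ids.
#' @export
setGeneric("siteIds", function(x) standardGeneric("siteIds"))

#' Kernel-eligible gene identifiers
#' @param x a `GeneSiteIndex`.
#' @return character vector of gene ids (sorted).
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Has the inverse-normal transformation been applied?
#' @param x a `MethylationSet`.
#' @return logical flag.
#' @export
setGeneric("isTransformed", function(x) standardGeneric("isTransformed"))

#' Expected kinship matrix from a pedigree
#'
#' Computes the expected kinship coefficients \eqn{\phi_{ij}} by the standard
#' recursive (tabular) method over a topological order of the pedigree:
#' \eqn{\phi_{ii} = (1 + \phi_{fm})/2} and, for j already processed,
#' \eqn{\phi_{ij} = (\phi_{fj} + \phi_{mj})/2}, missing parents contributing 0.
#'
#' @param ped a [Pedigree-class] object.
#' @return a [KinshipMatrix-class]; rows/columns follow the pedigree's
#'   first-appearance order.
#' @examples
#' ped <- Pedigree(id = c("f", "m", "c"), father = c(NA, NA, "f"),
#'                 mother = c(NA, NA, "m"), sex = c("male", "female", "unknown"))
#' phi(kinshipMatrix(ped))["f", "c"]  # parent-offspring: 0.25
#' @export
setGeneric("kinshipMatrix", function(ped) standardGeneric("kinshipMatrix"))

#' Additive (numerator) relationship matrix
#'
#' Returns \eqn{2\Phi}, the additive genetic relationship matrix entering the
#' polygenic variance component; diagonal is 1 for outbred individuals.
#'
#' @param x a [KinshipMatrix-class] (or a plain kinship matrix).
#' @return symmetric numeric matrix `2 * phi(x)`.
#' @export
setGeneric("additiveMatrix", function(x) standardGeneric("additiveMatrix"))

#' Rank-based inverse-normal transformation, per site
#'
#' Replaces each site row by Blom-offset normal scores
#' \eqn{\Phi^{-1}((r_i - c) / (n - 2c + 1))} where \eqn{r_i} is the (average,
#' for ties) rank among the site's non-missing values and `offset` is c
#' (default 3/8). Missing values are excluded from ranking and stay missing;
#' sites with fewer than 3 non-missing values are dropped with a warning.
#'
#' @param x a `MethylationSet` with `isTransformed(x)` FALSE.
#' @param offset rank offset c, default `3/8` (Blom).
#' @return a transformed `MethylationSet`.
#' @export
setGeneric("inverseNormalize",
           function(x, offset = 3/8) standardGeneric("inverseNormalize"))

#' Fit principal components on a random subset of sites
#'
#' Randomizes the (inverse-normalized) sites with the given seed, keeps the
#' first `floor(subsetFraction * nSites)` of them, and computes principal
#' components with samples as observations and the subset sites as centered,
#' unscaled variables. Each sample receives one score per component; scores
#' are the batch-structure covariates used by [residualize()] and
#' [siteH2Scan()]. Subset membership depends only on the site-id set and the
#' seed, so the fit is invariant to site row order.
#'
#' @param x a transformed `MethylationSet`.
#' @param subsetFraction fraction of sites used, default 0.10.
#' @param nComponents number of leading components kept, default 20.
#' @param seed integer seed (mandatory).
#' @return a [PCModel-class].
#' @export
setGeneric("fitPCs",
  function(x, subsetFraction = 0.10, nComponents = 20L, seed)
    standardGeneric("fitPCs"))

#' Residualize site values on principal-component scores
#'
#' Replaces every site row by the residuals of its least-squares regression on
#' an intercept plus the PC scores, removing batch-like structure before
#' kernel construction. Idempotent; with a 0-component model it reduces to
#' row centering.
#'
#' @param x a `MethylationSet`.
#' @param pcs a [PCModel-class] fitted on the same samples.
#' @return a `MethylationSet` of residuals (`isTransformed` stays TRUE).
#' @export
setGeneric("residualize", function(x, pcs) standardGeneric("residualize"))

#' Build every eligible gene-specific methylation kernel
#'
#' For each kernel-eligible gene (deterministic, sorted gene-id order) the
#' gene-linked site rows are standardized ([standardizeSites()]) and turned
#' into a unit-diagonal kernel ([buildKernel()]). Genes whose usable site
#' count falls below the index threshold (e.g. after constant-site drops) are
#' skipped and listed, with reasons, in the `"skipped"` attribute of the
#' result.
#'
#' @param x a transformed (and typically PC-corrected) `MethylationSet`.
#' @param index a [GeneSiteIndex-class].
#' @param sdMethod standard-deviation convention for standardization,
#'   `"sample"` (n-1, default) or `"population"`.
#' @param maxMissing maximum tolerated per-site missingness, default 0.2.
#' @return named list of [MethylKernel-class] objects with attribute
#'   `"skipped"` (data.frame: gene_id, reason).
#' @export
setGeneric("kernelScan",
  function(x, index, sdMethod = c("sample", "population"), maxMissing = 0.2)
    standardGeneric("kernelScan"))

#' Kinship coefficients as a plain matrix
#' @param x a `KinshipMatrix`.
#' @return the symmetric numeric matrix of kinship coefficients.
#' @export
setGeneric("phi", function(x) standardGeneric("phi"))

#' Kernel matrix accessor
#' @param x a `MethylKernel`.
#' @return the symmetric unit-diagonal kernel matrix.
#' @export
setGeneric("kernelMatrix", function(x) standardGeneric("kernelMatrix"))

#' PC score accessor
#' @param x a `PCModel`.
#' @return samples x components score matrix.
#' @export
setGeneric("pcScores", function(x) standardGeneric("pcScores"))

#' Variance fractions of a fit
#' @param x a `VarCompFit`.
#' @return named vector of kernel fractions plus `e2`.
#' @export
setGeneric("varFractions", function(x) standardGeneric("varFractions"))

#' Maximized log-likelihood of a fit
#' @param x a `VarCompFit`.
#' @return numeric log-likelihood.
#' @export
setGeneric("fitLogLik", function(x) standardGeneric("fitLogLik"))
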
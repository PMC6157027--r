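#' @import methods
#' @useDynLib methylVC, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay
#' @importFrom S4Vectors metadata
#' @importFrom stats qnorm pnorm pchisq rnorm runif optimize rbinom setNames
#'   complete.cases sd var cor prcomp lm.fit quantile ks.test
#' @importFrom utils read.delim write.table packageVersion
NULL

#' Pedigree of related individuals
#'
#' Holds a validated pedigree: one record per individual with optional father,
#' mother and family labels. Parents must themselves be listed (founders have
#' both parents missing; half-founders one) and the parent graph must be
#' acyclic. Construct with [readPedigree()] or [Pedigree()].
#'
#' @slot id character vector of unique individual identifiers.
#' @slot father,mother character vectors of parent ids (`NA` = unknown/founder).
#' @slot sex character vector, one of `"male"`, `"female"`, `"unknown"`.
#' @slot family character vector of family labels (`NA` allowed).
#'
#' @seealso [kinshipMatrix()], [simulatePedigree()]
#' @exportClass Pedigree
setClass("Pedigree",
  representation(id = "character", father = "character", mother = "character",
                 sex = "character", family = "character"))

setValidity("Pedigree", function(object) {
  msg <- character()
  n <- length(object@id)
  if (any(lengths(list(object@father, object@mother, object@sex,
                       object@family)) != n))
    return("id, father, mother, sex and family must have equal length")
  dup <- unique(object@id[duplicated(object@id)])
  if (length(dup))
    msg <- c(msg, paste0("duplicate individual id(s): ",
                         paste(dup, collapse = ", ")))
  par <- c(object@father, object@mother)
  bad <- unique(setdiff(par[!is.na(par)], object@id))
  if (length(bad))
    msg <- c(msg, paste0("unknown parent id(s): ",
                         paste(bad, collapse = ", ")))
  if (!all(object@sex %in% c("male", "female", "unknown")))
    msg <- c(msg, "sex must be one of 'male', 'female', 'unknown'")
  if (!length(msg)) {
    ord <- .pedTopoOrder(object@id, object@father, object@mother)
    cyc <- attr(ord, "cycle")
    if (!is.null(cyc))
      msg <- c(msg, paste0("pedigree contains a cycle involving: ",
                           paste(cyc, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Expected kinship matrix
#'
#' Symmetric matrix of expected kinship coefficients \eqn{\phi_{ij}} (the
#' probability that one allele drawn at random from each of two individuals is
#' identical by descent), computed from a pedigree. Twice this matrix is the
#' additive (numerator) relationship matrix used as the polygenic structuring
#' kernel.
#'
#' @slot phi symmetric numeric matrix with individual ids as dimnames; entries
#'   in \[0, 1\], founder diagonal 0.5.
#'
#' @seealso [kinshipMatrix()], [additiveMatrix()]
#' @exportClass KinshipMatrix
setClass("KinshipMatrix", representation(phi = "matrix"))

setValidity("KinshipMatrix", function(object) {
  p <- object@phi
  if (is.null(rownames(p)) || is.null(colnames(p)))
    return("phi must carry individual ids as dimnames")
  if (!identical(rownames(p), colnames(p)))
    return("phi row and column names differ")
  if (max(abs(p - t(p))) > 1e-12) return("phi is not symmetric")
  if (min(p) < 0 || max(p) > 1) return("kinship coefficients must be in [0, 1]")
  TRUE
})

#' Methylation matrix container
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding a sites-by-samples
#' methylation matrix (assay `"meth"`). Before transformation values are beta
#' values in \[0, 1\]; after [inverseNormalize()] (or [residualize()]) they are
#' unbounded rank-normal scores and `isTransformed()` is `TRUE`.
#'
#' @slot transformed logical flag: has the per-site rank-based inverse-normal
#'   transformation been applied?
#'
#' @seealso [readMethylation()], [inverseNormalize()], [fitPCs()]
#' @exportClass MethylationSet
setClass("MethylationSet",
  contains = "SummarizedExperiment",
  representation(transformed = "logical"))

setValidity("MethylationSet", function(object) {
  v <- SummarizedExperiment::assay(object, "meth")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("site and sample ids are required as dimnames")
  if (anyDuplicated(rownames(v))) return("duplicate site ids")
  if (anyDuplicated(colnames(v))) return("duplicate sample ids")
  if (length(object@transformed) != 1L) return("transformed must be a flag")
  if (!object@transformed) {
    r <- suppressWarnings(range(v, na.rm = TRUE))
    if (is.finite(r[1]) && (r[1] < -1e-9 || r[2] > 1 + 1e-9))
      return("untransformed beta values must lie in [0, 1]")
  }
  TRUE
})

#' Gene-to-site index
#'
#' Maps each kernel-eligible gene (one with at least `minSites` annotated
#' methylation sites) to its ordered site ids. Built by [buildGeneIndex()].
#'
#' @slot index named list, gene id -> character vector of site ids.
#' @slot minSites integer eligibility threshold (inclusive).
#' @slot dropped data.frame of excluded genes (`gene_id`, `n_sites`).
#'
#' @exportClass GeneSiteIndex
setClass("GeneSiteIndex",
  representation(index = "list", minSites = "integer", dropped = "data.frame"))

setValidity("GeneSiteIndex", function(object) {
  if (length(object@index) && is.null(names(object@index)))
    return("index must be a named list")
  if (any(lengths(object@index) < object@minSites))
    return("index contains genes below the minSites threshold")
  TRUE
})

#' Principal components of a methylation matrix
#'
#' Principal components fitted on a seeded random subset of (inverse-normalized)
#' methylation sites, with samples as observations: each sample receives one
#' score per component, suitable as fixed-effect covariates or for
#' residualizing site values ([residualize()]).
#'
#' @slot scores samples x components numeric matrix (centered columns).
#' @slot explainedVariance fraction of subset variance per component,
#'   non-increasing.
#' @slot nComponents,seed integers recording the fit configuration.
#' @slot subsetFraction fraction of sites sampled for the fit.
#' @slot subsetSites character vector of the site ids actually used.
#'
#' @exportClass PCModel
setClass("PCModel",
  representation(scores = "matrix", explainedVariance = "numeric",
                 nComponents = "integer", subsetFraction = "numeric",
                 seed = "integer", subsetSites = "character"))

setValidity("PCModel", function(object) {
  if (ncol(object@scores) != object@nComponents)
    return("scores must have nComponents columns")
  if (object@nComponents > 0 && is.null(rownames(object@scores)))
    return("scores must carry sample ids as rownames")
  ev <- object@explainedVariance
  if (length(ev) > 1 && any(diff(ev) > 1e-12))
    return("explainedVariance must be non-increasing")
  TRUE
})

#' Gene-specific methylation relationship kernel
#'
#' Samples-by-samples covariance kernel K for one gene: gene-linked site
#' vectors are standardized into Z (samples x sites), R = Z Z^T is formed and
#' scaled to exact unit diagonal. K is symmetric positive semi-definite with
#' off-diagonals in \[-1, 1\].
#'
#' @slot geneId gene identifier.
#' @slot K symmetric numeric matrix with sample ids as dimnames, unit diagonal.
#' @slot nSites number of usable sites that entered the kernel.
#'
#' @seealso [buildKernel()], [kernelScan()]
#' @exportClass MethylKernel
setClass("MethylKernel",
  representation(geneId = "character", K = "matrix", nSites = "integer"))

setValidity("MethylKernel", function(object) {
  K <- object@K
  if (is.null(rownames(K)) || !identical(rownames(K), colnames(K)))
    return("K must carry matching sample ids as dimnames")
  if (max(abs(K - t(K))) > 1e-12) return("K is not symmetric")
  if (max(abs(diag(K) - 1)) > 1e-10) return("K diagonal must equal 1")
  if (max(abs(K)) > 1 + 1e-10) return("kernel entries must lie in [-1, 1]")
  TRUE
})

#' Maximum-likelihood variance-component fit
#'
#' Result of fitting the mixed model
#' \eqn{\Omega = \sigma^2_{Total}(\sum_k h_k^2 K_k + e^2 I)} by ML with fixed
#' effects profiled by GLS and the total variance profiled in closed form.
#' Variance fractions live on the simplex (each \eqn{\ge 0}, sum with
#' \eqn{e^2} equal to 1); boundary solutions are exact.
#'
#' @slot sigma2 total phenotypic variance estimate (trait units squared).
#' @slot fractions named numeric vector of per-kernel variance fractions.
#' @slot e2 residual (environmental) fraction, `1 - sum(fractions)`.
#' @slot betas named fixed-effect estimates.
#' @slot loglik maximized log-likelihood.
#' @slot converged logical.
#' @slot nEvals number of covariance-structure evaluations used.
#' @slot method `"ML"` or `"REML"`.
#'
#' @seealso [fitVarComp()], [fitNullAndFull()]
#' @exportClass VarCompFit
setClass("VarCompFit",
  representation(sigma2 = "numeric", fractions = "numeric", e2 = "numeric",
                 betas = "numeric", loglik = "numeric", converged = "logical",
                 nEvals = "integer", method = "character"))

setValidity("VarCompFit", function(object) {
  fr <- c(object@fractions, object@e2)
  if (any(fr < -1e-8) || any(fr > 1 + 1e-8))
    return("variance fractions must lie in [0, 1]")
  if (abs(sum(fr) - 1) > 1e-6) return("variance fractions must sum to 1")
  if (object@sigma2 <= 0) return("sigma2 must be positive")
  TRUE
})
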
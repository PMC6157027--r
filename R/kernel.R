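#' Standardize selected site rows into the Z matrix
#'
#' Extracts the given sites, transposes to samples x sites, and standardizes
#' every site column to mean 0 and unit variance over its non-missing samples.
#' Standardized missing entries are imputed to 0 (the column mean), which
#' keeps \eqn{Z Z^T} a valid Gram matrix. Constant sites and sites exceeding
#' the missingness cap are dropped with a warning and listed in the
#' `"dropped"` attribute.
#'
#' @param x a `MethylationSet`.
#' @param sites character vector of site ids (all must be present).
#' @param sdMethod `"sample"` (n-1 denominator, default) or `"population"`
#'   (n). The unit-diagonal scaling in [buildKernel()] makes the kernel
#'   invariant to this choice.
#' @param maxMissing maximum tolerated fraction of missing values per site,
#'   default 0.2.
#' @return numeric matrix Z (samples x usable sites) with attribute
#'   `"dropped"` (data.frame: site_id, reason).
#' @export
standardizeSites <- function(x, sites, sdMethod = c("sample", "population"),
                             maxMissing = 0.2) {
  sdMethod <- match.arg(sdMethod)
  miss <- setdiff(sites, siteIds(x))
  if (length(miss))
    stop("site(s) not present: ", paste(miss, collapse = ", "))
  z <- t(methValues(x)[sites, , drop = FALSE])
  n <- nrow(z)
  dropped <- data.frame(site_id = character(0), reason = character(0))
  keep <- logical(ncol(z))
  for (j in seq_len(ncol(z))) {
    col <- z[, j]
    ok <- !is.na(col)
    if (mean(!ok) > maxMissing) {
      dropped <- rbind(dropped, data.frame(site_id = sites[j],
                                           reason = "missingness"))
      next
    }
    m <- sum(ok)
    mu <- mean(col[ok])
    ss <- sum((col[ok] - mu)^2)
    s <- sqrt(ss / if (sdMethod == "sample") (m - 1) else m)
    if (m < 2L || !is.finite(s) || s < 1e-12 ||
        length(unique(col[ok])) < 2L) {
      dropped <- rbind(dropped, data.frame(site_id = sites[j],
                                           reason = "constant"))
      next
    }
    col <- (col - mu) / s
    col[!ok] <- 0
    z[, j] <- col
    keep[j] <- TRUE
  }
  if (nrow(dropped))
    warning(nrow(dropped), " site(s) dropped during standardization (",
            paste(unique(dropped$reason), collapse = ", "), ")")
  z <- z[, keep, drop = FALSE]
  attr(z, "dropped") <- dropped
  z
}

#' Build a unit-diagonal methylation kernel from a standardized Z
#'
#' Forms the cross-product \eqn{R = Z Z^T} over samples and applies the
#' scaling \eqn{K = D^{-1/2} R D^{-1/2}} with \eqn{D = diag(R)}, so that every
#' diagonal element equals 1 exactly. Equivalently K is the pairwise sample
#' correlation of the standardized site vectors.
#'
#' @param Z samples x sites matrix from [standardizeSites()]; sample ids as
#'   rownames.
#' @param geneId gene identifier stored in the kernel.
#' @return a [MethylKernel-class].
#' @export
buildKernel <- function(Z, geneId) {
  if (ncol(Z) < 1L) stop("Z has no site columns")
  if (is.null(rownames(Z))) stop("Z must carry sample ids as rownames")
  R <- tcrossprod(Z)
  d <- diag(R)
  if (any(d <= 0))
    stop("zero kernel diagonal for sample(s): ",
         paste(rownames(Z)[d <= 0], collapse = ", "))
  s <- sqrt(d)
  K <- R / tcrossprod(s)
  K <- (K + t(K)) / 2
  K[K > 1] <- 1
  K[K < -1] <- -1
  diag(K) <- 1
  new("MethylKernel", geneId = as.character(geneId), K = K,
      nSites = ncol(Z))
}

#' @rdname kernelMatrix
setMethod("kernelMatrix", "MethylKernel", function(x) x@K)

#' @rdname sampleIds
setMethod("sampleIds", "MethylKernel", function(x) rownames(x@K))

#' Gene id of a kernel
#' @param x a `MethylKernel`.
#' @return character gene id.
#' @export
kernelGene <- function(x) x@geneId

#' Number of sites behind a kernel
#' @param x a `MethylKernel`.
#' @return integer site count.
#' @export
kernelSites <- function(x) x@nSites

setMethod("show", "MethylKernel", function(object) {
  cat("MethylKernel for", object@geneId, ":", nrow(object@K), "samples,",
      object@nSites, "sites\n")
})

#' @rdname kernelScan
setMethod("kernelScan", c("MethylationSet", "GeneSiteIndex"),
  function(x, index, sdMethod = c("sample", "population"), maxMissing = 0.2) {
  sdMethod <- match.arg(sdMethod)
  genes <- geneIds(index)   # already sorted
  kernels <- list()
  skipped <- data.frame(gene_id = character(0), reason = character(0))
  for (g in genes) {
    res <- tryCatch({
      Z <- suppressWarnings(
        standardizeSites(x, geneSites(index, g), sdMethod = sdMethod,
                         maxMissing = maxMissing))
      if (ncol(Z) < index@minSites)
        stop("only ", ncol(Z), " usable site(s) after drops")
      buildKernel(Z, g)
    }, error = function(e) conditionMessage(e))
    if (is.character(res))
      skipped <- rbind(skipped, data.frame(gene_id = g, reason = res))
    else
      kernels[[g]] <- res
  }
  attr(kernels, "skipped") <- skipped
  kernels
})

#' Export a kernel as a square-matrix TSV or GCTA-GRM-like pairs
#'
#' @param kernel a [MethylKernel-class].
#' @param path output file.
#' @param format `"matrix"` (sample-id header + square matrix) or `"pairs"`
#'   (id1, id2, n_sites, value; lower triangle incl. diagonal).
#' @return `path`, invisibly.
#' @export
writeKernel <- function(kernel, path, format = c("matrix", "pairs")) {
  format <- match.arg(format)
  K <- kernelMatrix(kernel)
  if (format == "matrix") {
    df <- data.frame(sample_id = rownames(K), K, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    lt <- which(lower.tri(K, diag = TRUE), arr.ind = TRUE)
    df <- data.frame(id1 = rownames(K)[lt[, 1]], id2 = colnames(K)[lt[, 2]],
                     n_sites = kernelSites(kernel), value = K[lt])
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
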
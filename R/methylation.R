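#' Construct a MethylationSet
#'
#' @param values sites x samples numeric matrix with site ids as rownames and
#'   sample ids as colnames.
#' @param transformed has the inverse-normal transformation already been
#'   applied? Default `FALSE` (beta values in \[0, 1\]).
#' @return a [MethylationSet-class].
#' @export
MethylationSet <- function(values, transformed = FALSE) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(meth = values))
  new("MethylationSet", se, transformed = transformed)
}

#' Methylation values accessor
#' @param x a `MethylationSet`.
#' @return the sites x samples numeric matrix.
#' @export
methValues <- function(x) SummarizedExperiment::assay(x, "meth")

#' @rdname sampleIds
setMethod("sampleIds", "MethylationSet", function(x) colnames(x))

#' @rdname siteIds
setMethod("siteIds", "MethylationSet", function(x) rownames(x))

#' @rdname isTransformed
setMethod("isTransformed", "MethylationSet", function(x) x@transformed)

setMethod("show", "MethylationSet", function(object) {
  cat("MethylationSet:", nrow(object), "sites x", ncol(object), "samples;",
      if (object@transformed) "inverse-normalized" else "beta values", "\n")
})

#' Read a methylation matrix from TSV
#'
#' Expects a tab-separated file with a header of sample ids and one row per
#' site (first field the site id). The header may or may not carry a leading
#' label for the site-id column. Empty, `NA` and `NaN` cells become missing
#' values; any other non-numeric cell, and any ragged row, is a parse error
#' naming the offending line.
#'
#' @param path file path.
#' @param transformed flag passed to [MethylationSet()]; default `FALSE`.
#' @return a [MethylationSet-class].
#' @export
readMethylation <- function(path, transformed = FALSE) {
  if (!file.exists(path)) stop("methylation file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("methylation file has no data rows")
  hdr <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  row2 <- strsplit(lines[[2L]], "\t", fixed = TRUE)[[1L]]
  samples <- if (length(row2) == length(hdr)) hdr[-1L] else hdr
  if (anyDuplicated(samples))
    stop("duplicate sample id(s) in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  nc <- length(samples) + 1L
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  bad <- which(lengths(body) != nc)
  if (length(bad))
    stop("ragged row: line ", paste(bad + 1L, collapse = ", "),
         " does not have ", nc, " fields")
  ids <- vapply(body, `[[`, "", 1L)
  raw <- unlist(lapply(body, `[`, -1L), use.names = FALSE)
  missing <- raw %in% c("", "NA", "NaN", "na")
  num <- suppressWarnings(as.numeric(raw))
  badCell <- which(is.na(num) & !missing)
  if (length(badCell)) {
    line <- (badCell[1L] - 1L) %/% length(samples) + 2L
    stop("non-numeric cell '", raw[badCell[1L]], "' at line ", line)
  }
  values <- matrix(num, nrow = length(ids), byrow = TRUE,
                   dimnames = list(ids, samples))
  MethylationSet(values, transformed = transformed)
}

#' Write a methylation matrix to TSV
#' @param x a `MethylationSet`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMethylation <- function(x, path) {
  v <- methValues(x)
  df <- data.frame(site_id = rownames(v), v, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname inverseNormalize
setMethod("inverseNormalize", "MethylationSet", function(x, offset = 3/8) {
  if (x@transformed)
    stop("MethylationSet is already inverse-normalized")
  v <- methValues(x)
  nOK <- rowSums(!is.na(v))
  if (any(nOK < 3L)) {
    warning(sum(nOK < 3L),
            " site(s) with fewer than 3 non-missing values dropped")
    v <- v[nOK >= 3L, , drop = FALSE]
  }
  out <- t(apply(v, 1L, function(row) {
    ok <- !is.na(row)
    n <- sum(ok)
    r <- rank(row[ok], ties.method = "average")
    row[ok] <- qnorm((r - offset) / (n - 2 * offset + 1))
    row
  }))
  dimnames(out) <- dimnames(v)
  MethylationSet(out, transformed = TRUE)
})

#' Read a CpG-to-gene annotation table
#'
#' TSV with one row per site-gene link; required columns `site_id` and
#' `gene_id`, optional `chromosome` and `position` (1-based bp). A site may be
#' linked to several genes (one row each).
#'
#' @param path file path.
#' @param zeroBased if `TRUE`, positions are BED-like 0-based and are shifted
#'   to 1-based on read.
#' @return data.frame with columns `site_id`, `gene_id`, and, when present,
#'   `chromosome` and `position`.
#' @export
readSiteAnnotation <- function(path, zeroBased = FALSE) {
  ann <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("site_id", "gene_id")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation lacks column(s): ", paste(miss, collapse = ", "))
  if (zeroBased && "position" %in% names(ann))
    ann$position <- ann$position + 1L
  ann
}

#' Build the gene-to-site index with the minimum-site filter
#'
#' Groups annotation rows by gene and keeps genes with at least `minSites`
#' distinct sites (inclusive threshold); this is the validity filter for
#' kernel construction, since kernels from very few sites produce spuriously
#' high pairwise correlations. Within a gene, sites are ordered by position
#' (then site id) when positions are available, otherwise by site id, so the
#' index is independent of annotation row order. Multi-gene sites contribute
#' to every gene they are linked to.
#'
#' @param annotation data.frame as returned by [readSiteAnnotation()].
#' @param minSites inclusive eligibility threshold, default 5.
#' @return a [GeneSiteIndex-class]; excluded genes are recorded in its
#'   `dropped` slot.
#' @examples
#' ann <- data.frame(site_id = paste0("cg", 1:8),
#'                   gene_id = rep(c("A", "B"), c(3, 5)))
#' geneIds(buildGeneIndex(ann))          # "B" only
#' geneIds(buildGeneIndex(ann, minSites = 1))
#' @export
buildGeneIndex <- function(annotation, minSites = 5L) {
  minSites <- as.integer(minSites)
  if (nrow(annotation) == 0L) {
    warning("empty annotation: gene index is empty")
    return(new("GeneSiteIndex", index = structure(list(), names = character(0)),
               minSites = minSites,
               dropped = data.frame(gene_id = character(0),
                                    n_sites = integer(0))))
  }
  hasPos <- "position" %in% names(annotation)
  rows <- split(seq_len(nrow(annotation)), annotation$gene_id)
  index <- lapply(rows, function(i) {
    sub <- annotation[i, , drop = FALSE]
    sub <- sub[!duplicated(sub$site_id), , drop = FALSE]
    o <- if (hasPos) order(sub$position, sub$site_id) else order(sub$site_id)
    sub$site_id[o]
  })
  index <- index[order(names(index))]
  n <- lengths(index)
  dropped <- data.frame(gene_id = names(index)[n < minSites],
                        n_sites = unname(n[n < minSites]))
  if (nrow(dropped))
    message(nrow(dropped), " gene(s) below the ", minSites, "-site threshold")
  new("GeneSiteIndex", index = index[n >= minSites], minSites = minSites,
      dropped = dropped)
}

#' @rdname geneIds
setMethod("geneIds", "GeneSiteIndex", function(x) names(x@index))

#' Site ids linked to one gene
#' @param index a `GeneSiteIndex`.
#' @param gene gene id.
#' @return character vector of site ids.
#' @export
geneSites <- function(index, gene) {
  if (!gene %in% names(index@index)) stop("gene not in index: ", gene)
  index@index[[gene]]
}

#' Eligibility threshold of an index
#' @param index a `GeneSiteIndex`.
#' @return integer `minSites`.
#' @export
minSites <- function(index) index@minSites

setMethod("show", "GeneSiteIndex", function(object) {
  cat("GeneSiteIndex:", length(object@index), "eligible genes (>=",
      object@minSites, "sites);", nrow(object@dropped), "excluded\n")
})
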
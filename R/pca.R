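#' @rdname fitPCs
setMethod("fitPCs", "MethylationSet",
  function(x, subsetFraction = 0.10, nComponents = 20L, seed) {
  if (!x@transformed)
    stop("fitPCs expects an inverse-normalized MethylationSet")
  if (missing(seed)) stop("a seed is required for the site subsampling")
  seed <- as.integer(seed)
  nComponents <- as.integer(nComponents)
  stopifnot(subsetFraction > 0, subsetFraction <= 1, nComponents >= 0L)
  ids <- sort(siteIds(x))
  nSub <- max(0L, as.integer(floor(subsetFraction * length(ids))))
  if (nComponents > 0L) {
    if (nSub < nComponents)
      stop("site subset (", nSub, ") smaller than nComponents (",
           nComponents, ")")
    if (nComponents > ncol(x) - 1L)
      stop("nComponents exceeds number of samples - 1")
  }
  set.seed(seed)
  sel <- sort(sample(ids)[seq_len(nSub)])
  if (nComponents == 0L) {
    sc <- matrix(numeric(0), nrow = ncol(x), ncol = 0L,
                 dimnames = list(sampleIds(x), NULL))
    return(new("PCModel", scores = sc, explainedVariance = numeric(0),
               nComponents = 0L, subsetFraction = subsetFraction,
               seed = seed, subsetSites = sel))
  }
  m <- t(methValues(x)[sel, , drop = FALSE])   # samples x subset sites
  if (anyNA(m)) {
    mu <- colMeans(m, na.rm = TRUE)
    na <- which(is.na(m), arr.ind = TRUE)
    m[na] <- mu[na[, 2L]]
  }
  pr <- prcomp(m, center = TRUE, scale. = FALSE)
  k <- seq_len(nComponents)
  scores <- pr$x[, k, drop = FALSE]
  rownames(scores) <- sampleIds(x)
  ev <- (pr$sdev^2 / sum(pr$sdev^2))[k]
  new("PCModel", scores = scores, explainedVariance = ev,
      nComponents = nComponents, subsetFraction = subsetFraction,
      seed = seed, subsetSites = sel)
})

#' @rdname pcScores
setMethod("pcScores", "PCModel", function(x) x@scores)

#' @rdname sampleIds
setMethod("sampleIds", "PCModel", function(x) rownames(x@scores))

#' Explained-variance fractions of a PC model
#' @param x a `PCModel`.
#' @return numeric vector, one fraction per kept component.
#' @export
explainedVariance <- function(x) x@explainedVariance

setMethod("show", "PCModel", function(object) {
  cat("PCModel:", object@nComponents, "components on",
      length(object@subsetSites), "subset sites (fraction",
      object@subsetFraction, ", seed", object@seed, ")\n")
})

#' @rdname residualize
setMethod("residualize", c("MethylationSet", "PCModel"), function(x, pcs) {
  sc <- pcScores(pcs)
  if (pcs@nComponents > 0L || nrow(sc) > 0L) {
    if (!setequal(rownames(sc), sampleIds(x)) ||
        is.null(rownames(sc)))
      stop("sample mismatch between MethylationSet and PCModel")
    sc <- sc[sampleIds(x), , drop = FALSE]
  }
  v <- methValues(x)
  D <- cbind(`(Intercept)` = 1, sc)
  if (!anyNA(v)) {
    # residual = y - D (D'D)^-1 D'y, vectorized over site rows
    B <- t(qr.solve(crossprod(D), t(v %*% D)))
    out <- v - B %*% t(D)
  } else {
    out <- v
    for (i in seq_len(nrow(v))) {
      ok <- !is.na(v[i, ])
      fit <- lm.fit(D[ok, , drop = FALSE], v[i, ok])
      out[i, ok] <- fit$residuals
    }
  }
  dimnames(out) <- dimnames(v)
  MethylationSet(out, transformed = TRUE)
})

#' Write PC scores to TSV
#' @param pcs a [PCModel-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePCScores <- function(pcs, path) {
  sc <- pcScores(pcs)
  colnames(sc) <- paste0("PC", seq_len(ncol(sc)))
  df <- data.frame(sample_id = rownames(sc), sc, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
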
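#' P-value under the 50:50 boundary mixture null
#'
#' A variance component tested on its lower boundary gives a likelihood-ratio
#' statistic distributed, under the null, as a 50:50 mixture of a point mass
#' at zero and a 1-df chi-square. For `lrt > 0` the p-value is
#' `0.5 * P(chisq_1 >= lrt)`; a statistic of exactly 0 falls in the point mass
#' and is reported as p = 1 (never significant). Statistics in
#' `[-1e-6, 0)` are clamped to 0 (factorization noise); anything more negative
#' is a nesting violation and an error.
#'
#' @param lrt numeric vector of likelihood-ratio statistics.
#' @return numeric vector of p-values in (0, 1\].
#' @examples
#' mixturePvalue(c(0, 2.7055, 3.8415))  # 1, ~0.05, ~0.025
#' @export
mixturePvalue <- function(lrt) {
  if (any(lrt < -1e-6))
    stop("negative LRT beyond tolerance: nesting violation")
  lrt <- pmax(lrt, 0)
  ifelse(lrt == 0, 1, 0.5 * pchisq(lrt, df = 1, lower.tail = FALSE))
}

#' Bonferroni-corrected significance threshold
#'
#' @param nTests number of tests performed (>= 1).
#' @param alpha family-wise error rate, default 0.05.
#' @return `alpha / nTests`.
#' @export
bonferroniThreshold <- function(nTests, alpha = 0.05) {
  if (length(nTests) != 1L || is.na(nTests) || nTests < 1)
    stop("nTests must be a positive count")
  alpha / nTests
}

#' Gene-level association scan of methylation kernels
#'
#' Fits the polygenic null model once, then for every kernel fits the full
#' model (polygenic + gene kernel) and records the likelihood-ratio statistic
#' `2 * (llFull - llNull)` with its boundary-mixture p-value. Statistics
#' below `1e-8` are reported as exactly 0. Kernels are aligned to the trait's
#' sample order by id; per-gene failures are logged in the `"errors"`
#' attribute and skipped.
#'
#' @param trait numeric response, named by sample id (or `sampleIds` given).
#' @param covariates optional fixed-effect covariates (intercept added);
#'   typically sex, age and optionally PC scores.
#' @param phi2 additive relationship matrix \eqn{2\Phi} with sample dimnames.
#' @param kernels named list of [MethylKernel-class] objects (e.g. from
#'   [kernelScan()]).
#' @param annotation optional annotation data.frame used to attach a
#'   chromosome and representative position (minimum site position) per gene.
#' @param alpha family-wise error rate for the reported threshold.
#' @param ... passed to [fitVarComp()].
#' @return data.frame with one row per gene (deterministic gene-id order):
#'   `gene_id`, `chromosome`, `position`, `n_sites`, `lrt`, `p_value`,
#'   `h_meth2`, `h_r2_full`, `loglik_null`, `loglik_full`, `converged`;
#'   attributes `n_tests`, `threshold` and `errors`.
#' @export
geneScan <- function(trait, covariates = NULL, phi2, kernels,
                     annotation = NULL, alpha = 0.05, ...) {
  ids <- names(trait)
  if (is.null(ids)) ids <- rownames(phi2)
  if (is.null(ids)) stop("trait must be named by sample id")
  stopifnot(!is.null(rownames(phi2)), setequal(rownames(phi2), ids))
  phi2 <- phi2[ids, ids]
  null <- fitVarComp(trait, covariates, list(h_r2 = phi2), ...)
  genes <- sort(vapply(kernels, kernelGene, ""))
  kernels <- kernels[order(vapply(kernels, kernelGene, ""))]
  rows <- vector("list", length(kernels))
  errors <- data.frame(gene_id = character(0), reason = character(0))
  for (i in seq_along(kernels)) {
    kn <- kernels[[i]]
    g <- kernelGene(kn)
    res <- tryCatch({
      K <- kernelMatrix(kn)
      if (!setequal(rownames(K), ids))
        stop("kernel samples do not match the trait")
      K <- K[ids, ids]
      full <- fitVarComp(trait, covariates,
                         list(h_r2 = phi2, h_meth2 = K), ...)
      lrt <- 2 * (full@loglik - null@loglik)
      if (lrt < -1e-6) stop("nesting violation for gene ", g)
      if (lrt < 1e-8) lrt <- 0
      data.frame(gene_id = g, n_sites = kernelSites(kn), lrt = lrt,
                 p_value = mixturePvalue(lrt),
                 h_meth2 = unname(full@fractions["h_meth2"]),
                 h_r2_full = unname(full@fractions["h_r2"]),
                 loglik_null = null@loglik, loglik_full = full@loglik,
                 converged = full@converged && null@converged)
    }, error = function(e) conditionMessage(e))
    if (is.character(res))
      errors <- rbind(errors, data.frame(gene_id = g, reason = res))
    else rows[[i]] <- res
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(gene_id = character(0), n_sites = integer(0),
                      lrt = numeric(0), p_value = numeric(0),
                      h_meth2 = numeric(0), h_r2_full = numeric(0),
                      loglik_null = numeric(0), loglik_full = numeric(0),
                      converged = logical(0))
  out <- .attachGenePos(out, annotation)
  nTests <- sum(out$converged)
  attr(out, "n_tests") <- nTests
  attr(out, "threshold") <-
    if (nTests >= 1) bonferroniThreshold(nTests, alpha) else NA_real_
  attr(out, "errors") <- errors
  rownames(out) <- NULL
  out
}

.attachGenePos <- function(out, annotation) {
  chrom <- rep(NA_character_, nrow(out))
  pos <- rep(NA_real_, nrow(out))
  if (!is.null(annotation) && nrow(out) &&
      all(c("gene_id", "position") %in% names(annotation))) {
    byg <- split(annotation, annotation$gene_id)
    hit <- match(out$gene_id, names(byg))
    for (i in which(!is.na(hit))) {
      sub <- byg[[hit[i]]]
      pos[i] <- min(sub$position, na.rm = TRUE)
      if ("chromosome" %in% names(sub))
        chrom[i] <- as.character(sub$chromosome[[1L]])
    }
  }
  cbind(data.frame(gene_id = out$gene_id, chromosome = chrom,
                   position = pos), out[, -1L, drop = FALSE])
}

#' Per-site narrow-sense heritability scan
#'
#' For every methylation site, fits the polygenic model (site values as the
#' trait, kernel \eqn{2\Phi}) against the sporadic model (no genetic
#' component, the h2 = 0 boundary of the same profile) and reports the ML
#' heritability with its boundary-mixture p-value. PC scores can be supplied
#' as additional fixed-effect covariates to reproduce the batch-corrected
#' scan. The kinship eigendecomposition is shared across sites, so each site
#' costs only a 1-D profiled search.
#'
#' @param x a transformed `MethylationSet`.
#' @param phi2 additive relationship matrix with sample dimnames.
#' @param covariates optional per-sample covariates (intercept added).
#' @param pcs optional [PCModel-class]; its scores are appended to the
#'   covariates.
#' @return data.frame: `site_id`, `h2`, `loglik_poly`, `loglik_sporadic`,
#'   `lrt`, `p_value`.
#' @export
siteH2Scan <- function(x, phi2, covariates = NULL, pcs = NULL) {
  if (!isTransformed(x))
    stop("siteH2Scan expects an inverse-normalized MethylationSet")
  ids <- sampleIds(x)
  stopifnot(setequal(rownames(phi2), ids))
  phi2 <- phi2[ids, ids]
  if (!is.null(pcs)) {
    sc <- pcScores(pcs)[ids, , drop = FALSE]
    colnames(sc) <- paste0("PC", seq_len(ncol(sc)))
    covariates <- if (is.null(covariates)) sc else cbind(covariates, sc)
  }
  X <- .designMatrix(length(ids), covariates)
  ed <- eigen(phi2, symmetric = TRUE)
  Xt <- crossprod(ed$vectors, X)
  v <- methValues(x)
  res <- vector("list", nrow(v))
  for (i in seq_len(nrow(v))) {
    y <- v[i, ]
    if (anyNA(y)) {
      ok <- !is.na(y)
      rot <- .vcRotate(y[ok], X[ok, , drop = FALSE],
                       phi2[ok, ok, drop = FALSE])
      ft <- .vcFit1(rot$d, rot$yt, rot$Xt)
      ll0 <- .vcProfile(0, rot$d, rot$yt, rot$Xt)$ll
    } else {
      yt <- drop(crossprod(ed$vectors, y))
      ft <- .vcFit1(ed$values, yt, Xt)
      ll0 <- .vcProfile(0, ed$values, yt, Xt)$ll
    }
    lrt <- max(0, 2 * (ft$ll - ll0))
    if (lrt < 1e-8) lrt <- 0
    res[[i]] <- data.frame(site_id = rownames(v)[i], h2 = ft$s,
                           loglik_poly = ft$ll, loglik_sporadic = ll0,
                           lrt = lrt, p_value = mixturePvalue(lrt))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Export Manhattan and Q-Q plot data
#'
#' Writes two plot-ready TSVs: a Manhattan table (`gene_id`, `chromosome`,
#' `position`, `p_value`, `neglog10_p`; genes without coordinates go to an
#' `"unplaced"` track) and a Q-Q table of observed p-values against expected
#' quantiles under the 50:50 mixture null (not plain uniform: half the null
#' statistics are exactly 0 with p = 1, so uniform expectations would fake
#' deflation).
#'
#' @param results data.frame from [geneScan()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix, default `"assoc"`.
#' @return character vector of the two file paths, invisibly.
#' @export
exportPlotData <- function(results, dir, prefix = "assoc") {
  if (!nrow(results)) stop("empty results")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- data.frame(
    gene_id = results$gene_id,
    chromosome = ifelse(is.na(results$chromosome), "unplaced",
                        as.character(results$chromosome)),
    position = results$position,
    p_value = results$p_value,
    neglog10_p = -log10(results$p_value))
  manPath <- file.path(dir, paste0(prefix, "_manhattan.tsv"))
  write.table(man, manPath, sep = "\t", quote = FALSE, row.names = FALSE)
  qq <- qqMixtureTable(results$p_value)
  qqPath <- file.path(dir, paste0(prefix, "_qq.tsv"))
  write.table(qq, qqPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(manhattan = manPath, qq = qqPath))
}

#' Observed vs expected p-value quantiles under the mixture null
#'
#' Expected quantiles use the null distribution of the mixture p-value: with
#' probability 1/2 the statistic is 0 and p = 1; otherwise p is uniform on
#' (0, 0.5\]. Its quantile function is `q(u) = u` for `u < 0.5` and 1 beyond.
#'
#' @param p numeric vector of p-values.
#' @return data.frame sorted by observed p: `expected`, `observed`,
#'   `neglog10_expected`, `neglog10_observed`.
#' @export
qqMixtureTable <- function(p) {
  p <- sort(p)
  n <- length(p)
  u <- (seq_len(n) - 0.5) / n
  expected <- ifelse(u < 0.5, u, 1)
  data.frame(expected = expected, observed = p,
             neglog10_expected = -log10(expected),
             neglog10_observed = -log10(p))
}

#' Manhattan plot of a gene scan
#'
#' @param results data.frame from [geneScan()].
#' @param threshold optional significance threshold drawn as a line (defaults
#'   to the scan's Bonferroni attribute).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the plotted data.frame.
#' @export
plotManhattan <- function(results, threshold = attr(results, "threshold"),
                          ...) {
  chrom <- ifelse(is.na(results$chromosome), "unplaced",
                  as.character(results$chromosome))
  ord <- order(suppressWarnings(as.numeric(chrom)), chrom, results$position)
  r <- results[ord, ]
  cf <- factor(ifelse(is.na(r$chromosome), "unplaced",
                      as.character(r$chromosome)),
               levels = unique(ifelse(is.na(r$chromosome), "unplaced",
                                      as.character(r$chromosome))))
  graphics::plot(seq_len(nrow(r)), -log10(r$p_value),
                 col = as.integer(cf) %% 2 + 1, pch = 16,
                 xlab = "gene rank (by chromosome, position)",
                 ylab = expression(-log[10](p)), ...)
  if (!is.null(threshold) && is.finite(threshold))
    graphics::abline(h = -log10(threshold), lty = 2)
  invisible(r)
}

#' Q-Q plot of a gene scan under the mixture null
#'
#' @param results data.frame from [geneScan()] (or a numeric p-value vector).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the Q-Q data.frame from [qqMixtureTable()].
#' @export
plotQQ <- function(results, ...) {
  p <- if (is.data.frame(results)) results$p_value else results
  qq <- qqMixtureTable(p)
  graphics::plot(qq$neglog10_expected, qq$neglog10_observed, pch = 16,
                 xlab = expression(Expected ~ -log[10](p)),
                 ylab = expression(Observed ~ -log[10](p)), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(qq)
}
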
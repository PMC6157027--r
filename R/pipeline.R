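# End-to-end wiring: normalize -> pca -> kernels -> association (optionally
# per-site h2), with stamped TSV/JSON artifacts on disk. A config hash is
# written into every output header so stale intermediates are detectable.

.defaultConfig <- function() {
  list(minSites = 5L, subsetFraction = 0.10, nComponents = 20L,
       alpha = 0.05, seed = NULL, traitColumn = "trait",
       covariateColumns = c("sex", "age"), residualizeBeforeKernel = TRUE,
       pcCovariatesInH2 = TRUE, siteH2 = FALSE, maxMissing = 0.2)
}

.configHash <- function(config) {
  config$outdir <- NULL   # the output location does not define the run
  config <- config[order(names(config))]
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                         null = "null")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}

.writeStamped <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# methylVC config_hash=", hash), con)
  suppressWarnings(
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' Read a pipeline artifact, checking its config hash
#'
#' @param path a TSV written by [runPipeline()] (or the CLI stages).
#' @param expectHash if non-NULL, stop when the artifact was produced under a
#'   different configuration.
#' @return data.frame.
#' @export
readStamped <- function(path, expectHash = NULL) {
  first <- readLines(path, n = 1L)
  hash <- sub("^# methylVC config_hash=", "", first)
  if (!is.null(expectHash) && !identical(hash, expectHash))
    stop("stale artifact: ", path, " was produced under config ", hash,
         ", expected ", expectHash)
  read.delim(path, skip = 1L, stringsAsFactors = FALSE)
}

#' Run the full methylation variance-component pipeline
#'
#' Executes normalize -> PC correction -> kernel construction -> gene-level
#' association (and optionally the per-site heritability scan) from the four
#' input tables, writing intermediate artifacts and a run summary into
#' `outdir`. Rerunning with identical inputs and config reproduces
#' byte-identical outputs.
#'
#' @param config named list (or path to a YAML/JSON file) with paths
#'   (`pedigree`, `methylation`, `annotation`, `phenotype`, `outdir`) and
#'   parameters: `minSites` (5), `subsetFraction` (0.10), `nComponents` (20),
#'   `alpha` (0.05), `seed` (required), `traitColumn` (`"trait"`),
#'   `covariateColumns` (`c("sex","age")`), `residualizeBeforeKernel`
#'   (`TRUE`; otherwise kernels are built from uncorrected values and PCs
#'   enter only as covariates), `pcCovariatesInH2` (`TRUE`), `siteH2`
#'   (`FALSE`), `maxMissing` (0.2).
#' @return the run summary (also written to `summary.json`), invisibly.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- .readConfigFile(config)
  cfg <- utils::modifyList(.defaultConfig(), config)
  for (p in c("pedigree", "methylation", "annotation", "phenotype", "outdir"))
    if (is.null(cfg[[p]])) stop("config lacks required entry '", p, "'")
  if (is.null(cfg$seed)) stop("config must set a seed")
  hash <- .configHash(cfg)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  fail <- function(e) {
    writeLines(conditionMessage(e), file.path(cfg$outdir, "FAILED"))
    stop(e)
  }
  tryCatch({
    pheno <- read.delim(cfg$phenotype, stringsAsFactors = FALSE)
    need <- c("sample_id", cfg$traitColumn, cfg$covariateColumns)
    miss <- setdiff(need, names(pheno))
    if (length(miss))
      stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
    ped <- readPedigree(cfg$pedigree)
    ms <- readMethylation(cfg$methylation)
    ann <- readSiteAnnotation(cfg$annotation)
    ids <- pheno$sample_id
    if (length(bad <- setdiff(ids, sampleIds(ped))))
      stop("phenotype sample(s) not in pedigree: ",
           paste(bad, collapse = ", "))
    if (length(bad <- setdiff(ids, sampleIds(ms))))
      stop("phenotype sample(s) not in methylation matrix: ",
           paste(bad, collapse = ", "))
    phi2 <- additiveMatrix(kinshipMatrix(ped))[ids, ids]
    ms <- ms[, ids]

    msNorm <- inverseNormalize(ms)
    pcs <- fitPCs(msNorm, subsetFraction = cfg$subsetFraction,
                  nComponents = cfg$nComponents, seed = cfg$seed)
    writePCScores(pcs, file.path(cfg$outdir, "pc_scores.tsv"))
    msKernel <- if (cfg$residualizeBeforeKernel)
      residualize(msNorm, pcs) else msNorm

    index <- buildGeneIndex(ann, minSites = cfg$minSites)
    kernels <- kernelScan(msKernel, index, maxMissing = cfg$maxMissing)
    skipped <- attr(kernels, "skipped")
    if (nrow(skipped))
      .writeStamped(skipped, file.path(cfg$outdir, "kernel_skips.tsv"), hash)

    trait <- setNames(pheno[[cfg$traitColumn]], ids)
    covs <- as.matrix(pheno[, cfg$covariateColumns, drop = FALSE])
    rownames(covs) <- ids
    assoc <- geneScan(trait, covs, phi2, kernels, annotation = ann,
                      alpha = cfg$alpha)
    .writeStamped(assoc, file.path(cfg$outdir, "assoc.tsv"), hash)
    if (nrow(assoc)) exportPlotData(assoc, cfg$outdir)

    siteH2 <- NULL
    if (isTRUE(cfg$siteH2)) {
      siteH2 <- siteH2Scan(msNorm, phi2, covariates = covs,
                           pcs = if (cfg$pcCovariatesInH2) pcs else NULL)
      .writeStamped(siteH2, file.path(cfg$outdir, "site_h2.tsv"), hash)
    }

    summary <- list(
      package = as.character(packageVersion("methylVC")),
      config_hash = hash,
      n_samples = length(ids),
      n_sites = nrow(msNorm),
      n_genes_eligible = length(geneIds(index)),
      n_genes_skipped = nrow(skipped),
      n_tests = attr(assoc, "n_tests"),
      n_nonconverged = sum(!assoc$converged),
      threshold = attr(assoc, "threshold"),
      top_gene = if (nrow(assoc)) assoc$gene_id[which.min(assoc$p_value)]
                 else NA,
      min_p = if (nrow(assoc)) min(assoc$p_value) else NA)
    jsonlite::write_json(summary, file.path(cfg$outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
    unlink(file.path(cfg$outdir, "FAILED"))
    invisible(summary)
  }, error = fail)
}

.readConfigFile <- function(path) {
  if (grepl("\\.json$", path)) return(jsonlite::read_json(path,
                                                          simplifyVector = TRUE))
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the yaml package")
  yaml::read_yaml(path)
}
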
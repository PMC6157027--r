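# Topological order of a pedigree (founders first). Returns integer indices;
# on a cycle, returns with attr "cycle" naming the offending individuals.
.pedTopoOrder <- function(id, father, mother) {
  n <- length(id)
  idx <- seq_len(n)
  names(idx) <- id
  fi <- unname(idx[father])  # NA for founders
  mi <- unname(idx[mother])
  indeg <- integer(n)       # number of unplaced parents
  indeg <- (!is.na(fi)) + (!is.na(mi))
  children <- vector("list", n)
  for (i in idx) {
    if (!is.na(fi[i])) children[[fi[i]]] <- c(children[[fi[i]]], i)
    if (!is.na(mi[i])) children[[mi[i]]] <- c(children[[mi[i]]], i)
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    out <- c(out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) {
    res <- integer(0)
    attr(res, "cycle") <- id[setdiff(idx, out)]
    return(res)
  }
  out
}

#' Construct a Pedigree
#'
#' @param id character vector of unique individual ids.
#' @param father,mother parent ids; `NA`, `""` or `"0"` mean unknown (founder
#'   or half-founder side).
#' @param sex one of `"male"`, `"female"`, `"unknown"` (also accepts PED codes
#'   1/2/0 and M/F).
#' @param family optional family labels.
#' @return a validated [Pedigree-class] object.
#' @export
Pedigree <- function(id, father = NA, mother = NA, sex = "unknown",
                     family = NA) {
  n <- length(id)
  norm <- function(x) {
    x <- as.character(x)
    x <- rep_len(x, n)
    x[x %in% c("0", "") | is.na(x)] <- NA_character_
    x
  }
  sex <- rep_len(as.character(sex), n)
  sex <- c(male = "male", female = "female", unknown = "unknown",
           m = "male", f = "female", "1" = "male", "2" = "female",
           "0" = "unknown")[tolower(sex)]
  sex[is.na(sex)] <- "unknown"
  new("Pedigree", id = as.character(id), father = norm(father),
      mother = norm(mother), sex = unname(sex),
      family = { fam <- as.character(rep_len(family, n)); fam })
}

#' Read a pedigree file
#'
#' Accepts the two common dialects: classic whitespace-delimited PED columns
#' (`family id father mother sex ...`, or without the family column) and a
#' headered TSV with columns `id`, `father`, `mother`, `sex` and optionally
#' `family`. Missing parents may be coded `0` or left empty.
#'
#' @param path file path.
#' @param dialect `"auto"` (default), `"ped"` or `"tsv"`.
#' @return a validated [Pedigree-class]; individuals keep file order.
#' @examples
#' tf <- tempfile()
#' writeLines(c("c f m 1", "f 0 0 1", "m 0 0 2"), tf)
#' readPedigree(tf)
#' @export
readPedigree <- function(path, dialect = c("auto", "ped", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  first <- readLines(path, n = 1L)
  if (dialect == "auto") {
    toks <- tolower(strsplit(trimws(first), "[ \t]+")[[1]])
    dialect <- if (any(toks %in% c("id", "iid", "father", "mother", "sex")))
      "tsv" else "ped"
  }
  if (dialect == "tsv") {
    df <- read.delim(path, header = TRUE, colClasses = "character")
    names(df) <- tolower(names(df))
    need <- c("id", "father", "mother", "sex")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("pedigree TSV lacks column(s): ", paste(miss, collapse = ", "))
    fam <- if ("family" %in% names(df)) df$family else NA
    return(Pedigree(df$id, df$father, df$mother, df$sex, fam))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 4))
    stop("pedigree line(s) with fewer than 4 fields: line ",
         paste(which(nf < 4), collapse = ", "))
  hasFam <- all(nf >= 5)
  get <- function(k) vapply(fields, `[[`, "", k)
  if (hasFam)
    Pedigree(get(2), get(3), get(4), get(5), family = get(1))
  else
    Pedigree(get(1), get(2), get(3), get(4))
}

#' @rdname kinshipMatrix
setMethod("kinshipMatrix", "Pedigree", function(ped) {
  n <- length(ped@id)
  idx <- seq_len(n)
  names(idx) <- ped@id
  fi <- unname(idx[ped@father])
  mi <- unname(idx[ped@mother])
  ord <- .pedTopoOrder(ped@id, ped@father, ped@mother)
  phi <- matrix(0, n, n, dimnames = list(ped@id, ped@id))
  for (k in seq_len(n)) {
    i <- ord[k]
    f <- fi[i]; m <- mi[i]
    if (k > 1L) {
      js <- ord[seq_len(k - 1L)]
      pf <- if (is.na(f)) 0 else phi[f, js]
      pm <- if (is.na(m)) 0 else phi[m, js]
      v <- 0.5 * (pf + pm)
      phi[i, js] <- v
      phi[js, i] <- v
    }
    phi[i, i] <- 0.5 * (1 + if (is.na(f) || is.na(m)) 0 else phi[f, m])
  }
  new("KinshipMatrix", phi = phi)
})

#' @rdname additiveMatrix
setMethod("additiveMatrix", "KinshipMatrix", function(x) 2 * x@phi)

#' @rdname additiveMatrix
setMethod("additiveMatrix", "matrix", function(x) 2 * x)

#' @rdname phi
setMethod("phi", "KinshipMatrix", function(x) x@phi)

#' @rdname sampleIds
setMethod("sampleIds", "Pedigree", function(x) x@id)

#' @rdname sampleIds
setMethod("sampleIds", "KinshipMatrix", function(x) rownames(x@phi))

#' Number of founders in a pedigree
#' @param ped a `Pedigree`.
#' @return integer count of individuals with both parents unknown.
#' @export
nFounders <- function(ped) sum(is.na(ped@father) & is.na(ped@mother))

#' Write kinship coefficients to TSV
#'
#' @param x a [KinshipMatrix-class].
#' @param path output file.
#' @param format `"pairs"` (id1, id2, phi; upper triangle incl. diagonal) or
#'   `"matrix"` (square with header row of ids).
#' @return `path`, invisibly.
#' @export
writeKinship <- function(x, path, format = c("pairs", "matrix")) {
  format <- match.arg(format)
  p <- phi(x)
  if (format == "matrix") {
    df <- data.frame(id = rownames(p), p, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    ut <- which(upper.tri(p, diag = TRUE), arr.ind = TRUE)
    df <- data.frame(id1 = rownames(p)[ut[, 1]], id2 = colnames(p)[ut[, 2]],
                     phi = p[ut])
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

setMethod("show", "Pedigree", function(object) {
  cat("Pedigree with", length(object@id), "individuals,",
      nFounders(object), "founders",
      if (!all(is.na(object@family)))
        paste0("in ", length(unique(object@family)), " families"), "\n")
})

setMethod("show", "KinshipMatrix", function(object) {
  cat("KinshipMatrix over", nrow(object@phi), "individuals; mean diagonal",
      signif(mean(diag(object@phi)), 4), "\n")
})
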
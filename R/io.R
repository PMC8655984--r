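# Readers and writers for every external format the pipeline touches:
# STRING links (optionally gzipped), plain gene lists, GMT annotation
# files, and the tab-separated screening results table.

#' Read a STRING-style protein links file
#'
#' Parses whitespace-separated `protein1 protein2 combined_score` rows. A
#' single header line starting with `protein1` is skipped. Gzipped files
#' are detected by the `.gz` extension.
#'
#' @param path path to the links file (plain text or `.gz`).
#' @param minScore keep only rows with `combined_score > minScore`
#'   (default 0, i.e. every positive score).
#' @return data.frame with columns `protein1`, `protein2`,
#'   `combined_score`, rows in file order.
#' @examples
#' f <- tempfile()
#' writeLines(c("protein1 protein2 combined_score", "a b 900", "b a 900"), f)
#' readStringLinks(f)
#' @export
readStringLinks <- function(path, minScore = 0) {
  if (!file.exists(path)) {
    .inputError(sprintf("links file not found: %s", path))
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lineno <- seq_along(lines)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]; lineno <- lineno[keep]
  if (length(lines) && startsWith(lines[1], "protein1")) {
    lines <- lines[-1]; lineno <- lineno[-1]
  }
  if (!length(lines)) {
    .inputError(sprintf("no edge rows in links file: %s", path))
  }
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- lengths(fields)
  if (any(nf < 3)) {
    .inputError(sprintf("malformed row (need 3 columns) at line %d of %s",
                        lineno[which(nf < 3)[1]], path))
  }
  p1 <- vapply(fields, `[[`, "", 1)
  p2 <- vapply(fields, `[[`, "", 2)
  sc <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  if (anyNA(sc)) {
    .inputError(sprintf("non-numeric combined_score at line %d of %s",
                        lineno[which(is.na(sc))[1]], path))
  }
  out <- data.frame(protein1 = p1, protein2 = p2, combined_score = sc,
                    stringsAsFactors = FALSE)
  out[out$combined_score > minScore, , drop = FALSE]
}

#' Read a gene set from a plain-text list
#'
#' One identifier per line; lines starting with `#` and blank lines are
#' ignored. Duplicates are dropped with a warning; input order of first
#' occurrence is preserved.
#'
#' @param path path to the gene list.
#' @return character vector of unique identifiers.
#' @export
readGeneSet <- function(path) {
  if (!file.exists(path)) {
    .inputError(sprintf("gene list not found: %s", path))
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    .inputError(sprintf("no gene identifiers in %s", path))
  }
  if (anyDuplicated(lines)) {
    warning(sprintf("%d duplicate identifier(s) dropped from %s",
                    sum(duplicated(lines)), path))
    lines <- lines[!duplicated(lines)]
  }
  lines
}

#' Restrict a gene set to the network
#'
#' Drops identifiers absent from the network, preserving input order, as
#' seed lists routinely contain genes outside the interaction network.
#'
#' @param genes character vector of identifiers.
#' @param net a [PPINetwork-class].
#' @return the intersection, in input order.
#' @export
restrictToNetwork <- function(genes, net) {
  keep <- genes %in% nodes(net)
  if (!any(keep)) {
    .inputError("no supplied gene is present in the network")
  }
  if (any(!keep)) {
    message(sprintf("dropped %d identifier(s) not in the network",
                    sum(!keep)))
  }
  genes[keep]
}

#' Read a GMT annotation file
#'
#' Tab-separated `term<TAB>description<TAB>gene1<TAB>gene2...`. Terms with
#' no genes are dropped with a warning; duplicate genes within a term are
#' deduplicated.
#'
#' @param path path to the GMT file.
#' @return an [AnnotationMap-class].
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) {
    .inputError(sprintf("annotation file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  keep <- nzchar(lines)
  lines <- lines[keep]; lineno <- lineno[keep]
  if (!length(lines)) {
    .inputError(sprintf("empty annotation file: %s", path))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2)) {
    .inputError(sprintf("malformed GMT row (need term and description) at line %d of %s",
                        lineno[which(nf < 2)[1]], path))
  }
  termIds <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(termIds)) {
    .inputError(sprintf("duplicate term id at line %d of %s",
                        lineno[which(duplicated(termIds))[1]], path))
  }
  descs <- vapply(fields, `[[`, "", 2)
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning(sprintf("dropped %d term(s) with no genes (e.g. %s)",
                    sum(empty), termIds[empty][1]))
  }
  sets <- sets[!empty]
  names(sets) <- termIds[!empty]
  descs <- structure(descs[!empty], names = termIds[!empty])
  new("AnnotationMap", sets = sets, descriptions = descs)
}

#' @rdname termIds
#' @export
setMethod("termIds", "AnnotationMap", function(x) names(x@sets))

#' @rdname termGenes
#' @export
setMethod("termGenes", "AnnotationMap", function(x, term) {
  if (!term %in% names(x@sets)) {
    .inputError(sprintf("unknown term: %s", term))
  }
  x@sets[[term]]
})

setMethod("show", "AnnotationMap", function(object) {
  cat(sprintf("AnnotationMap with %d terms over %d genes\n",
              length(object@sets),
              length(unique(unlist(object@sets, use.names = FALSE)))))
})

#' Write screening records to a results table
#'
#' Tab-separated with header `gene probability z_score mls mes
#' pass_permutation pass_linkage pass_enrichment inferred`, sorted by
#' descending maximum enrichment score then gene identifier. Floats are
#' written at full precision so a read-back is lossless.
#'
#' @param path output file path.
#' @param records data.frame of screening records from [applyFilters()].
#' @return the path, invisibly.
#' @export
writeResults <- function(path, records) {
  cols <- c("gene", "probability", "z_score", "mls", "mes",
            "pass_permutation", "pass_linkage", "pass_enrichment",
            "inferred")
  if (!all(cols %in% names(records))) {
    .inputError("records table is missing screening columns")
  }
  records <- records[order(-xtfrm(records$mes), records$gene), cols,
                     drop = FALSE]
  fmt <- function(x) {
    ifelse(is.na(x), "NA", vapply(x, function(v) sprintf("%.17g", v), ""))
  }
  rows <- paste(records$gene,
                fmt(records$probability), fmt(records$z_score),
                fmt(records$mls), fmt(records$mes),
                records$pass_permutation, records$pass_linkage,
                records$pass_enrichment, records$inferred,
                sep = "\t")
  out <- tryCatch(file(path, "wt"),
                  error = function(e) .inputError(
                    sprintf("cannot open results path: %s", path)))
  on.exit(close(out))
  writeLines(c(paste(cols, collapse = "\t"), rows), out)
  invisible(path)
}

#' Read back a results table written by [writeResults()]
#'
#' @param path path to the results TSV.
#' @return data.frame with the screening columns, numerics restored at full
#'   precision.
#' @export
readResults <- function(path) {
  if (!file.exists(path)) {
    .inputError(sprintf("results file not found: %s", path))
  }
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("probability", "z_score", "mls", "mes")) {
    out[[col]] <- as.numeric(out[[col]])
  }
  for (col in c("pass_permutation", "pass_linkage", "pass_enrichment",
                "inferred")) {
    out[[col]] <- as.logical(out[[col]])
  }
  out
}
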
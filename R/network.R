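# Construction and interrogation of the confidence-weighted PPI network.
# STRING-style inputs list every pair in both directions with equal scores;
# buildNetwork collapses them and keeps the maximum on genuine conflict.

#' Build a PPI network from an edge list
#'
#' Constructs an undirected, confidence-weighted network from a table of
#' protein pairs. Pairs may appear in either direction or twice (STRING
#' files list both directions); duplicates collapse to a single undirected
#' edge. When duplicate listings disagree, the maximum score is kept and a
#' warning is raised. Self-loops are dropped with a warning. Node order is
#' fixed to the lexicographic sort of all identifiers so that every derived
#' matrix and vector is reproducible.
#'
#' @param edges data.frame with columns `protein1`, `protein2`,
#'   `combined_score` (as returned by [readStringLinks()]), or any
#'   three-column data.frame in that order.
#' @return a [PPINetwork-class].
#' @examples
#' buildNetwork(data.frame(protein1 = c("a", "b"),
#'                         protein2 = c("b", "a"),
#'                         combined_score = c(900, 900)))
#' @export
buildNetwork <- function(edges) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 3) {
    .inputError("edge table must have columns protein1, protein2, combined_score")
  }
  p1 <- as.character(edges[[1]])
  p2 <- as.character(edges[[2]])
  w <- edges[[3]]
  if (!is.numeric(w)) {
    bad <- which(is.na(suppressWarnings(as.numeric(w))))[1]
    .inputError(sprintf("non-numeric confidence score at edge row %d",
                        if (is.na(bad)) 1L else bad))
  }
  w <- as.numeric(w)
  if (anyNA(p1) || anyNA(p2) || anyNA(w)) {
    .inputError(sprintf("missing value at edge row %d",
                        which(is.na(p1) | is.na(p2) | is.na(w))[1]))
  }
  if (any(w <= 0)) {
    .inputError(sprintf("non-positive confidence score at edge row %d",
                        which(w <= 0)[1]))
  }

  ids <- sort(unique(c(p1, p2)))  # loop-only nodes stay, as isolated
  loops <- p1 == p2
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s) (e.g. %s)",
                    sum(loops), p1[loops][1]))
  }
  keep <- !loops
  p1 <- p1[keep]; p2 <- p2[keep]; w <- w[keep]
  n <- length(ids)
  i <- match(p1, ids)
  j <- match(p2, ids)
  lo <- pmin(i, j)
  hi <- pmax(i, j)

  if (length(lo)) {
    key <- (lo - 1) * n + hi
    agg <- tapply(w, key, max)
    rng <- tapply(w, key, function(x) max(x) - min(x))
    if (any(rng > 0)) {
      warning(sprintf(
        "%d duplicate edge(s) with conflicting scores; kept the maximum",
        sum(rng > 0)))
    }
    ukey <- as.numeric(names(agg))
    ulo <- (ukey - 1) %/% n + 1
    uhi <- ukey - (ulo - 1) * n
    A <- Matrix::sparseMatrix(
      i = c(ulo, uhi), j = c(uhi, ulo), x = rep(as.numeric(agg), 2),
      dims = c(n, n), dimnames = list(ids, ids)
    )
  } else {
    A <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(n, n), dimnames = list(ids, ids))
  }
  new("PPINetwork", adjacency = methods::as(A, "CsparseMatrix"))
}

#' @rdname nodes
#' @export
setMethod("nodes", "PPINetwork", function(x) rownames(x@adjacency))

#' @rdname numNodes
#' @export
setMethod("numNodes", "PPINetwork", function(x) nrow(x@adjacency))

#' @rdname numEdges
#' @export
setMethod("numEdges", "PPINetwork",
          function(x) as.integer(Matrix::nnzero(x@adjacency) / 2))

#' @rdname edgeTable
#' @export
setMethod("edgeTable", "PPINetwork", function(x) {
  A <- x@adjacency
  tri <- Matrix::which(Matrix::triu(A, k = 1) != 0, arr.ind = TRUE)
  ids <- rownames(A)
  out <- data.frame(
    protein1 = ids[tri[, 1]],
    protein2 = ids[tri[, 2]],
    combined_score = A[tri],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$protein1, out$protein2), , drop = FALSE]
  rownames(out) <- NULL
  out
})

#' @rdname confidence
#' @export
setMethod("confidence", "PPINetwork", function(net, u, v) {
  ids <- nodes(net)
  missing <- setdiff(c(u, v), ids)
  if (length(missing)) {
    .inputError(sprintf("node(s) not in network: %s",
                        paste(missing, collapse = ", ")))
  }
  as.numeric(net@adjacency[u, v])
})

#' @rdname transitionMatrix
#' @export
setMethod("transitionMatrix", "PPINetwork", function(net) {
  A <- net@adjacency
  cs <- Matrix::colSums(A)
  inv <- ifelse(cs > 0, 1 / cs, 0)
  M <- A %*% Matrix::Diagonal(x = inv)
  dimnames(M) <- dimnames(A)
  methods::as(M, "CsparseMatrix")
})

#' @rdname degrees
#' @export
setMethod("degrees", "PPINetwork", function(net, minScore = 0) {
  A <- net@adjacency
  if (minScore > 0) {
    A <- Matrix::drop0(A * (A >= minScore))
  }
  structure(as.integer(Matrix::colSums(A != 0)), names = nodes(net))
})

#' @rdname degrees
#' @export
setMethod("neighborsOf", "PPINetwork", function(net, node, minScore = 0) {
  ids <- nodes(net)
  if (!node %in% ids) {
    .inputError(sprintf("node not in network: %s", node))
  }
  col <- net@adjacency[, node]
  ids[col != 0 & col >= minScore]
})

setMethod("show", "PPINetwork", function(object) {
  cat(sprintf("PPINetwork with %d nodes and %d edges\n",
              numNodes(object), numEdges(object)))
  w <- object@adjacency@x
  if (length(w)) {
    cat(sprintf("  confidence scores: %g-%g (median %g)\n",
                min(w), max(w), stats::median(w)))
  }
})
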
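#' Node identifiers of a network
#'
#' @param x a [PPINetwork-class].
#' @return character vector of node identifiers in the fixed
#'   (lexicographic) network order.
#' @examples
#' net <- buildNetwork(data.frame(protein1 = "b", protein2 = "a",
#'                                combined_score = 900))
#' nodes(net)
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' Number of nodes in a network
#' @param x a [PPINetwork-class].
#' @return integer scalar.
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' Number of (undirected) edges in a network
#' @param x a [PPINetwork-class].
#' @return integer scalar.
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' Edge table of a network
#' @param x a [PPINetwork-class].
#' @return data.frame with columns `protein1`, `protein2`, `combined_score`,
#'   one row per undirected edge, `protein1 < protein2`, sorted.
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' Confidence score of a protein pair
#'
#' Looks up the edge weight between two nodes; 0 for a non-adjacent pair.
#' Symmetric in its arguments.
#'
#' @param net a [PPINetwork-class].
#' @param u,v node identifiers, both present in the network.
#' @return numeric scalar confidence score (0 if no edge).
#' @examples
#' net <- buildNetwork(data.frame(protein1 = "a", protein2 = "b",
#'                                combined_score = 998))
#' confidence(net, "a", "b")
#' confidence(net, "b", "a")
#' @export
setGeneric("confidence", function(net, u, v) standardGeneric("confidence"))

#' Column-stochastic transition operator of a network
#'
#' Normalizes the weighted adjacency matrix column-wise: entry (i, j) is the
#' probability of stepping from node j to node i, proportional to the edge
#' confidence. Columns of isolated nodes are all-zero.
#'
#' @param net a [PPINetwork-class].
#' @return sparse `dgCMatrix`; every column over a non-isolated node sums
#'   to 1.
#' @examples
#' net <- buildNetwork(data.frame(protein1 = c("a", "b"),
#'                                protein2 = c("b", "c"),
#'                                combined_score = c(500, 500)))
#' Matrix::colSums(transitionMatrix(net))
#' @export
setGeneric("transitionMatrix",
           function(net) standardGeneric("transitionMatrix"))

#' Per-node weighted degree and neighbor access
#'
#' `degrees` returns the number of neighbors of every node (optionally only
#' counting edges at or above a confidence cutoff); `neighborsOf` returns
#' the neighbor identifiers of one node.
#'
#' @param net a [PPINetwork-class].
#' @param minScore count only edges with confidence >= `minScore`
#'   (edges always have positive confidence, so the default keeps all).
#' @return `degrees`: named integer vector over all nodes.
#' @export
setGeneric("degrees", function(net, minScore = 0) standardGeneric("degrees"))

#' @rdname degrees
#' @param node a node identifier.
#' @return `neighborsOf`: character vector of adjacent node identifiers.
#' @export
setGeneric("neighborsOf",
           function(net, node, minScore = 0) standardGeneric("neighborsOf"))

#' Probabilities of a ProbabilityVector
#' @param x a [ProbabilityVector-class].
#' @return named numeric vector aligned to the network node order.
#' @export
setGeneric("probabilities", function(x) standardGeneric("probabilities"))

#' Terms of an annotation map
#' @param x an [AnnotationMap-class].
#' @return character vector of term identifiers in fixed order.
#' @export
setGeneric("termIds", function(x) standardGeneric("termIds"))

#' Gene set of one term
#' @param x an [AnnotationMap-class].
#' @param term a term identifier.
#' @return character vector of annotated genes.
#' @export
setGeneric("termGenes", function(x, term) standardGeneric("termGenes"))
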
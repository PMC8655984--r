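#' @import methods
#' @import Matrix
NULL

#' Confidence-weighted protein-protein interaction network
#'
#' An undirected network over protein identifiers with one positive
#' confidence weight per edge (STRING combined scores, 1-999, in typical
#' use). The network is stored as a symmetric sparse adjacency matrix whose
#' row/column order is the lexicographically sorted node set, so every
#' derived vector and matrix is reproducible across runs.
#'
#' @slot adjacency symmetric `dgCMatrix` with zero diagonal; entry (i, j) is
#'   the confidence score of edge i-j, 0 if absent.
#'
#' @seealso [buildNetwork()], [transitionMatrix()], [confidence()]
#' @export
setClass("PPINetwork", slots = c(adjacency = "dgCMatrix"))

setValidity("PPINetwork", function(object) {
  A <- object@adjacency
  msg <- character()
  if (nrow(A) != ncol(A)) {
    msg <- c(msg, "adjacency matrix must be square")
  }
  dn <- dimnames(A)
  if (is.null(dn) || is.null(dn[[1]]) || is.null(dn[[2]])) {
    msg <- c(msg, "adjacency matrix must carry node names as dimnames")
  } else {
    if (!identical(dn[[1]], dn[[2]])) {
      msg <- c(msg, "row and column names must be identical")
    }
    if (anyDuplicated(dn[[1]])) {
      msg <- c(msg, "node identifiers must be unique")
    }
    if (is.unsorted(dn[[1]])) {
      msg <- c(msg, "node identifiers must be lexicographically sorted")
    }
  }
  if (length(A@x) && any(A@x < 0)) {
    msg <- c(msg, "edge weights must be positive")
  }
  if (nrow(A) > 0 && any(Matrix::diag(A) != 0)) {
    msg <- c(msg, "self-loops are not permitted")
  }
  if (!isSymmetric(A, tol = 0)) {
    msg <- c(msg, "adjacency matrix must be symmetric")
  }
  if (length(msg)) msg else TRUE
})

#' Per-node probability vector from random walk with restart
#'
#' Holds the stationary probabilities returned by [rwr()], aligned to the
#' network's node ordering, together with the restart probability, the
#' number of iterations performed and the final L1 residual.
#'
#' @slot probs named numeric vector of per-node probabilities (>= 0).
#' @slot restart restart probability r used for the walk.
#' @slot iterations number of update steps performed.
#' @slot residual final L1 difference between successive iterates.
#' @slot seeds identifiers of the seed nodes used for initialization.
#'
#' @seealso [rwr()], [selectCandidates()]
#' @export
setClass("ProbabilityVector",
  slots = c(
    probs = "numeric",
    restart = "numeric",
    iterations = "integer",
    residual = "numeric",
    seeds = "character"
  )
)

setValidity("ProbabilityVector", function(object) {
  msg <- character()
  if (is.null(names(object@probs))) {
    msg <- c(msg, "probabilities must be named by node")
  }
  if (any(object@probs < 0)) {
    msg <- c(msg, "probabilities must be non-negative")
  }
  if (length(object@restart) != 1 || object@restart <= 0 ||
      object@restart > 1) {
    msg <- c(msg, "restart probability must be in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Term-to-gene annotation map
#'
#' Maps functional terms (GO terms, KEGG pathways, ...) to the sets of genes
#' they annotate, with an optional free-text description per term. Term
#' order is fixed at construction and shared by every enrichment vector
#' derived from the map.
#'
#' @slot sets named list; each element is a character vector of unique gene
#'   identifiers (at least one per term).
#' @slot descriptions named character vector of term descriptions, aligned
#'   with `sets`.
#'
#' @seealso [readGmt()], [enrichmentVector()]
#' @export
setClass("AnnotationMap",
  slots = c(sets = "list", descriptions = "character")
)

setValidity("AnnotationMap", function(object) {
  msg <- character()
  if (length(object@sets)) {
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets))) {
      msg <- c(msg, "term identifiers must be unique and named")
    }
    sizes <- lengths(object@sets)
    if (any(sizes < 1)) {
      msg <- c(msg, "every term must annotate at least one gene")
    }
    if (any(vapply(object@sets, anyDuplicated, 0L) > 0)) {
      msg <- c(msg, "gene sets must not contain duplicates")
    }
    if (!identical(names(object@sets), names(object@descriptions))) {
      msg <- c(msg, "descriptions must align with term sets")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Permutation null distribution for candidate probabilities
#'
#' Per-candidate mean and standard deviation of random-walk probabilities
#' obtained from repeated runs with random seed sets of the same size as the
#' true seed set. Used to standardize each candidate's probability into a
#' Z-score.
#'
#' @slot mean named numeric vector: per-candidate null mean probability.
#' @slot sd named numeric vector: per-candidate sample standard deviation.
#' @slot nEffective named integer vector: number of draws entering each
#'   candidate's summary (equals `nPerm` unless self-seeded draws are
#'   excluded).
#' @slot nPerm number of random seed sets drawn.
#' @slot rngSeed RNG seed used to draw them.
#' @slot degreeMatched whether random sets were degree-matched to the seeds.
#' @slot excludeSelfDraws whether draws containing the candidate itself
#'   were excluded from its null summary.
#'
#' @seealso [permutationTest()], [zScore()]
#' @export
setClass("PermutationNull",
  slots = c(
    mean = "numeric",
    sd = "numeric",
    nEffective = "integer",
    nPerm = "integer",
    rngSeed = "integer",
    degreeMatched = "logical",
    excludeSelfDraws = "logical"
  )
)

setValidity("PermutationNull", function(object) {
  msg <- character()
  if (!identical(names(object@mean), names(object@sd)) ||
      !identical(names(object@mean), names(object@nEffective))) {
    msg <- c(msg, "mean, sd and nEffective must cover the same candidates")
  }
  if (any(object@sd < 0)) {
    msg <- c(msg, "standard deviations must be non-negative")
  }
  if (length(object@nPerm) != 1 || object@nPerm < 2) {
    msg <- c(msg, "at least two permutations are required")
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic benchmark bundle
#'
#' A self-contained desk-scale test bed: a weighted background network with
#' a densely interconnected high-confidence planted module, a seed set
#' sampled from the module (the "validated" genes), the held-out module
#' members (ground truth for recovery), the remaining decoy genes, and a
#' term-to-gene annotation map enriched in the module.
#'
#' @slot network the [PPINetwork-class] with the planted module.
#' @slot seeds module members used as seed genes.
#' @slot truths module members withheld from the seeds.
#' @slot decoys all non-module genes.
#' @slot annotations the [AnnotationMap-class] over the network's genes.
#' @slot params named list of every generation parameter, including the
#'   RNG seed.
#'
#' @seealso [makeBenchmark()], [writeFixtureBundle()]
#' @export
setClass("FixtureBundle",
  slots = c(
    network = "PPINetwork",
    seeds = "character",
    truths = "character",
    decoys = "character",
    annotations = "AnnotationMap",
    params = "list"
  )
)

setValidity("FixtureBundle", function(object) {
  msg <- character()
  nd <- nodes(object@network)
  if (length(intersect(object@seeds, object@truths))) {
    msg <- c(msg, "seeds and held-out truths must be disjoint")
  }
  if (!all(c(object@seeds, object@truths, object@decoys) %in% nd)) {
    msg <- c(msg, "all gene sets must lie inside the network")
  }
  if (length(msg)) msg else TRUE
})
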
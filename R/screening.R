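# The three screening filters applied to RWR candidates:
#   1. permutation Z-score against random seed sets of equal size
#      (controls hub bias: some nodes score highly whatever the seeds);
#   2. maximum linkage score (MLS): strongest direct edge to any validated
#      gene, cut at STRING's highest-confidence band (>= 900);
#   3. maximum enrichment score (MES): cosine similarity between
#      hypergeometric functional-annotation profiles, cut at >= 0.98.

#' Permutation null distribution of candidate probabilities
#'
#' Draws `nPerm` random seed sets of the same size as the true seed set,
#' reruns the random walk for each, and records every candidate's
#' probability, returning per-candidate mean and sample standard deviation.
#' Random sets are drawn uniformly from all network nodes (which may
#' include true seeds); with `degreeMatched = TRUE` each random node is
#' instead drawn from the degree decile of the seed it replaces, a stricter
#' null for hub-dominated networks.
#'
#' By default (`excludeSelfDraws = TRUE`) the draws in which a candidate
#' was itself sampled into the random seed set are excluded from that
#' candidate's mean and standard deviation: a self-seeded node receives at
#' least r/m restart probability directly, typically an order of magnitude
#' above anything propagation can deliver, and those spikes would swamp
#' the null standard deviation and drive every Z-score toward zero
#' regardless of signal. The null then measures what the candidate
#' receives *from* random seed sets, which is the quantity the true-seed
#' probability is compared against. Set `excludeSelfDraws = FALSE` for the
#' raw all-draws summary.
#'
#' @param net a [PPINetwork-class].
#' @param seeds the true seed set (defines the size of each random set).
#' @param candidates candidate genes: a character vector or the data.frame
#'   from [selectCandidates()].
#' @param nPerm number of random seed sets; default 1000.
#' @param rngSeed integer seed for the draws (required for
#'   reproducibility).
#' @param r,tol,maxIter random-walk parameters, as in [rwr()].
#' @param degreeMatched draw degree-matched rather than uniform sets.
#' @param excludeSelfDraws drop a candidate's self-seeded draws from its
#'   own null summary (default `TRUE`).
#' @return a [PermutationNull-class].
#' @export
permutationTest <- function(net, seeds, candidates, nPerm = 1000L,
                            rngSeed = 1L, r = 0.8, tol = 1e-6,
                            maxIter = 10000L, degreeMatched = FALSE,
                            excludeSelfDraws = TRUE) {
  if (!is.numeric(nPerm) || length(nPerm) != 1 || nPerm < 2) {
    .configError("at least 2 permutations are required (std undefined below)")
  }
  nPerm <- as.integer(nPerm)
  if (is.data.frame(candidates)) candidates <- candidates$gene
  candidates <- as.character(candidates)
  ids <- nodes(net)
  missing <- setdiff(candidates, ids)
  if (length(missing)) {
    .inputError(sprintf("candidate(s) not in network: %s",
                        paste(missing, collapse = ", ")))
  }
  seeds <- unique(as.character(seeds))
  m <- length(seeds)
  if (m > length(ids)) {
    .configError("seed set larger than the network")
  }

  M <- transitionMatrix(net)
  cidx <- match(candidates, ids)
  draws <- matrix(NA_real_, nrow = nPerm, ncol = length(candidates))
  selfSeeded <- matrix(FALSE, nrow = nPerm, ncol = length(candidates))

  if (degreeMatched) {
    deg <- degrees(net)
    bins <- .degreeBins(deg)
    seedBins <- bins[match(seeds, ids)]
    binMembers <- split(seq_along(ids), bins)
  }

  withr::with_seed(as.integer(rngSeed), {
    for (b in seq_len(nPerm)) {
      if (degreeMatched) {
        pick <- unlist(lapply(seedBins, function(bn) {
          pool <- binMembers[[as.character(bn)]]
          pool[sample.int(length(pool), 1)]
        }), use.names = FALSE)
        pick <- unique(pick)
        # collisions are resampled uniformly from unused nodes in any bin
        while (length(pick) < m) {
          extra <- sample.int(length(ids), m - length(pick))
          pick <- unique(c(pick, extra))
        }
      } else {
        pick <- sample.int(length(ids), m)
      }
      p0 <- numeric(length(ids))
      p0[pick] <- 1 / m
      p <- if (r == 1) p0 else .rwrIterate(M, p0, r, tol, maxIter)$p
      draws[b, ] <- p[cidx]
      selfSeeded[b, ] <- cidx %in% pick
      if (b %% 100 == 0) {
        message(sprintf("permutation %d/%d", b, nPerm))
      }
    }
  })

  use <- if (excludeSelfDraws) !selfSeeded else
    matrix(TRUE, nPerm, length(candidates))
  nEff <- colSums(use)
  if (any(nEff < 2)) {
    # a candidate drawn into nearly every random set keeps all its draws
    warning(sprintf(
      "%d candidate(s) self-seeded in all but <2 draws; using all draws for them",
      sum(nEff < 2)))
    use[, nEff < 2] <- TRUE
    nEff <- colSums(use)
  }
  mu <- vapply(seq_along(cidx),
               function(k) mean(draws[use[, k], k]), 0)
  sdv <- vapply(seq_along(cidx),
                function(k) stats::sd(draws[use[, k], k]), 0)
  new("PermutationNull",
      mean = structure(mu, names = candidates),
      sd = structure(sdv, names = candidates),
      nEffective = structure(as.integer(nEff), names = candidates),
      nPerm = nPerm, rngSeed = as.integer(rngSeed),
      degreeMatched = isTRUE(degreeMatched),
      excludeSelfDraws = isTRUE(excludeSelfDraws))
}

# Degree deciles over all nodes; constant-degree networks collapse to one
# bin.
.degreeBins <- function(deg) {
  qs <- unique(stats::quantile(deg, probs = seq(0, 1, 0.1)))
  if (length(qs) < 2) return(rep(1L, length(deg)))
  as.integer(cut(deg, breaks = qs, include.lowest = TRUE))
}

setMethod("show", "PermutationNull", function(object) {
  cat(sprintf(
    "PermutationNull over %d candidates (%d permutations, rngSeed %d%s%s)\n",
    length(object@mean), object@nPerm, object@rngSeed,
    if (object@degreeMatched) ", degree-matched" else "",
    if (object@excludeSelfDraws) ", self-draws excluded" else ""))
})

#' Permutation Z-score
#'
#' Standardizes a candidate's true-seed probability against its permutation
#' null: (pro - prom) / prostd. When the null standard deviation is zero
#' the score is +Inf when the probability exceeds the null mean, -Inf when
#' below it, and 0 when equal, preserving the pass/fail semantics of the
#' 1.96 cut.
#'
#' @param pro probability under the true seed set.
#' @param prom,prostd null mean and standard deviation (from
#'   [permutationTest()]).
#' @return numeric Z-score(s); vectorized.
#' @export
zScore <- function(pro, prom, prostd) {
  if (any(prostd < 0, na.rm = TRUE)) {
    .configError("null standard deviation must be non-negative")
  }
  z <- (pro - prom) / prostd
  deg <- prostd == 0
  if (any(deg)) {
    z[deg] <- sign(pro[deg] - prom[deg]) * Inf
    z[deg][pro[deg] == prom[deg]] <- 0
  }
  z
}

#' Maximum linkage score
#'
#' The strongest direct interaction between a candidate and any validated
#' gene: max over validated g' of the confidence score Q(candidate, g').
#' 0 when the candidate is adjacent to no validated gene.
#'
#' @param net a [PPINetwork-class].
#' @param candidate a node identifier.
#' @param validated character vector of validated gene identifiers.
#' @return numeric scalar in [0, max score].
#' @export
maxLinkageScore <- function(net, candidate, validated) {
  validated <- unique(as.character(validated))
  if (!length(validated)) {
    .inputError("validated gene set is empty")
  }
  ids <- nodes(net)
  if (!candidate %in% ids) {
    .inputError(sprintf("candidate not in network: %s", candidate))
  }
  validated <- intersect(validated, ids)
  if (!length(validated)) {
    .inputError("no validated gene is present in the network")
  }
  max(0, as.numeric(net@adjacency[validated, candidate]))
}

#' Hypergeometric enrichment score
#'
#' -log10 of the hypergeometric upper-tail probability of observing at
#' least `m` of a gene's `n` network neighbors inside a term annotating
#' `M` of `N` genes:
#' \deqn{ES = -\log_{10} \sum_{k=m}^{\min(n,M)}
#'   \frac{\binom{M}{k}\binom{N-M}{n-k}}{\binom{N}{n}}}
#' Computed in log space via [stats::phyper()] so small tails do not
#' underflow. `m = 0` gives a tail of 1 and a score of exactly 0.
#'
#' @param m overlap count (neighbors of the gene annotated by the term).
#' @param M number of genes annotated by the term.
#' @param n number of network neighbors of the gene.
#' @param N total number of genes in the universe.
#' @return numeric score(s) >= 0; vectorized over `m`, `M`, `n`.
#' @examples
#' hypergeomEnrichment(4, 5, 4, 10)  # -log10(5/210)
#' @export
hypergeomEnrichment <- function(m, M, n, N) {
  if (any(N < n) || any(N < M)) {
    .inputError("universe size N must be at least n and M")
  }
  if (any(m > pmin(n, M))) {
    .inputError("overlap m cannot exceed min(n, M)")
  }
  if (any(c(m, M, n, N) < 0)) {
    .inputError("hypergeometric counts must be non-negative")
  }
  -stats::phyper(m - 1, M, N - M, n, lower.tail = FALSE, log.p = TRUE) /
    log(10)
}

#' Enrichment score between a gene and one term
#'
#' Computes [hypergeomEnrichment()] with `n` the number of the gene's
#' network neighbors (its interacting genes), `m` the overlap between those
#' neighbors and the term's gene set, and `M` the term's size.
#'
#' @param gene a node identifier.
#' @param term a term identifier present in `ann`.
#' @param ann an [AnnotationMap-class].
#' @param net a [PPINetwork-class].
#' @param N total number of genes in the universe (default 20000, roughly
#'   the human protein-coding gene count).
#' @param neighborMinScore count only neighbors at confidence >= this
#'   (default 0: any positive confidence).
#' @return numeric scalar score.
#' @export
enrichmentScore <- function(gene, term, ann, net, N = 20000L,
                            neighborMinScore = 0) {
  nb <- neighborsOf(net, gene, minScore = neighborMinScore)
  genes <- termGenes(ann, term)
  hypergeomEnrichment(m = length(intersect(nb, genes)),
                      M = length(genes), n = length(nb), N = N)
}

#' Enrichment vector of a gene over all terms
#'
#' The per-term enrichment scores, in the annotation map's fixed term
#' order; every gene's vector shares that ordering so vectors are directly
#' comparable. A gene with no network neighbors gets an all-zero vector
#' (with a warning): n = 0 forces m = 0 and a tail of 1 for every term.
#'
#' @inheritParams enrichmentScore
#' @return named numeric vector over all terms.
#' @export
enrichmentVector <- function(gene, ann, net, N = 20000L,
                             neighborMinScore = 0) {
  nb <- neighborsOf(net, gene, minScore = neighborMinScore)
  if (!length(nb)) {
    warning(sprintf("gene %s has no network neighbors; zero vector", gene))
  }
  ms <- vapply(ann@sets, function(g) length(intersect(nb, g)), 0L)
  Ms <- lengths(ann@sets)
  structure(hypergeomEnrichment(m = ms, M = Ms, n = length(nb), N = N),
            names = names(ann@sets))
}

#' Enrichment vectors for many genes
#'
#' @inheritParams enrichmentScore
#' @param genes character vector of node identifiers.
#' @return numeric matrix, genes in rows and terms in columns.
#' @export
enrichmentVectors <- function(genes, ann, net, N = 20000L,
                              neighborMinScore = 0) {
  genes <- unique(as.character(genes))
  out <- matrix(0, nrow = length(genes), ncol = length(ann@sets),
                dimnames = list(genes, names(ann@sets)))
  for (g in genes) {
    out[g, ] <- suppressWarnings(
      enrichmentVector(g, ann, net, N = N,
                       neighborMinScore = neighborMinScore))
  }
  out
}

#' Cosine similarity between two enrichment vectors
#'
#' Dot product over the product of Euclidean norms; defined as 0 when
#' either vector has zero norm. For non-negative vectors the value lies in
#' [0, 1], reaching 1 only for positive multiples.
#'
#' @param v1,v2 numeric vectors of equal length.
#' @return numeric scalar.
#' @export
cosineSimilarity <- function(v1, v2) {
  if (length(v1) != length(v2)) {
    .inputError("enrichment vectors differ in length")
  }
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) return(0)
  sum(v1 * v2) / (n1 * n2)
}

#' Maximum enrichment score of a candidate
#'
#' The largest cosine similarity between the candidate's enrichment vector
#' and any validated gene's vector.
#'
#' @param candidate a gene identifier with a row in `vectors`.
#' @param validated validated gene identifiers, all with rows in `vectors`.
#' @param vectors matrix of enrichment vectors (genes in rows), from
#'   [enrichmentVectors()].
#' @return numeric scalar similarity.
#' @export
maxEnrichmentScore <- function(candidate, validated, vectors) {
  validated <- unique(as.character(validated))
  missing <- setdiff(c(candidate, validated), rownames(vectors))
  if (length(missing)) {
    .inputError(sprintf("no enrichment vector for: %s",
                        paste(missing, collapse = ", ")))
  }
  v <- vectors[candidate, ]
  max(vapply(validated, function(g) cosineSimilarity(v, vectors[g, ]), 0))
}

#' Apply the three screening filters to the candidate set
#'
#' Scores every candidate and flags the three cuts: permutation Z-score
#' strictly above `zCut`, maximum linkage score at or above `mlsCut`, and
#' maximum enrichment score at or above `mesCut`. A candidate passing all
#' three is marked inferred. With `lazy = TRUE`, MLS is computed only for
#' Z-passing genes and MES only for genes also passing MLS; skipped scores
#' are recorded as `NA` (distinguishable from a computed 0) and their pass
#' flags are `FALSE`.
#'
#' @param candidates data.frame from [selectCandidates()].
#' @param null a [PermutationNull-class] covering every candidate.
#' @param net a [PPINetwork-class].
#' @param validated validated gene identifiers.
#' @param vectors enrichment-vector matrix covering candidates and
#'   validated genes (rows), from [enrichmentVectors()].
#' @param zCut Z-score cut (strict >); default 1.96.
#' @param mlsCut linkage cut (inclusive >=); default 900.
#' @param mesCut enrichment cut (inclusive >=); default 0.98.
#' @param lazy skip MLS/MES for genes already eliminated.
#' @return data.frame of screening records, one row per candidate, sorted
#'   by descending MES then gene.
#' @export
applyFilters <- function(candidates, null, net, validated, vectors,
                         zCut = 1.96, mlsCut = 900, mesCut = 0.98,
                         lazy = FALSE) {
  if (!is.numeric(zCut) || length(zCut) != 1) {
    .configError("zCut must be a single number")
  }
  if (!is.numeric(mlsCut) || length(mlsCut) != 1 || mlsCut < 0) {
    .configError("mlsCut must be a single non-negative number")
  }
  if (!is.numeric(mesCut) || length(mesCut) != 1 || mesCut < 0 ||
      mesCut > 1) {
    .configError("mesCut must lie in [0, 1]")
  }
  genes <- candidates$gene
  miss <- setdiff(genes, names(null@mean))
  if (length(miss)) {
    .inputError(sprintf("candidate(s) missing from permutation null: %s",
                        paste(miss, collapse = ", ")))
  }
  pro <- candidates$probability
  z <- zScore(pro, unname(null@mean[genes]), unname(null@sd[genes]))
  passZ <- z > zCut

  mls <- rep(NA_real_, length(genes))
  doMls <- if (lazy) passZ else rep(TRUE, length(genes))
  mls[doMls] <- vapply(genes[doMls],
                       function(g) maxLinkageScore(net, g, validated), 0)
  passMls <- !is.na(mls) & mls >= mlsCut

  mes <- rep(NA_real_, length(genes))
  doMes <- if (lazy) passZ & passMls else rep(TRUE, length(genes))
  mes[doMes] <- vapply(genes[doMes],
                       function(g) maxEnrichmentScore(g, validated, vectors),
                       0)
  passMes <- !is.na(mes) & mes >= mesCut

  out <- data.frame(
    gene = genes,
    probability = pro,
    z_score = z,
    mls = mls,
    mes = mes,
    pass_permutation = passZ,
    pass_linkage = passMls,
    pass_enrichment = passMes,
    inferred = passZ & passMls & passMes,
    stringsAsFactors = FALSE
  )
  out <- out[order(-xtfrm(out$mes), out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
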
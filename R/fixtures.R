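# Desk-scale synthetic benchmarks with planted structure. The background
# is a preferential-attachment graph (hub-containing, like real PPI
# networks, and the very structure that motivates the permutation test);
# a densely interconnected high-confidence module is planted on top, seed
# genes are sampled from the module, and annotation terms are enriched in
# it, so every pipeline stage has recoverable signal.

.nodeNames <- function(n) {
  sprintf(paste0("g%0", nchar(as.character(n)), "d"), seq_len(n))
}

#' Generate a preferential-attachment background network
#'
#' Barabasi-Albert topology: each new node attaches to `attachDegree`
#' existing nodes with probability proportional to their degree, yielding
#' the heavy-tailed hub structure of real interaction networks. Integer
#' confidence weights are drawn uniformly from `weightRange`.
#'
#' @param nNodes number of nodes (> `attachDegree`).
#' @param attachDegree edges added per incoming node; default 3.
#' @param weightRange integer `c(low, high)` within 1..999; default
#'   `c(100, 899)`, i.e. everything below STRING's highest-confidence band.
#' @param rngSeed integer RNG seed.
#' @return a connected [PPINetwork-class].
#' @export
generateNetwork <- function(nNodes, attachDegree = 3L,
                            weightRange = c(100L, 899L), rngSeed = 1L) {
  if (!is.numeric(nNodes) || nNodes < attachDegree + 1) {
    .configError("nNodes must be at least attachDegree + 1")
  }
  if (length(weightRange) != 2 || weightRange[1] < 1 ||
      weightRange[2] > 999 || weightRange[1] > weightRange[2]) {
    .configError("weightRange must be 1 <= low <= high <= 999")
  }
  nNodes <- as.integer(nNodes)
  ids <- .nodeNames(nNodes)
  withr::with_seed(as.integer(rngSeed), {
    g <- igraph::sample_pa(nNodes, m = as.integer(attachDegree),
                           directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    wpool <- seq.int(weightRange[1], weightRange[2])
    w <- wpool[sample.int(length(wpool), nrow(el), replace = TRUE)]
  })
  buildNetwork(data.frame(protein1 = ids[el[, 1]], protein2 = ids[el[, 2]],
                          combined_score = as.numeric(w)))
}

#' Plant a high-confidence module into a network
#'
#' Chooses `moduleSize` nodes and connects each within-module pair
#' independently with probability `density` at confidence `withinWeight`;
#' existing edges are upgraded to the maximum of old and new weight. This
#' creates the densely interconnected, functionally coherent community a
#' disease-gene neighborhood is assumed to form.
#'
#' @param net a [PPINetwork-class].
#' @param moduleSize number of module nodes (>= 2).
#' @param withinWeight within-module confidence; default 950 (inside the
#'   >= 900 highest-confidence band so the linkage filter can recover the
#'   module).
#' @param density probability of each within-module edge; default 0.8.
#' @param rngSeed integer RNG seed.
#' @return list with `network` (the augmented [PPINetwork-class]) and
#'   `module` (character vector of module node identifiers).
#' @export
plantModule <- function(net, moduleSize, withinWeight = 950L,
                        density = 0.8, rngSeed = 1L) {
  if (!is.numeric(moduleSize) || moduleSize < 2) {
    .configError("moduleSize must be at least 2")
  }
  if (moduleSize > numNodes(net)) {
    .configError("moduleSize exceeds the network size")
  }
  if (density < 0 || density > 1) {
    .configError("density must lie in [0, 1]")
  }
  ids <- nodes(net)
  withr::with_seed(as.integer(rngSeed), {
    module <- sort(sample(ids, as.integer(moduleSize)))
    pairs <- utils::combn(module, 2)
    on <- stats::runif(ncol(pairs)) < density
  })
  if (any(on)) {
    A <- net@adjacency
    i <- match(pairs[1, on], ids)
    j <- match(pairs[2, on], ids)
    ij <- cbind(c(i, j), c(j, i))
    A[ij] <- pmax(A[ij], as.numeric(withinWeight))
    net <- new("PPINetwork",
               adjacency = methods::as(Matrix::drop0(A), "CsparseMatrix"))
  }
  list(network = net, module = module)
}

#' Generate term-to-gene annotations enriched in a module
#'
#' Produces `nModuleTerms` terms each covering at least 80% of the module
#' genes plus a few random filler genes, and `nBackgroundTerms` terms of
#' random genes, so that module genes share functional profiles the
#' enrichment filter can exploit.
#'
#' @param net a [PPINetwork-class].
#' @param module character vector of module gene identifiers.
#' @param nModuleTerms number of module-enriched terms; default 8.
#' @param nBackgroundTerms number of random background terms; default 40.
#' @param termSizeRange integer `c(low, high)` size of background terms;
#'   default `c(10, 40)`.
#' @param rngSeed integer RNG seed.
#' @return an [AnnotationMap-class].
#' @export
generateAnnotations <- function(net, module, nModuleTerms = 8L,
                                nBackgroundTerms = 40L,
                                termSizeRange = c(10L, 40L),
                                rngSeed = 1L) {
  if (nModuleTerms < 0 || nBackgroundTerms < 0) {
    .configError("term counts must be non-negative")
  }
  ids <- nodes(net)
  if (max(termSizeRange) > length(ids)) {
    .configError("term size exceeds the number of genes in the network")
  }
  other <- setdiff(ids, module)
  sets <- list()
  descs <- character()
  withr::with_seed(as.integer(rngSeed), {
    for (t in seq_len(nModuleTerms)) {
      coverage <- stats::runif(1, 0.8, 1)
      core <- sample(module, max(1, ceiling(coverage * length(module))))
      nFill <- sample.int(max(1, round(0.2 * length(module))), 1)
      fill <- sample(other, min(nFill, length(other)))
      id <- sprintf("MOD%03d", t)
      sets[[id]] <- unique(c(core, fill))
      descs[id] <- sprintf("module-enriched term %d", t)
    }
    for (t in seq_len(nBackgroundTerms)) {
      size <- sample(seq.int(termSizeRange[1], termSizeRange[2]), 1)
      id <- sprintf("BG%03d", t)
      sets[[id]] <- sort(sample(ids, size))
      descs[id] <- sprintf("background term %d", t)
    }
  })
  new("AnnotationMap", sets = sets, descriptions = descs)
}

#' Compose a complete planted-module benchmark
#'
#' Generates the background network, plants the module, splits it into
#' seed genes and held-out truth genes, and builds module-enriched
#' annotations. All generation parameters and the RNG seed are recorded in
#' the bundle.
#'
#' @param nNodes background network size; default 500.
#' @param moduleSize planted module size; default 40.
#' @param seedFraction fraction of the module used as seeds (the rest are
#'   held-out truths); default 0.5.
#' @param rngSeed integer RNG seed.
#' @param attachDegree,weightRange,withinWeight,density,nModuleTerms,nBackgroundTerms,termSizeRange
#'   passed to the component generators.
#' @return a [FixtureBundle-class].
#' @export
makeBenchmark <- function(nNodes = 500L, moduleSize = 40L,
                          seedFraction = 0.5, rngSeed = 1L,
                          attachDegree = 3L, weightRange = c(100L, 899L),
                          withinWeight = 950L, density = 0.8,
                          nModuleTerms = 8L, nBackgroundTerms = 40L,
                          termSizeRange = c(10L, 40L)) {
  if (seedFraction <= 0 || seedFraction >= 1) {
    .configError("seedFraction must lie strictly between 0 and 1")
  }
  rngSeed <- as.integer(rngSeed)
  net0 <- generateNetwork(nNodes, attachDegree, weightRange,
                          rngSeed = rngSeed)
  planted <- plantModule(net0, moduleSize, withinWeight, density,
                         rngSeed = rngSeed + 1L)
  ann <- generateAnnotations(planted$network, planted$module,
                             nModuleTerms, nBackgroundTerms,
                             termSizeRange, rngSeed = rngSeed + 2L)
  module <- planted$module
  nSeeds <- round(seedFraction * length(module))
  nSeeds <- min(max(nSeeds, 1L), length(module) - 1L)
  shuffled <- withr::with_seed(rngSeed + 3L, sample(module))
  seeds <- sort(shuffled[seq_len(nSeeds)])
  truths <- sort(shuffled[-seq_len(nSeeds)])
  new("FixtureBundle",
      network = planted$network, seeds = seeds, truths = truths,
      decoys = setdiff(nodes(planted$network), module),
      annotations = ann,
      params = list(nNodes = as.integer(nNodes),
                    moduleSize = as.integer(moduleSize),
                    seedFraction = seedFraction, rngSeed = rngSeed,
                    attachDegree = as.integer(attachDegree),
                    weightRange = as.integer(weightRange),
                    withinWeight = as.integer(withinWeight),
                    density = density,
                    nModuleTerms = as.integer(nModuleTerms),
                    nBackgroundTerms = as.integer(nBackgroundTerms),
                    termSizeRange = as.integer(termSizeRange)))
}

setMethod("show", "FixtureBundle", function(object) {
  cat(sprintf(
    "FixtureBundle: %d-node network, module of %d (%d seeds + %d truths), %d terms\n",
    numNodes(object@network),
    length(object@seeds) + length(object@truths),
    length(object@seeds), length(object@truths),
    length(object@annotations@sets)))
})

#' Write a fixture bundle to disk
#'
#' Emits `network.txt` (STRING links dialect, both edge directions listed,
#' with header), `seeds.txt`, `truths.txt`, `terms.gmt` and
#' `manifest.json` (generation parameters) into a directory, ready to feed
#' the pipeline.
#'
#' @param bundle a [FixtureBundle-class].
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
writeFixtureBundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  et <- edgeTable(bundle@network)
  lines <- c("protein1 protein2 combined_score",
             paste(et$protein1, et$protein2, et$combined_score),
             paste(et$protein2, et$protein1, et$combined_score))
  writeLines(lines, file.path(dir, "network.txt"))
  writeLines(bundle@seeds, file.path(dir, "seeds.txt"))
  writeLines(bundle@truths, file.path(dir, "truths.txt"))
  ann <- bundle@annotations
  gmt <- vapply(names(ann@sets), function(t) {
    paste(c(t, ann@descriptions[[t]], ann@sets[[t]]), collapse = "\t")
  }, "")
  writeLines(gmt, file.path(dir, "terms.gmt"))
  jsonlite::write_json(bundle@params, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a fixture bundle written by [writeFixtureBundle()]
#'
#' @param dir the fixture directory.
#' @return a [FixtureBundle-class].
#' @export
readFixtureBundle <- function(dir) {
  need <- file.path(dir, c("network.txt", "seeds.txt", "truths.txt",
                           "terms.gmt", "manifest.json"))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    .inputError(sprintf("fixture file(s) missing: %s",
                        paste(missing, collapse = ", ")))
  }
  net <- buildNetwork(readStringLinks(file.path(dir, "network.txt")))
  params <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                simplifyVector = TRUE)
  new("FixtureBundle",
      network = net,
      seeds = readGeneSet(file.path(dir, "seeds.txt")),
      truths = readGeneSet(file.path(dir, "truths.txt")),
      decoys = setdiff(nodes(net),
                       c(readGeneSet(file.path(dir, "seeds.txt")),
                         readGeneSet(file.path(dir, "truths.txt")))),
      annotations = readGmt(file.path(dir, "terms.gmt")),
      params = as.list(params))
}
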
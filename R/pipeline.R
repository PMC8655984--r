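# End-to-end orchestration: read inputs -> restrict seeds -> random walk ->
# candidate extraction -> permutation null -> three filters -> results +
# manifest. The manifest records every parameter, input checksum and
# per-stage count so a run is fully reproducible and auditable.

#' Assemble and validate a pipeline configuration
#'
#' @param network path to a STRING-style links file.
#' @param seeds path to a seed gene list.
#' @param annotations path to a GMT annotation file.
#' @param outDir output directory (created if absent).
#' @param r restart probability; default 0.8.
#' @param tol random-walk L1 tolerance; default 1e-6.
#' @param probThreshold candidate probability cutoff; default 1e-5.
#' @param nPerm permutation count; default 1000.
#' @param zCut,mlsCut,mesCut filter cuts; defaults 1.96, 900, 0.98.
#' @param totalGenes universe size N for enrichment; default 20000.
#' @param rngSeed integer RNG seed for the permutation draws.
#' @param maxIter random-walk iteration cap.
#' @param lazy skip MLS/MES for already-eliminated genes.
#' @param degreeMatchedNull degree-matched permutation draws.
#' @param excludeSelfDraws drop a candidate's self-seeded draws from its
#'   permutation null (see [permutationTest()]); default `TRUE`.
#' @param neighborMinScore confidence cutoff when counting enrichment
#'   neighbors; default 0 (any positive confidence).
#' @return a validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(network, seeds, annotations, outDir,
                           r = 0.8, tol = 1e-6, probThreshold = 1e-5,
                           nPerm = 1000L, zCut = 1.96, mlsCut = 900,
                           mesCut = 0.98, totalGenes = 20000L,
                           rngSeed = 1L, maxIter = 10000L, lazy = FALSE,
                           degreeMatchedNull = FALSE,
                           excludeSelfDraws = TRUE,
                           neighborMinScore = 0) {
  chkNum <- function(x, nm, lo = -Inf, hi = Inf, strictLo = FALSE) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) ||
        (if (strictLo) x <= lo else x < lo) || x > hi) {
      .configError(sprintf("invalid %s: %s", nm,
                           paste(format(x), collapse = ",")))
    }
  }
  chkNum(r, "restart probability r", 0, 1, strictLo = TRUE)
  chkNum(tol, "tolerance", 0, strictLo = TRUE)
  chkNum(probThreshold, "probability threshold", 0, strictLo = TRUE)
  chkNum(nPerm, "permutation count", 2)
  chkNum(zCut, "z cut")
  chkNum(mlsCut, "mls cut", 0)
  chkNum(mesCut, "mes cut", 0, 1)
  chkNum(totalGenes, "total gene count N", 1)
  chkNum(maxIter, "iteration cap", 1)
  chkNum(neighborMinScore, "neighbor min score", 0)
  structure(list(
    network = network, seeds = seeds, annotations = annotations,
    outDir = outDir, r = r, tol = tol, probThreshold = probThreshold,
    nPerm = as.integer(nPerm), zCut = zCut, mlsCut = mlsCut,
    mesCut = mesCut, totalGenes = as.integer(totalGenes),
    rngSeed = as.integer(rngSeed), maxIter = as.integer(maxIter),
    lazy = isTRUE(lazy), degreeMatchedNull = isTRUE(degreeMatchedNull),
    excludeSelfDraws = isTRUE(excludeSelfDraws),
    neighborMinScore = neighborMinScore
  ), class = "PipelineConfig")
}

#' Read a pipeline configuration file
#'
#' YAML (or simple `key: value`) file holding any subset of the
#' [pipelineConfig()] arguments; unspecified values fall back to defaults
#' and are overridden by explicit arguments in `...`.
#'
#' @param path path to the YAML config file.
#' @param ... overrides passed on to [pipelineConfig()].
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path, ...) {
  if (!file.exists(path)) {
    .inputError(sprintf("config file not found: %s", path))
  }
  vals <- yaml::read_yaml(path)
  over <- list(...)
  vals[names(over)] <- over
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    .configError(sprintf("unknown config key(s): %s",
                         paste(bad, collapse = ", ")))
  }
  do.call(pipelineConfig, vals)
}

.stageMessage <- function(stage, t0) {
  message(sprintf("[%s] done in %.2fs", stage,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full prioritization pipeline
#'
#' Executes read -> restrict seeds to network -> random walk with restart
#' -> candidate extraction -> permutation test -> three screening filters,
#' writes `results.tsv`, `interaction_summary.tsv` and `manifest.json` to
#' the output directory, and returns the in-memory results.
#'
#' @param config a `PipelineConfig` from [pipelineConfig()].
#' @return invisibly, a list with `records` (screening table), `summary`
#'   (the [interactionSummary()] of the inferred genes, `NULL` when none),
#'   and `manifest` (named list as written to JSON).
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "PipelineConfig")) {
    .configError("config must come from pipelineConfig()")
  }
  for (p in c(config$network, config$seeds, config$annotations)) {
    if (!file.exists(p)) .inputError(sprintf("input file not found: %s", p))
  }
  if (!dir.exists(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE)
  }

  stage <- function(name, expr) {
    t0 <- as.numeric(Sys.time())
    out <- withCallingHandlers(
      expr,
      error = function(e) {
        e$message <- sprintf("[stage %s] %s", name, conditionMessage(e))
        stop(e)
      })
    .stageMessage(name, t0)
    out
  }

  links <- stage("read-network", readStringLinks(config$network))
  net <- stage("build-network", buildNetwork(links))
  seedsRaw <- stage("read-seeds", readGeneSet(config$seeds))
  ann <- stage("read-annotations", readGmt(config$annotations))
  seeds <- stage("restrict-seeds", restrictToNetwork(seedsRaw, net))

  pv <- stage("rwr", rwr(net, seeds, r = config$r, tol = config$tol,
                         maxIter = config$maxIter))
  candidates <- stage("select-candidates",
                      selectCandidates(pv, seeds,
                                       threshold = config$probThreshold))

  if (nrow(candidates)) {
    null <- stage("permutation-test",
                  permutationTest(net, seeds, candidates,
                                  nPerm = config$nPerm,
                                  rngSeed = config$rngSeed,
                                  r = config$r, tol = config$tol,
                                  maxIter = config$maxIter,
                                  degreeMatched = config$degreeMatchedNull,
                                  excludeSelfDraws =
                                    config$excludeSelfDraws))
    vectors <- stage("enrichment-vectors",
                     enrichmentVectors(c(candidates$gene, seeds), ann, net,
                                       N = config$totalGenes,
                                       neighborMinScore =
                                         config$neighborMinScore))
    records <- stage("apply-filters",
                     applyFilters(candidates, null, net, seeds, vectors,
                                  zCut = config$zCut,
                                  mlsCut = config$mlsCut,
                                  mesCut = config$mesCut,
                                  lazy = config$lazy))
  } else {
    records <- data.frame(
      gene = character(), probability = numeric(), z_score = numeric(),
      mls = numeric(), mes = numeric(), pass_permutation = logical(),
      pass_linkage = logical(), pass_enrichment = logical(),
      inferred = logical(), stringsAsFactors = FALSE)
  }

  inferred <- records$gene[records$inferred]
  summary <- NULL
  if (length(inferred)) {
    summary <- interactionSummary(inferred, seeds, net,
                                  cutoff = config$mlsCut)
    .writeInteractionSummary(file.path(config$outDir,
                                       "interaction_summary.tsv"), summary)
  }

  writeResults(file.path(config$outDir, "results.tsv"), records)

  manifest <- list(
    parameters = config[setdiff(names(config),
                                c("network", "seeds", "annotations",
                                  "outDir"))],
    inputs = lapply(
      stats::setNames(
        c(config$network, config$seeds, config$annotations),
        c("network", "seeds", "annotations")),
      function(p) list(path = p, md5 = unname(tools::md5sum(p)))),
    counts = list(
      network_nodes = numNodes(net),
      network_edges = numEdges(net),
      seeds_supplied = length(seedsRaw),
      seeds_in_network = length(seeds),
      candidates = nrow(records),
      z_pass = sum(records$pass_permutation),
      mls_pass = sum(records$pass_permutation & records$pass_linkage),
      inferred = sum(records$inferred)
    )
  )
  jsonlite::write_json(manifest,
                       file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(records = records, summary = summary,
                 manifest = manifest))
}

#' Summarize high-confidence interactions of the inferred genes
#'
#' For each inferred gene, counts its validated interaction partners at
#' confidence at or above the cutoff, and reports the mean count and the
#' fraction of inferred genes with more than five such partners.
#'
#' @param inferred character vector of inferred gene identifiers.
#' @param validated character vector of validated gene identifiers.
#' @param net a [PPINetwork-class].
#' @param cutoff confidence cutoff (inclusive); default 900.
#' @return list with `counts` (named integer vector), `mean`, and
#'   `fractionOver5`.
#' @export
interactionSummary <- function(inferred, validated, net, cutoff = 900) {
  inferred <- unique(as.character(inferred))
  if (!length(inferred)) {
    .inputError("inferred gene set is empty")
  }
  validated <- intersect(unique(as.character(validated)), nodes(net))
  counts <- vapply(inferred, function(g) {
    nb <- neighborsOf(net, g, minScore = cutoff)
    length(intersect(nb, validated))
  }, 0L)
  list(counts = counts, mean = mean(counts),
       fractionOver5 = mean(counts > 5))
}

.writeInteractionSummary <- function(path, summary) {
  rows <- c(
    "gene\thigh_confidence_validated_partners",
    paste(names(summary$counts), summary$counts, sep = "\t"),
    sprintf("#mean\t%.17g", summary$mean),
    sprintf("#fraction_over_5\t%.17g", summary$fractionOver5)
  )
  writeLines(rows, path)
  invisible(path)
}
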
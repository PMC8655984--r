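# Random walk with restart over the column-stochastic transition operator:
#   P(t+1) = (1 - r) * M %*% P(t) + r * P0,   P(0) = P0,
# iterated until the L1 change drops below tol. With restart probability r
# the map contracts at factor (1 - r) per step, so convergence is fast and
# a blown iteration cap signals bad input rather than slow mixing.

#' Initial probability vector over seed nodes
#'
#' Each of the m seed nodes receives probability 1/m; every other node 0.
#'
#' @param net a [PPINetwork-class].
#' @param seeds character vector of seed identifiers, all present in the
#'   network.
#' @return a [ProbabilityVector-class] with zero iterations.
#' @export
initProbability <- function(net, seeds) {
  seeds <- unique(as.character(seeds))
  if (!length(seeds)) {
    .inputError("at least one seed gene is required")
  }
  ids <- nodes(net)
  missing <- setdiff(seeds, ids)
  if (length(missing)) {
    .inputError(sprintf("seed gene(s) not in network: %s",
                        paste(missing, collapse = ", ")))
  }
  p0 <- structure(numeric(length(ids)), names = ids)
  p0[seeds] <- 1 / length(seeds)
  new("ProbabilityVector", probs = p0, restart = 1, iterations = 0L,
      residual = 0, seeds = seeds)
}

# Core iteration on a prebuilt transition matrix; used directly by the
# permutation test so the matrix is factored out of the per-permutation
# cost.
.rwrIterate <- function(M, p0, r, tol, maxIter) {
  p <- p0
  for (iter in seq_len(maxIter)) {
    pNext <- as.numeric((1 - r) * (M %*% p)) + r * p0
    res <- sum(abs(pNext - p))
    p <- pNext
    if (res < tol) {
      return(list(p = p, iterations = iter, residual = res))
    }
  }
  .convergenceError(
    sprintf("random walk did not converge in %d iterations (L1 residual %.3g)",
            maxIter, res),
    residual = res
  )
}

#' Random walk with restart
#'
#' Propagates probability from the seed nodes across the network and
#' returns the converged per-node probabilities. The walker restarts at the
#' seed distribution with probability `r` at every step; the remaining mass
#' moves along edges proportionally to confidence scores.
#'
#' If the network has isolated nodes their zero transition columns leak
#' probability mass; a warning is raised when the converged vector sums to
#' less than 1 by more than 1e-9, rather than silently renormalizing.
#'
#' @param net a [PPINetwork-class].
#' @param seeds character vector of seed identifiers.
#' @param r restart probability in (0, 1]; default 0.8.
#' @param tol L1 convergence tolerance; default 1e-6.
#' @param maxIter iteration cap; default 10000.
#' @return a [ProbabilityVector-class].
#' @examples
#' net <- buildNetwork(data.frame(protein1 = "n1", protein2 = "n2",
#'                                combined_score = 500))
#' probabilities(rwr(net, "n1"))  # (0.8333, 0.1667)
#' @export
rwr <- function(net, seeds, r = 0.8, tol = 1e-6, maxIter = 10000L) {
  if (!is.numeric(r) || length(r) != 1 || r <= 0 || r > 1) {
    .configError("restart probability r must be in (0, 1]")
  }
  if (!is.numeric(tol) || length(tol) != 1 || tol <= 0) {
    .configError("tolerance must be positive")
  }
  p0vec <- initProbability(net, seeds)
  p0 <- p0vec@probs
  if (r == 1) {
    return(new("ProbabilityVector", probs = p0, restart = 1,
               iterations = 1L, residual = 0, seeds = p0vec@seeds))
  }
  M <- transitionMatrix(net)
  fit <- .rwrIterate(M, p0, r, tol, as.integer(maxIter))
  probs <- structure(fit$p, names = names(p0))
  if (abs(sum(probs) - 1) > 1e-9) {
    warning(sprintf(
      "probability mass %.12f differs from 1 (isolated nodes leak mass)",
      sum(probs)))
  }
  new("ProbabilityVector", probs = probs, restart = r,
      iterations = as.integer(fit$iterations), residual = fit$residual,
      seeds = p0vec@seeds)
}

#' @rdname probabilities
#' @export
setMethod("probabilities", "ProbabilityVector", function(x) x@probs)

setMethod("show", "ProbabilityVector", function(object) {
  cat(sprintf(
    "ProbabilityVector over %d nodes (%d seeds, r = %g, %d iterations, L1 residual %.3g)\n",
    length(object@probs), length(object@seeds), object@restart,
    object@iterations, object@residual))
  top <- sort(object@probs, decreasing = TRUE)
  top <- utils::head(top, 5)
  cat("  top nodes:", paste(sprintf("%s=%.3g", names(top), top),
                            collapse = ", "), "\n")
})

#' Extract candidate genes above a probability threshold
#'
#' Non-seed nodes whose converged probability is at or above the threshold,
#' sorted by descending probability with ties broken by gene identifier.
#' Seed genes are excluded: the goal is novel candidates, and retaining
#' seeds would contaminate every downstream filter.
#'
#' @param p a [ProbabilityVector-class].
#' @param seeds seed identifiers to exclude (defaults to the seeds recorded
#'   in `p`).
#' @param threshold inclusive probability cutoff; default 1e-5.
#' @return data.frame with columns `gene`, `probability`.
#' @export
selectCandidates <- function(p, seeds = p@seeds, threshold = 1e-5) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    .configError("probability threshold must be positive")
  }
  probs <- p@probs
  keep <- probs >= threshold & !(names(probs) %in% seeds)
  genes <- names(probs)[keep]
  vals <- unname(probs[keep])
  ord <- order(-vals, genes)
  out <- data.frame(gene = genes[ord], probability = vals[ord],
                    stringsAsFactors = FALSE)
  if (!nrow(out)) {
    message("no candidate gene reached the probability threshold")
  }
  rownames(out) <- NULL
  out
}
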
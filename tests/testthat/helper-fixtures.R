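# Shared builders and independent oracles for the test suite.

edgeDf <- function(p1, p2, w) {
  data.frame(protein1 = p1, protein2 = p2, combined_score = w,
             stringsAsFactors = FALSE)
}

# a - b - c path with equal weights
pathNet <- function(w = 500) {
  buildNetwork(edgeDf(c("a", "b"), c("b", "c"), c(w, w)))
}

# Random connected network (Erdos-Renyi, retried until connected), with
# uniform positive weights; used as the random case pool for property
# tests.
randomConnectedNet <- function(n, pEdge = 0.15, seed = 1) {
  withr::with_seed(seed, {
    repeat {
      g <- igraph::sample_gnp(n, pEdge)
      if (igraph::is_connected(g)) break
    }
    el <- igraph::as_edgelist(g, names = FALSE)
    w <- sample(1:999, nrow(el), replace = TRUE)
  })
  ids <- sprintf("n%03d", seq_len(n))
  buildNetwork(edgeDf(ids[el[, 1]], ids[el[, 2]], as.numeric(w)))
}

# Independent RWR oracle: direct linear solve of the fixed point
# P = r (I - (1-r) M)^{-1} P0 with dense base-R arithmetic.
rwrLinearSolve <- function(net, seeds, r = 0.8) {
  M <- as.matrix(transitionMatrix(net))
  ids <- nodes(net)
  p0 <- numeric(length(ids))
  p0[match(seeds, ids)] <- 1 / length(seeds)
  structure(as.numeric(solve(diag(length(ids)) - (1 - r) * M, r * p0)),
            names = ids)
}

# Independent hypergeometric oracle: exhaustive enumeration of the upper
# tail with choose(), no phyper.
hyperTailEnum <- function(m, M, n, N) {
  ks <- seq.int(m, min(n, M))
  ks <- ks[ks >= max(0, n - (N - M))]
  if (!length(ks)) return(0)
  sum(choose(M, ks) * choose(N - M, n - ks)) / choose(N, n)
}
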
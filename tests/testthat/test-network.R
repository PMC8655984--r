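test_that("buildNetwork collapses duplicates, drops self-loops, rejects bad scores", {
  # symmetric duplicate (STRING lists both directions) collapses to one edge
  net <- buildNetwork(edgeDf(c("a", "b"), c("b", "a"), c(900, 900)))
  expect_equal(numNodes(net), 2L)
  expect_equal(numEdges(net), 1L)
  expect_equal(confidence(net, "a", "b"), 900)

  net2 <- buildNetwork(edgeDf(c("a", "b"), c("b", "c"), c(900, 150)))
  expect_equal(numNodes(net2), 3L)
  expect_equal(numEdges(net2), 2L)

  # self-loop dropped with warning
  expect_warning(net3 <- buildNetwork(edgeDf("a", "a", 500)), "self-loop")
  expect_equal(numNodes(net3), 1L)
  expect_equal(numEdges(net3), 0L)

  # conflicting duplicate keeps the maximum, with a warning
  expect_warning(
    net4 <- buildNetwork(edgeDf(c("a", "a"), c("b", "b"), c(900, 800))),
    "conflicting")
  expect_equal(confidence(net4, "a", "b"), 900)

  expect_error(buildNetwork(edgeDf("a", "b", 0)), "non-positive")
  expect_error(buildNetwork(edgeDf("a", "b", -5)), "non-positive")
})

test_that("node ordering is lexicographic and invariant to input order", {
  e <- edgeDf(c("zeta", "alpha", "mid"), c("alpha", "mid", "zeta"),
              c(10, 20, 30))
  net1 <- buildNetwork(e)
  net2 <- buildNetwork(e[c(3, 1, 2), ])
  net3 <- buildNetwork(edgeDf(e$protein2, e$protein1, e$combined_score))
  expect_identical(nodes(net1), c("alpha", "mid", "zeta"))
  expect_identical(net1@adjacency, net2@adjacency)
  expect_identical(net1@adjacency, net3@adjacency)
})

test_that("transition matrix is column-stochastic with hand-checked entries", {
  # single edge: each node steps to its only neighbor with probability 1
  net <- buildNetwork(edgeDf("a", "b", 777))
  M <- as.matrix(transitionMatrix(net))
  expect_equal(unname(M), rbind(c(0, 1), c(1, 0)))

  # path a-b-c equal weights: column for b splits evenly
  Mp <- as.matrix(transitionMatrix(pathNet()))
  expect_equal(unname(Mp[, "b"]), c(0.5, 0, 0.5))

  # star with weights 1 and 3: center column normalizes to 1/4, 3/4
  star <- buildNetwork(edgeDf(c("c", "c"), c("l1", "l2"), c(1, 3)))
  Ms <- as.matrix(transitionMatrix(star))
  expect_equal(unname(Ms[c("l1", "l2"), "c"]), c(0.25, 0.75))
})

test_that("columns sum to one on random networks; isolated nodes give zero columns", {
  for (s in 1:20) {
    net <- randomConnectedNet(sample(5:40, 1), seed = s)
    cs <- Matrix::colSums(transitionMatrix(net))
    expect_lt(max(abs(cs - 1)), 1e-12)
  }
  # a node with no edges: its column is all zero
  expect_warning(iso <- buildNetwork(edgeDf(c("a", "c"), c("b", "c"),
                                            c(5, 5))), "self-loop")
  cs <- Matrix::colSums(transitionMatrix(iso))
  expect_equal(unname(cs[c("a", "b")]), c(1, 1))
  expect_equal(unname(cs["c"]), 0)
})

test_that("confidence lookup is symmetric and errors on unknown nodes", {
  net <- buildNetwork(edgeDf(c("a", "b"), c("b", "c"), c(998, 150)))
  expect_equal(confidence(net, "a", "b"), 998)
  expect_equal(confidence(net, "b", "a"), 998)
  expect_equal(confidence(net, "a", "c"), 0)
  expect_error(confidence(net, "a", "nope"), "not in network")
  # symmetry across all pairs of a random network
  net2 <- randomConnectedNet(12, seed = 3)
  ids <- nodes(net2)
  for (u in ids[1:4]) for (v in ids) {
    expect_identical(confidence(net2, u, v), confidence(net2, v, u))
  }
})

test_that("degrees and neighborsOf honor the confidence cutoff", {
  net <- buildNetwork(edgeDf(c("a", "a", "b"), c("b", "c", "c"),
                             c(950, 100, 400)))
  expect_equal(unname(degrees(net)), c(2L, 2L, 2L))
  expect_equal(unname(degrees(net, minScore = 900)), c(1L, 1L, 0L))
  expect_identical(neighborsOf(net, "a"), c("b", "c"))
  expect_identical(neighborsOf(net, "a", minScore = 900), "b")
})

test_that("edgeTable inverts buildNetwork", {
  net <- randomConnectedNet(15, seed = 9)
  et <- edgeTable(net)
  net2 <- buildNetwork(et)
  expect_identical(net@adjacency, net2@adjacency)
  expect_true(all(et$protein1 < et$protein2))
})
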
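test_that("background network has the construction-rule edge count and is reproducible", {
  net <- generateNetwork(100, attachDegree = 2, rngSeed = 4)
  expect_equal(numNodes(net), 100L)
  # d(d+1)/2 seed edges + d per later node: 3 + 2*97 = 197
  expect_equal(numEdges(net), 197L)
  g <- igraph::graph_from_data_frame(edgeTable(net), directed = FALSE)
  expect_true(igraph::is_connected(g))

  same <- generateNetwork(100, attachDegree = 2, rngSeed = 4)
  expect_identical(net@adjacency, same@adjacency)
  other <- generateNetwork(100, attachDegree = 2, rngSeed = 5)
  expect_false(identical(net@adjacency, other@adjacency))

  fixed <- generateNetwork(30, attachDegree = 2,
                           weightRange = c(900, 900), rngSeed = 1)
  expect_true(all(fixed@adjacency@x == 900))
  expect_error(generateNetwork(2, attachDegree = 3), "attachDegree")
  expect_error(generateNetwork(10, weightRange = c(0, 10)), "weightRange")
})

test_that("module planting densifies the chosen nodes at the given weight", {
  net <- generateNetwork(60, rngSeed = 2)
  res <- plantModule(net, 5, density = 1, rngSeed = 8)
  A <- res$network@adjacency[res$module, res$module]
  off <- A[upper.tri(as.matrix(A))]
  expect_true(all(off >= 950))  # clique; pre-existing stronger edges kept

  unchanged <- plantModule(net, 5, density = 0, rngSeed = 8)
  expect_identical(unchanged$network@adjacency, net@adjacency)

  # planted modules have higher within-module confidence than random sets
  res2 <- plantModule(net, 8, density = 0.8, rngSeed = 9)
  meanWithin <- function(nodeSet) {
    A <- res2$network@adjacency[nodeSet, nodeSet]
    mean(A[upper.tri(as.matrix(A))])
  }
  planted <- meanWithin(res2$module)
  rand <- withr::with_seed(10, replicate(100, {
    meanWithin(sample(nodes(net), 8))
  }))
  expect_gte(mean(planted > rand), 0.99)
  expect_error(plantModule(net, 1), "moduleSize")
})

test_that("annotations cover the module densely and are reproducible", {
  net <- generateNetwork(80, rngSeed = 3)
  module <- nodes(net)[1:10]
  ann <- generateAnnotations(net, module, nModuleTerms = 4,
                             nBackgroundTerms = 6, rngSeed = 12)
  expect_equal(length(termIds(ann)), 10L)
  modTerms <- grep("^MOD", termIds(ann), value = TRUE)
  expect_equal(length(modTerms), 4L)
  for (t in modTerms) {
    expect_gte(length(intersect(termGenes(ann, t), module)),
               ceiling(0.8 * length(module)))
  }
  same <- generateAnnotations(net, module, nModuleTerms = 4,
                              nBackgroundTerms = 6, rngSeed = 12)
  expect_identical(ann@sets, same@sets)

  noMod <- generateAnnotations(net, module, nModuleTerms = 0,
                               nBackgroundTerms = 3, rngSeed = 1)
  expect_false(any(startsWith(termIds(noMod), "MOD")))
  expect_error(generateAnnotations(net, module, termSizeRange = c(10, 1e5)),
               "term size")
})

test_that("benchmark bundle splits the module and serializes round-trip", {
  b <- makeBenchmark(nNodes = 120, moduleSize = 12, rngSeed = 6)
  expect_equal(length(b@seeds), 6L)
  expect_equal(length(b@truths), 6L)
  expect_length(intersect(b@seeds, b@truths), 0)
  expect_setequal(c(b@seeds, b@truths, b@decoys), nodes(b@network))

  b2 <- makeBenchmark(nNodes = 120, moduleSize = 12, seedFraction = 0.9,
                      rngSeed = 6)
  expect_equal(length(b2@seeds), 11L)  # round(0.9*12)
  expect_equal(length(b2@truths), 1L)

  d <- withr::local_tempdir()
  writeFixtureBundle(b, d)
  back <- readFixtureBundle(d)
  expect_identical(back@network@adjacency, b@network@adjacency)
  expect_identical(back@seeds, b@seeds)
  expect_identical(back@truths, b@truths)
  expect_identical(back@annotations@sets, b@annotations@sets)

  expect_error(makeBenchmark(seedFraction = 1), "seedFraction")
})
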
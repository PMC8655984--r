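test_that("z-score arithmetic and degenerate-sd policy", {
  expect_equal(zScore(0.5, 0.3, 0.1), 2.0)
  expect_equal(zScore(0.3, 0.3, 0.1), 0)
  expect_identical(zScore(0.2, 0.1, 0), Inf)
  expect_identical(zScore(0.1, 0.2, 0), -Inf)
  expect_identical(zScore(0.1, 0.1, 0), 0)
  # vectorized with mixed degenerate entries
  expect_equal(zScore(c(0.5, 0.2, 0.1), c(0.3, 0.1, 0.1), c(0.1, 0, 0)),
               c(2, Inf, 0))
  expect_error(zScore(0.1, 0.1, -1), "non-negative")
})

test_that("permutation null is reproducible and matches a high-rep reference", {
  net <- randomConnectedNet(30, seed = 21)
  seeds <- nodes(net)[1:4]
  cand <- setdiff(nodes(net), seeds)[1:6]

  n1 <- permutationTest(net, seeds, cand, nPerm = 200, rngSeed = 9)
  n2 <- permutationTest(net, seeds, cand, nPerm = 200, rngSeed = 9)
  expect_identical(n1@mean, n2@mean)
  expect_identical(n1@sd, n2@sd)
  expect_true(all(n1@sd >= 0))
  expect_equal(n1@nPerm, 200L)

  # mean agrees with an independent higher-rep run within 3 standard errors
  ref <- permutationTest(net, seeds, cand, nPerm = 2000, rngSeed = 101)
  se <- ref@sd / sqrt(n1@nEffective)
  expect_true(all(abs(n1@mean - ref@mean) < 3 * se))

  expect_error(permutationTest(net, seeds, cand, nPerm = 1), "2 permutations")
})

test_that("self-seeded draws are excluded from a candidate's null by default", {
  net <- randomConnectedNet(20, seed = 31)
  seeds <- nodes(net)[1:5]
  cand <- setdiff(nodes(net), seeds)[1:5]
  withSelf <- permutationTest(net, seeds, cand, nPerm = 150, rngSeed = 3,
                              excludeSelfDraws = FALSE)
  noSelf <- permutationTest(net, seeds, cand, nPerm = 150, rngSeed = 3)
  # with 5 of 20 nodes drawn each time, every candidate self-seeds often;
  # dropping those r/m spikes must shrink both the mean and the sd
  expect_true(all(noSelf@mean < withSelf@mean))
  expect_true(all(noSelf@sd < withSelf@sd))
  expect_true(all(noSelf@nEffective < 150L))
  expect_true(all(withSelf@nEffective == 150L))
})

test_that("maximum linkage score takes the strongest validated edge", {
  net <- buildNetwork(edgeDf(c("x", "x", "x", "v2"),
                             c("v1", "v2", "v3", "v3"),
                             c(300, 950, 10, 999)))
  expect_equal(maxLinkageScore(net, "x", c("v1", "v2", "v3")), 950)
  # no adjacency to any validated gene
  expect_equal(maxLinkageScore(net, "v1", c("v2", "v3")), 0)
  # exactly 900 passes the inclusive cut downstream
  net2 <- buildNetwork(edgeDf("c", "v", 900))
  expect_equal(maxLinkageScore(net2, "c", "v"), 900)
  expect_error(maxLinkageScore(net, "x", character()), "empty")
  expect_error(maxLinkageScore(net, "nope", "v1"), "not in network")
})

test_that("hypergeometric scores match exhaustive enumeration", {
  # hand-checked: N=10, M=5, n=4 -> tails 5/210 and 155/210
  expect_equal(hypergeomEnrichment(4, 5, 4, 10), -log10(5 / 210),
               tolerance = 1e-10)
  expect_equal(hypergeomEnrichment(2, 5, 4, 10), -log10(155 / 210),
               tolerance = 1e-10)
  expect_equal(hypergeomEnrichment(0, 5, 4, 10), 0)

  for (N in c(5, 11, 17, 20)) {
    for (M in 0:N) {
      for (n in c(0, 1, N %/% 2, N)) {
        for (m in 0:min(n, M)) {
          expect_equal(hypergeomEnrichment(m, M, n, N),
                       -log10(hyperTailEnum(m, M, n, N)),
                       tolerance = 1e-10)
        }
      }
    }
  }
  expect_error(hypergeomEnrichment(3, 2, 4, 10), "exceed")
  expect_error(hypergeomEnrichment(1, 2, 12, 10), "universe")
})

test_that("enrichment vectors share term order and handle edge cases", {
  net <- buildNetwork(edgeDf(c("g", "g", "g", "g", "h", "h", "h", "h"),
                             c("x1", "x2", "x3", "x4",
                               "x1", "x2", "x3", "x4"),
                             rep(500, 8)))
  f <- withr::local_tempfile()
  writeLines(c("T1\td\tx1\tx2\tx3\tx4\tzz",
               "T2\td\tx1\ty1\ty2\ty3"), f)
  ann <- readGmt(f)

  # op-level hand case: N=10, M=5, n=4, m=4
  expect_equal(enrichmentScore("g", "T1", ann, net, N = 10),
               -log10(5 / 210), tolerance = 1e-10)

  vg <- enrichmentVector("g", ann, net, N = 10)
  expect_identical(names(vg), c("T1", "T2"))
  # identical neighborhoods give identical vectors
  vh <- enrichmentVector("h", ann, net, N = 10)
  expect_identical(vg, vh)

  # a neighbor-less gene gets an all-zero vector with a warning
  expect_warning(netIso <- buildNetwork(edgeDf(c("a", "z"), c("b", "z"),
                                               c(5, 5))), "self-loop")
  expect_warning(vz <- enrichmentVector("z", ann, netIso, N = 10),
                 "no network neighbors")
  expect_true(all(vz == 0))

  mat <- suppressWarnings(enrichmentVectors(c("g", "h", "x1"), ann, net,
                                            N = 10))
  expect_identical(dim(mat), c(3L, 2L))
  expect_equal(mat["g", ], vg)
})

test_that("cosine similarity is bounded, symmetric, and hand-checked", {
  v <- c(1, 2, 3)
  expect_equal(cosineSimilarity(v, 2 * v), 1)
  expect_equal(cosineSimilarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosineSimilarity(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_equal(cosineSimilarity(c(0, 0), c(1, 1)), 0)  # zero norm
  expect_error(cosineSimilarity(c(1, 2), c(1, 2, 3)), "length")
  # bounded in [0, 1] for non-negative vectors; 1 only for multiples
  withr::with_seed(5, {
    for (i in 1:25) {
      a <- runif(6); b <- runif(6)
      s <- cosineSimilarity(a, b)
      expect_gte(s, 0); expect_lte(s, 1)
      expect_lt(s, 1)  # independent draws are almost surely not parallel
    }
  })
})

test_that("maximum enrichment score maximizes over validated vectors", {
  vectors <- rbind(cand = c(1, 1, 0), v1 = c(0.3, 0, 1), v2 = c(2, 2, 0))
  expect_equal(maxEnrichmentScore("cand", c("v1", "v2"), vectors), 1)
  vOrth <- rbind(cand = c(1, 0), v1 = c(0, 1))
  expect_equal(maxEnrichmentScore("cand", "v1", vOrth), 0)
  expect_error(maxEnrichmentScore("cand", "ghost", vectors), "ghost")
  # invariant to iteration order over validated genes
  expect_equal(maxEnrichmentScore("cand", c("v2", "v1"), vectors),
               maxEnrichmentScore("cand", c("v1", "v2"), vectors))
})

test_that("filter cascade computes all scores with correct boundary semantics", {
  net <- buildNetwork(edgeDf(c("c1", "c2", "c1", "s1"),
                             c("s1", "s2", "s2", "s2"),
                             c(950, 899, 900, 999)))
  cand <- data.frame(gene = c("c1", "c2"), probability = c(4e-4, 2e-5),
                     stringsAsFactors = FALSE)
  null <- new("PermutationNull",
              mean = c(c1 = 1e-4, c2 = 1e-5),
              sd = c(c1 = 1e-4, c2 = 1e-5),
              nEffective = c(c1 = 100L, c2 = 100L),
              nPerm = 100L, rngSeed = 1L, degreeMatched = FALSE,
              excludeSelfDraws = TRUE)
  vecs <- rbind(c1 = c(3, 3, 0.1), c2 = c(0, 1, 5),
                s1 = c(3.2, 2.9, 0), s2 = c(0.1, 0.2, 4))

  rec <- applyFilters(cand, null, net, c("s1", "s2"), vecs, mesCut = 0.9)
  r1 <- rec[rec$gene == "c1", ]
  expect_equal(r1$z_score, 3)                 # (4e-4 - 1e-4)/1e-4
  expect_equal(r1$mls, 950)
  expect_true(r1$pass_permutation && r1$pass_linkage)
  expect_true(r1$inferred == (r1$pass_permutation && r1$pass_linkage &&
                              r1$pass_enrichment))

  # z exactly at the cut fails (strict); mls exactly at 900 passes
  cand2 <- data.frame(gene = "c1", probability = 1e-4 + 1.96 * 1e-4)
  rec2 <- applyFilters(cand2, null, net, "s2", vecs)
  expect_false(rec2$pass_permutation)
  expect_equal(rec2$mls, 900)
  expect_true(rec2$pass_linkage)

  # mes exactly at the cut passes (inclusive)
  vecsEq <- rbind(c1 = c(1, 0), c2 = c(0, 1), s2 = c(1, 0))
  rec3 <- applyFilters(cand, null, net, "s2", vecsEq, mesCut = 1)
  expect_true(rec3$pass_enrichment[rec3$gene == "c1"])
  expect_false(rec3$pass_enrichment[rec3$gene == "c2"])

  expect_error(applyFilters(cand, null, net, "s2", vecs, mesCut = 2),
               "mesCut")
})

test_that("lazy evaluation records skipped scores as NA, never as zero", {
  net <- buildNetwork(edgeDf(c("c1", "c2"), c("s1", "s1"), c(950, 950)))
  cand <- data.frame(gene = c("c1", "c2"), probability = c(4e-4, 1e-5))
  null <- new("PermutationNull",
              mean = c(c1 = 1e-4, c2 = 1e-4),
              sd = c(c1 = 1e-4, c2 = 1e-4),
              nEffective = c(c1 = 50L, c2 = 50L),
              nPerm = 50L, rngSeed = 1L, degreeMatched = FALSE,
              excludeSelfDraws = TRUE)
  vecs <- rbind(c1 = c(1, 1), c2 = c(1, 1), s1 = c(1, 1))
  rec <- applyFilters(cand, null, net, "s1", vecs, lazy = TRUE)
  r2 <- rec[rec$gene == "c2", ]  # fails Z, so MLS/MES skipped
  expect_false(r2$pass_permutation)
  expect_true(is.na(r2$mls) && is.na(r2$mes))
  expect_false(r2$pass_linkage || r2$pass_enrichment || r2$inferred)
  r1 <- rec[rec$gene == "c1", ]
  expect_false(is.na(r1$mls) || is.na(r1$mes))
  expect_true(r1$inferred)
})
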
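# Seed scoring, local/global core mining and Markov clustering

test_that("edge clustering coefficient matches triangle arithmetic", {
  k3 <- makeClique(c("a", "b", "c"))
  expect_equal(edgeClusteringCoefficient(k3, "a", "b"), 1 / 2)
  path <- makeNet(data.frame(u = c("a", "b"), v = c("b", "c"), w = 1))
  expect_equal(edgeClusteringCoefficient(path, "a", "b"), 0)
  k4 <- makeClique(c("a", "b", "c", "d"))
  expect_equal(edgeClusteringCoefficient(k4, "a", "b"), 2 / 3)
})

test_that("neighborhood AWD enumerates the edge neighborhood graph", {
  iso <- makeNet(data.frame(u = "a", v = "b", w = 1))
  expect_equal(neighborhoodAWD(iso, "a", "b"), 1)
  tri <- makeClique(c("a", "b", "c"))
  expect_equal(neighborhoodAWD(tri, "a", "b"), 2)
  star <- makeNet(data.frame(u = rep("hub", 3),
                             v = c("l1", "l2", "l3"), w = 0.5))
  expect_equal(neighborhoodAWD(star, "hub", "l1"), 2 * 1.5 / 4)
})

test_that("seed queue keeps only edges scoring strictly above the mean", {
  # all-identical scores: nothing strictly exceeds the mean
  k3 <- makeClique(c("a", "b", "c"))
  expect_equal(nrow(buildSeedQueue(k3)), 0L)

  # a triangle with one heavy edge plus a pendant: recompute by hand
  g <- makeNet(data.frame(u = c("a", "a", "b", "c"),
                          v = c("b", "c", "c", "d"),
                          w = c(1, 0.2, 0.2, 0.2)))
  sc <- seedScores(g)
  q <- buildSeedQueue(g)
  expect_true(all(q$score > mean(sc$score)))
  expect_equal(nrow(q) + sum(sc$score <= mean(sc$score)), nrow(sc))
})

test_that("seed queue ordering equals a full-sort oracle with
           lexicographic ties", {
  set.seed(9)
  nodes <- sprintf("n%02d", 1:8)
  pairs <- t(combn(nodes, 2))
  sel <- sample(nrow(pairs), 10)
  g <- makeNet(data.frame(u = pairs[sel, 1], v = pairs[sel, 2],
                          w = round(runif(10), 2)))
  sc <- seedScores(g)
  q <- buildSeedQueue(g)
  oracle <- sc[sc$score > mean(sc$score), ]
  oracle <- oracle[order(-oracle$score, oracle$u, oracle$v), ]
  expect_equal(q$u, oracle$u)
  expect_equal(q$v, oracle$v)
  expect_equal(q$score, oracle$score)
})

test_that("average edge weight follows the node-count normalization", {
  one <- makeNet(data.frame(u = "a", v = "b", w = 1))
  expect_equal(avgEdgeWeight(one), 0.5)
  tri <- makeClique(c("a", "b", "c"))
  expect_equal(avgEdgeWeight(tri), 1)
  expect_equal(avgEdgeWeight(tri, perEdge = TRUE), 1)
  noEdges <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(noEdges)$name <- c("a", "b", "c")
  expect_equal(avgEdgeWeight(noEdges), 0)
})

test_that("local cores recover a heavy clique against sparse periphery", {
  g <- heavyCliqueNet()
  cores <- mineLocalCores(g)
  expect_gte(length(cores), 1L)
  expect_equal(members(cores)[[1]], c("a", "b", "c", "d"))
})

test_that("no admissible neighbor leaves the seed pair as the core", {
  g <- makeNet(data.frame(u = c("a", "b", "b"),
                          v = c("b", "c", "d"),
                          w = c(1, 0.05, 0.05)))
  cores <- mineLocalCores(g)
  expect_equal(members(cores), list(c("a", "b")))
})

test_that("two disjoint heavy cliques yield two disjoint cores and seed
           endpoints are consumed", {
  g <- uniteNets(heavyCliqueNet("x_"), heavyCliqueNet("y_"))
  cores <- mineLocalCores(g)
  mem <- members(cores)
  # several seed edges may regrow the same clique; dedup is downstream
  cliqueCores <- unique(mem[vapply(mem, length, 1L) == 4L])
  expect_length(cliqueCores, 2L)
  expect_length(intersect(cliqueCores[[1]], cliqueCores[[2]]), 0L)
  # every mined core is connected and has >= 2 members
  for (m in mem) {
    expect_gte(length(m), 2L)
    expect_true(igraph::is_connected(igraph::induced_subgraph(g, m)))
  }
})

test_that("Markov clustering separates two cliques joined by one edge", {
  g <- uniteNets(makeClique(c("a", "b", "c")),
                 makeClique(c("x", "y", "z")),
                 makeNet(data.frame(u = "c", v = "x", w = 1)))
  cl <- markovClustering(g, inflation = 2)
  expect_setequal(lapply(cl, sort), list(c("a", "b", "c"),
                                         c("x", "y", "z")))
  one <- markovClustering(makeClique(c("a", "b", "c")))
  expect_equal(one, list(c("a", "b", "c")))
})

test_that("Markov clustering partitions the nodes of its graph", {
  set.seed(3)
  g <- igraph::sample_gnp(20, 0.25)
  igraph::V(g)$name <- sprintf("v%02d", 1:20)
  cl <- suppressWarnings(markovClustering(g, inflation = 2))
  expect_setequal(unlist(cl), igraph::V(g)$name)
  expect_equal(anyDuplicated(unlist(cl)), 0L)
})

test_that("global cores cluster per functional group and merge high
           overlaps", {
  g <- uniteNets(makeClique(c("a", "b", "c")),
                 makeClique(c("x", "y", "z")),
                 makeNet(data.frame(u = "c", v = "x", w = 0.2)))
  # one term annotating one clique -> that clique as a core
  ev1 <- EvidenceSet(goTerms = list(a = "t1", b = "t1", c = "t1"))
  cores1 <- mineGlobalCores(g, ev1)
  expect_equal(members(cores1), list(c("a", "b", "c")))

  # two terms annotating the identical set -> merged to one core (NA = 1)
  ev2 <- EvidenceSet(goTerms = list(a = c("t1", "t2"), b = c("t1", "t2"),
                                    c = c("t1", "t2")))
  cores2 <- mineGlobalCores(g, ev2)
  expect_equal(length(cores2), 1L)

  # no annotations -> warning, empty result
  expect_warning(empty <- mineGlobalCores(g, EvidenceSet()), "no GO")
  expect_equal(length(empty), 0L)
})

test_that("functional groups sharing a protein merge only when NA clears
           the threshold", {
  g <- makeClique(letters[1:6])
  # groups t1 = {a,b,c,d}, t2 = {c,d,e,f}:
  # NA({a,b,c,d},{c,d,e,f}) = 2^2/16 = 0.25 < 0.8 -> both kept
  ev <- EvidenceSet(goTerms = list(
    a = "t1", b = "t1", c = c("t1", "t2"), d = c("t1", "t2"),
    e = "t2", f = "t2"))
  cores <- mineGlobalCores(g, ev, overlapThres = 0.8)
  expect_equal(length(cores), 2L)
  # at threshold 0.2 they merge
  merged <- mineGlobalCores(g, ev, overlapThres = 0.2)
  expect_equal(length(merged), 1L)
  expect_equal(members(merged)[[1]], letters[1:6])
})

test_that("core deduplication collapses identical protein sets", {
  a <- ComplexSet(list(c("A", "B"), c("C", "D")))
  b <- ComplexSet(list(c("B", "A")))
  expect_equal(length(combineDedupCores(a, b)), 2L)

  disjoint <- combineDedupCores(ComplexSet(list(c("A", "B"))),
                                ComplexSet(list(c("C", "D"))))
  expect_equal(length(disjoint), 2L)

  # 20 random cores with 5 planted duplicates -> exactly 5 removed
  set.seed(7)
  base <- replicate(15, sample(letters, sample(2:5, 1)), simplify = FALSE)
  while (anyDuplicated(vapply(lapply(base, sort), paste, "",
                              collapse = ","))) {
    base <- replicate(15, sample(letters, sample(2:5, 1)),
                      simplify = FALSE)
  }
  dups <- lapply(base[1:5], sample)     # same sets, shuffled order
  combined <- combineDedupCores(ComplexSet(base), ComplexSet(dups))
  expect_equal(length(combined), 15L)
})
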
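# Network loading and the four evidence similarities

test_that("edge-list loading drops self-loops and duplicate interactions", {
  f <- withr::local_tempfile(lines = c("A\tB", "B\tA", "C\tC", "A\tB"))
  g <- loadNetwork(f, quiet = TRUE)
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))
  expect_equal(igraph::ecount(g), 1L)

  f2 <- withr::local_tempfile(lines = c("A B", "B C"))
  g2 <- loadNetwork(f2, quiet = TRUE)
  expect_equal(igraph::vcount(g2), 3L)
  expect_equal(igraph::ecount(g2), 2L)
})

test_that("loading errors carry line numbers; empty files error", {
  bad <- withr::local_tempfile(lines = c("A\tB", "Conly"))
  expect_error(loadNetwork(bad, quiet = TRUE), "line 2")
  empty <- withr::local_tempfile(lines = "# only a comment")
  expect_error(loadNetwork(empty, quiet = TRUE), "empty")
})

test_that("random edge lists dedup to the set-oracle count", {
  set.seed(42)
  prot <- sprintf("N%02d", 1:12)
  a <- sample(prot, 50, replace = TRUE)
  b <- sample(prot, 50, replace = TRUE)
  f <- withr::local_tempfile(lines = paste(a, b, sep = "\t"))
  g <- loadNetwork(f, quiet = TRUE)
  keep <- a != b
  oracle <- length(unique(paste(pmin(a[keep], b[keep]),
                                pmax(a[keep], b[keep]))))
  expect_equal(igraph::ecount(g), oracle)
})

test_that("evidence tables parse, reject duplicates and non-numeric cells", {
  ex <- withr::local_tempfile(lines = c("protein\tt1\tt2\tt3\tt4",
                                        "A\t1\t2\t3\t4"))
  go <- withr::local_tempfile(lines = c("A\tt1", "A\tt2"))
  ev <- loadEvidence(ex, go, quiet = TRUE)
  expect_equal(unname(ev@expression["A", ]), c(1, 2, 3, 4))
  expect_setequal(ev@goTerms[["A"]], c("t1", "t2"))

  dup <- withr::local_tempfile(lines = c("protein\tt1\tt2",
                                         "A\t1\t2", "A\t3\t4"))
  expect_error(loadEvidence(dup, quiet = TRUE), "A")
  bad <- withr::local_tempfile(lines = c("protein\tt1\tt2",
                                         "A\t1\tx"))
  expect_error(loadEvidence(bad, quiet = TRUE), "non-numeric")
})

test_that("co-expression similarity rescales Pearson correlation", {
  expect_equal(coexpressionSimilarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(coexpressionSimilarity(c(1, 2, 3), c(3, 2, 1)), 0)
  # hand-coded covariance-formula oracle
  x <- c(1, 2, 4, 3); y <- c(2, 2, 5, 2)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(coexpressionSimilarity(x, y), (r + 1) / 2)
  # zero-variance profiles carry no signal
  expect_equal(coexpressionSimilarity(c(2, 2, 2), c(1, 2, 3)), 0)
  expect_error(coexpressionSimilarity(1:3, 1:4), "length")
})

test_that("functional, localization and topological similarities match
           their set formulas", {
  expect_equal(functionalSimilarity(character(0), "t1"), 0)
  expect_equal(functionalSimilarity(c("t1", "t2"), c("t2", "t3", "t4")),
               1 / 2)
  expect_equal(functionalSimilarity(c("t1", "t2"), c("t1", "t2")), 1)

  expect_equal(localizationSimilarity("c1", "c1"), 1)
  expect_equal(localizationSimilarity("c1", "c2"), 0)
  expect_equal(localizationSimilarity(c("c1", "c2"), c("c2", "c3")), 0.5)
  expect_equal(localizationSimilarity(character(0), character(0)), 0)

  expect_equal(topologicalSimilarity(c(1, 1), c(1, 1)), 1)
  expect_equal(topologicalSimilarity(c(1, 0), c(0, 1)), 0)
  expect_equal(topologicalSimilarity(c(1, 1), c(-1, -1)), 0)  # clamped
  expect_equal(topologicalSimilarity(c(0, 0), c(1, 1)), 0)
})

test_that("all similarity operations are symmetric", {
  set.seed(1)
  for (i in 1:10) {
    x <- rnorm(5); y <- rnorm(5)
    expect_equal(coexpressionSimilarity(x, y),
                 coexpressionSimilarity(y, x))
    expect_equal(topologicalSimilarity(x, y),
                 topologicalSimilarity(y, x))
    a <- sample(letters, 4); b <- sample(letters, 6)
    expect_equal(functionalSimilarity(a, b), functionalSimilarity(b, a))
    expect_equal(localizationSimilarity(a, b),
                 localizationSimilarity(b, a))
  }
})

test_that("composite weight is the mean of four evidences; zero-weight
           edges are removed and nodes kept", {
  g <- igraph::delete_edge_attr(
    makeNet(data.frame(u = c("A", "B"), v = c("B", "C"), w = 1)),
    "weight")
  # A,B share everything; B,C share nothing and have no embedding signal
  ev <- EvidenceSet(
    expression = matrix(c(1, 2, 3, 1, 2, 3), 2, 3, byrow = TRUE,
                        dimnames = list(c("A", "B"), NULL)),
    goTerms = list(A = "t1", B = "t1"),
    localizations = list(A = c("c1", "c2"), B = "c1"),
    embeddings = matrix(0, 3, 4, dimnames = list(c("A", "B", "C"), NULL)))
  w <- buildWeightedNetwork(g, ev, quiet = TRUE)
  el <- igraph::as_edgelist(w)
  expect_equal(nrow(el), 1L)            # B-C had weight exactly 0
  expect_setequal(el[1, ], c("A", "B"))
  # mean of (1, 1, 2*1/3, 0) / 4
  expect_equal(igraph::E(w)$weight, (1 + 1 + 2 / 3 + 0) / 4)
  expect_equal(igraph::vcount(w), 3L)   # node set unchanged
})

test_that("edge with similarities (1, 0.5, 0.5, 0) weighs 0.5", {
  g <- igraph::delete_edge_attr(
    makeNet(data.frame(u = "A", v = "B", w = 1)), "weight")
  ev <- EvidenceSet(
    expression = matrix(c(1, 2, 3, 1, 2, 3), 2, 3, byrow = TRUE,
                        dimnames = list(c("A", "B"), NULL)),      # PCC' = 1
    goTerms = list(A = c("t1", "t2"), B = c("t1", "t3", "t4")),   # 1/2
    localizations = list(A = c("c1", "c2"), B = c("c2", "c3")),   # 1/2
    embeddings = matrix(c(1, 0, 0, 1), 2, 2,
                        dimnames = list(c("A", "B"), NULL)))      # 0
  w <- buildWeightedNetwork(g, ev, quiet = TRUE)
  expect_equal(igraph::E(w)$weight, 0.5)
})

test_that("embeddings are deterministic, sized, and separate communities", {
  path <- igraph::make_ring(10, circular = FALSE)
  igraph::V(path)$name <- letters[1:10]
  e1 <- embedNetwork(path, dims = 16, walkLength = 20, numWalks = 4,
                     seed = 5)
  e2 <- embedNetwork(path, dims = 16, walkLength = 20, numWalks = 4,
                     seed = 5)
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(10L, 16L))

  # two disconnected triangles: within-triangle cosine beats cross
  tri2 <- uniteNets(makeClique(c("a", "b", "c")),
                    makeClique(c("x", "y", "z")))
  within <- cross <- numeric(0)
  for (s in 1:10) {
    em <- embedNetwork(tri2, dims = 8, walkLength = 30, numWalks = 5,
                       seed = s)
    cs <- function(u, v) topologicalSimilarity(em[u, ], em[v, ])
    within <- c(within, cs("a", "b"), cs("b", "c"), cs("x", "y"))
    cross <- c(cross, cs("a", "x"), cs("b", "y"), cs("c", "z"))
  }
  expect_gt(mean(within), mean(cross))
})

test_that("isolated nodes receive zero vectors with a warning", {
  g <- makeNet(data.frame(u = "A", v = "B", w = 1))
  g <- igraph::add_vertices(g, 1, name = "LONER")
  expect_warning(em <- embedNetwork(g, dims = 4, walkLength = 10,
                                    numWalks = 2, seed = 1),
                 "isolated")
  expect_equal(unname(em["LONER", ]), rep(0, 4))
})
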
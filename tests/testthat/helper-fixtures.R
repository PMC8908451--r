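# Shared fixtures: small weighted graphs built in code, and a cached toy
# trained ensemble so model-dependent tests stay fast.

# weighted undirected graph from a data.frame u, v, w
makeNet <- function(edges) {
  g <- igraph::graph_from_edgelist(as.matrix(edges[, 1:2]),
                                   directed = FALSE)
  igraph::E(g)$weight <- edges[[3]]
  g
}

# complete graph on the given nodes, unit weights unless stated
makeClique <- function(nodes, w = 1) {
  pairs <- t(combn(nodes, 2))
  makeNet(data.frame(u = pairs[, 1], v = pairs[, 2], w = w,
                     stringsAsFactors = FALSE))
}

uniteNets <- function(...) {
  gs <- list(...)
  edges <- do.call(rbind, lapply(gs, function(g) {
    el <- igraph::as_edgelist(g)
    data.frame(u = el[, 1], v = el[, 2], w = igraph::E(g)$weight,
               stringsAsFactors = FALSE)
  }))
  makeNet(edges)
}

# heavy K4 clique with a weak pendant chain: core-growth thresholds admit
# exactly the clique (avg weight = (6 + 0.6) / 10 = 0.66; chain weights
# 0.1 < 0.66; clique ECC 2/3 > avg ECC 1/3)
heavyCliqueNet <- function(prefix = "") {
  cl <- paste0(prefix, c("a", "b", "c", "d"))
  chain <- paste0(prefix, c("e", "f", "g", "h", "i", "j"))
  uniteNets(makeClique(cl),
            makeNet(data.frame(u = c(cl[3], chain[-6]),
                               v = chain, w = 0.1)))
}

# Small benchmark + trained model, computed once per test run.
.fixtureCache <- new.env(parent = emptyenv())

toyBenchmark <- function() {
  if (is.null(.fixtureCache$bench))
    .fixtureCache$bench <- generateBenchmark(
      nComplexes = 4L, nBackground = 25L, seed = 11L)
  .fixtureCache$bench
}

# weighted network + ensemble trained on the toy benchmark's truth
toyTrained <- function() {
  if (is.null(.fixtureCache$trained)) {
    b <- toyBenchmark()
    w <- suppressMessages(
      buildWeightedNetwork(b$network, b$evidence, dims = 16, seed = 11L))
    mapped <- mapComplexes(b$truth, w)
    neg <- sampleFalseComplexes(w, mapped, ratio = 5L, seed = 11L)
    ts <- buildTrainingSet(mapped, neg, w)
    model <- fitEnsemble(ts$x, ts$y, seed = 11L)
    .fixtureCache$trained <- list(bench = b, net = w, mapped = mapped,
                                  negatives = neg, train = ts,
                                  model = model)
  }
  .fixtureCache$trained
}

# exhaustive maximum-weight bipartite matching by recursion (oracle)
bruteMatchWeight <- function(mat) {
  nr <- nrow(mat); nc <- ncol(mat)
  rec <- function(i, usedCols) {
    if (i > nr) return(0)
    best <- rec(i + 1L, usedCols)          # leave row i unmatched
    for (j in seq_len(nc)) {
      if (!usedCols[j] && mat[i, j] > 0) {
        usedCols[j] <- TRUE
        best <- max(best, mat[i, j] + rec(i + 1L, usedCols))
        usedCols[j] <- FALSE
      }
    }
    best
  }
  rec(1L, rep(FALSE, nc))
}
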
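# Complex-core mining: seed-edge scoring, local core growth, and
# function-group Markov clustering for global cores.

edgeWeights <- function(net) {
  w <- igraph::E(net)$weight
  if (is.null(w)) rep(1, igraph::ecount(net)) else w
}

#' Edge clustering coefficient
#'
#' Number of triangles built on edge (u,v) divided by the smaller endpoint
#' degree — an upper bound on the number of triangles the edge could join.
#' Triangle counts are unweighted.
#'
#' @param net igraph.
#' @param u,v endpoint protein IDs of an existing edge.
#' @return ECC value in \[0,1\].
#' @export
edgeClusteringCoefficient <- function(net, u, v) {
  nu <- igraph::neighbors(net, u)$name
  nv <- igraph::neighbors(net, v)$name
  z <- length(intersect(nu, nv))
  z / min(length(nu), length(nv))
}

#' Average weighted degree of an edge's neighborhood graph
#'
#' The neighborhood graph of edge (u,v) is the subgraph induced by
#' \eqn{N(u) \cup N(v) \cup \{u, v\}} with every network edge among those
#' nodes. Its average weighted degree is twice the total internal edge
#' weight divided by the node count.
#'
#' @param net weighted igraph.
#' @param u,v endpoint protein IDs of an existing edge.
#' @return AWD value >= 0.
#' @export
neighborhoodAWD <- function(net, u, v) {
  vs <- union(union(igraph::neighbors(net, u)$name,
                    igraph::neighbors(net, v)$name), c(u, v))
  sub <- igraph::induced_subgraph(net, vs)
  2 * sum(edgeWeights(sub)) / length(vs)
}

#' Seed-edge scores for every edge
#'
#' Score(u,v) = w(u,v) x AWD of the edge's neighborhood graph. Returned as
#' a data.frame (u, v, weight, score) in the network's edge order.
#'
#' @param net weighted igraph.
#' @return data.frame with one row per edge.
#' @export
seedScores <- function(net) {
  el <- igraph::as_edgelist(net)
  w <- edgeWeights(net)
  score <- vapply(seq_len(nrow(el)), function(i)
    w[i] * neighborhoodAWD(net, el[i, 1L], el[i, 2L]), numeric(1))
  data.frame(u = pmin(el[, 1L], el[, 2L]), v = pmax(el[, 1L], el[, 2L]),
             weight = w, score = score, stringsAsFactors = FALSE)
}

#' Build the seed-edge queue
#'
#' Keeps exactly the edges whose score strictly exceeds the mean score over
#' all edges, sorted non-ascending by score; ties are broken
#' lexicographically by the sorted endpoint pair for reproducibility.
#'
#' @param net weighted igraph.
#' @return data.frame (u, v, weight, score), possibly empty.
#' @export
buildSeedQueue <- function(net) {
  if (igraph::ecount(net) == 0L)
    return(data.frame(u = character(0), v = character(0),
                      weight = numeric(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  sc <- seedScores(net)
  keep <- sc[sc$score > mean(sc$score), , drop = FALSE]
  keep[order(-keep$score, keep$u, keep$v), , drop = FALSE]
}

#' Network-level average edge weight
#'
#' Total edge weight divided by the number of nodes (the normalization used
#' by the core-growth admission threshold). Set \code{perEdge = TRUE} to
#' divide by the number of edges instead.
#'
#' @param net weighted igraph.
#' @param perEdge divide by |E| rather than |V|.
#' @return scalar >= 0 (0 for an empty edge set).
#' @export
avgEdgeWeight <- function(net, perEdge = FALSE) {
  if (igraph::ecount(net) == 0L) return(0)
  sum(edgeWeights(net)) / (if (perEdge) igraph::ecount(net)
                           else igraph::vcount(net))
}

#' Mine local protein-complex cores from seed edges
#'
#' Walks the seed queue in score order. Each unused seed edge (neither
#' endpoint already consumed by a previous seed) starts a core of its two
#' endpoints; neighbors x of any current member t are admitted when both
#' w(x,t) >= the network average edge weight and ECC(x,t) > the network
#' average ECC, repeating (in lexicographic frontier order) until no
#' neighbor qualifies. Seed endpoints are then marked used.
#'
#' @param net weighted igraph.
#' @param perEdge passed to \code{\link{avgEdgeWeight}}.
#' @return a \linkS4class{ComplexSet} of cores (size >= 2), provenance
#'   "seed:<u>|<v>".
#' @export
mineLocalCores <- function(net, perEdge = FALSE) {
  queue <- buildSeedQueue(net)
  if (nrow(queue) == 0L) return(ComplexSet(list()))
  avgW <- avgEdgeWeight(net, perEdge = perEdge)
  el <- igraph::as_edgelist(net)
  w <- edgeWeights(net)
  eccAll <- vapply(seq_len(nrow(el)), function(i)
    edgeClusteringCoefficient(net, el[i, 1L], el[i, 2L]), numeric(1))
  avgECC <- mean(eccAll)
  # fast edge lookup tables
  ekey <- paste(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]))
  wTab <- stats::setNames(w, ekey)
  eccTab <- stats::setNames(eccAll, ekey)
  adj <- lapply(stats::setNames(
    igraph::as_adj_list(net, mode = "all"), igraph::V(net)$name),
    function(x) x$name)

  used <- character(0)
  cores <- list(); prov <- character(0)
  for (i in seq_len(nrow(queue))) {
    u <- queue$u[i]; v <- queue$v[i]
    if (u %in% used || v %in% used) next
    core <- c(u, v)
    repeat {
      cand <- sort(setdiff(unique(unlist(adj[core])), core))
      added <- FALSE
      for (x in cand) {
        ts <- intersect(adj[[x]], core)
        key <- paste(pmin(x, ts), pmax(x, ts))
        ok <- wTab[key] >= avgW & eccTab[key] > avgECC
        if (any(ok)) {
          core <- c(core, x)
          added <- TRUE
        }
      }
      if (!added) break
    }
    used <- c(used, u, v)
    cores[[length(cores) + 1L]] <- core
    prov <- c(prov, paste0("seed:", u, "|", v))
  }
  ComplexSet(cores, provenance = prov)
}

#' Markov clustering (MCL)
#'
#' Expansion/inflation iteration on the column-stochastic flow matrix of a
#' graph: expansion raises the matrix to the \code{expansion}-th power,
#' inflation raises entries elementwise to the \code{inflation} power and
#' renormalizes columns. Self-loops are added before normalization, the
#' standard stabilization. Clusters are read off the converged matrix as
#' connected components of its support. Fully deterministic.
#'
#' @param g igraph (edge weights used if present).
#' @param inflation inflation exponent (> 1, default 2).
#' @param expansion matrix-power exponent (default 2).
#' @param maxIter iteration cap (default 100; non-convergence warns and
#'   returns the current clustering).
#' @param tol convergence threshold on the max absolute entry change.
#' @return list of character vectors (node clusters partitioning the graph).
#' @export
markovClustering <- function(g, inflation = 2, expansion = 2L,
                             maxIter = 100L, tol = 1e-6) {
  if (igraph::vcount(g) == 0L) stop("empty graph")
  if (inflation <= 1) stop("inflation must exceed 1")
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  A <- as.matrix(igraph::as_adjacency_matrix(
    g, attr = if (!is.null(igraph::E(g)$weight)) "weight" else NULL,
    sparse = FALSE))
  diag(A) <- 1                       # self-loops
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    Mexp <- M
    for (e in seq_len(expansion - 1L)) Mexp <- Mexp %*% M
    Minf <- Mexp^inflation
    Minf <- sweep(Minf, 2, colSums(Minf), "/")
    if (max(abs(Minf - M)) < tol) {
      M <- Minf
      converged <- TRUE
      break
    }
    M <- Minf
  }
  if (!converged)
    warning("MCL did not converge within ", maxIter, " iterations")
  supp <- (M > 1e-8) | t(M > 1e-8)
  cg <- igraph::graph_from_adjacency_matrix(supp, mode = "undirected",
                                            diag = FALSE)
  comp <- igraph::components(cg)$membership
  unname(lapply(split(nodes, comp), sort))
}

#' Mine global cores by per-function Markov clustering
#'
#' For each GO-slim term, the subgraph induced by the term's annotated
#' proteins present in the network is clustered with
#' \code{\link{markovClustering}}; clusters from all terms are pooled and
#' pairs with neighborhood affinity >= \code{overlapThres} are merged
#' (union) until stable. Clusters of size >= 2 are returned as cores.
#'
#' @param net weighted igraph.
#' @param evidence \linkS4class{EvidenceSet} supplying GO-slim annotations.
#' @param overlapThres NA merge threshold (default 0.8).
#' @param inflation MCL inflation (default 2).
#' @return a \linkS4class{ComplexSet} with provenance "global".
#' @export
mineGlobalCores <- function(net, evidence, overlapThres = 0.8,
                            inflation = 2) {
  go <- evidence@goTerms
  if (length(go) == 0L) {
    warning("no GO annotations: no global cores mined")
    return(ComplexSet(list()))
  }
  nodes <- igraph::V(net)$name
  byTerm <- split(rep(names(go), lengths(go)), unlist(go))
  clusters <- list()
  for (term in sort(names(byTerm))) {
    prots <- intersect(sort(unique(byTerm[[term]])), nodes)
    if (length(prots) < 2L) next
    sub <- igraph::induced_subgraph(net, prots)
    if (igraph::ecount(sub) == 0L) next
    cl <- markovClustering(sub, inflation = inflation)
    clusters <- c(clusters, cl[lengths(cl) >= 2L])
  }
  # merge highly overlapping clusters across functional groups
  repeat {
    merged <- FALSE
    nC <- length(clusters)
    if (nC >= 2L) {
      for (i in seq_len(nC - 1L)) {
        for (j in (i + 1L):nC) {
          if (neighborhoodAffinity(clusters[[i]], clusters[[j]]) >=
              overlapThres) {
            clusters[[i]] <- sort(union(clusters[[i]], clusters[[j]]))
            clusters[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
    }
    if (!merged) break
  }
  clusters <- clusters[lengths(clusters) >= 2L]
  ComplexSet(clusters, provenance = rep("global", length(clusters)))
}

#' Combine and deduplicate local and global cores
#'
#' Union of both lists with cores holding identical protein sets collapsed
#' to the first occurrence (local cores first).
#'
#' @param localCores,globalCores \linkS4class{ComplexSet} objects.
#' @return deduplicated \linkS4class{ComplexSet}.
#' @export
combineDedupCores <- function(localCores, globalCores) {
  mem <- c(members(localCores), members(globalCores))
  prov <- c(localCores@provenance, globalCores@provenance)
  keys <- vapply(mem, setKey, "")
  keep <- !duplicated(keys)
  ComplexSet(mem[keep], provenance = prov[keep])
}
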
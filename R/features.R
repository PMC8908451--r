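# 65-feature topological representation of a candidate complex.
# The registry below is the single source of truth for feature order.

# quantities reused by the "topological change" features
clusterShape <- function(mem, net, adjFull, wTabFull) {
  n <- length(mem)
  inMem <- stats::setNames(rep(TRUE, n), mem)
  intEdges <- 0L; intW <- 0; cutE <- 0L; cutW <- 0
  degIn <- stats::setNames(integer(n), mem)
  for (u in mem) {
    nb <- adjFull[[u]]
    inside <- nb[!is.na(inMem[nb])]
    outside <- nb[is.na(inMem[nb])]
    degIn[u] <- length(inside)
    intEdges <- intEdges + length(inside)
    cutE <- cutE + length(outside)
    if (length(inside) > 0)
      intW <- intW + sum(wTabFull[paste(pmin(u, inside), pmax(u, inside))])
    if (length(outside) > 0)
      cutW <- cutW + sum(wTabFull[paste(pmin(u, outside),
                                        pmax(u, outside))])
  }
  intEdges <- intEdges / 2L
  intW <- intW / 2
  dens <- if (n >= 2) intEdges / (n * (n - 1) / 2) else 0
  wdens <- if (n >= 2) intW / (n * (n - 1) / 2) else 0
  cond <- if (2 * intEdges + cutE > 0) cutE / (2 * intEdges + cutE) else 0
  wcond <- if (2 * intW + cutW > 0) cutW / (2 * intW + cutW) else 0
  # mean local clustering inside the induced subgraph
  cc <- 0
  if (n >= 3) {
    ccs <- vapply(mem, function(u) {
      nb <- intersect(adjFull[[u]], mem)
      k <- length(nb)
      if (k < 2) return(0)
      # count unordered neighbor pairs that are linked
      links <- 0L
      for (ai in seq_len(k - 1L)) {
        links <- links + length(intersect(adjFull[[nb[ai]]],
                                          nb[(ai + 1L):k]))
      }
      2 * links / (k * (k - 1))
    }, numeric(1))
    cc <- mean(ccs)
  }
  list(n = n, intEdges = intEdges, intW = intW, cutE = cutE, cutW = cutW,
       degIn = degIn, density = dens, wdensity = wdens,
       conductance = cond, wconductance = wcond, meanCC = cc)
}

#' Names and definitions of the 65 cluster features
#'
#' Fixed-order registry of the topological features used to represent a
#' candidate complex for the voting regressor. Statistics are computed on
#' the subgraph induced by the cluster unless stated otherwise; boundary
#' quantities (conductance, modularity, boundary weights) use the full
#' network. Undefined values (empty sets, zero denominators) are imputed 0.
#'
#' Features whose published names carry no formula are given explicit
#' package definitions, flagged below:
#' \itemize{
#'   \item 1-2 graph/weight entropy: Shannon entropy of the internal degree
#'     distribution / of normalized internal edge weights.
#'   \item 35 average edge modularity: mean edge clustering coefficient
#'     over internal edges of the induced subgraph (package definition).
#'   \item 42-47 "topological feature" statistics: per-node topological
#'     coefficient (Cytoscape definition) over the induced subgraph
#'     (package definition).
#'   \item 48-52 degree correlation: per internal edge, the ratio
#'     min(deg)/max(deg) of endpoint subgraph degrees (package definition).
#'   \item 53-54 community model: cohesion score
#'     2 m_in / (sqrt(n) (n-1)), unweighted / weighted (package
#'     definition matching the structural-modularity cohesion term).
#'   \item 55-62 topological change 1-8: relative change in density,
#'     conductance, weight density and mean clustering when the maximum-
#'     degree node (55-58) or minimum-degree node (59-62) is removed.
#'   \item 63-65 leading three eigenvalues of the unweighted adjacency
#'     spectrum of the induced subgraph (zero-padded).
#' }
#'
#' @return character vector of 65 feature names.
#' @export
featureRegistry <- function() {
  c("graph_entropy", "graph_weight_entropy", "node_size", "edge_size",
    "graph_clustering_coefficient", "max_degree", "min_degree",
    "mean_degree", "median_degree", "var_degree", "sd_degree",
    "max_weight_degree", "min_weight_degree", "mean_weight_degree",
    "median_weight_degree", "sd_weight_degree", "density",
    "weight_density", "edge_mean_weight", "edge_median_weight",
    "edge_var_weight", "edge_sd_weight", "avg_shortest_path", "diameter",
    "max_clustering", "min_clustering", "mean_clustering",
    "median_clustering", "var_clustering", "conductance",
    "weight_conductance", "modularity", "weight_modularity",
    "avg_boundary_weight", "avg_edge_modularity", "mean_common_neighbor",
    "sd_common_neighbor", "var_common_neighbor", "min_common_neighbor",
    "median_common_neighbor", "max_common_neighbor",
    "mean_topological_coef", "median_topological_coef",
    "var_topological_coef", "max_topological_coef", "min_topological_coef",
    "sd_topological_coef", "mean_degree_correlation",
    "min_degree_correlation", "var_degree_correlation",
    "max_degree_correlation", "median_degree_correlation",
    "community_model", "weight_community_model",
    paste0("topological_change_", 1:8),
    paste0("adjacency_eigenvalue_", 1:3))
}

#' Extract the 65-feature vector for a cluster
#'
#' Computes the fixed-order topological feature vector (see
#' \code{\link{featureRegistry}}) describing a cluster within its network.
#' Deterministic; permuting protein labels leaves the vector unchanged.
#'
#' @param cluster character vector of >= 2 protein IDs, all present in
#'   \code{net}.
#' @param net weighted igraph.
#' @return named numeric vector of length 65 with no NaN/Inf (undefined
#'   entries imputed 0).
#' @export
extractFeatures <- function(cluster, net) {
  mem <- sort(unique(as.character(cluster)))
  nodes <- igraph::V(net)$name
  if (!all(mem %in% nodes))
    stop("cluster contains proteins absent from the network: ",
         paste(head(setdiff(mem, nodes), 3), collapse = ", "))
  if (length(mem) < 2L) stop("cluster must contain >= 2 proteins")

  adjFull <- lapply(stats::setNames(
    igraph::as_adj_list(net, mode = "all"), nodes),
    function(x) x$name)
  el <- igraph::as_edgelist(net)
  wAll <- edgeWeights(net)
  wTabFull <- stats::setNames(wAll, paste(pmin(el[, 1], el[, 2]),
                                          pmax(el[, 1], el[, 2])))
  sub <- igraph::induced_subgraph(net, mem)
  n <- length(mem)
  m <- igraph::ecount(sub)
  deg <- igraph::degree(sub)
  strength <- if (m > 0 && !is.null(igraph::E(sub)$weight))
    igraph::strength(sub) else igraph::degree(sub) * 0
  ew <- if (m > 0) edgeWeights(sub) else numeric(0)
  shape <- clusterShape(mem, net, adjFull, wTabFull)

  entropy <- function(x) {
    x <- x[x > 0]
    if (length(x) == 0) return(0)
    p <- x / sum(x)
    -sum(p * log2(p))
  }
  # degree-distribution entropy: probability of each observed degree value
  degDist <- as.numeric(table(deg))

  # shortest paths / diameter on the largest component
  comp <- igraph::components(sub)
  big <- igraph::induced_subgraph(
    sub, which(comp$membership == which.max(comp$csize)))
  apl <- if (igraph::vcount(big) >= 2)
    igraph::mean_distance(big, weights = NA) else 0
  diam <- if (igraph::vcount(big) >= 2)
    igraph::diameter(big, weights = NA) else 0

  localCC <- igraph::transitivity(sub, type = "local", isolates = "zero")
  globalCC <- fin0(igraph::transitivity(sub, type = "global"))

  # Newman modularity contribution of this single community
  M <- igraph::ecount(net)
  Wtot <- sum(wAll)
  volU <- sum(vapply(mem, function(u) length(adjFull[[u]]), 1L))
  volW <- 2 * shape$intW + shape$cutW
  mod <- if (M > 0) shape$intEdges / M - (volU / (2 * M))^2 else 0
  wmod <- if (Wtot > 0) shape$intW / Wtot - (volW / (2 * Wtot))^2 else 0

  avgBoundaryW <- if (shape$cutE > 0) shape$cutW / shape$cutE else 0

  # per-internal-edge quantities within the induced subgraph
  adjSub <- lapply(mem, function(u) intersect(adjFull[[u]], mem))
  names(adjSub) <- mem
  if (m > 0) {
    elSub <- igraph::as_edgelist(sub)
    cn <- vapply(seq_len(m), function(i)
      length(intersect(adjSub[[elSub[i, 1]]], adjSub[[elSub[i, 2]]])),
      numeric(1))
    eccSub <- vapply(seq_len(m), function(i) {
      d <- min(length(adjSub[[elSub[i, 1]]]), length(adjSub[[elSub[i, 2]]]))
      if (d == 0) 0 else cn[i] / d
    }, numeric(1))
    dcorr <- vapply(seq_len(m), function(i) {
      d1 <- length(adjSub[[elSub[i, 1]]]); d2 <- length(adjSub[[elSub[i, 2]]])
      if (max(d1, d2) == 0) 0 else min(d1, d2) / max(d1, d2)
    }, numeric(1))
  } else {
    cn <- eccSub <- dcorr <- numeric(0)
  }

  # per-node topological coefficient (Cytoscape definition) in subgraph
  tc <- vapply(mem, function(u) {
    nb <- adjSub[[u]]
    if (length(nb) < 2) return(0)
    others <- setdiff(mem, u)
    js <- vapply(others, function(v) {
      shared <- length(intersect(nb, adjSub[[v]]))
      if (shared == 0) return(NA_real_)
      shared + as.numeric(v %in% nb)
    }, numeric(1))
    js <- js[!is.na(js)]
    if (length(js) == 0) return(0)
    mean(js) / length(nb)
  }, numeric(1))

  cohesion <- function(mIn) 2 * mIn / (sqrt(n) * (n - 1))

  # relative change in four shape quantities under node removal
  topoChange <- function(drop) {
    memR <- setdiff(mem, drop)
    if (length(memR) < 2) return(rep(0, 4))
    s2 <- clusterShape(memR, net, adjFull, wTabFull)
    rel <- function(a, b) if (a == 0) 0 else (b - a) / a
    c(rel(shape$density, s2$density),
      rel(shape$conductance, s2$conductance),
      rel(shape$wdensity, s2$wdensity),
      rel(shape$meanCC, s2$meanCC))
  }
  maxNode <- mem[which.max(deg[mem])]
  minNode <- mem[which.min(deg[mem])]

  A <- as.matrix(igraph::as_adjacency_matrix(sub, sparse = FALSE))
  ev <- sort(eigen(A, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev3 <- c(ev, 0, 0, 0)[1:3]

  st <- function(x, f) if (length(x) == 0) 0 else fin0(f(x))
  out <- c(
    entropy(degDist), entropy(ew), n, m, globalCC,
    st(deg, max), st(deg, min), st(deg, mean), st(deg, median),
    st(deg, var), st(deg, sd),
    st(strength, max), st(strength, min), st(strength, mean),
    st(strength, median), st(strength, sd),
    if (n >= 2) m / (n * (n - 1) / 2) else 0,
    shape$wdensity,
    st(ew, mean), st(ew, median), st(ew, var), st(ew, sd),
    fin0(apl), diam,
    st(localCC, max), st(localCC, min), st(localCC, mean),
    st(localCC, median), st(localCC, var),
    shape$conductance, shape$wconductance, mod, wmod, avgBoundaryW,
    st(eccSub, mean),
    st(cn, mean), st(cn, sd), st(cn, var), st(cn, min), st(cn, median),
    st(cn, max),
    st(tc, mean), st(tc, median), st(tc, var), st(tc, max), st(tc, min),
    st(tc, sd),
    st(dcorr, mean), st(dcorr, min), st(dcorr, var), st(dcorr, max),
    st(dcorr, median),
    cohesion(m), cohesion(shape$intW),
    topoChange(maxNode), topoChange(minNode),
    ev3)
  out <- fin0(as.numeric(out))
  names(out) <- featureRegistry()
  stopifnot(length(out) == 65L)
  out
}
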
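#' Node embeddings by biased random walks + PPMI factorization
#'
#' Learns a low-dimensional vector per node that captures network topology,
#' in the node2vec family: second-order random walks biased by the return
#' parameter \code{p} and in-out parameter \code{q} generate node
#' "sentences"; skip-gram co-occurrence statistics within a context window
#' are then factorized via the positive pointwise mutual information (PPMI)
#' matrix and a truncated SVD — the classical closed-form counterpart of
#' skip-gram with negative sampling. The factorization makes the embedding
#' deterministic given the walk seed.
#'
#' Isolated nodes receive a zero vector (with a warning): no walk ever
#' visits them, so they carry no topological signal.
#'
#' @param net igraph (edge weights, if present, bias the walk transitions).
#' @param dims embedding dimension (default 64).
#' @param walkLength steps per walk (default 80).
#' @param numWalks walks started per node (default 10).
#' @param p return parameter: high values discourage immediate backtracking.
#' @param q in-out parameter: q > 1 keeps walks local (BFS-like), q < 1
#'   lets them range (DFS-like).
#' @param window skip-gram context window (default 10).
#' @param seed RNG seed; the caller's RNG state is restored afterwards.
#' @return numeric matrix, one row per network node, \code{dims} columns.
#' @export
embedNetwork <- function(net, dims = 64, walkLength = 80, numWalks = 10,
                         p = 1, q = 1, window = 10, seed = 1L) {
  if (igraph::vcount(net) == 0L) stop("cannot embed an empty network")
  nodes <- igraph::V(net)$name
  n <- length(nodes)
  adj <- igraph::as_adj_list(net, mode = "all")
  adj <- lapply(adj, as.integer)
  wl <- NULL
  if (!is.null(igraph::E(net)$weight)) {
    inc <- igraph::as_adj_edge_list(net, mode = "all")
    ew <- igraph::E(net)$weight
    wl <- lapply(inc, function(es) ew[as.integer(es)])
  }
  deg <- lengths(adj)
  if (any(deg == 0L))
    warning(sum(deg == 0L), " isolated node(s) receive zero embeddings")

  walks <- withSeed(seed, {
    out <- vector("list", n * numWalks)
    k <- 0L
    for (rep in seq_len(numWalks)) {
      for (s in seq_len(n)) {
        if (deg[s] == 0L) next
        walk <- integer(walkLength)
        walk[1L] <- s
        prev <- 0L
        for (step in 2:walkLength) {
          cur <- walk[step - 1L]
          nbrs <- adj[[cur]]
          wts <- if (is.null(wl)) rep(1, length(nbrs)) else wl[[cur]]
          if (prev != 0L && (p != 1 || q != 1)) {
            bias <- ifelse(nbrs == prev, 1 / p,
                           ifelse(nbrs %in% adj[[prev]], 1, 1 / q))
            wts <- wts * bias
          }
          nxt <- if (length(nbrs) == 1L) nbrs else
            sample(nbrs, 1L, prob = wts)
          walk[step] <- nxt
          prev <- cur
        }
        k <- k + 1L
        out[[k]] <- walk
      }
    }
    out[seq_len(k)]
  })

  # skip-gram co-occurrence within the window, accumulated symmetrically
  # via linear-index tabulation (avoids an O(pairs) interpreted loop)
  idxParts <- vector("list", length(walks))
  for (wi in seq_along(walks)) {
    walk <- walks[[wi]]
    L <- length(walk)
    ii <- jj <- vector("list", min(window, L - 1L))
    for (d in seq_len(min(window, L - 1L))) {
      ii[[d]] <- walk[seq_len(L - d)]
      jj[[d]] <- walk[(1L + d):L]
    }
    i <- unlist(ii); j <- unlist(jj)
    idxParts[[wi]] <- c((j - 1L) * n + i, (i - 1L) * n + j)
  }
  counts <- tabulate(unlist(idxParts), nbins = n * n)
  cooc <- matrix(as.numeric(counts), n, n)
  total <- sum(cooc)
  emb <- matrix(0, n, dims)
  if (total > 0) {
    rs <- rowSums(cooc)
    active <- which(rs > 0)
    pm <- cooc[active, active, drop = FALSE] * total /
      outer(rs[active], rs[active])
    ppmi <- log(pmax(pm, 1))            # PPMI: negatives truncated at 0
    sv <- svd(ppmi)
    k <- min(dims, ncol(sv$u))
    emb[active, seq_len(k)] <-
      sv$u[, seq_len(k), drop = FALSE] %*% diag(sqrt(sv$d[seq_len(k)]),
                                                nrow = k)
  }
  rownames(emb) <- nodes
  emb
}
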
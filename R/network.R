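#' Load a PPI network from an edge-list file
#'
#' Reads a whitespace/tab-separated edge list (`proteinA proteinB [weight]`,
#' `#` comments allowed), drops self-interactions and collapses duplicate or
#' reversed-duplicate interactions, as is standard when preparing raw PPI
#' data. If a third numeric column is present it is kept as the edge weight
#' (first occurrence wins on duplicates).
#'
#' @param path path to the edge-list file.
#' @param quiet suppress the node/edge count message.
#' @return an undirected simple \code{igraph} object.
#' @export
loadNetwork <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) stop("empty network file: ", path)
  parts <- strsplit(trimws(lines[idx]), "\\s+")
  nf <- vapply(parts, length, 1L)
  if (any(nf < 2L))
    stop("malformed edge line ", idx[which(nf < 2L)[1L]],
         ": expected at least 2 columns")
  a <- vapply(parts, `[`, "", 1L)
  b <- vapply(parts, `[`, "", 2L)
  w <- rep(NA_real_, length(a))
  has3 <- nf >= 3L
  if (any(has3)) {
    wraw <- suppressWarnings(as.numeric(vapply(parts[has3], `[`, "", 3L)))
    if (anyNA(wraw))
      stop("malformed weight on line ",
           idx[has3][which(is.na(wraw))[1L]])
    w[has3] <- wraw
  }
  nodes <- sort(unique(c(a, b)))
  loop <- a == b
  a2 <- a[!loop]; b2 <- b[!loop]; w2 <- w[!loop]
  key <- ifelse(a2 < b2, paste(a2, b2), paste(b2, a2))
  first <- !duplicated(key)
  eseq <- rbind(pmin(a2, b2)[first], pmax(a2, b2)[first])
  g <- igraph::graph_from_edgelist(t(eseq), directed = FALSE)
  g <- igraph::add_vertices(g, length(setdiff(nodes, igraph::V(g)$name)),
                            name = setdiff(nodes, igraph::V(g)$name))
  if (any(!is.na(w2[first])))
    igraph::E(g)$weight <- ifelse(is.na(w2[first]), 1, w2[first])
  if (!quiet)
    message("loaded network: ", igraph::vcount(g), " nodes, ",
            igraph::ecount(g), " edges")
  g
}

#' Load evidence tables
#'
#' Reads the biological evidence files used for edge weighting: an
#' expression TSV (header row of time labels, one protein per row), and
#' two-column `protein<TAB>term` TSVs for GO-slim annotations and
#' subcellular localizations. All arguments are optional; missing tables
#' leave the corresponding evidence channel empty.
#'
#' @param exprPath expression TSV path or NULL.
#' @param goPath GO-slim mapping TSV path or NULL.
#' @param locPath localization mapping TSV path or NULL.
#' @param embeddings optional precomputed embedding matrix.
#' @param network optional igraph; when given, per-table coverage of the
#'   network's nodes is reported.
#' @param quiet suppress coverage messages.
#' @return an \linkS4class{EvidenceSet}.
#' @export
loadEvidence <- function(exprPath = NULL, goPath = NULL, locPath = NULL,
                         embeddings = NULL, network = NULL, quiet = FALSE) {
  expr <- NULL
  if (!is.null(exprPath)) {
    tab <- read.delim(exprPath, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE,
                      comment.char = "#")
    ids <- as.character(tab[[1L]])
    if (anyDuplicated(ids))
      stop("duplicate protein row in expression table: ",
           ids[duplicated(ids)][1L])
    mat <- as.matrix(tab[, -1L, drop = FALSE])
    if (!is.numeric(mat)) {
      num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat)))
      badRow <- which(rowSums(is.na(num) & !is.na(mat)) > 0)
      stop("non-numeric expression value for protein ",
           ids[badRow[1L]])
    }
    rownames(mat) <- ids
    expr <- mat
  }
  go <- if (is.null(goPath)) NULL else readMappingTSV(goPath)
  loc <- if (is.null(locPath)) NULL else readMappingTSV(locPath)
  ev <- EvidenceSet(expression = expr, goTerms = go, localizations = loc,
                    embeddings = embeddings)
  if (!is.null(network) && !quiet) {
    nodes <- igraph::V(network)$name
    cov <- function(ids) if (length(nodes)) mean(nodes %in% ids) else 0
    message(sprintf(
      "evidence coverage: expression %.2f, GO %.2f, localization %.2f",
      cov(rownames(ev@expression)), cov(names(ev@goTerms)),
      cov(names(ev@localizations))))
  }
  ev
}

#' Co-expression similarity of two expression profiles
#'
#' Rescaled Pearson correlation \eqn{(PCC(X,Y)+1)/2}, mapping correlation
#' from \[-1,1\] to \[0,1\]. Profiles with zero variance carry no
#' co-expression signal and score 0.
#'
#' @param x,y numeric vectors of equal length (>= 2 time points).
#' @return similarity in \[0,1\].
#' @export
coexpressionSimilarity <- function(x, y) {
  if (length(x) != length(y)) stop("expression profiles differ in length")
  if (length(x) < 2L) stop("expression profiles need >= 2 time points")
  if (sd(x) == 0 || sd(y) == 0) return(0)
  (cor(x, y) + 1) / 2
}

#' Functional similarity of two GO-slim term sets
#'
#' Shared-annotation fraction \eqn{|A \cap B| / \min(|A|, |B|)}; 0 when
#' either protein has no annotation.
#'
#' @param ga,gb character vectors of term IDs.
#' @return similarity in \[0,1\].
#' @export
functionalSimilarity <- function(ga, gb) {
  ga <- unique(ga); gb <- unique(gb)
  m <- min(length(ga), length(gb))
  if (m < 1L) return(0)
  length(intersect(ga, gb)) / m
}

#' Subcellular localization similarity
#'
#' Dice coefficient \eqn{2|A \cap B| / (|A| + |B|)} of two compartment
#' sets; 0 when both are empty.
#'
#' @param la,lb character vectors of compartment IDs.
#' @return similarity in \[0,1\].
#' @export
localizationSimilarity <- function(la, lb) {
  la <- unique(la); lb <- unique(lb)
  tot <- length(la) + length(lb)
  if (tot == 0L) return(0)
  2 * length(intersect(la, lb)) / tot
}

#' Topological similarity of two embedding vectors
#'
#' Cosine similarity of node-embedding vectors, clamped at 0 so the value
#' stays in \[0,1\] (a negative cosine means no topological affinity).
#'
#' @param fa,fb numeric vectors of equal length.
#' @return similarity in \[0,1\].
#' @export
topologicalSimilarity <- function(fa, fb) {
  if (length(fa) != length(fb)) stop("embedding vectors differ in length")
  na <- sqrt(sum(fa^2)); nb <- sqrt(sum(fb^2))
  if (na == 0 || nb == 0) return(0)
  max(0, sum(fa * fb) / (na * nb))
}

#' Build the composite weighted PPI network
#'
#' Assigns each edge the arithmetic mean of four evidence similarities —
#' co-expression, GO-slim functional, localization and embedding-based
#' topological similarity. A protein pair missing a given evidence channel
#' contributes 0 for that channel while the divisor stays 4. Edges whose
#' composite weight is exactly 0 (all four evidences absent or zero) are
#' treated as noise and removed.
#'
#' @param net undirected simple igraph (raw PPI network).
#' @param evidence an \linkS4class{EvidenceSet}; if its embeddings slot is
#'   empty, embeddings are computed with \code{\link{embedNetwork}}.
#' @param dims,walkLength,numWalks,p,q,window embedding hyperparameters,
#'   passed to \code{\link{embedNetwork}}.
#' @param seed RNG seed for the embedding walks.
#' @param quiet suppress the removed-edge report.
#' @return weighted igraph with edge attribute \code{weight} in (0,1].
#' @export
buildWeightedNetwork <- function(net, evidence, dims = 64, walkLength = 80,
                                 numWalks = 10, p = 1, q = 1, window = 10,
                                 seed = 1L, quiet = FALSE) {
  emb <- evidence@embeddings
  if (nrow(emb) == 0L && igraph::ecount(net) > 0L)
    emb <- embedNetwork(net, dims = dims, walkLength = walkLength,
                        numWalks = numWalks, p = p, q = q,
                        window = window, seed = seed)
  expr <- evidence@expression
  go <- evidence@goTerms
  loc <- evidence@localizations
  el <- igraph::as_edgelist(net)
  w <- numeric(nrow(el))
  for (i in seq_len(nrow(el))) {
    u <- el[i, 1L]; v <- el[i, 2L]
    pcc <- if (u %in% rownames(expr) && v %in% rownames(expr))
      coexpressionSimilarity(expr[u, ], expr[v, ]) else 0
    fs <- if (!is.null(go[[u]]) && !is.null(go[[v]]))
      functionalSimilarity(go[[u]], go[[v]]) else 0
    sl <- if (!is.null(loc[[u]]) && !is.null(loc[[v]]))
      localizationSimilarity(loc[[u]], loc[[v]]) else 0
    tss <- if (u %in% rownames(emb) && v %in% rownames(emb))
      topologicalSimilarity(emb[u, ], emb[v, ]) else 0
    w[i] <- (pcc + fs + sl + tss) / 4
  }
  g <- net
  igraph::E(g)$weight <- w
  drop <- which(w == 0)
  if (length(drop) > 0L) g <- igraph::delete_edges(g, drop)
  if (!quiet)
    message("weighted network: removed ", length(drop),
            " zero-weight edges, kept ", igraph::ecount(g))
  g
}

#' Write a (weighted) network as an edge list
#'
#' @param net igraph; the \code{weight} edge attribute, if present, is
#'   written as a third column.
#' @param path output TSV path.
#' @export
writeWeightedNetwork <- function(net, path) {
  el <- igraph::as_edgelist(net)
  if (nrow(el) > 0L) {
    o <- order(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    el <- el[o, , drop = FALSE]
    if (!is.null(igraph::E(net)$weight)) {
      lines <- sprintf("%s\t%s\t%.10g", el[, 1], el[, 2],
                       igraph::E(net)$weight[o])
    } else {
      lines <- sprintf("%s\t%s", el[, 1], el[, 2])
    }
  } else lines <- character(0)
  writeLines(lines, path)
  invisible(path)
}
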
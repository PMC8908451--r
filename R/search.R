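# Graph heuristic search: grow each core into a complex by alternating
# fitness-maximizing expansion and contraction, then filter redundancy.

#' Outer boundary candidates of a core
#'
#' Direct neighbors of the core, scored by how many core members they are
#' connected to. Neighbors sharing fewer than two core members are
#' discarded as low quality; of the rest, the top half (ceiling) by score
#' is returned, ties broken lexicographically.
#'
#' @param core character vector of protein IDs.
#' @param net igraph.
#' @param minShared minimum shared core members (default 2).
#' @return character vector of candidate proteins (possibly empty).
#' @export
outerBoundary <- function(core, net, minShared = 2L) {
  nodes <- igraph::V(net)$name
  core <- intersect(core, nodes)
  if (length(core) == 0L) return(character(0))
  nbrs <- setdiff(unique(unlist(lapply(core, function(u)
    igraph::neighbors(net, u)$name))), core)
  if (length(nbrs) == 0L) return(character(0))
  shared <- vapply(nbrs, function(b)
    length(intersect(igraph::neighbors(net, b)$name, core)), 1L)
  keep <- nbrs[shared >= minShared]
  if (length(keep) == 0L) return(character(0))
  sh <- shared[match(keep, nbrs)]
  keep <- keep[order(-sh, keep)]
  keep[seq_len(ceiling(length(keep) / 2))]
}

#' One expansion step
#'
#' Evaluates the ensemble fitness of the core with each outer-boundary
#' candidate temporarily added; the argmax candidate is inserted iff it
#' strictly increases fitness.
#'
#' @param core character vector of protein IDs (>= 2).
#' @param net weighted igraph.
#' @param model \linkS4class{VotingEnsemble}.
#' @param current optional precomputed fitness of \code{core}.
#' @return list(core, improved, fitness).
#' @export
expandStep <- function(core, net, model, current = NULL) {
  if (is.null(current)) current <- fitnessScore(core, net, model)
  cand <- outerBoundary(core, net)
  if (length(cand) == 0L)
    return(list(core = core, improved = FALSE, fitness = current))
  gains <- vapply(cand, function(b)
    fitnessScore(c(core, b), net, model), numeric(1))
  best <- which.max(gains)
  if (gains[best] > current)
    list(core = sort(c(core, cand[best])), improved = TRUE,
         fitness = unname(gains[best]))
  else
    list(core = core, improved = FALSE, fitness = current)
}

#' One contraction step
#'
#' Evaluates fitness with each inner-boundary member (a member with at
#' least one neighbor outside the core) temporarily removed; removes the
#' best strictly improving member. Never shrinks a core below 3 proteins.
#'
#' @inheritParams expandStep
#' @return list(core, improved, fitness).
#' @export
contractStep <- function(core, net, model, current = NULL) {
  if (is.null(current)) current <- fitnessScore(core, net, model)
  if (length(core) <= 3L)
    return(list(core = core, improved = FALSE, fitness = current))
  inner <- Filter(function(p) {
    length(setdiff(igraph::neighbors(net, p)$name, core)) > 0
  }, core)
  if (length(inner) == 0L)
    return(list(core = core, improved = FALSE, fitness = current))
  inner <- sort(inner)
  gains <- vapply(inner, function(p) {
    rest <- setdiff(core, p)
    sub <- igraph::induced_subgraph(net, rest)
    if (igraph::ecount(sub) == 0L) return(-Inf)
    fitnessScore(rest, net, model)
  }, numeric(1))
  best <- which.max(gains)
  if (gains[best] > current)
    list(core = sort(setdiff(core, inner[best])), improved = TRUE,
         fitness = unname(gains[best]))
  else
    list(core = core, improved = FALSE, fitness = current)
}

#' Refine a core into a complex
#'
#' Alternates an expansion phase (accepted insertions until no candidate
#' improves fitness) and a contraction phase (accepted removals likewise)
#' until a full round changes nothing or \code{maxRounds} is reached.
#' Every accepted move strictly increases fitness, so the fitness trace is
#' non-decreasing and the search terminates.
#'
#' @param core character vector of protein IDs (>= 2).
#' @param net weighted igraph.
#' @param model \linkS4class{VotingEnsemble}.
#' @param maxRounds safety cap on expand/contract rounds (default 50).
#' @param trace return the per-accepted-move fitness trace as an attribute.
#' @return character vector of >= 3 proteins with attribute
#'   \code{fitness}, or NULL if the refined cluster stays below 3 proteins.
#' @export
refineCore <- function(core, net, model, maxRounds = 50L, trace = FALSE) {
  cur <- sort(unique(core))
  fit <- fitnessScore(cur, net, model)
  tr <- fit
  for (round in seq_len(maxRounds)) {
    changed <- FALSE
    repeat {
      st <- expandStep(cur, net, model, current = fit)
      if (!st$improved) break
      cur <- st$core; fit <- st$fitness; changed <- TRUE
      tr <- c(tr, fit)
    }
    repeat {
      st <- contractStep(cur, net, model, current = fit)
      if (!st$improved) break
      cur <- st$core; fit <- st$fitness; changed <- TRUE
      tr <- c(tr, fit)
    }
    if (!changed) break
  }
  if (length(cur) < 3L) return(NULL)
  attr(cur, "fitness") <- fit
  if (trace) attr(cur, "trace") <- tr
  cur
}

#' Filter redundant complexes
#'
#' Drops complexes below \code{minSize}, then greedily keeps complexes in
#' decreasing fitness order, discarding any whose neighborhood affinity
#' with an already-kept complex reaches \code{naThres} (exact duplicates
#' always collapse, NA = 1).
#'
#' @param complexes \linkS4class{ComplexSet} with fitness scores.
#' @param naThres redundancy threshold (default 0.8).
#' @param minSize minimum complex size (default 3).
#' @return filtered \linkS4class{ComplexSet}.
#' @export
filterRedundant <- function(complexes, naThres = 0.8, minSize = 3L) {
  mem <- members(complexes)
  sc <- scores(complexes)
  prov <- complexes@provenance
  keep <- vapply(mem, length, 1L) >= minSize
  mem <- mem[keep]; sc <- sc[keep]; prov <- prov[keep]
  if (length(mem) == 0L) return(ComplexSet(list()))
  ord <- order(-ifelse(is.na(sc), 0, sc),
               vapply(mem, setKey, ""))
  kept <- integer(0)
  for (i in ord) {
    redundant <- any(vapply(kept, function(j)
      neighborhoodAffinity(mem[[i]], mem[[j]]) >= naThres, logical(1)))
    if (!redundant) kept <- c(kept, i)
  }
  kept <- sort(kept)
  ComplexSet(mem[kept], score = sc[kept], provenance = prov[kept])
}

#' Detect protein complexes (full pipeline)
#'
#' Orchestrates the whole framework: (1) weight the PPI network by the
#' four evidence channels, (2) mine local seed-edge cores and global
#' per-function Markov-clustering cores, (3) train the voting ensemble on
#' the catalogue (mapped positives + sampled connected negatives) unless a
#' trained model is supplied, (4) refine every core by the graph heuristic
#' search, (5) filter small and redundant complexes. Deterministic given
#' \code{seed}.
#'
#' @param network igraph; treated as already weighted when it carries a
#'   \code{weight} edge attribute, otherwise weighted from
#'   \code{evidence}.
#' @param evidence \linkS4class{EvidenceSet}.
#' @param catalogue reference complex catalogue (list or
#'   \linkS4class{ComplexSet}) used for training when \code{model} is
#'   NULL.
#' @param model optional pre-trained \linkS4class{VotingEnsemble}.
#' @param ratio negatives per positive for training (default 5).
#' @param minSize minimum output complex size (default 3).
#' @param redundancyNA redundancy filter threshold (default 0.8).
#' @param seed RNG seed driving embedding walks and negative sampling.
#' @param dims embedding dimension (default 64).
#' @param quiet suppress stage messages.
#' @return list with \code{complexes} (a scored
#'   \linkS4class{ComplexSet}), \code{model}, \code{weighted} (the
#'   weighted igraph) and \code{cores}.
#' @export
detectComplexes <- function(network, evidence, catalogue = NULL,
                            model = NULL, ratio = 5L, minSize = 3L,
                            redundancyNA = 0.8, seed = 1L, dims = 64,
                            quiet = FALSE) {
  if (igraph::ecount(network) == 0L)
    return(list(complexes = ComplexSet(list()), model = model,
                weighted = network, cores = ComplexSet(list())))
  say <- function(...) if (!quiet) message(...)
  weighted <- if (!is.null(igraph::E(network)$weight)) network
    else buildWeightedNetwork(network, evidence, dims = dims, seed = seed,
                              quiet = quiet)
  say("[weighting] ", igraph::ecount(weighted), " weighted edges")

  localCores <- mineLocalCores(weighted)
  globalCores <- mineGlobalCores(weighted, evidence)
  cores <- combineDedupCores(localCores, globalCores)
  say("[cores] ", length(localCores), " local + ", length(globalCores),
      " global -> ", length(cores), " after dedup")

  if (is.null(model)) {
    if (is.null(catalogue))
      stop("[training] either a trained model or a catalogue is required")
    mapped <- mapComplexes(catalogue, weighted, minSize = minSize)
    if (length(mapped) == 0L)
      stop("[training] no catalogue complex maps onto the network")
    negatives <- sampleFalseComplexes(weighted, mapped, ratio = ratio,
                                      seed = seed)
    ts <- buildTrainingSet(mapped, negatives, weighted)
    model <- fitEnsemble(ts$x, ts$y, seed = seed)
    say("[training] ", length(mapped), " positives, ", length(negatives),
        " negatives")
  }

  refined <- list(); fits <- numeric(0); prov <- character(0)
  for (i in seq_along(members(cores))) {
    res <- refineCore(members(cores)[[i]], weighted, model)
    if (!is.null(res)) {
      refined[[length(refined) + 1L]] <- as.character(res)
      fits <- c(fits, attr(res, "fitness"))
      prov <- c(prov, cores@provenance[i])
    }
  }
  say("[search] ", length(refined), " refined complexes")
  out <- filterRedundant(
    ComplexSet(refined, score = fits, provenance = prov),
    naThres = redundancyNA, minSize = minSize)
  say("[filter] ", length(out), " complexes after redundancy filtering")
  list(complexes = out, model = model, weighted = weighted, cores = cores)
}

#' Write complexes to a TSV file
#'
#' One complex per line, tab-separated protein IDs (lexicographic within a
#' line; lines ordered by decreasing fitness then lexicographically for
#' byte-stable output). With \code{scorePath}, a sidecar TSV of fitness
#' scores is written.
#'
#' @param complexes \linkS4class{ComplexSet}.
#' @param path output path.
#' @param scorePath optional sidecar TSV path (complex_id, size, fitness).
#' @export
writeComplexes <- function(complexes, path, scorePath = NULL) {
  mem <- members(complexes)
  sc <- scores(complexes)
  ord <- order(-ifelse(is.na(sc), 0, sc), vapply(mem, setKey, ""))
  lines <- vapply(mem[ord], function(m) paste(m, collapse = "\t"), "")
  writeLines(lines, path)
  if (!is.null(scorePath)) {
    df <- data.frame(complex_id = seq_along(ord),
                     size = vapply(mem[ord], length, 1L),
                     fitness = round(sc[ord], 10))
    write.table(df, scorePath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Read complexes from a TSV file (one complex per line)
#'
#' @param path input path; lines are whitespace-separated protein IDs.
#' @return a \linkS4class{ComplexSet}.
#' @export
readComplexes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  ComplexSet(strsplit(trimws(lines), "\\s+"))
}
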
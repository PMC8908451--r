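# Synthetic benchmark with planted core-attachment complexes plus
# consistent evidence tables, so the whole pipeline is testable offline.

#' Generate a synthetic PPI benchmark with planted complexes
#'
#' Emulates the core-attachment organization of real complexes: each
#' planted complex is a near-clique core (every core edge present with
#' probability \code{pCore}) plus attachment proteins wired to at least
#' two core members; background proteins interact sparsely at random.
#' Evidence tables are generated consistently with the planted structure:
#' complex members share a latent expression profile (plus Gaussian
#' noise), a set of GO terms and a subcellular compartment, while
#' background proteins get independent profiles and annotations. Planted
#' complexes use disjoint protein sets, so any two have neighborhood
#' affinity 0. Each planted complex is checked to induce a connected
#' subgraph (a spanning cycle of the core backs up unlucky edge draws).
#' Fully reproducible from \code{seed}.
#'
#' @param nComplexes planted complexes (default 8).
#' @param coreSize inclusive core-size range (default c(4, 8)).
#' @param nAttach inclusive attachments-per-complex range (default
#'   c(1, 3)).
#' @param pCore within-core edge probability (default 0.9).
#' @param pAttach attachment-to-core edge probability (default 0.6).
#' @param nBackground background proteins (default 60).
#' @param pBackground background edge probability (default 0.02).
#' @param mTimepoints expression profile length (default 12).
#' @param noiseSd expression noise standard deviation (default 0.3).
#' @param nSharedTerms GO terms shared by each complex (default 2).
#' @param seed RNG seed (default 7).
#' @return list with \code{network} (raw igraph), \code{evidence}
#'   (\linkS4class{EvidenceSet} without embeddings), and \code{truth}
#'   (\linkS4class{ComplexSet} of planted complexes, all of size >= 3).
#' @export
generateBenchmark <- function(nComplexes = 8L, coreSize = c(4L, 8L),
                              nAttach = c(1L, 3L), pCore = 0.9,
                              pAttach = 0.6, nBackground = 60L,
                              pBackground = 0.02, mTimepoints = 12L,
                              noiseSd = 0.3, nSharedTerms = 2L,
                              seed = 7L) {
  if (coreSize[1] < 2L) stop("core size must be >= 2")
  if (pCore <= pBackground)
    stop("within-core edge probability must exceed background")
  withSeed(seed, {
    edges <- character(0)
    addEdge <- function(u, v) {
      edges[[length(edges) + 1L]] <<- paste(min(u, v), max(u, v), sep = "\t")
    }
    nid <- 0L
    newProt <- function(k) {
      ids <- sprintf("P%04d", nid + seq_len(k))
      nid <<- nid + k
      ids
    }
    truth <- list()
    complexOf <- character(0)     # protein -> complex index, for evidence
    for (ci in seq_len(nComplexes)) {
      csize <- sample(seq(coreSize[1], coreSize[2]), 1L)
      core <- newProt(csize)
      for (i in seq_len(csize - 1L)) for (j in (i + 1L):csize)
        if (runif(1) < pCore) addEdge(core[i], core[j])
      # spanning cycle keeps the core connected whatever the draws
      for (i in seq_len(csize))
        addEdge(core[i], core[if (i == csize) 1L else i + 1L])
      na <- sample(seq(nAttach[1], nAttach[2]), 1L)
      attach <- newProt(na)
      for (a in attach) {
        linked <- core[runif(csize) < pAttach]
        if (length(linked) < 2L) linked <- sample(core, 2L)
        for (t in linked) addEdge(a, t)
      }
      memb <- c(core, attach)
      truth[[ci]] <- memb
      complexOf[memb] <- as.character(ci)
    }
    bg <- newProt(nBackground)
    allProt <- sprintf("P%04d", seq_len(nid))
    for (b in bg) {
      partners <- allProt[runif(nid) < pBackground]
      partners <- setdiff(partners, b)
      # every background protein interacts at least once, as in a real
      # edge-list-borne PPI network (isolated proteins never appear)
      if (length(partners) == 0L)
        partners <- sample(setdiff(allProt, b), 1L)
      for (t in partners) addEdge(b, t)
    }
    edges <- unique(edges)
    el <- do.call(rbind, strsplit(edges, "\t"))
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    missing <- setdiff(allProt, igraph::V(g)$name)
    if (length(missing) > 0L)
      g <- igraph::add_vertices(g, length(missing), name = missing)
    g <- igraph::simplify(g)

    # expression: latent profile per complex, noise per member
    latent <- matrix(rnorm(nComplexes * mTimepoints, sd = 1),
                     nComplexes, mTimepoints)
    expr <- matrix(0, nid, mTimepoints,
                   dimnames = list(allProt,
                                   paste0("t", seq_len(mTimepoints))))
    for (pr in allProt) {
      ci <- complexOf[pr]
      expr[pr, ] <- if (!is.na(ci))
        latent[as.integer(ci), ] + rnorm(mTimepoints, sd = noiseSd)
      else rnorm(mTimepoints)
    }

    # GO terms: nSharedTerms per complex; background gets decoy terms
    goPool <- sprintf("GO:BG%02d", 1:10)
    go <- lapply(stats::setNames(allProt, allProt), function(pr) {
      ci <- complexOf[pr]
      if (!is.na(ci))
        sprintf("GO:C%s_%d", ci, seq_len(nSharedTerms))
      else sample(goPool, sample(1:2, 1L))
    })

    # localization: one compartment per complex, random for background
    locPool <- sprintf("compartment%02d", 1:6)
    loc <- lapply(stats::setNames(allProt, allProt), function(pr) {
      ci <- complexOf[pr]
      if (!is.na(ci)) sprintf("compartment_C%s", ci)
      else sample(locPool, 1L)
    })

    list(network = g,
         evidence = EvidenceSet(expression = expr, goTerms = go,
                                localizations = loc),
         truth = ComplexSet(truth,
                            provenance = rep("truth", length(truth))))
  })
}

#' Write a benchmark to its five TSV files
#'
#' Emits edge list (\code{network.tsv}), expression matrix
#' (\code{expression.tsv}), GO mapping (\code{go.tsv}), localization
#' mapping (\code{localization.tsv}) and planted truth complexes
#' (\code{truth_complexes.tsv}) in the package's TSV dialects.
#' Output is byte-stable for a fixed benchmark.
#'
#' @param bench result of \code{\link{generateBenchmark}}.
#' @param dir output directory (created if needed).
#' @return named character vector of the five file paths.
#' @export
writeBenchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(network = file.path(dir, "network.tsv"),
             expression = file.path(dir, "expression.tsv"),
             go = file.path(dir, "go.tsv"),
             localization = file.path(dir, "localization.tsv"),
             truth = file.path(dir, "truth_complexes.tsv"))
  writeWeightedNetwork(bench$network, paths["network"])
  expr <- bench$evidence@expression
  exprLines <- c(paste(c("protein", colnames(expr)), collapse = "\t"),
                 vapply(rownames(expr), function(pr)
                   paste(c(pr, sprintf("%.6f", expr[pr, ])),
                         collapse = "\t"), ""))
  writeLines(exprLines, paths["expression"])
  writeMapping <- function(tab, path) {
    lines <- unlist(lapply(sort(names(tab)), function(pr)
      paste(pr, sort(tab[[pr]]), sep = "\t")))
    writeLines(lines, path)
  }
  writeMapping(bench$evidence@goTerms, paths["go"])
  writeMapping(bench$evidence@localizations, paths["localization"])
  writeComplexes(bench$truth, paths["truth"])
  paths
}

#' Run the full pipeline from a configuration
#'
#' Convenience end-to-end driver: loads (or takes) a network, evidence and
#' truth/training catalogue, runs \code{\link{detectComplexes}}, evaluates
#' against the catalogue and writes all artifacts (weighted network,
#' cores, complexes + fitness sidecar, evaluation report JSON, log) into
#' \code{outDir}.
#'
#' @param config named list (or path to a YAML file when the \code{yaml}
#'   package is available) with entries: \code{network}, \code{expression},
#'   \code{go}, \code{localization}, \code{complexes} (paths), optional
#'   \code{seed}, \code{ratio}, \code{minSize}, \code{redundancyNA},
#'   \code{dims}.
#' @param outDir artifact directory.
#' @param quiet suppress stage messages.
#' @return invisible list with \code{complexes}, \code{report},
#'   \code{model}, and the artifact paths.
#' @export
runPipeline <- function(config, outDir, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  need <- c("network", "expression", "go", "localization", "complexes")
  missing <- setdiff(need, names(config))
  if (length(missing) > 0L)
    stop("config is missing entries: ", paste(missing, collapse = ", "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  net <- loadNetwork(config$network, quiet = quiet)
  ev <- loadEvidence(config$expression, config$go, config$localization,
                     network = net, quiet = quiet)
  truth <- readComplexes(config$complexes)
  res <- detectComplexes(
    net, ev, catalogue = truth,
    ratio = if (is.null(config$ratio)) 5L else as.integer(config$ratio),
    minSize = if (is.null(config$minSize)) 3L
              else as.integer(config$minSize),
    redundancyNA = if (is.null(config$redundancyNA)) 0.8
                   else as.numeric(config$redundancyNA),
    dims = if (is.null(config$dims)) 64 else as.numeric(config$dims),
    seed = seed, quiet = quiet)

  report <- evaluateComplexes(truth, res$complexes,
                              annotations = ev@goTerms,
                              universe = igraph::vcount(net))
  paths <- c(weighted = file.path(outDir, "weighted_network.tsv"),
             cores = file.path(outDir, "cores.tsv"),
             complexes = file.path(outDir, "complexes.tsv"),
             fitness = file.path(outDir, "complex_fitness.tsv"),
             report = file.path(outDir, "evaluation.json"),
             log = file.path(outDir, "pipeline.log"))
  writeWeightedNetwork(res$weighted, paths["weighted"])
  writeComplexes(res$cores, paths["cores"])
  writeComplexes(res$complexes, paths["complexes"],
                 scorePath = paths["fitness"])
  jsonlite::write_json(as.list(metrics(report)), paths["report"],
                       auto_unbox = TRUE, digits = NA)
  writeLines(c(
    sprintf("seed\t%d", seed),
    sprintf("nodes\t%d", igraph::vcount(net)),
    sprintf("edges\t%d", igraph::ecount(net)),
    sprintf("weighted_edges\t%d", igraph::ecount(res$weighted)),
    sprintf("cores\t%d", length(res$cores)),
    sprintf("complexes\t%d", length(res$complexes))),
    paths["log"])
  invisible(list(complexes = res$complexes, report = report,
                 model = res$model, paths = paths))
}
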
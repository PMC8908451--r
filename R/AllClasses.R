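#' @import methods
#' @importFrom stats cor lm median phyper predict rnorm runif sd var
#' @importFrom utils head read.delim write.table combn
NULL

setOldClass("igraph")
setOldClass("rpart")
setOldClass("svm")

#' Evidence tables attached to a PPI network
#'
#' Container for the per-protein biological evidence used to weight network
#' edges: gene-expression profiles, GO-slim term sets, subcellular
#' localization sets, and node-embedding vectors. Any table may cover only a
#' subset of the network; proteins absent from a table contribute similarity
#' 0 for that evidence channel.
#'
#' @slot expression numeric matrix, one row per protein, columns are time
#'   points (>= 2 columns when non-empty).
#' @slot goTerms named list of character vectors of GO-slim term IDs.
#' @slot localizations named list of character vectors of compartment IDs.
#' @slot embeddings numeric matrix, one row per protein; all rows share one
#'   embedding dimension.
#' @export
setClass("EvidenceSet",
  representation(expression = "matrix", goTerms = "list",
                 localizations = "list", embeddings = "matrix"),
  prototype(expression = matrix(numeric(0), 0, 0),
            goTerms = structure(list(), names = character(0)),
            localizations = structure(list(), names = character(0)),
            embeddings = matrix(numeric(0), 0, 0)))

setValidity("EvidenceSet", function(object) {
  msg <- character(0)
  if (nrow(object@expression) > 0) {
    if (is.null(rownames(object@expression)))
      msg <- c(msg, "expression matrix must have protein rownames")
    if (ncol(object@expression) < 2)
      msg <- c(msg, "expression profiles need >= 2 time points")
    if (!is.numeric(object@expression))
      msg <- c(msg, "expression matrix must be numeric")
  }
  if (nrow(object@embeddings) > 0 && is.null(rownames(object@embeddings)))
    msg <- c(msg, "embeddings matrix must have protein rownames")
  for (nm in c("goTerms", "localizations")) {
    tab <- slot(object, nm)
    if (length(tab) > 0 && is.null(names(tab)))
      msg <- c(msg, paste(nm, "must be a named list"))
  }
  dups <- unlist(lapply(list(rownames(object@expression),
                             names(object@goTerms),
                             names(object@localizations)),
                        function(x) x[duplicated(x)]))
  if (length(dups) > 0)
    msg <- c(msg, paste("duplicate protein entry:", dups[1L]))
  if (length(msg)) msg else TRUE
})

#' Construct an EvidenceSet
#'
#' @param expression numeric matrix (proteins x time points) or NULL.
#' @param goTerms named list of GO-slim term sets or NULL.
#' @param localizations named list of compartment sets or NULL.
#' @param embeddings numeric matrix (proteins x dims) or NULL.
#' @return An \linkS4class{EvidenceSet}.
#' @export
EvidenceSet <- function(expression = NULL, goTerms = NULL,
                        localizations = NULL, embeddings = NULL) {
  emptyList <- structure(list(), names = character(0))
  new("EvidenceSet",
      expression = if (is.null(expression)) matrix(numeric(0), 0, 0)
                   else as.matrix(expression),
      goTerms = if (is.null(goTerms)) emptyList else goTerms,
      localizations = if (is.null(localizations)) emptyList
                      else localizations,
      embeddings = if (is.null(embeddings)) matrix(numeric(0), 0, 0)
                   else as.matrix(embeddings))
}

setMethod("show", "EvidenceSet", function(object) {
  cat("EvidenceSet\n")
  cat("  expression :", nrow(object@expression), "proteins x",
      ncol(object@expression), "time points\n")
  cat("  goTerms    :", length(object@goTerms), "proteins\n")
  cat("  localizations:", length(object@localizations), "proteins\n")
  cat("  embeddings :", nrow(object@embeddings), "proteins x",
      ncol(object@embeddings), "dims\n")
})

#' A collection of protein clusters (cores or complexes)
#'
#' Holds protein sets together with an optional per-cluster score (ensemble
#' fitness for detected complexes) and a provenance tag ("seed:<u>|<v>",
#' "global", "truth", ...).
#'
#' @slot members list of character vectors (protein IDs).
#' @slot score numeric vector, one per cluster (NA when unscored).
#' @slot provenance character vector, one per cluster.
#' @export
setClass("ComplexSet",
  representation(members = "list", score = "numeric",
                 provenance = "character"),
  prototype(members = list(), score = numeric(0), provenance = character(0)))

setValidity("ComplexSet", function(object) {
  n <- length(object@members)
  if (length(object@score) != n || length(object@provenance) != n)
    return("members, score and provenance must have equal length")
  if (n > 0 && any(vapply(object@members, length, 1L) < 1L))
    return("clusters must contain at least one protein")
  TRUE
})

#' Construct a ComplexSet
#'
#' @param members list of character vectors of protein IDs.
#' @param score optional numeric score per cluster.
#' @param provenance optional character tag per cluster.
#' @return A \linkS4class{ComplexSet}.
#' @export
ComplexSet <- function(members, score = NULL, provenance = NULL) {
  members <- lapply(members, function(m) sort(unique(as.character(m))))
  n <- length(members)
  new("ComplexSet", members = members,
      score = if (is.null(score)) rep(NA_real_, n) else as.numeric(score),
      provenance = if (is.null(provenance)) rep(NA_character_, n)
                   else as.character(provenance))
}

#' @describeIn ComplexSet number of clusters
#' @param x a ComplexSet
#' @export
setMethod("length", "ComplexSet", function(x) length(x@members))

#' Cluster membership accessor
#' @param x a \linkS4class{ComplexSet}
#' @return list of character vectors.
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname members
#' @export
setMethod("members", "ComplexSet", function(x) x@members)

#' Cluster score accessor
#' @param x a \linkS4class{ComplexSet}
#' @return numeric vector of per-cluster scores.
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname scores
#' @export
setMethod("scores", "ComplexSet", function(x) x@score)

setMethod("show", "ComplexSet", function(object) {
  sizes <- vapply(object@members, length, 1L)
  cat("ComplexSet with", length(object@members), "clusters\n")
  if (length(sizes) > 0) {
    cat("  size range:", min(sizes), "-", max(sizes),
        " mean:", round(mean(sizes), 2), "\n")
    if (!all(is.na(object@score)))
      cat("  score range:", round(min(object@score, na.rm = TRUE), 3), "-",
          round(max(object@score, na.rm = TRUE), 3), "\n")
  }
})

#' Four-learner voting regression ensemble
#'
#' The trained supervised half of the cluster-scoring model: ordinary least
#' squares, Bayesian ridge, a regression tree and a linear-kernel support
#' vector regressor, combined by an unweighted mean of the four predictions.
#'
#' @slot olsCoef numeric coefficient vector (intercept first) of the OLS fit.
#' @slot ridge list holding the Bayesian-ridge posterior (coef, intercept,
#'   centering info, alpha/lambda trace).
#' @slot tree fitted \code{rpart} regression tree.
#' @slot svr fitted \code{e1071::svm} linear eps-regression model.
#' @slot featureNames the 65 feature names the model was trained on.
#' @slot seed integer seed used during fitting.
#' @export
setClass("VotingEnsemble",
  representation(olsCoef = "numeric", ridge = "list", tree = "rpart",
                 svr = "svm", featureNames = "character", seed = "integer"))

setValidity("VotingEnsemble", function(object) {
  if (length(object@featureNames) == 0)
    return("featureNames must be non-empty")
  TRUE
})

setMethod("show", "VotingEnsemble", function(object) {
  cat("VotingEnsemble (OLS + Bayesian ridge + tree + linear SVR)\n")
  cat("  features:", length(object@featureNames),
      " seed:", object@seed, "\n")
})

#' Evaluation report for a set of predicted complexes
#'
#' All clustering-quality metrics against a reference catalogue, plus the
#' composite total score (F-measure + CR + ACC + MMR + Jaccard) and optional
#' per-complex enrichment p-values.
#'
#' @slot metrics named numeric vector: numPredicted, precision, recall,
#'   fMeasure, sn, ppv, acc, mmr, cr, jaccard, totalScore.
#' @slot perComplex data.frame of per-complex enrichment results (possibly
#'   empty).
#' @export
setClass("EvalReport",
  representation(metrics = "numeric", perComplex = "data.frame"),
  prototype(metrics = numeric(0), perComplex = data.frame()))

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport\n")
  m <- object@metrics
  for (nm in names(m)) cat(sprintf("  %-12s %.4f\n", nm, m[[nm]]))
  if (nrow(object@perComplex) > 0)
    cat("  enrichment: ", sum(object@perComplex$significant), "of",
        nrow(object@perComplex), "complexes significant\n")
})

#' Metric accessor for EvalReport
#' @param x an \linkS4class{EvalReport}
#' @return named numeric vector of metric values.
#' @export
setGeneric("metrics", function(x) standardGeneric("metrics"))

#' @rdname metrics
#' @export
setMethod("metrics", "EvalReport", function(x) x@metrics)
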
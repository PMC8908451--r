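# Supervised half of the cluster-scoring model: training-set construction,
# the four-learner voting regressor, and the structural-modularity scorer.

#' Map a complex catalogue onto a network
#'
#' Intersects each catalogued complex with the network's node set and keeps
#' those retaining at least \code{minSize} proteins. Connectivity is not
#' required: a mapped complex may have missing internal edges, which the
#' downstream scoring tolerates.
#'
#' @param catalogue list of character vectors, or a
#'   \linkS4class{ComplexSet}.
#' @param net igraph.
#' @param minSize minimum mapped size (default 3).
#' @return a \linkS4class{ComplexSet} of mapped complexes.
#' @export
mapComplexes <- function(catalogue, net, minSize = 3L) {
  if (is(catalogue, "ComplexSet")) catalogue <- members(catalogue)
  nodes <- igraph::V(net)$name
  mapped <- lapply(catalogue, function(cx) intersect(cx, nodes))
  mapped <- mapped[vapply(mapped, length, 1L) >= minSize]
  ComplexSet(mapped, provenance = rep("mapped", length(mapped)))
}

#' Sample false complexes as connected neighborhood subgraphs
#'
#' Generates \code{ratio} negatives per mapped positive. Each negative's
#' target size is drawn with replacement from the mapped-complex size
#' distribution (so both share the same distribution), then grown as a
#' connected subgraph by randomized breadth-first expansion from a random
#' start node. A candidate is rejected if its neighborhood affinity with
#' any mapped complex reaches \code{naReject}, or if it duplicates an
#' already-sampled negative.
#'
#' @param net igraph.
#' @param mapped \linkS4class{ComplexSet} of mapped positives (non-empty).
#' @param ratio negatives per positive (default 5).
#' @param naReject NA rejection threshold (default 0.2).
#' @param seed RNG seed.
#' @param maxTries retry budget per requested negative (default 200).
#' @return a \linkS4class{ComplexSet} of negatives (provenance
#'   "sampled-negative"); warns if the quota could not be reached.
#' @export
sampleFalseComplexes <- function(net, mapped, ratio = 5L, naReject = 0.2,
                                 seed = 1L, maxTries = 200L) {
  pos <- members(mapped)
  if (length(pos) == 0L) stop("no mapped complexes to sample against")
  sizes <- vapply(pos, length, 1L)
  quota <- ratio * length(pos)
  nodes <- igraph::V(net)$name
  adj <- lapply(stats::setNames(
    igraph::as_adj_list(net, mode = "all"), nodes), function(x) x$name)
  out <- list()
  seen <- character(0)
  withSeed(seed, {
    tries <- 0L
    while (length(out) < quota && tries < maxTries * quota) {
      tries <- tries + 1L
      target <- sample(sizes, 1L)
      cur <- sample(nodes, 1L)
      while (length(cur) < target) {
        frontier <- setdiff(unique(unlist(adj[cur])), cur)
        if (length(frontier) == 0L) break
        cur <- c(cur, sample(frontier, 1L))
      }
      if (length(cur) < target) next
      maxNA <- max(vapply(pos, function(p)
        neighborhoodAffinity(cur, p), numeric(1)))
      if (maxNA >= naReject) next
      key <- setKey(cur)
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- cur
    }
  })
  if (length(out) < quota)
    warning("sampled only ", length(out), " of ", quota,
            " false complexes")
  ComplexSet(out, provenance = rep("sampled-negative", length(out)))
}

#' Assemble the supervised training matrix
#'
#' Extracts the 65-feature vector for every mapped positive (label 1) and
#' sampled negative (label 0).
#'
#' @param positives,negatives \linkS4class{ComplexSet} objects.
#' @param net weighted igraph.
#' @return list with \code{x} (matrix), \code{y} (numeric labels) and
#'   \code{origin} (character tags).
#' @export
buildTrainingSet <- function(positives, negatives, net) {
  clusters <- c(members(positives), members(negatives))
  y <- c(rep(1, length(positives)), rep(0, length(negatives)))
  x <- t(vapply(clusters, extractFeatures, numeric(65), net = net))
  stopifnot(!anyNA(x))
  list(x = x, y = y,
       origin = c(rep("mapped-positive", length(positives)),
                  rep("sampled-negative", length(negatives))))
}

# Bayesian ridge regression via evidence maximization (iterative update of
# the noise precision alpha and weight precision lambda), on centered data.
bayesRidgeFit <- function(x, y, maxIter = 300L, tol = 1e-3) {
  xm <- colMeans(x); ym <- mean(y)
  xc <- sweep(x, 2, xm); yc <- y - ym
  n <- nrow(xc); d <- ncol(xc)
  sv <- svd(xc)
  s2 <- sv$d^2
  uty <- crossprod(sv$u, yc)
  alpha <- 1 / max(var(yc), 1e-7)
  lambda <- 1
  for (it in seq_len(maxIter)) {
    coefS <- alpha * sv$d * uty / (lambda + alpha * s2)
    w <- sv$v %*% coefS
    gamma <- sum(alpha * s2 / (lambda + alpha * s2))
    rss <- sum((yc - xc %*% w)^2)
    lambdaNew <- (gamma + 1e-6) / (sum(w^2) + 1e-6)
    alphaNew <- (n - gamma + 1e-6) / (rss + 1e-6)
    if (abs(lambdaNew - lambda) < tol && abs(alphaNew - alpha) < tol) {
      lambda <- lambdaNew; alpha <- alphaNew
      break
    }
    lambda <- lambdaNew; alpha <- alphaNew
  }
  coefS <- alpha * sv$d * uty / (lambda + alpha * s2)
  w <- as.numeric(sv$v %*% coefS)
  list(coef = w, intercept = ym - sum(xm * w), alpha = alpha,
       lambda = lambda)
}

bayesRidgePredict <- function(fit, x) {
  as.numeric(x %*% fit$coef + fit$intercept)
}

# OLS via QR with rank-deficiency-safe coefficients (NA -> 0)
olsFit <- function(x, y) {
  fit <- stats::lm.fit(cbind(1, x), y)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  unname(cf)
}

#' Fit the four-learner voting regression ensemble
#'
#' Trains ordinary least squares, Bayesian ridge, a regression tree
#' (\code{rpart}, default parameters) and a linear-kernel support vector
#' regressor (\code{e1071::svm}, eps-regression) on identical data. The
#' ensemble prediction is the unweighted mean of the four base
#' predictions. Labels are 1 for true complexes, 0 for false ones, so the
#' prediction estimates the probability that a cluster is a real complex.
#'
#' @param x numeric feature matrix (rows = examples, 65 columns).
#' @param y numeric labels with at least two distinct values.
#' @param seed RNG seed (tree fitting is seeded for bit reproducibility).
#' @return a \linkS4class{VotingEnsemble}.
#' @export
fitEnsemble <- function(x, y, seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) < 10L) stop("need >= 10 training examples")
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class")
  if (is.null(colnames(x))) colnames(x) <- featureRegistry()[seq_len(ncol(x))]
  withSeed(seed, {
    ols <- olsFit(x, y)
    ridge <- bayesRidgeFit(x, y)
    df <- data.frame(y = y, x, check.names = FALSE)
    tree <- rpart::rpart(y ~ ., data = df, method = "anova")
    svr <- e1071::svm(x = x, y = y, type = "eps-regression",
                      kernel = "linear", scale = FALSE)
    new("VotingEnsemble", olsCoef = ols, ridge = ridge, tree = tree,
        svr = svr, featureNames = colnames(x), seed = as.integer(seed))
  })
}

#' Predict with a voting ensemble
#'
#' Returns the unweighted mean of the four base-learner predictions
#' (unclipped; \code{\link{fitnessScore}} clips to \[0,1\] before use).
#'
#' @param object a \linkS4class{VotingEnsemble}.
#' @param newdata numeric matrix or vector of 65 features.
#' @param perLearner return the 4-column matrix of base predictions too.
#' @return numeric vector of ensemble predictions (or a list when
#'   \code{perLearner = TRUE}).
#' @export
setMethod("predict", "VotingEnsemble",
          function(object, newdata, perLearner = FALSE) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  x <- as.matrix(newdata)
  colnames(x) <- object@featureNames
  pOls <- as.numeric(cbind(1, x) %*% object@olsCoef)
  pRidge <- bayesRidgePredict(object@ridge, x)
  pTree <- unname(predict(object@tree,
                          newdata = as.data.frame(x, check.names = FALSE)))
  pSvr <- unname(predict(object@svr, newdata = x))
  base <- cbind(ols = pOls, ridge = pRidge, tree = pTree, svr = pSvr)
  combined <- rowMeans(base)
  if (perLearner) list(combined = combined, base = base) else combined
})

#' Structural modularity of a cluster
#'
#' Cohesion/(Cohesion + Coupling), where Cohesion =
#' \eqn{2 W_{in} / (\sqrt{|C|} (|C|-1))} rewards internal edge weight
#' scaled for the sparsity expected of larger complexes, and Coupling =
#' \eqn{W_{out} / |C|} penalizes boundary edge weight. High values mean a
#' cluster that is internally dense and well separated from the rest of
#' the network. Returns 0 when both terms vanish.
#'
#' @param cluster character vector of >= 2 protein IDs.
#' @param net weighted igraph.
#' @return SM value in \[0,1\].
#' @export
structuralModularity <- function(cluster, net) {
  mem <- unique(as.character(cluster))
  n <- length(mem)
  if (n < 2L) stop("cluster must contain >= 2 proteins")
  sub <- igraph::induced_subgraph(net, mem)
  win <- sum(edgeWeights(sub))
  # boundary weight
  inc <- igraph::incident_edges(net, mem)
  wAll <- edgeWeights(net)
  eIdx <- unique(unlist(lapply(inc, as.integer)))
  el <- igraph::as_edgelist(net)
  wout <- 0
  if (length(eIdx) > 0) {
    both <- (el[eIdx, 1] %in% mem) & (el[eIdx, 2] %in% mem)
    wout <- sum(wAll[eIdx][!both])
  }
  cohesion <- 2 * win / (sqrt(n) * (n - 1))
  coupling <- wout / n
  if (cohesion + coupling == 0) return(0)
  cohesion / (cohesion + coupling)
}

#' Ensemble fitness of a cluster
#'
#' The ensemble learning score guiding complex search: the voting-regressor
#' prediction (clipped to \[0,1\]) multiplied by the structural modularity.
#'
#' @param cluster character vector of >= 2 protein IDs.
#' @param net weighted igraph.
#' @param model a \linkS4class{VotingEnsemble}.
#' @return fitness in \[0,1\].
#' @export
fitnessScore <- function(cluster, net, model) {
  vrc <- clip01(predict(model, extractFeatures(cluster, net)))
  vrc * structuralModularity(cluster, net)
}
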
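# Clustering-quality metrics against a reference catalogue, plus
# hypergeometric GO enrichment.

asClusterList <- function(x) {
  if (is(x, "ComplexSet")) members(x) else lapply(x, as.character)
}

#' Neighborhood affinity of two protein sets
#'
#' \eqn{NA(S, D) = |S \cap D|^2 / (|S| |D|)}; 1 for identical sets, 0 for
#' disjoint ones. Values >= 0.2 conventionally count as a match.
#'
#' @param s,d non-empty character vectors.
#' @return affinity in \[0,1\].
#' @export
neighborhoodAffinity <- function(s, d) {
  s <- unique(s); d <- unique(d)
  if (length(s) == 0L || length(d) == 0L)
    stop("neighborhood affinity of an empty set is undefined")
  length(intersect(s, d))^2 / (length(s) * length(d))
}

naMatrix <- function(S, D) {
  outer(seq_along(S), seq_along(D),
        Vectorize(function(i, j) neighborhoodAffinity(S[[i]], D[[j]])))
}

overlapMatrix <- function(S, D) {
  outer(seq_along(S), seq_along(D),
        Vectorize(function(i, j) length(intersect(S[[i]], D[[j]]))))
}

#' Precision, recall and F-measure of predicted complexes
#'
#' A reference complex is matched when some prediction reaches
#' neighborhood affinity >= \code{omega} with it (and vice versa). Recall
#' = matched references / |S|, precision = matched predictions / |D|,
#' F-measure their harmonic mean (0 when both are 0).
#'
#' @param S reference complexes (list or \linkS4class{ComplexSet}).
#' @param D predicted complexes.
#' @param omega match threshold (default 0.2).
#' @return named list (precision, recall, fMeasure).
#' @export
fMeasure <- function(S, D, omega = 0.2) {
  S <- asClusterList(S); D <- asClusterList(D)
  if (length(S) == 0L || length(D) == 0L)
    return(list(precision = 0, recall = 0, fMeasure = 0))
  na <- naMatrix(S, D)
  recall <- mean(apply(na, 1, max) >= omega)
  precision <- mean(apply(na, 2, max) >= omega)
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, fMeasure = f)
}

#' Protein-level sensitivity, PPV and geometric accuracy
#'
#' From the overlap matrix T (shared protein counts): Sn = sum of per-
#' reference best overlaps over total reference protein count; PPV = sum
#' of per-prediction best overlaps over the total of all overlaps; ACC is
#' their geometric mean. Zero denominators yield 0.
#'
#' @param S reference complexes.
#' @param D predicted complexes.
#' @return named list (sn, ppv, acc).
#' @export
accuracyMetrics <- function(S, D) {
  S <- asClusterList(S); D <- asClusterList(D)
  if (length(S) == 0L || length(D) == 0L)
    return(list(sn = 0, ppv = 0, acc = 0))
  Tm <- overlapMatrix(S, D)
  Ni <- vapply(S, function(s) length(unique(s)), 1L)
  sn <- if (sum(Ni) > 0) sum(apply(Tm, 1, max)) / sum(Ni) else 0
  ppv <- if (sum(Tm) > 0) sum(apply(Tm, 2, max)) / sum(Tm) else 0
  list(sn = sn, ppv = ppv, acc = sqrt(sn * ppv))
}

#' Maximum matching ratio
#'
#' Builds the reference-prediction bipartite graph weighted by
#' neighborhood affinity. In \code{"matching"} mode (default), selects
#' disjoint edges maximizing the total weight (maximum-weight bipartite
#' matching) and divides the matched weight by |S|; \code{"rowmax"}
#' instead sums each reference's best affinity without the disjointness
#' constraint.
#'
#' @param S reference complexes.
#' @param D predicted complexes.
#' @param mode "matching" (one-to-one) or "rowmax".
#' @return MMR in \[0,1\].
#' @export
mmr <- function(S, D, mode = c("matching", "rowmax")) {
  mode <- match.arg(mode)
  S <- asClusterList(S); D <- asClusterList(D)
  if (length(S) == 0L || length(D) == 0L) return(0)
  na <- naMatrix(S, D)
  if (mode == "rowmax") return(sum(apply(na, 1, max)) / length(S))
  idx <- which(na > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0)
  g <- igraph::make_empty_graph(n = length(S) + length(D),
                                directed = FALSE)
  igraph::V(g)$type <- c(rep(FALSE, length(S)), rep(TRUE, length(D)))
  g <- igraph::add_edges(g, rbind(idx[, 1], length(S) + idx[, 2]))
  m <- igraph::max_bipartite_match(
    g, weights = na[idx])
  sum(m$matching_weight) / length(S)
}

#' Coverage rate
#'
#' Fraction of reference-complex proteins covered by each reference's
#' best-overlapping prediction: sum_i max_j T_ij / sum_i N_i.
#'
#' @param S reference complexes.
#' @param D predicted complexes.
#' @return CR in \[0,1\].
#' @export
coverageRate <- function(S, D) {
  S <- asClusterList(S); D <- asClusterList(D)
  if (length(S) == 0L || length(D) == 0L) return(0)
  Tm <- overlapMatrix(S, D)
  Ni <- vapply(S, function(s) length(unique(s)), 1L)
  if (sum(Ni) == 0) return(0)
  sum(apply(Tm, 1, max)) / sum(Ni)
}

#' Composite Jaccard score
#'
#' Size-weighted average of each side's best per-complex Jaccard indices
#' (JaccardD over predictions, JaccardS over references), combined by
#' their harmonic mean. 0 when both sides are 0.
#'
#' @param S reference complexes.
#' @param D predicted complexes.
#' @return composite Jaccard in \[0,1\].
#' @export
jaccardComposite <- function(S, D) {
  S <- asClusterList(S); D <- asClusterList(D)
  if (length(S) == 0L || length(D) == 0L) return(0)
  jac <- outer(seq_along(S), seq_along(D), Vectorize(function(i, j) {
    length(intersect(S[[i]], D[[j]])) / length(union(S[[i]], D[[j]]))
  }))
  sizeS <- vapply(S, length, 1L); sizeD <- vapply(D, length, 1L)
  jD <- sum(sizeD * apply(jac, 2, max)) / sum(sizeD)
  jS <- sum(sizeS * apply(jac, 1, max)) / sum(sizeS)
  if (jD + jS == 0) return(0)
  2 * jD * jS / (jD + jS)
}

#' Hypergeometric enrichment p-value
#'
#' Upper-tail probability of observing at least \code{k} proteins of a
#' functional group of size \code{F} in a complex of size \code{C} drawn
#' from a network of \code{N} proteins. Computed via the log-space stable
#' hypergeometric tail.
#'
#' @param C complex size.
#' @param k annotated members observed in the complex.
#' @param F functional-group size in the network.
#' @param N network protein count.
#' @return p-value in \[0,1\].
#' @export
enrichmentPvalue <- function(C, k, F, N) {
  if (k < 0 || F > N || C > N || k > min(C, F))
    stop("infeasible enrichment counts (need 0 <= k <= min(C, F) <= N)")
  if (k == 0) return(1)
  phyper(k - 1, F, N - F, C, lower.tail = FALSE)
}

#' Per-complex GO enrichment report
#'
#' For each complex, tests every GO term annotated to at least one member
#' with the hypergeometric upper tail, applies a Bonferroni correction by
#' the number of terms tested for that complex (capped at 1), and reports
#' the minimum corrected p-value. A complex with no annotated member gets
#' p = 1. Significance: corrected p < \code{alpha}.
#'
#' @param complexes list of protein sets or \linkS4class{ComplexSet}.
#' @param annotations named list protein -> character vector of terms.
#' @param universe total protein count N (default: number of annotated
#'   proteins).
#' @param alpha significance level (default 0.01).
#' @return data.frame (complex_id, size, best_term, p_raw, p_corrected,
#'   n_terms_tested, significant).
#' @export
enrichmentReport <- function(complexes, annotations, universe = NULL,
                             alpha = 0.01) {
  complexes <- asClusterList(complexes)
  if (length(annotations) == 0L) stop("annotation table is empty")
  byTerm <- split(rep(names(annotations), lengths(annotations)),
                  unlist(annotations))
  byTerm <- lapply(byTerm, unique)
  N <- if (is.null(universe)) length(annotations) else universe
  rows <- lapply(seq_along(complexes), function(i) {
    cx <- complexes[[i]]
    terms <- sort(unique(unlist(annotations[intersect(cx, names(annotations))])))
    if (length(terms) == 0L)
      return(data.frame(complex_id = i, size = length(cx),
                        best_term = NA_character_, p_raw = 1,
                        p_corrected = 1, n_terms_tested = 0L,
                        significant = FALSE))
    ps <- vapply(terms, function(t) {
      grp <- byTerm[[t]]
      k <- length(intersect(cx, grp))
      enrichmentPvalue(C = length(cx), k = k,
                       F = min(length(grp), N), N = N)
    }, numeric(1))
    corrected <- pmin(1, ps * length(terms))
    best <- which.min(corrected)
    data.frame(complex_id = i, size = length(cx),
               best_term = terms[best], p_raw = ps[best],
               p_corrected = corrected[best],
               n_terms_tested = length(terms),
               significant = corrected[best] < alpha)
  })
  do.call(rbind, rows)
}

#' Full evaluation report
#'
#' Computes all metrics of predicted complexes against a reference
#' catalogue and the composite total score = F-measure + CR + ACC + MMR +
#' Jaccard. When annotations are supplied, a per-complex enrichment table
#' is attached.
#'
#' @param S reference complexes.
#' @param D predicted complexes.
#' @param annotations optional named list protein -> terms.
#' @param universe optional protein universe size for enrichment.
#' @param omega NA match threshold (default 0.2).
#' @param mmrMode "matching" or "rowmax".
#' @return an \linkS4class{EvalReport}.
#' @export
evaluateComplexes <- function(S, D, annotations = NULL, universe = NULL,
                              omega = 0.2,
                              mmrMode = c("matching", "rowmax")) {
  mmrMode <- match.arg(mmrMode)
  Sl <- asClusterList(S); Dl <- asClusterList(D)
  if (length(Sl) == 0L) stop("reference catalogue is empty")
  fm <- fMeasure(Sl, Dl, omega = omega)
  ac <- accuracyMetrics(Sl, Dl)
  mm <- mmr(Sl, Dl, mode = mmrMode)
  cr <- coverageRate(Sl, Dl)
  jc <- jaccardComposite(Sl, Dl)
  m <- c(numPredicted = length(Dl), precision = fm$precision,
         recall = fm$recall, fMeasure = fm$fMeasure, sn = ac$sn,
         ppv = ac$ppv, acc = ac$acc, mmr = mm, cr = cr, jaccard = jc,
         totalScore = fm$fMeasure + cr + ac$acc + mm + jc)
  per <- if (!is.null(annotations) && length(Dl) > 0)
    enrichmentReport(Dl, annotations, universe = universe)
  else data.frame()
  new("EvalReport", metrics = m, perComplex = per)
}
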
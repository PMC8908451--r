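# Evaluation metrics and GO enrichment

test_that("neighborhood affinity matches its closed form", {
  expect_equal(neighborhoodAffinity(letters[1:4], letters[1:4]), 1)
  expect_equal(neighborhoodAffinity(letters[1:3], letters[10:12]), 0)
  expect_equal(neighborhoodAffinity(letters[1:4], letters[1:2]), 0.5)
  expect_equal(neighborhoodAffinity(c("a", "b"), c("a", "b", "c", "d")),
               neighborhoodAffinity(c("a", "b", "c", "d"), c("a", "b")))
  expect_error(neighborhoodAffinity(character(0), "a"), "empty")
})

test_that("F-measure counts omega-matched complexes on both sides", {
  S <- list(letters[1:4], letters[5:8], letters[9:12])
  expect_equal(fMeasure(S, S),
               list(precision = 1, recall = 1, fMeasure = 1))
  D0 <- list(c("z1", "z2", "z3"))
  expect_equal(fMeasure(S, D0)$fMeasure, 0)

  # 3 references vs 2 predictions, hand-enumerated NA matrix
  D <- list(c("a", "b", "c"), c("e", "f", "z1", "z2"))
  # NA(S1,D1) = 9/12 >= .2; NA(S2,D2) = 4/16 >= .2; S3 unmatched
  fm <- fMeasure(S, D)
  expect_equal(fm$recall, 2 / 3)
  expect_equal(fm$precision, 1)
  expect_equal(fm$fMeasure, 2 * (2 / 3) / (1 + 2 / 3))
})

test_that("Sn/PPV/ACC reproduce hand-summed overlap matrices", {
  S <- list(letters[1:4], letters[5:8])
  expect_equal(accuracyMetrics(S, S), list(sn = 1, ppv = 1, acc = 1))

  # prediction covering nothing: PPV denominator 0 -> 0 convention
  ac0 <- accuracyMetrics(S, list(c("z1", "z2")))
  expect_equal(ac0$ppv, 0)
  expect_equal(ac0$acc, 0)

  # 2x2 toy with hand sums: T = [[2,1],[0,2]]
  D <- list(c("a", "b", "x"), c("d", "g", "h", "y"))
  ac <- accuracyMetrics(S, D)
  expect_equal(ac$sn, (2 + 2) / 8)
  expect_equal(ac$ppv, (2 + 2) / 5)
  expect_equal(ac$acc, sqrt(0.5 * 0.8))
})

test_that("matching MMR forces disjoint pairs; rowmax mode does not", {
  S <- list(letters[1:4], letters[5:8])
  expect_equal(mmr(S, S), 1)

  # 2 references, 1 prediction: matching can keep only one edge, so MMR
  # is the larger affinity over |S|; rowmax sums both row maxima
  Sx <- list(c("a", "b", "c", "d", "e", "f", "g", "h"),
             c("p", "q", "r", "s", "t"))
  Dx <- list(c("a", "b", "c", "d", "p", "q", "r", "s", "t", "u"))
  na1 <- neighborhoodAffinity(Sx[[1]], Dx[[1]])
  na2 <- neighborhoodAffinity(Sx[[2]], Dx[[1]])
  expect_equal(mmr(Sx, Dx), max(na1, na2) / 2)
  expect_equal(mmr(Sx, Dx, mode = "rowmax"), (na1 + na2) / 2)
})

test_that("matching MMR equals brute-force enumeration on random NA
           matrices", {
  set.seed(2)
  pool <- sprintf("m%02d", 1:40)
  for (rep in 1:20) {
    S <- replicate(sample(4:6, 1), sample(pool, sample(3:6, 1)),
                   simplify = FALSE)
    D <- replicate(sample(4:6, 1), sample(pool, sample(3:6, 1)),
                   simplify = FALSE)
    na <- outer(seq_along(S), seq_along(D), Vectorize(function(i, j)
      neighborhoodAffinity(S[[i]], D[[j]])))
    expect_equal(mmr(S, D), bruteMatchWeight(na) / length(S),
                 tolerance = 1e-9)
  }
})

test_that("coverage rate is the best-overlap protein fraction", {
  S <- list(letters[1:4], letters[5:8])
  expect_equal(coverageRate(S, S), 1)
  # predictions covering exactly half of each reference
  D <- list(letters[1:2], letters[5:6])
  expect_equal(coverageRate(S, D), 0.5)
  expect_equal(coverageRate(S, list(c("z1", "z2"))), 0)
})

test_that("composite Jaccard combines both size-weighted sides
           harmonically", {
  S <- list(letters[1:4], letters[5:8])
  expect_equal(jaccardComposite(S, S), 1)
  expect_equal(jaccardComposite(S, list(c("z1", "z2"))), 0)

  # 2-vs-2 toy, hand computation
  D <- list(c("a", "b", "c"), c("e", "f", "x", "y"))
  j11 <- 3 / 4; j12 <- 0; j21 <- 0; j22 <- 2 / 6
  jD <- (3 * j11 + 4 * j22) / 7
  jS <- (4 * j11 + 4 * j22) / 8
  expect_equal(jaccardComposite(S, D), 2 * jD * jS / (jD + jS))
})

test_that("hypergeometric enrichment agrees with draw enumeration", {
  expect_equal(enrichmentPvalue(C = 3, k = 0, F = 4, N = 10), 1)
  # N=10, F=5, C=2, k=2: 1 - (C(5,0)C(5,2)+C(5,1)C(5,1))/C(10,2) = 10/45
  expect_equal(enrichmentPvalue(C = 2, k = 2, F = 5, N = 10), 10 / 45)
  # when every network protein carries the term, all-hits is certain
  expect_equal(enrichmentPvalue(C = 6, k = 6, F = 6, N = 6), 1)
  # all members drawn from a strict-subset group is near-impossible
  expect_equal(enrichmentPvalue(C = 5, k = 5, F = 5, N = 10),
               1 / choose(10, 5))
  expect_error(enrichmentPvalue(C = 2, k = 3, F = 5, N = 10),
               "infeasible")

  # exhaustive enumeration oracle for N <= 12
  for (case in list(c(8, 3, 4), c(12, 5, 6), c(9, 4, 4))) {
    N <- case[1]; C <- case[2]; F <- case[3]
    grp <- seq_len(F)
    draws <- combn(N, C)
    for (k in 0:min(C, F)) {
      frac <- mean(apply(draws, 2, function(d)
        sum(d %in% grp) >= k))
      expect_equal(enrichmentPvalue(C = C, k = k, F = F, N = N), frac,
                   tolerance = 1e-12)
    }
  }
})

test_that("the enrichment report applies per-complex Bonferroni
           correction", {
  ann <- list(a = c("t1", "t2", "t3"), b = c("t1", "t2", "t3"),
              c = "t1", d = "t2", e = "t3", f = "t9", g = "t9",
              h = "t9", i = "t9", j = "t9")
  rep3 <- enrichmentReport(list(c("a", "b", "c")), ann)
  # three terms tested -> corrected = raw * 3 capped at 1
  raws <- vapply(c("t1", "t2", "t3"), function(t) {
    grp <- names(ann)[vapply(ann, function(x) t %in% x, logical(1))]
    enrichmentPvalue(C = 3, k = length(intersect(c("a", "b", "c"), grp)),
                     F = length(grp), N = 10)
  }, numeric(1))
  expect_equal(rep3$n_terms_tested, 3L)
  expect_equal(rep3$p_corrected, min(pmin(1, raws * 3)))

  # complex with no annotated member -> p = 1, not significant
  rep0 <- enrichmentReport(list(c("z1", "z2", "z3")), ann)
  expect_equal(rep0$p_corrected, 1)
  expect_false(rep0$significant)

  # single-term universe: corrected equals raw
  ann1 <- list(a = "t1", b = "t1", c = "t1", d = "t1")
  rep1 <- enrichmentReport(list(c("a", "b")), ann1)
  expect_equal(rep1$p_raw, rep1$p_corrected)
})

test_that("the full report composes its metric operations and D = S
           scores a total of 5", {
  S <- list(letters[1:4], letters[5:8], letters[9:11])
  rep <- evaluateComplexes(S, S)
  m <- metrics(rep)
  expect_equal(unname(m["totalScore"]), 5)
  expect_equal(unname(m["numPredicted"]), 3)

  D <- list(c("a", "b", "c"), c("e", "f", "x", "y"), c("i", "j", "k"))
  m2 <- metrics(evaluateComplexes(S, D))
  expect_equal(unname(m2["fMeasure"]), fMeasure(S, D)$fMeasure)
  expect_equal(unname(m2["acc"]), accuracyMetrics(S, D)$acc)
  expect_equal(unname(m2["mmr"]), mmr(S, D))
  expect_equal(unname(m2["cr"]), coverageRate(S, D))
  expect_equal(unname(m2["jaccard"]), jaccardComposite(S, D))
  expect_equal(unname(m2["totalScore"]),
               unname(sum(m2[c("fMeasure", "cr", "acc", "mmr",
                               "jaccard")])))
})

test_that("metrics are invariant under reordering of either catalogue", {
  set.seed(5)
  pool <- sprintf("r%02d", 1:30)
  S <- replicate(5, sample(pool, sample(3:6, 1)), simplify = FALSE)
  D <- replicate(4, sample(pool, sample(3:6, 1)), simplify = FALSE)
  m1 <- metrics(evaluateComplexes(S, D))
  m2 <- metrics(evaluateComplexes(S[c(3, 1, 5, 2, 4)],
                                  D[c(4, 2, 1, 3)]))
  expect_equal(m1, m2)
})
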
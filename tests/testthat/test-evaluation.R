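# Baseline selectors and evaluation statistics.

test_that("hub selection thresholds at mean + 2 sd of the degree distribution", {
  expect_identical(hubGenes(starNet(9)), "HUB")
  expect_length(hubGenes(completeNet(4)), 0L)   # regular: sd = 0, strict >
  expect_length(hubGenes(pathNet()), 0L)        # w = 4/3 + 2*0.577 > 2
})

test_that("differential-expression selectors follow their definitions", {
  normal <- c(G1 = 10, G2 = 8, G3 = 5)
  tumor <- c(G1 = 40, G2 = 8, G3 = 0)
  sel <- degSelect(normal, tumor, "foldchange")
  expect_identical(as.character(sel), "G1")     # log2(4) = 2 > 1
  expect_equal(attr(sel, "skipped"), 1L)        # G3 has a non-positive value

  set.seed(21)
  refs <- matrix(rnorm(3 * 30, mean = 5), 3, 30,
                 dimnames = list(names(normal), NULL))
  tum2 <- c(G1 = mean(refs["G1", ]), G2 = 5 + 10 * sd(refs["G2", ]), G3 = 5)
  selP <- degSelect(normal, tum2, "pvalue", refs = refs)
  expect_false("G1" %in% selP)                  # exactly the mean: p = 1
  expect_true("G2" %in% selP)
  selF <- degSelect(normal, tum2, "fdr", refs = refs)
  expect_true(all(selF %in% selP))              # BH only removes calls
})

test_that("F-measure matches hand values and the harmonic-mean bound", {
  bg <- sprintf("G%02d", 1:20)
  expect_equal(fMeasure(bg[1:5], bg[1:5], bg),
               c(precision = 1, recall = 1, F = 1))
  # P = 1, R = 0.5 -> F = 2/3
  expect_equal(fMeasure(bg[1:2], bg[1:4], bg)[["F"]], 2 / 3)
  expect_equal(fMeasure(bg[1:3], bg[10:12], bg)[["F"]], 0)
  expect_error(fMeasure(bg[1], c("ZZ"), bg), "background")
  set.seed(22)
  for (rep in 1:20) {
    pred <- sample(bg, sample(0:10, 1))
    gold <- sample(bg, sample(1:10, 1))
    f <- fMeasure(pred, gold, bg)
    expect_gte(f[["F"]] + 1e-12, min(f[["precision"]], f[["recall"]]))
    expect_lte(f[["F"]] - 1e-12, max(f[["precision"]], f[["recall"]]))
  }
})

test_that("hypergeometric tail matches exhaustive enumeration for N <= 12", {
  for (N in c(5, 8, 12)) {
    for (K in 1:N) for (n in 1:N) {
      # enumerate all C(N, n) draws once, count overlap distribution
      draws <- combn(N, n)
      overlap <- colSums(draws <= K)
      for (k in 0:min(n, K)) {
        pEnum <- mean(overlap >= k)
        expect_equal(hypergeomEnrichment(N, K, n, k)$p, pEnum,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("hypergeometric p is 1 at k = 0 or K = N and non-increasing in k", {
  expect_equal(hypergeomEnrichment(100, 30, 10, 0)$p, 1)
  expect_equal(hypergeomEnrichment(10, 10, 4, 4)$p, 1)
  expect_equal(hypergeomEnrichment(10, 5, 2, 2)$p, 10 / 45, tolerance = 1e-12)
  p <- vapply(0:5, function(k) hypergeomEnrichment(40, 10, 5, k)$p, 1)
  expect_true(all(diff(p) <= 1e-15))
  expect_error(hypergeomEnrichment(10, 5, 2, 3), "k <= min")
})

test_that("BH adjustment is monotone and never below the raw p-values", {
  set.seed(23)
  p <- runif(50)
  adj <- p.adjust(p, "BH")
  expect_true(all(adj >= p - 1e-15))
  ord <- order(p)
  expect_true(all(diff(adj[ord]) >= -1e-15))
})

test_that("driver frequency classes split at 0.3 / 0.6 / 0.8", {
  sets <- c(lapply(1:7, function(i) c("A", "B")),
            lapply(1:3, function(i) c("B", "C")))
  names(sets) <- sprintf("p%02d", 1:10)
  sets[["p01"]] <- c(sets[["p01"]], "D")  # D appears once
  # A: 0.7 -> high; B: 1.0 -> cohort driver; C: 0.3 -> low; D: 0.1 -> low
  fr <- driverFrequency(sets)
  expect_equal(fr$class[fr$gene == "A"], "high")
  expect_true(fr$cohortDriver[fr$gene == "B"])
  expect_false(fr$cohortDriver[fr$gene == "A"])
  expect_equal(fr$class[fr$gene == "C"], "low")
  # exactly 0.6 is medium (inclusive upper bound)
  sets6 <- c(lapply(1:6, function(i) "X"), lapply(1:4, function(i) "Y"))
  fr6 <- driverFrequency(sets6)
  expect_equal(fr6$class[fr6$gene == "X"], "medium")
  expect_error(driverFrequency(list()), "at least one")
})

test_that("per-gene sub-network statistics aggregate across patients", {
  n1 <- makeStn("p1", cbind(c("TT", "TT"), c("A", "B")))
  n2 <- makeStn("p2", cbind("TT", c("A", "B", "C", "D")))
  expr <- c(TT = 2, A = 2, B = 2, C = 2, D = 2)
  pairs <- list(p1 = patientPair("p1", expr, expr),
                p2 = patientPair("p2", expr, expr))
  mut <- matrix(0, 1, 2, dimnames = list("TT", c("p1", "p2")))
  st <- geneSubnetworkStats("TT", list(p1 = n1, p2 = n2), pairs,
                            driverSets = list(p1 = "TT", p2 = "A"),
                            mutations = mut)
  expect_equal(st$mean_degree, 3)          # degrees 2 and 4
  expect_equal(st$mean_abs_log2fc, 0)      # tumor == normal
  expect_equal(st$mutation_frequency, 0)
  expect_equal(st$driver_frequency, 0.5)
  expect_error(geneSubnetworkStats("ZZ", list(p1 = n1), pairs["p1"]),
               "absent")
})

test_that("gene-set enrichment composes the hypergeometric test over a collection", {
  bg <- sprintf("G%02d", 1:30)
  coll <- list(hit = bg[1:5], miss = bg[20:25])
  res <- enrichGeneSets(bg[1:5], coll, bg)
  expect_equal(res$k[res$set == "hit"], 5L)
  expect_equal(res$k[res$set == "miss"], 0L)
  expect_equal(res$p[res$set == "miss"], 1)
  expect_lt(res$p[res$set == "hit"], 0.001)
})
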
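# Per-patient network construction: paired XOR rule, single-sample
# baseline, LIONESS interpolation.

test_that("an identical tumor and normal sample yields an empty paired network", {
  set.seed(11)
  expr <- matrix(rnorm(5 * 30), 5, 30,
                 dimnames = list(paste0("G", 1:5), NULL))
  net <- geneNetwork(t(combn(paste0("G", 1:5), 2)))
  v <- setNames(rnorm(5), paste0("G", 1:5))
  stn <- pairedSSN(expr, patientPair("p", v, v), net)
  expect_equal(nrow(networkEdges(stn)), 0L)
})

test_that("every construction stays inside the reference edge set", {
  set.seed(12)
  expr <- matrix(rnorm(12 * 40), 12, 40,
                 dimnames = list(sprintf("G%02d", 1:12), NULL))
  allPairs <- t(combn(sprintf("G%02d", 1:12), 2))
  net <- geneNetwork(allPairs[sample(nrow(allPairs), 30), ])
  pp <- patientPair("p", setNames(rnorm(12), rownames(expr)),
                    setNames(rnorm(12), rownames(expr)))
  tum <- matrix(rnorm(12 * 8), 12, 8,
                dimnames = list(rownames(expr), paste0("t", 1:8)))
  for (stn in list(pairedSSN(expr, pp, net),
                   ssnNetwork(expr, pp, net),
                   lionessNetwork(tum, "t3", net))) {
    if (nrow(networkEdges(stn)) > 0)
      expect_true(all(edgesIn(networkEdges(stn), net)))
  }
})

test_that("ssn baseline at alpha = 0 is empty and a reference-like sample is near-empty", {
  set.seed(13)
  expr <- matrix(rnorm(6 * 50), 6, 50,
                 dimnames = list(paste0("G", 1:6), NULL))
  net <- geneNetwork(t(combn(paste0("G", 1:6), 2)))
  smp <- setNames(rnorm(6), paste0("G", 1:6))
  expect_equal(nrow(networkEdges(ssnNetwork(expr, smp, net, alpha = 0))), 0L)
  # a sample identical to a reference column perturbs correlations little
  smp2 <- expr[, 1]
  stn <- ssnNetwork(expr, smp2, net, alpha = 0.05)
  expect_lte(nrow(networkEdges(stn)), 2L)
})

test_that("lioness weights follow the interpolation identity against a cor() oracle", {
  set.seed(14)
  Ns <- 10
  tum <- matrix(rnorm(6 * Ns), 6, Ns,
                dimnames = list(paste0("G", 1:6), paste0("t", 1:Ns)))
  net <- geneNetwork(t(combn(paste0("G", 1:6), 2)))
  stn <- lionessNetwork(tum, "t4", net)
  if (nrow(networkEdges(stn)) > 0) {
    for (i in seq_len(nrow(networkEdges(stn)))) {
      a <- networkEdges(stn)[i, 1]; b <- networkEdges(stn)[i, 2]
      eAll <- cor(tum[a, ], tum[b, ])
      eMinus <- cor(tum[a, -4], tum[b, -4])
      expect_equal(stn@edgeInfo$weight[i],
                   Ns * (eAll - eMinus) + eMinus, tolerance = 1e-10)
    }
  }
  # the hand identity: e_all = 0.5, e_minus = 0.4, Ns = 10 -> 1.4
  expect_equal(10 * (0.5 - 0.4) + 0.4, 1.4)
  # e_all == e_minus: the interpolation collapses to the common value
  expect_equal(10 * (0.3 - 0.3) + 0.3, 0.3)
})

test_that("a single-edge network cannot beat the mean + 2 sd threshold", {
  set.seed(15)
  tum <- matrix(rnorm(2 * 8), 2, 8,
                dimnames = list(c("G1", "G2"), paste0("t", 1:8)))
  net <- geneNetwork(cbind("G1", "G2"))
  stn <- lionessNetwork(tum, "t1", net)
  expect_equal(nrow(networkEdges(stn)), 0L)
})

test_that("planted rewiring is recovered and the paired rule beats the baseline on false calls", {
  coh <- genPlantedCohort(nPatients = 8, seed = 31)
  refKeys <- paste(coh@network@edges[, 1], coh@network@edges[, 2])
  recalls <- fpPaired <- fpBase <- numeric(length(coh@pairs))
  for (i in seq_along(coh@pairs)) {
    stn <- pairedSSN(coh@refExpr, coh@pairs[[i]], coh@network)
    base <- ssnNetwork(coh@refExpr, coh@pairs[[i]], coh@network)
    pe <- coh@plantedEdges[[i]]
    pKeys <- paste(pmin(pe[, 1], pe[, 2]), pmax(pe[, 1], pe[, 2]))
    sKeys <- paste(networkEdges(stn)[, 1], networkEdges(stn)[, 2])
    bKeys <- paste(networkEdges(base)[, 1], networkEdges(base)[, 2])
    nonPlanted <- setdiff(refKeys, pKeys)
    recalls[i] <- mean(pKeys %in% sKeys)
    fpPaired[i] <- mean(nonPlanted %in% sKeys)
    fpBase[i] <- mean(nonPlanted %in% bKeys)
  }
  expect_gte(mean(recalls), 0.8)
  expect_lt(mean(fpPaired), 2 * 0.05)
  expect_lt(mean(fpPaired), mean(fpBase))
})
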
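# Generators: scale-free static model, Erdos-Renyi, planted cohorts.

test_that("static-model networks hit the target mean degree and are reproducible", {
  net <- genSFNetwork(2000, gamma = 2.5, kAvg = 4, seed = 7)
  k <- mean(nodeDegrees(net))
  expect_gt(k, 3.6); expect_lt(k, 4.4)
  net2 <- genSFNetwork(2000, gamma = 2.5, kAvg = 4, seed = 7)
  expect_identical(networkEdges(net), networkEdges(net2))
  expect_error(genSFNetwork(200, 2.5, 250, seed = 1), "infeasible")
  expect_error(genSFNetwork(50, 2.5, 4, seed = 1), "at least 100")
})

test_that("a large exponent approaches Erdos-Renyi degree homogeneity", {
  sf <- genSFNetwork(1500, gamma = 10, kAvg = 4, seed = 3)
  er <- genERNetwork(1500, kAvg = 4, seed = 3)
  heavy <- genSFNetwork(1500, gamma = 2.2, kAvg = 4, seed = 3)
  vSF <- var(nodeDegrees(sf)); vER <- var(nodeDegrees(er))
  expect_lt(abs(vSF - vER) / vER, 0.5)
  expect_gt(var(nodeDegrees(heavy)), 3 * vER)
})

test_that("Erdos-Renyi generation respects p and the seed", {
  er <- genERNetwork(1000, kAvg = 4, seed = 9)
  k <- mean(nodeDegrees(er))
  expect_gt(k, 3.6); expect_lt(k, 4.4)
  expect_identical(networkEdges(er),
                   networkEdges(genERNetwork(1000, kAvg = 4, seed = 9)))
  empty <- genERNetwork(500, kAvg = 0, seed = 1)
  expect_equal(nrow(networkEdges(empty)), 0L)
})

test_that("planted cohorts are seed-deterministic with consistent ground truth", {
  a <- genPlantedCohort(nPatients = 3, seed = 5)
  b <- genPlantedCohort(nPatients = 3, seed = 5)
  expect_identical(a@refExpr, b@refExpr)
  expect_identical(a@plantedEdges, b@plantedEdges)
  expect_identical(a@pairs[[2]]@tumor, b@pairs[[2]]@tumor)
  # planted edges live in the reference network; drivers cover them
  for (i in seq_along(a@pairs)) {
    pe <- a@plantedEdges[[i]]
    expect_true(all(edgesIn(pe, a@network)))
    drv <- a@plantedDrivers[[i]]
    expect_true(all(pe[, 1] %in% drv | pe[, 2] %in% drv))
    # ground truth is a matching: one driver per planted pair is minimal
    expect_length(drv, nrow(pe))
  }
})

test_that("the reference panel carries the designed pair correlation", {
  coh <- genPlantedCohort(nRef = 200, nPatients = 1, seed = 6)
  prs <- attr(coh@network, "coexprPairs")
  rs <- vapply(seq_len(nrow(prs)), function(i)
    cor(coh@refExpr[prs[i, 1], ], coh@refExpr[prs[i, 2], ]), 1)
  expect_equal(mean(rs), coh@params$rho0, tolerance = 0.05)
  # non-pair genes are uncorrelated on average
  others <- setdiff(rownames(coh@refExpr), c(prs))[1:20]
  r0 <- cor(t(coh@refExpr[others, ]))
  expect_lt(mean(abs(r0[upper.tri(r0)])), 0.12)
})

test_that("a zero effect leaves tumor and normal exchangeable", {
  coh <- genPlantedCohort(nPatients = 6, effect = 0, seed = 21)
  rates <- vapply(coh@pairs, function(pp) {
    stn <- pairedSSN(coh@refExpr, pp, coh@network)
    nrow(networkEdges(stn)) / nrow(networkEdges(coh@network))
  }, 1)
  expect_lt(mean(rates), 2 * 0.05)
})

test_that("an oversized planting request is refused", {
  expect_error(genPlantedCohort(nPlanted = 1000, seed = 1), "exceeds")
})
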
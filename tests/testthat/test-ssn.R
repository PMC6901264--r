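# The single-sample differential-correlation statistic and its null.

test_that("the z statistic matches hand-evaluated cases", {
  # pcc_ref = 0, pcc_pert = 0.5, n = 26: z = 0.5 / (1/25) = 12.5
  s <- netDrivers:::ssnZ(0, 0.5, 26)
  expect_equal(s$delta, 0.5)
  expect_equal(s$z, 12.5)
  # pcc_ref = 0.4, pcc_pert = 0.7, n = 101: z = 0.3 / (0.84/100)
  s <- netDrivers:::ssnZ(0.4, 0.7, 101)
  expect_equal(s$z, 0.3 * 100 / 0.84, tolerance = 1e-12)
  expect_equal(s$z, 35.714, tolerance = 1e-4)
  # identical correlations: delta 0, z 0, p 1
  s <- netDrivers:::ssnZ(0.3, 0.3, 50)
  expect_equal(s$delta, 0)
  expect_equal(s$z, 0)
  expect_equal(s$p, 1)
})

test_that("edgeStats agrees with a textbook cor() oracle and inverts exactly", {
  set.seed(101)
  for (rep in 1:5) {
    n <- sample(10:40, 1)
    expr <- matrix(rnorm(6 * n), 6, n,
                   dimnames = list(paste0("G", 1:6), NULL))
    smp <- setNames(rnorm(6), rownames(expr))
    edges <- t(combn(rownames(expr), 2))
    st <- edgeStats(expr, smp, edges)
    for (i in seq_len(nrow(st))) {
      x <- expr[st$gene_a[i], ]; y <- expr[st$gene_b[i], ]
      r0 <- cor(x, y)
      r1 <- cor(c(x, smp[st$gene_a[i]]), c(y, smp[st$gene_b[i]]))
      expect_equal(st$pcc_ref[i], r0, tolerance = 1e-10)
      expect_equal(st$pcc_pert[i], r1, tolerance = 1e-10)
    }
    # inversion: delta == z (1 - pcc_ref^2) / (n - 1)
    expect_equal(st$delta,
                 st$z * (1 - st$pcc_ref^2) / (n - 1),
                 tolerance = 1e-12)
    expect_true(all(st$delta >= 0 & st$z >= 0))
    expect_true(all(st$p > 0 & st$p <= 1))
  }
})

test_that("degenerate reference genes are excluded with a count", {
  expr <- rbind(G1 = rnorm(10), G2 = rep(1, 10), G3 = rnorm(10))
  smp <- c(G1 = 0, G2 = 0, G3 = 0)
  edges <- cbind(c("G1", "G1"), c("G2", "G3"))
  expect_message(st <- edgeStats(expr, smp, edges), "1 edge")
  expect_equal(nrow(st), 1L)
  expect_equal(attr(st, "excluded"), 1L)
})

test_that("significantEdges thresholds strictly and handles boundaries", {
  st <- data.frame(gene_a = c("A", "B", "C"), gene_b = c("B", "C", "D"),
                   p = c(0.01, 0.2, 0.05))
  expect_equal(nrow(significantEdges(st, 0.05)), 1L)   # 0.05 is not < 0.05
  expect_equal(nrow(significantEdges(st, 0.9999)), 3L)
  expect_error(significantEdges(st, 1.0), "alpha")
  empty <- st[0, , drop = FALSE]
  expect_equal(nrow(significantEdges(empty, 0.05)), 0L)
})

test_that("volcano null calibrates against the closed-form inversion", {
  crit <- vapply(c(20, 50, 100), function(n)
    volcanoNull(n, 2e4, seed = 7)$critical, 1)
  ref <- 1.96 / (c(20, 50, 100) - 1)
  expect_true(all(abs(crit - ref) / ref < 0.2))
  # monotone: more reference samples, smaller critical perturbation
  expect_true(crit[1] > crit[2] && crit[2] > crit[3])
})

test_that("volcano null is seed-deterministic", {
  a <- volcanoNull(20, 1e4, seed = 3)
  b <- volcanoNull(20, 1e4, seed = 3)
  expect_identical(a$sample, b$sample)
})
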
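# Structural-control driver sets: bipartite reformulation, exact cover
# solver against the enumeration oracle, controllability.

test_that("the bipartite reformulation has two links per bottom node", {
  b <- buildBipartite(pathNet())
  expect_length(b$top, 3L)
  expect_length(b$bottom, 2L)
  expect_equal(nrow(b$links), 4L)

  tri <- completeNet(3)
  b <- buildBipartite(tri)
  expect_length(b$bottom, 3L)
  expect_equal(nrow(b$links), 6L)
  expect_true(all(table(b$links[, "edge"]) == 2L))

  lone <- geneNetwork(matrix(character(0), 0, 2), nodes = c("A", "B"))
  b <- buildBipartite(lone)
  expect_length(b$bottom, 0L)
  expect_equal(nrow(b$links), 0L)
})

test_that("known minimum covers are found exactly", {
  expect_identical(drivers(ncuaDrivers(pathNet())), "B")
  expect_equal(ncuaDrivers(cycleNet(5))@objective, 3L)
  expect_identical(drivers(ncuaDrivers(starNet(5))), "HUB")
  expect_equal(ncuaDrivers(completeNet(4))@objective, 3L)
})

test_that("the brute-force oracle behaves on small graphs and guards its size", {
  expect_equal(bruteForceCover(pathNet())$size, 1L)
  expect_equal(bruteForceCover(completeNet(3))$size, 2L)
  edgeless <- geneNetwork(matrix(character(0), 0, 2), nodes = LETTERS[1:3])
  expect_equal(bruteForceCover(edgeless)$size, 0L)
  big <- randomGnp(25, 0.2, seed = 1)
  expect_error(bruteForceCover(big), "20 nodes")
})

test_that("solver and enumeration oracle agree on random graphs", {
  set.seed(77)
  for (rep in 1:60) {
    net <- randomGnp(sample(4:12, 1), runif(1, 0.2, 0.6), seed = rep)
    r <- ncuaDrivers(net)
    b <- bruteForceCover(net)
    expect_equal(r@objective, b$size)
    # feasibility: every edge covered
    e <- networkEdges(net)
    if (nrow(e))
      expect_true(all(e[, 1] %in% drivers(r) | e[, 2] %in% drivers(r)))
  }
})

test_that("cover size is monotone under edge addition and matching-bounded", {
  set.seed(99)
  for (rep in 1:10) {
    ids <- sprintf("m%02d", 1:10)
    pairs <- t(combn(ids, 2))
    pairs <- pairs[sample(nrow(pairs)), ]
    sizes <- integer(0)
    for (m in c(5, 10, 15, 20)) {
      net <- geneNetwork(pairs[1:m, ])
      r <- ncuaDrivers(net)
      sizes <- c(sizes, r@objective)
      # any maximal matching m satisfies m <= cover <= 2 m
      used <- character(0); gm <- 0L
      e <- networkEdges(net)
      for (i in seq_len(nrow(e)))
        if (!(e[i, 1] %in% used) && !(e[i, 2] %in% used)) {
          used <- c(used, e[i, ]); gm <- gm + 1L
        }
      expect_gte(r@objective, gm)
      expect_lte(r@objective, 2L * gm)
    }
    expect_true(all(diff(sizes) >= 0))
  }
})

test_that("deterministic branching returns a reproducible driver set", {
  net <- randomGnp(30, 0.15, seed = 8)
  expect_identical(drivers(ncuaDrivers(net)), drivers(ncuaDrivers(net)))
})

test_that("controllability follows |D| / |connected nodes|", {
  star <- starNet(4)
  expect_equal(controllability(star, "HUB"), 0.2)
  k3 <- completeNet(3)
  expect_equal(controllability(k3, c("A", "B")), 2 / 3)
  expect_equal(controllability(k3, c("A", "B", "C")), 1)
  expect_error(controllability(k3, "Z"), "subset")
  edgeless <- geneNetwork(matrix(character(0), 0, 2), nodes = c("A", "B"))
  expect_error(controllability(edgeless, "A"), "edgeless")
  # isolated nodes do not enter the denominator
  withIso <- geneNetwork(cbind("A", "B"), nodes = c("A", "B", "Z"))
  expect_equal(controllability(withIso, "A"), 0.5)
})

test_that("an exhausted node budget raises an error carrying the incumbent", {
  net <- randomGnp(60, 0.3, seed = 4)
  err <- tryCatch(ncuaDrivers(net, nodeLimit = 2),
                  ncuaTimeout = function(e) e)
  expect_s3_class(err, "ncuaTimeout")
  inc <- err$incumbent
  expect_s4_class(inc, "DriverResult")
  expect_identical(inc@status, "node_limit")
  e <- networkEdges(net)
  expect_true(all(e[, 1] %in% drivers(inc) | e[, 2] %in% drivers(inc)))
  # same budget with onTimeout = "incumbent" returns instead of erroring
  r <- ncuaDrivers(net, nodeLimit = 2, onTimeout = "incumbent")
  expect_identical(r@status, "node_limit")
})
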
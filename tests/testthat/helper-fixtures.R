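# Shared fixtures, built in code. The default planted cohort is cached so
# several test files can reuse one simulation.

pathNet <- function(genes = c("A", "B", "C")) {
  geneNetwork(cbind(genes[-length(genes)], genes[-1]))
}

cycleNet <- function(n) {
  g <- sprintf("V%02d", seq_len(n))
  geneNetwork(cbind(g, c(g[-1], g[1])))
}

starNet <- function(nLeaves, center = "HUB") {
  geneNetwork(cbind(center, sprintf("L%02d", seq_len(nLeaves))))
}

completeNet <- function(n) {
  g <- LETTERS[seq_len(n)]
  geneNetwork(t(combn(g, 2)))
}

randomGnp <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  ids <- sprintf("n%02d", seq_len(n))
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) == 0) return(geneNetwork(matrix(character(0), 0, 2), nodes = ids))
  geneNetwork(cbind(ids[el[, 1]], ids[el[, 2]]), nodes = ids)
}

# edge membership helper: which rows of `edges` occur in network `net`
edgesIn <- function(edges, net) {
  a <- pmin(edges[, 1], edges[, 2]); b <- pmax(edges[, 1], edges[, 2])
  paste(a, b) %in% paste(net@edges[, 1], net@edges[, 2])
}

defaultCohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- genPlantedCohort(seed = 2026)
    cache
  }
})

# run paired-SSN + drivers over a cohort once, cached; several acceptance
# and property tests consume the same run
cohortRun <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    coh <- defaultCohort()
    res <- lapply(names(coh@pairs), function(pid) {
      stn <- pairedSSN(coh@refExpr, coh@pairs[[pid]], coh@network)
      base <- ssnNetwork(coh@refExpr, coh@pairs[[pid]], coh@network)
      drv <- ncuaDrivers(stn)
      list(stn = stn, base = base, drv = drv)
    })
    names(res) <- names(coh@pairs)
    cache <<- res
    res
  }
})

# minimal state transition network for evaluation tests
makeStn <- function(pid, edges) {
  e <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  new("StateTransitionNetwork", nodes = sort(unique(c(e))), edges = e,
      patientId = pid, method = "paired_ssn",
      edgeInfo = data.frame(p_tumor = rep(0.01, nrow(e)),
                            p_normal = rep(0.5, nrow(e))))
}
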
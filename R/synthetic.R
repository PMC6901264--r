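# Seed-deterministic generators: scale-free (static model) and
# Erdos-Renyi graphs for controllability-versus-structure experiments, and
# paired normal/tumor expression cohorts with planted tumor-specific
# co-expression rewiring for end-to-end recovery tests.

#' Scale-free network by the static model
#'
#' Nodes carry weights w_i proportional to i^(-1/(gamma-1)); edges are
#' sampled with probability proportional to w_i w_j (rejecting self-loops
#' and duplicates) until the target edge count n kAvg / 2 is reached. The
#' resulting degree distribution follows a power law with exponent gamma.
#'
#' @param n number of nodes (>= 100).
#' @param gamma target degree exponent (> 1); large gamma approaches an
#'   Erdos-Renyi-like homogeneous graph.
#' @param kAvg target mean degree; must be feasible (kAvg < n - 1).
#' @param seed RNG seed; the edge set is a pure function of the arguments.
#' @return a \linkS4class{GeneNetwork} with nodes "g0001", "g0002", ...
#' @examples
#' net <- genSFNetwork(200, gamma = 2.5, kAvg = 4, seed = 1)
#' mean(nodeDegrees(net))
#' @export
genSFNetwork <- function(n, gamma, kAvg, seed) {
  if (n < 100) stop("n must be at least 100")
  if (gamma <= 1) stop("gamma must exceed 1")
  if (kAvg >= n - 1) stop("infeasible mean degree: kAvg >= n - 1")
  m <- round(n * kAvg / 2)
  set.seed(seed)
  w <- seq_len(n)^(-1 / (gamma - 1))
  w <- w / sum(w)
  keys <- character(0)
  edges <- matrix(integer(0), 0, 2)
  while (nrow(edges) < m) {
    b <- 2L * (m - nrow(edges)) + 100L
    a1 <- sample.int(n, b, replace = TRUE, prob = w)
    a2 <- sample.int(n, b, replace = TRUE, prob = w)
    ok <- a1 != a2
    e <- cbind(pmin(a1[ok], a2[ok]), pmax(a1[ok], a2[ok]))
    k <- paste(e[, 1], e[, 2])
    new <- !duplicated(k) & !(k %in% keys)
    e <- e[new, , drop = FALSE]
    take <- seq_len(min(nrow(e), m - nrow(edges)))
    edges <- rbind(edges, e[take, , drop = FALSE])
    keys <- c(keys, k[new][take])
  }
  ids <- sprintf("g%04d", seq_len(n))
  geneNetwork(cbind(ids[edges[, 1]], ids[edges[, 2]]), nodes = ids)
}

#' Erdos-Renyi random network
#'
#' G(n, p) with p = kAvg / (n - 1); the homogeneous-degree reference for
#' the controllability experiments.
#'
#' @param n number of nodes.
#' @param kAvg target mean degree; 0 gives an edgeless graph.
#' @param seed RNG seed.
#' @return a \linkS4class{GeneNetwork} with nodes "g0001", ...
#' @export
genERNetwork <- function(n, kAvg, seed) {
  p <- kAvg / (n - 1)
  if (p < 0 || p > 1) stop("kAvg out of range")
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  ids <- sprintf("g%04d", seq_len(n))
  el <- igraph::as_edgelist(g, names = FALSE)
  geneNetwork(cbind(ids[el[, 1]], ids[el[, 2]]), nodes = ids)
}

#' Default modular cohort network
#'
#' The reference interaction network used by the planted-cohort generator
#' when none is supplied: \code{nCoexprPairs} disjoint co-expressed gene
#' pairs (the "modules" that carry real correlation) plus
#' \code{nBackground} random background edges between genes with no
#' underlying co-expression, over \code{nGenes} genes in total.
#'
#' @param nGenes total genes (default 400).
#' @param nCoexprPairs co-expressed partner pairs (default 60).
#' @param nBackground background edges (default 40).
#' @param seed RNG seed.
#' @return a \linkS4class{GeneNetwork}; the co-expressed pairs are stored
#'   in attribute \code{"coexprPairs"} (two-column character matrix).
#' @export
cohortNetwork <- function(nGenes = 400, nCoexprPairs = 60,
                          nBackground = 40, seed = 1) {
  if (2 * nCoexprPairs > nGenes) stop("too many pairs for the gene count")
  set.seed(seed)
  ids <- sprintf("g%03d", seq_len(nGenes))
  pg <- matrix(sample(ids, 2 * nCoexprPairs), ncol = 2)
  pg <- normalizeEdges(pg)
  keys <- edgeKeys(pg)
  bg <- matrix(character(0), 0, 2)
  while (nrow(bg) < nBackground) {
    cand <- normalizeEdges(matrix(sample(ids, 2), 1, 2))
    k <- edgeKeys(cand)
    if (cand[1, 1] == cand[1, 2] || k %in% keys) next
    bg <- rbind(bg, cand)
    keys <- c(keys, k)
  }
  net <- geneNetwork(rbind(pg, bg), nodes = ids)
  attr(net, "coexprPairs") <- pg[order(pg[, 1], pg[, 2]), , drop = FALSE]
  net
}

# one draw from the block-pair correlation model: standard normal
# everywhere, correlation rho0 within each co-expressed pair (2x2 blocks
# are always positive definite, so no repair is ever needed)
drawCohortSample <- function(genes, pairs, rho0) {
  z <- stats::setNames(rnorm(length(genes)), genes)
  z[pairs[, 2]] <- rho0 * z[pairs[, 1]] +
    sqrt(1 - rho0^2) * z[pairs[, 2]]
  z
}

#' Paired cohort with planted tumor-specific rewiring
#'
#' Simulates the inputs of a paired-sample driver study. Reference panel:
#' \code{nRef} draws from a block-pair correlation model in which each
#' co-expressed gene pair has Pearson correlation \code{rho0} and all other
#' genes are independent. Each patient contributes a normal and a tumor
#' sample sharing a patient-specific latent component (fraction
#' \code{sharedFraction} of the variance) and a set of
#' \code{nIdiosyncratic} genes with a patient-constant expression offset
#' present in both samples (a germline-like artifact: it inflates
#' single-sample false calls but cancels in the paired construction). The
#' tumor sample additionally rewires \code{nPlanted} randomly chosen
#' co-expressed pairs: the two partners are displaced discordantly by
#' (10/3) x \code{effect} reference standard deviations against the
#' co-expression axis, the single-sample signature of a dysregulated
#' driver pair (large, correlation-breaking fold changes).
#'
#' @param net reference \linkS4class{GeneNetwork} carrying a
#'   \code{"coexprPairs"} attribute (as built by
#'   \code{\link{cohortNetwork}}); by default a fresh default network is
#'   generated from the seed.
#' @param nRef reference (normal) panel size.
#' @param nPatients number of paired patients.
#' @param nPlanted rewired pairs per patient (<= number of co-expressed
#'   pairs).
#' @param effect perturbation magnitude in (0, 1]; 0 is allowed and means
#'   no rewiring (tumor and normal exchangeable).
#' @param seed RNG seed; the whole cohort is a pure function of the
#'   arguments.
#' @param rho0 co-expressed pair correlation.
#' @param sharedFraction fraction of each patient sample's variance shared
#'   between that patient's normal and tumor sample.
#' @param nIdiosyncratic patient-specific offset genes per patient.
#' @param idioMagnitude offset size in reference standard deviations.
#' @return a \linkS4class{PlantedCohort}; ground-truth planted covers are
#'   exact minimum covers of each planted subgraph (computed by
#'   enumeration per component).
#' @export
genPlantedCohort <- function(net = NULL, nRef = 100, nPatients = 20,
                             nPlanted = 20, effect = 0.6, seed = 1,
                             rho0 = 0.8, sharedFraction = 0.92,
                             nIdiosyncratic = 12, idioMagnitude = 2.5) {
  if (effect < 0 || effect > 1) stop("effect must lie in [0, 1]")
  if (abs(rho0) >= 1) stop("rho0 must lie in (-1, 1)")
  if (sharedFraction < 0 || sharedFraction >= 1)
    stop("sharedFraction must lie in [0, 1)")
  if (is.null(net)) net <- cohortNetwork(seed = seed)
  pairsMat <- attr(net, "coexprPairs")
  if (is.null(pairsMat)) {
    # derive disjoint co-expressed pairs from the network: greedy maximal
    # matching in lexicographic edge order (deterministic)
    used <- character(0)
    sel <- logical(nrow(net@edges))
    for (i in seq_len(nrow(net@edges))) {
      e <- net@edges[i, ]
      if (!(e[1] %in% used) && !(e[2] %in% used)) {
        sel[i] <- TRUE
        used <- c(used, e)
      }
    }
    pairsMat <- net@edges[sel, , drop = FALSE]
  }
  if (nPlanted > nrow(pairsMat))
    stop(sprintf("nPlanted (%d) exceeds the %d available co-expressed pairs",
                 nPlanted, nrow(pairsMat)))
  genes <- net@nodes
  set.seed(seed)
  refExpr <- vapply(seq_len(nRef),
                    function(i) drawCohortSample(genes, pairsMat, rho0),
                    numeric(length(genes)))
  rownames(refExpr) <- genes
  colnames(refExpr) <- sprintf("ref%03d", seq_len(nRef))

  disp <- (10 / 3) * effect
  w <- sharedFraction
  pairsList <- vector("list", nPatients)
  plantedEdges <- vector("list", nPatients)
  plantedDrivers <- vector("list", nPatients)
  for (p in seq_len(nPatients)) {
    shared <- drawCohortSample(genes, pairsMat, rho0)
    nrm <- sqrt(w) * shared + sqrt(1 - w) * drawCohortSample(genes, pairsMat, rho0)
    tum <- sqrt(w) * shared + sqrt(1 - w) * drawCohortSample(genes, pairsMat, rho0)
    idio <- sample(genes, nIdiosyncratic)
    off <- idioMagnitude * sample(c(-1, 1), nIdiosyncratic, replace = TRUE)
    nrm[idio] <- nrm[idio] + off
    tum[idio] <- tum[idio] + off
    sel <- sort(sample.int(nrow(pairsMat), nPlanted))
    sgn <- sample(c(-1, 1), nPlanted, replace = TRUE)
    pe <- pairsMat[sel, , drop = FALSE]
    tum[pe[, 1]] <- tum[pe[, 1]] + sgn * disp
    tum[pe[, 2]] <- tum[pe[, 2]] - sgn * disp
    pid <- sprintf("patient%02d", p)
    pairsList[[p]] <- patientPair(pid, nrm, tum)
    plantedEdges[[p]] <- pe
    plantedDrivers[[p]] <- plantedCover(pe)
  }
  names(pairsList) <- names(plantedEdges) <- names(plantedDrivers) <-
    vapply(pairsList, function(x) x@patientId, "")
  new("PlantedCohort", network = net, refExpr = refExpr,
      pairs = pairsList, plantedEdges = plantedEdges,
      plantedDrivers = plantedDrivers,
      params = list(nRef = nRef, nPatients = nPatients,
                    nPlanted = nPlanted, effect = effect, seed = seed,
                    rho0 = rho0, sharedFraction = sharedFraction,
                    nIdiosyncratic = nIdiosyncratic,
                    idioMagnitude = idioMagnitude,
                    displacement = disp))
}

# exact minimum cover of a planted subgraph, by enumeration per connected
# component (components are tiny; the brute-force guard applies per
# component)
plantedCover <- function(edges) {
  if (nrow(edges) == 0) return(character(0))
  sub <- geneNetwork(edges)
  g <- asIgraph(sub)
  cmp <- igraph::components(g)
  out <- character(0)
  for (ci in seq_len(cmp$no)) {
    vs <- names(cmp$membership)[cmp$membership == ci]
    if (length(vs) < 2) next
    keep <- edges[, 1] %in% vs & edges[, 2] %in% vs
    out <- c(out, bruteForceCover(geneNetwork(edges[keep, , drop = FALSE]))$witness)
  }
  sort(out)
}

#' Write a cohort's parameter and ground-truth manifest as JSON
#'
#' @param cohort a \linkS4class{PlantedCohort}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeCohortManifest <- function(cohort, path) {
  manifest <- list(
    params = cohort@params,
    patients = names(cohort@pairs),
    plantedEdges = lapply(cohort@plantedEdges, function(e)
      paste(e[, 1], e[, 2], sep = "|")),
    plantedDrivers = cohort@plantedDrivers)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
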
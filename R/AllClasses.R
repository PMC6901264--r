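#' @import methods
#' @importFrom stats cor pnorm quantile sd p.adjust rnorm runif rbinom setNames
#' @importFrom utils read.table write.table combn head
#' @useDynLib netDrivers, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Undirected gene interaction network
#'
#' A simple undirected graph over gene symbols: the reference interaction map
#' that all constructed per-patient networks are filtered against, and the
#' container for the per-patient networks themselves.
#'
#' @slot nodes character vector of gene symbols (unique, non-empty).
#' @slot edges two-column character matrix; each row is an unordered gene
#'   pair stored in sorted order, rows unique, no self-loops, endpoints all
#'   present in \code{nodes}.
#'
#' @examples
#' net <- geneNetwork(data.frame(a = c("A", "B"), b = c("B", "C")))
#' networkNodes(net)
#' networkEdges(net)
#' @export
setClass("GeneNetwork",
  representation(nodes = "character", edges = "matrix"))

setValidity("GeneNetwork", function(object) {
  e <- object@edges
  n <- object@nodes
  msg <- character(0)
  if (anyDuplicated(n)) msg <- c(msg, "duplicate node symbols")
  if (any(!nzchar(n))) msg <- c(msg, "empty node symbols")
  if (ncol(e) != 2 && length(e) > 0)
    msg <- c(msg, "edges must be a two-column matrix")
  if (nrow(e) > 0) {
    if (!is.character(e)) msg <- c(msg, "edges must be character")
    if (any(e[, 1] == e[, 2])) msg <- c(msg, "self-loops present")
    if (any(e[, 1] > e[, 2])) msg <- c(msg, "edge pairs must be stored sorted")
    key <- paste(e[, 1], e[, 2], sep = "\r")
    if (anyDuplicated(key)) msg <- c(msg, "duplicate edges")
    if (!all(c(e) %in% n)) msg <- c(msg, "edge endpoint not among nodes")
  }
  if (length(msg)) msg else TRUE
})

#' Per-patient state transition network
#'
#' A \linkS4class{GeneNetwork} holding the edges whose normal/tumor
#' co-expression changed significantly for one patient, together with the
#' per-edge evidence that put each edge there.
#'
#' @slot patientId single patient identifier.
#' @slot method one of \code{"paired_ssn"}, \code{"ssn"}, \code{"lioness"}.
#' @slot edgeInfo data.frame with one row per edge: the tumor/normal
#'   p-values (paired_ssn, ssn) or the interpolated edge weight (lioness).
#' @export
setClass("StateTransitionNetwork",
  contains = "GeneNetwork",
  representation(patientId = "character", method = "character",
                 edgeInfo = "data.frame"))

setValidity("StateTransitionNetwork", function(object) {
  msg <- character(0)
  if (length(object@patientId) != 1) msg <- c(msg, "patientId must be length 1")
  if (!object@method %in% c("paired_ssn", "ssn", "lioness"))
    msg <- c(msg, "method must be paired_ssn, ssn or lioness")
  if (nrow(object@edgeInfo) != nrow(object@edges))
    msg <- c(msg, "edgeInfo must have one row per edge")
  if (length(msg)) msg else TRUE
})

#' Paired normal/tumor expression of one patient
#'
#' @slot patientId single patient identifier.
#' @slot normal named numeric vector, one expression value per gene.
#' @slot tumor named numeric vector over the same genes.
#' @export
setClass("PatientPair",
  representation(patientId = "character", normal = "numeric",
                 tumor = "numeric"))

setValidity("PatientPair", function(object) {
  msg <- character(0)
  if (length(object@patientId) != 1) msg <- c(msg, "patientId must be length 1")
  if (is.null(names(object@normal)) || is.null(names(object@tumor)))
    msg <- c(msg, "normal and tumor vectors must be named by gene")
  else if (!identical(sort(names(object@normal)), sort(names(object@tumor))))
    msg <- c(msg, "normal and tumor must cover the same genes")
  if (any(!is.finite(object@normal)) || any(!is.finite(object@tumor)))
    msg <- c(msg, "expression values must be finite")
  if (length(msg)) msg else TRUE
})

#' Minimum personalized driver set of one patient
#'
#' The output of the structural-control step: a minimum node set covering
#' every edge of the patient's state transition network, plus the
#' controllability ratio |drivers| / |connected nodes|.
#'
#' @slot patientId single patient identifier.
#' @slot drivers character vector of driver gene symbols.
#' @slot nConnected number of nodes with degree >= 1.
#' @slot controllability |drivers| / nConnected (NA for an edgeless network).
#' @slot status solver status, \code{"optimal"} or \code{"node_limit"}.
#' @slot objective the ILP objective value (= number of drivers).
#' @export
setClass("DriverResult",
  representation(patientId = "character", drivers = "character",
                 nConnected = "integer", controllability = "numeric",
                 status = "character", objective = "integer"))

setValidity("DriverResult", function(object) {
  msg <- character(0)
  if (length(object@patientId) != 1) msg <- c(msg, "patientId must be length 1")
  if (length(object@objective) != 1 ||
      object@objective != length(object@drivers))
    msg <- c(msg, "objective must equal the driver count")
  if (!is.na(object@controllability) &&
      (object@controllability < 0 || object@controllability > 1))
    msg <- c(msg, "controllability must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Discrete power-law fit of a degree sequence
#'
#' Maximum-likelihood degree exponent with lower cutoff chosen by
#' Kolmogorov-Smirnov minimization and a semiparametric bootstrap
#' goodness-of-fit p-value.
#'
#' @slot gamma fitted degree exponent (> 1).
#' @slot kmin fitted lower cutoff.
#' @slot ks Kolmogorov-Smirnov distance of the tail fit.
#' @slot p bootstrap goodness-of-fit p-value; the fit is conventionally
#'   called plausible when p > 0.05.
#' @slot nTail number of observations at or above \code{kmin}.
#' @slot bootstrapReps number of bootstrap replicates used.
#' @export
setClass("PowerLawFit",
  representation(gamma = "numeric", kmin = "numeric", ks = "numeric",
                 p = "numeric", nTail = "integer", bootstrapReps = "integer"))

setValidity("PowerLawFit", function(object) {
  msg <- character(0)
  if (object@gamma <= 1) msg <- c(msg, "gamma must exceed 1")
  if (object@ks < 0) msg <- c(msg, "ks must be non-negative")
  if (!is.na(object@p) && (object@p < 0 || object@p > 1))
    msg <- c(msg, "p must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Synthetic paired cohort with planted tumor-specific rewiring
#'
#' A seed-deterministic simulated study: a reference interaction network, a
#' reference expression panel, per-patient paired normal/tumor samples, and
#' the ground truth (which edges were rewired in each tumor, and the minimum
#' cover of each planted subgraph).
#'
#' @slot network the reference \linkS4class{GeneNetwork}.
#' @slot refExpr genes x samples reference expression matrix.
#' @slot pairs list of \linkS4class{PatientPair}.
#' @slot plantedEdges per patient, a two-column character matrix of rewired
#'   edges (subset of the reference edges).
#' @slot plantedDrivers per patient, an exact minimum cover of the planted
#'   subgraph.
#' @slot params list of generator parameters (includes the seed).
#' @export
setClass("PlantedCohort",
  representation(network = "GeneNetwork", refExpr = "matrix",
                 pairs = "list", plantedEdges = "list",
                 plantedDrivers = "list", params = "list"))

setValidity("PlantedCohort", function(object) {
  msg <- character(0)
  if (length(object@pairs) != length(object@plantedEdges) ||
      length(object@pairs) != length(object@plantedDrivers))
    msg <- c(msg, "pairs, plantedEdges and plantedDrivers lengths differ")
  ref <- edgeKeys(object@network@edges)
  for (pe in object@plantedEdges) {
    if (nrow(pe) && !all(edgeKeys(normalizeEdges(pe)) %in% ref)) {
      msg <- c(msg, "planted edge outside the reference network")
      break
    }
  }
  if (length(msg)) msg else TRUE
})
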
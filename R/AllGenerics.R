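#' @rdname GeneNetwork-class
#' @param object,x a \linkS4class{GeneNetwork}
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname GeneNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname DriverResult-class
#' @export
setGeneric("drivers", function(x) standardGeneric("drivers"))

#' Controllability of a network under a driver set
#'
#' The fraction |D| / |V| where D is the driver set and |V| counts the
#' connected nodes (degree >= 1) of the network; the smaller the value, the
#' easier the network is to control.
#'
#' @param x a \linkS4class{GeneNetwork} (with \code{drivers} given) or a
#'   \linkS4class{DriverResult}.
#' @param drivers character vector of driver genes, a subset of the nodes.
#' @return a single numeric ratio in (0, 1].
#' @examples
#' star <- geneNetwork(data.frame(a = "HUB", b = paste0("L", 1:4)))
#' controllability(star, "HUB")  # 1/5
#' @export
setGeneric("controllability",
           function(x, drivers) standardGeneric("controllability"))

setMethod("networkNodes", "GeneNetwork", function(x) x@nodes)
setMethod("networkEdges", "GeneNetwork", function(x) x@edges)
setMethod("drivers", "DriverResult", function(x) x@drivers)

#' @rdname controllability
setMethod("controllability", signature("DriverResult", "missing"),
          function(x, drivers) x@controllability)

setMethod("show", "GeneNetwork", function(object) {
  cat(sprintf("%s with %d nodes and %d edges\n",
              class(object), length(object@nodes), nrow(object@edges)))
})

setMethod("show", "StateTransitionNetwork", function(object) {
  cat(sprintf(
    "StateTransitionNetwork [%s] for patient %s: %d nodes, %d edges\n",
    object@method, object@patientId, length(object@nodes),
    nrow(object@edges)))
})

setMethod("show", "PatientPair", function(object) {
  cat(sprintf("PatientPair %s over %d genes\n",
              object@patientId, length(object@normal)))
})

setMethod("show", "DriverResult", function(object) {
  cat(sprintf(
    "DriverResult for patient %s: %d drivers / %d connected nodes (controllability %.3f, %s)\n",
    object@patientId, length(object@drivers), object@nConnected,
    object@controllability, object@status))
})

setMethod("show", "PowerLawFit", function(object) {
  cat(sprintf(
    "PowerLawFit: gamma = %.3f, kmin = %g, KS = %.4f, bootstrap p = %.3f (n_tail = %d, %d reps)\n",
    object@gamma, object@kmin, object@ks, object@p, object@nTail,
    object@bootstrapReps))
})

setMethod("show", "PlantedCohort", function(object) {
  cat(sprintf(
    "PlantedCohort: %d patients, %d reference samples, network with %d nodes / %d edges\n",
    length(object@pairs), ncol(object@refExpr),
    length(object@network@nodes), nrow(object@network@edges)))
})
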
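# Structural control of undirected networks. Treating every undirected
# edge as a 2-cycle (feedback loop), a node set that intersects all loops
# — and can therefore steer the system between attractors — is a set
# covering every edge. Finding the minimum such set is posed on a
# node-edge bipartite graph as the 0/1 program
#
#   min sum_v y_v   s.t.  y_a + y_b >= 1 for every edge {a, b},
#
# i.e. a minimum vertex cover, solved exactly by branch and bound with
# reductions (in src/mvc.cpp).

#' Bipartite reformulation of the edge-cover program
#'
#' The top side holds the nodes of the graph, the bottom side its edges;
#' each bottom node links to its two endpoints. Selecting a minimum top-side
#' set that covers every bottom node is the driver-node program.
#'
#' @param net a \linkS4class{GeneNetwork}.
#' @return list with \code{top} (node symbols), \code{bottom} (edge labels
#'   "a|b"), and \code{links}, a two-column matrix (node, edge label) with
#'   exactly two rows per bottom node.
#' @examples
#' path <- geneNetwork(data.frame(a = c("A", "B"), b = c("B", "C")))
#' str(buildBipartite(path))
#' @export
buildBipartite <- function(net) {
  e <- net@edges
  lab <- paste(e[, 1], e[, 2], sep = "|")
  list(top = net@nodes,
       bottom = lab,
       links = cbind(node = c(e[, 1], e[, 2]), edge = c(lab, lab)))
}

#' Minimum personalized driver set by exact branch and bound
#'
#' Computes a minimum-cardinality node set covering every edge of the
#' network (solved per connected component and unioned), the number of
#' connected nodes, and the controllability ratio. Branching is ordered:
#' vertices are indexed in lexicographic symbol order and explored
#' deterministically, so the returned optimum is reproducible.
#'
#' @param net a \linkS4class{GeneNetwork} (e.g. a per-patient
#'   \linkS4class{StateTransitionNetwork}).
#' @param patientId identifier for the result; defaults to the network's
#'   own patient id when it has one.
#' @param timeLimit wall-clock budget in seconds (default 600).
#' @param nodeLimit branch-and-bound node budget (default 1e9).
#' @param onTimeout \code{"error"} (default): an exhausted budget raises an
#'   error whose condition carries the best incumbent found;
#'   \code{"incumbent"}: return the incumbent with status
#'   \code{"node_limit"}.
#' @return a \linkS4class{DriverResult}.
#' @examples
#' path <- geneNetwork(data.frame(a = c("A", "B"), b = c("B", "C")))
#' drivers(ncuaDrivers(path))   # "B"
#' @export
ncuaDrivers <- function(net, patientId = NULL, timeLimit = 600,
                        nodeLimit = 1e9, onTimeout = c("error", "incumbent")) {
  onTimeout <- match.arg(onTimeout)
  if (is.null(patientId))
    patientId <- if (is(net, "StateTransitionNetwork")) net@patientId else "network"
  nodes <- sort(net@nodes)
  e <- net@edges
  deg <- nodeDegrees(net)
  nConnected <- sum(deg > 0)
  if (nrow(e) == 0)
    return(new("DriverResult", patientId = as.character(patientId),
               drivers = character(0), nConnected = 0L,
               controllability = NA_real_, status = "optimal",
               objective = 0L))
  ia <- match(e[, 1], nodes) - 1L
  ib <- match(e[, 2], nodes) - 1L
  r <- mvc_solve_cpp(cbind(ia, ib), length(nodes), nodeLimit, timeLimit)
  drv <- sort(nodes[r$cover + 1L])
  status <- if (r$optimal) "optimal" else "node_limit"
  res <- new("DriverResult", patientId = as.character(patientId),
             drivers = drv, nConnected = as.integer(nConnected),
             controllability = length(drv) / nConnected,
             status = status, objective = as.integer(r$size))
  if (!r$optimal && onTimeout == "error") {
    cond <- structure(
      class = c("ncuaTimeout", "error", "condition"),
      list(message = sprintf(
        "solver budget exhausted (%g nodes); best incumbent has %d drivers",
        r$nodes, r$size),
        call = sys.call(), incumbent = res))
    stop(cond)
  }
  res
}

#' Exact minimum cover by subset enumeration (oracle)
#'
#' Enumerates node subsets in order of cardinality and returns the first
#' that covers every edge. Exponential; guarded to 20 nodes. This is the
#' independent correctness oracle for \code{\link{ncuaDrivers}}.
#'
#' @param net a \linkS4class{GeneNetwork} with at most 20 nodes.
#' @return list with \code{size} and \code{witness} (one minimum cover,
#'   the lexicographically first at that cardinality).
#' @export
bruteForceCover <- function(net) {
  nodes <- sort(net@nodes)
  if (length(nodes) > 20) stop("bruteForceCover is limited to 20 nodes")
  e <- net@edges
  if (nrow(e) == 0) return(list(size = 0L, witness = character(0)))
  for (k in seq(0, length(nodes))) {
    sets <- combn(nodes, k, simplify = FALSE)
    for (s in sets)
      if (all(e[, 1] %in% s | e[, 2] %in% s))
        return(list(size = as.integer(k), witness = s))
  }
}

#' @rdname controllability
setMethod("controllability", signature("GeneNetwork", "character"),
  function(x, drivers) {
    if (!all(drivers %in% x@nodes))
      stop("drivers must be a subset of the network's nodes")
    if (nrow(x@edges) == 0)
      stop("controllability is undefined for an edgeless network")
    nConnected <- sum(nodeDegrees(x) > 0)
    length(drivers) / nConnected
  })
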
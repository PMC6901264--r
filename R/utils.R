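# Internal edge bookkeeping. Edges are two-column character matrices with
# each row sorted so that A-B and B-A collapse to one key.

normalizeEdges <- function(e) {
  if (is.data.frame(e)) e <- as.matrix(e)
  if (length(e) == 0) return(matrix(character(0), 0, 2))
  storage.mode(e) <- "character"
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  dimnames(e) <- NULL
  e
}

edgeKeys <- function(e) {
  if (nrow(e) == 0) return(character(0))
  paste(e[, 1], e[, 2], sep = "\r")
}

#' Construct a gene interaction network
#'
#' Builds a \linkS4class{GeneNetwork} from an edge table, dropping
#' self-loops and collapsing duplicated unordered pairs.
#'
#' @param edges two-column data.frame or character matrix of gene pairs;
#'   extra columns (scores, interaction types) are ignored.
#' @param nodes optional character vector of nodes; defaults to the genes
#'   occurring in \code{edges}. Extra isolated nodes may be supplied.
#' @return a \linkS4class{GeneNetwork}.
#' @examples
#' geneNetwork(data.frame(a = c("A", "B", "C"), b = c("B", "C", "A")))
#' @export
geneNetwork <- function(edges, nodes = NULL) {
  e <- as.matrix(edges)[, 1:2, drop = FALSE]
  storage.mode(e) <- "character"
  e[] <- trimws(e)
  e <- e[nzchar(e[, 1]) & nzchar(e[, 2]), , drop = FALSE]
  nSelf <- sum(e[, 1] == e[, 2])
  if (nSelf > 0) {
    message(sprintf("dropping %d self-loop(s)", nSelf))
    e <- e[e[, 1] != e[, 2], , drop = FALSE]
  }
  e <- normalizeEdges(e)
  e <- e[!duplicated(edgeKeys(e)), , drop = FALSE]
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  nd <- sort(unique(c(c(e), trimws(nodes))))
  nd <- nd[nzchar(nd)]
  new("GeneNetwork", nodes = nd, edges = e)
}

# igraph view of a GeneNetwork (vertices keep gene symbols)
asIgraph <- function(net) {
  igraph::graph_from_data_frame(
    as.data.frame(net@edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = net@nodes, stringsAsFactors = FALSE))
}

#' Degree of every node
#'
#' @param net a \linkS4class{GeneNetwork}.
#' @return named integer vector over all nodes (isolated nodes have 0).
#' @export
nodeDegrees <- function(net) {
  d <- stats::setNames(integer(length(net@nodes)), net@nodes)
  if (nrow(net@edges)) {
    t1 <- table(net@edges[, 1])
    t2 <- table(net@edges[, 2])
    d[names(t1)] <- d[names(t1)] + as.integer(t1)
    d[names(t2)] <- d[names(t2)] + as.integer(t2)
  }
  d
}

#' Restrict a network to a gene universe
#'
#' Keeps only edges whose both endpoints are in \code{genes}; the fraction
#' of dropped edges is reported, since gene-identifier mismatch between an
#' expression matrix and an interaction network is the common cause.
#'
#' @param net a \linkS4class{GeneNetwork}.
#' @param genes character vector of gene symbols to keep.
#' @param quiet suppress the dropped-edge message.
#' @return a \linkS4class{GeneNetwork} over the intersection.
#' @export
restrictNetwork <- function(net, genes, quiet = FALSE) {
  e <- net@edges
  keep <- e[, 1] %in% genes & e[, 2] %in% genes
  if (!quiet && any(!keep))
    message(sprintf("restrictNetwork: dropped %d/%d edges (%.1f%%) outside the gene universe",
                    sum(!keep), nrow(e), 100 * mean(!keep)))
  new("GeneNetwork",
      nodes = intersect(net@nodes, genes),
      edges = e[keep, , drop = FALSE])
}

# derive a stream of distinct 32-bit sub-seeds from one user seed
subSeeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
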
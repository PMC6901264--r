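#' Read an undirected gene interaction network from an edge-list file
#'
#' Expects a text file with at least two columns of gene symbols per line
#' (tab- or whitespace-delimited). Edges are undirected: \code{A B} and
#' \code{B A} denote the same edge and are collapsed. Self-loops are dropped
#' with a message. Any extra columns (scores, interaction types) are
#' ignored. Gene symbols are matched case-sensitively after whitespace
#' stripping; silent case-folding would create false joins.
#'
#' @param path path to the edge-list file.
#' @param dedupe collapse duplicated unordered pairs (default TRUE; with
#'   FALSE a duplicated pair is an error).
#' @param header does the file carry a header line to skip?
#' @param sep field separator: \code{""} (any whitespace, default) or
#'   \code{"\t"}.
#' @return a \linkS4class{GeneNetwork}.
#' @examples
#' f <- tempfile()
#' writeLines(c("A\tB", "B\tC", "C\tA"), f)
#' readNetwork(f)
#' @export
readNetwork <- function(path, dedupe = TRUE, header = FALSE, sep = "") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (header) lines <- lines[-1]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty network file: ", path)
  splitter <- if (identical(sep, "")) "[ \t]+" else sep
  parts <- strsplit(trimws(lines), splitter)
  bad <- which(vapply(parts, length, 1L) < 2)
  if (length(bad))
    stop(sprintf("malformed line %d in %s: fewer than two fields",
                 bad[1] + header, path))
  e <- cbind(vapply(parts, `[[`, "", 1), vapply(parts, `[[`, "", 2))
  if (!dedupe) {
    key <- edgeKeys(normalizeEdges(e))
    if (anyDuplicated(key))
      stop("duplicated edge with dedupe = FALSE: ",
           sub("\r", "-", key[duplicated(key)][1]))
  }
  geneNetwork(e)
}

#' Write a network as a sorted two-column edge list
#'
#' Edges are emitted in lexicographic pair order, tab-delimited, so output
#' is diffable and bit-stable; reading the file back reproduces the network.
#'
#' @param net a \linkS4class{GeneNetwork}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeNetwork <- function(net, path) {
  e <- net@edges
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  write.table(e, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a genes-by-samples expression matrix
#'
#' Expects a tab-delimited file whose first column holds gene symbols and
#' whose header row holds sample identifiers. Every cell must be numeric
#' and finite; a missing or non-numeric value is an error naming the
#' offending gene and sample, because a silently dropped value would bias
#' every downstream correlation.
#'
#' @param path path to the TSV file.
#' @return a numeric matrix with genes as rownames, samples as colnames,
#'   in file order.
#' @export
readExpression <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "")
  if (ncol(df) < 2) stop("expression file needs a gene column plus samples")
  genes <- trimws(df[[1]])
  if (anyDuplicated(genes))
    stop("duplicated gene row: ", genes[duplicated(genes)][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  if (any(!is.finite(m))) {
    idx <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric or non-finite value at gene %s, sample %s",
                 genes[idx[1]], colnames(m)[idx[2]]))
  }
  rownames(m) <- genes
  m
}

#' Write an expression matrix as TSV
#'
#' @param m genes-by-samples numeric matrix.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeExpression <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a plain list or a GMT file
#'
#' \code{format = "list"} reads one gene symbol per line into a single set
#' named after the file stem (the shape of curated driver-gene lists such
#' as the Cancer Census Genes). \code{format = "gmt"} reads the standard
#' tab-delimited GMT layout: set name, description, then member genes.
#'
#' @param path input file.
#' @param format \code{"list"} or \code{"gmt"}.
#' @return a named list of character vectors; every set non-empty, names
#'   unique.
#' @export
readGeneSets <- function(path, format = c("list", "gmt")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "list") {
    genes <- unique(trimws(lines))
    if (length(genes) == 0) stop("empty gene set in ", path)
    sets <- list(genes)
    names(sets) <- tools::file_path_sans_ext(basename(path))
  } else {
    parts <- strsplit(lines, "\t")
    short <- which(vapply(parts, length, 1L) < 3)
    if (length(short))
      stop(sprintf("GMT line %d has fewer than 3 fields", short[1]))
    nms <- vapply(parts, `[[`, "", 1)
    if (anyDuplicated(nms)) stop("duplicated set name: ",
                                 nms[duplicated(nms)][1])
    sets <- lapply(parts, function(p) unique(trimws(p[-(1:2)])))
    sets <- lapply(sets, function(s) s[nzchar(s)])
    names(sets) <- nms
    if (any(lengths(sets) == 0))
      stop("empty gene set: ", nms[lengths(sets) == 0][1])
  }
  sets
}

#' Write a state transition network with its per-edge evidence
#'
#' @param stn a \linkS4class{StateTransitionNetwork}.
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
writeStateNetwork <- function(stn, path) {
  df <- data.frame(gene_a = stn@edges[, 1], gene_b = stn@edges[, 2],
                   stn@edgeInfo, check.names = FALSE)
  ord <- order(df$gene_a, df$gene_b)
  write.table(df[ord, , drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
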
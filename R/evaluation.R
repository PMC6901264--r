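# Baseline gene selectors and evaluation statistics: hub selection,
# differential-expression selectors, F-measure against gold-standard driver
# lists, hypergeometric enrichment, cohort driver-frequency profiling and
# per-gene sub-network summaries.

#' Hub genes of a network
#'
#' Genes whose degree strictly exceeds mean(U) + 2 sd(U), with U the degree
#' distribution over all nodes (sample standard deviation). The classical
#' "hubs as drivers" baseline.
#'
#' @param net a \linkS4class{GeneNetwork}.
#' @return character vector of hub genes (possibly empty; a regular graph
#'   has sd = 0 and, by the strict inequality, no hubs).
#' @examples
#' star <- geneNetwork(data.frame(a = "HUB", b = paste0("L", 1:9)))
#' hubGenes(star)   # "HUB"
#' @export
hubGenes <- function(net) {
  deg <- nodeDegrees(net)
  if (sum(deg > 0) < 2) stop("need at least 2 connected nodes")
  w <- mean(deg) + 2 * sd(deg)
  sort(names(deg)[deg > w])
}

#' Differential-expression gene selectors
#'
#' The three expression-only baselines: absolute log2 fold-change between
#' the patient's tumor and normal sample; a per-gene z-test of the tumor
#' value against the reference panel's per-gene distribution; and the same
#' test with Benjamini-Hochberg adjustment.
#'
#' @param normal,tumor named numeric expression vectors of one patient.
#' @param mode \code{"foldchange"} (needs strictly positive expression;
#'   selects |log2(tumor/normal)| > threshold), \code{"pvalue"} (two-sided
#'   normal p < threshold of the tumor value against the reference
#'   per-gene mean/sd), or \code{"fdr"} (BH-adjusted p < threshold).
#' @param refs reference expression matrix (required for pvalue/fdr, >= 3
#'   columns).
#' @param threshold default 1 for foldchange (i.e. two-fold), 0.05
#'   otherwise.
#' @return character vector of selected genes; genes skipped in foldchange
#'   mode for non-positive values are counted in attribute
#'   \code{"skipped"}.
#' @export
degSelect <- function(normal, tumor, mode = c("foldchange", "pvalue", "fdr"),
                      refs = NULL, threshold = NULL) {
  mode <- match.arg(mode)
  tumor <- tumor[names(normal)]
  if (mode == "foldchange") {
    threshold <- threshold %||% 1
    usable <- normal > 0 & tumor > 0
    lfc <- log2(tumor[usable] / normal[usable])
    out <- sort(names(lfc)[abs(lfc) > threshold])
    attr(out, "skipped") <- sum(!usable)
    return(out)
  }
  threshold <- threshold %||% 0.05
  if (is.null(refs) || ncol(refs) < 3)
    stop("pvalue/fdr modes need a reference matrix with >= 3 columns")
  genes <- intersect(names(tumor), rownames(refs))
  mu <- rowMeans(refs[genes, , drop = FALSE])
  sdv <- apply(refs[genes, , drop = FALSE], 1, sd)
  z <- (tumor[genes] - mu) / sdv
  p <- 2 * pnorm(-abs(z))
  if (mode == "fdr") p <- p.adjust(p, method = "BH")
  sort(genes[p < threshold])
}

#' Precision, recall and F-measure against a gold-standard list
#'
#' Recall is computed against the part of the gold standard that lies in
#' the background universe (the genes the method could possibly return,
#' i.e. the reference network's genes); a gold gene outside the universe
#' cannot be found by construction and would deflate recall artificially.
#'
#' @param predicted predicted gene set (subset of background).
#' @param gold gold-standard gene set.
#' @param background the gene universe.
#' @return named numeric vector with \code{precision}, \code{recall},
#'   \code{F}; F = 0 when precision + recall = 0, precision = 0 for an
#'   empty prediction.
#' @examples
#' fMeasure(c("A", "B"), c("B", "C"), LETTERS[1:10])
#' @export
fMeasure <- function(predicted, gold, background) {
  goldIn <- intersect(gold, background)
  if (length(goldIn) == 0)
    stop("gold standard does not intersect the background universe")
  tp <- length(intersect(predicted, goldIn))
  P <- if (length(predicted)) tp / length(predicted) else 0
  R <- tp / length(goldIn)
  Fv <- if (P + R > 0) 2 * P * R / (P + R) else 0
  c(precision = P, recall = R, F = Fv)
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability P(X >= k) of drawing k or more gold genes when n
#' genes are drawn without replacement from a universe of N genes
#' containing K gold genes; computed in log space for stability.
#'
#' @param N background universe size.
#' @param K gold (or pathway) set size within the background.
#' @param n predicted set size.
#' @param k overlap between predicted and gold.
#' @return list with the inputs and \code{p}; p = 1 when k = 0.
#' @examples
#' hypergeomEnrichment(10, 5, 2, 2)$p   # C(5,2)/C(10,2) = 10/45
#' @export
hypergeomEnrichment <- function(N, K, n, k) {
  if (K > N || n > N || k > min(n, K) || k < 0)
    stop("need 0 <= k <= min(n, K) and K, n <= N")
  # sum C(K,i) C(N-K, n-i) / C(N,n) for i = k..min(n,K), in log space
  i <- seq(k, min(n, K))
  logTerms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(logTerms)
  p <- exp(m) * sum(exp(logTerms - m))
  list(N = N, K = K, n = n, k = k, p = min(p, 1))
}

#' Gene-set enrichment of a predicted gene set
#'
#' Applies \code{\link{hypergeomEnrichment}} to every set of a collection
#' (e.g. pathways from a GMT file) against one predicted gene set.
#'
#' @param predicted predicted gene set.
#' @param collection named list of gene sets.
#' @param background the gene universe (N); sets and predictions are
#'   intersected with it.
#' @return data.frame with one row per set: set name, K, n, k, p and
#'   BH-adjusted p.
#' @export
enrichGeneSets <- function(predicted, collection, background) {
  predicted <- intersect(predicted, background)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(collection[[nm]], background)
    k <- length(intersect(predicted, set))
    p <- if (length(set) == 0) 1 else
      hypergeomEnrichment(length(background), length(set),
                          length(predicted), k)$p
    data.frame(set = nm, K = length(set), n = length(predicted), k = k,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out
}

#' Driver-gene frequency profile of a cohort
#'
#' For every gene, the fraction of patients whose personalized driver set
#' contains it, with the conventional frequency classes: high (f > 0.6),
#' medium (0.3 < f <= 0.6), low (f <= 0.3), and the cohort-driver flag
#' (f > 0.8) used to promote personalized calls to cohort-level drivers.
#'
#' @param perPatientDrivers named list: patient id -> character vector of
#'   driver genes (or a list of \linkS4class{DriverResult}).
#' @return data.frame with columns \code{gene}, \code{frequency},
#'   \code{class} and \code{cohortDriver}, sorted by decreasing frequency.
#' @export
driverFrequency <- function(perPatientDrivers) {
  if (length(perPatientDrivers) == 0) stop("need at least one patient")
  sets <- lapply(perPatientDrivers, function(x)
    if (is(x, "DriverResult")) x@drivers else x)
  nPat <- length(sets)
  tab <- table(unlist(lapply(sets, unique)))
  f <- as.numeric(tab) / nPat
  cls <- ifelse(f > 0.6, "high", ifelse(f > 0.3, "medium", "low"))
  out <- data.frame(gene = names(tab), frequency = f, class = cls,
                    cohortDriver = f > 0.8, stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene summary across the cohort's personalized sub-networks
#'
#' For one gene: its driver frequency, its mean degree across the patient
#' networks containing it, the mean absolute log2 fold-change between each
#' patient's tumor and normal value, and (when a binary mutation matrix is
#' supplied) the fraction of patients mutated.
#'
#' @param gene gene symbol.
#' @param networks named list of \linkS4class{StateTransitionNetwork}.
#' @param pairs named list of \linkS4class{PatientPair} (same patients).
#' @param driverSets named list of per-patient driver gene vectors (or
#'   \linkS4class{DriverResult}); optional, driver frequency is NA without.
#' @param mutations optional genes x patients binary matrix.
#' @return one-row data.frame: gene, driver_frequency, mean_abs_log2fc,
#'   mean_degree, mutation_frequency.
#' @export
geneSubnetworkStats <- function(gene, networks, pairs, driverSets = NULL,
                                mutations = NULL) {
  degs <- vapply(networks, function(nw)
    if (gene %in% nw@nodes) nodeDegrees(nw)[[gene]] else NA_integer_,
    1L)
  if (all(is.na(degs) | degs == 0))
    stop("gene absent from every patient network: ", gene)
  lfc <- vapply(pairs, function(pp) {
    tv <- pp@tumor[[gene]]; nv <- pp@normal[[gene]]
    if (is.null(tv) || is.null(nv) || tv <= 0 || nv <= 0) return(NA_real_)
    abs(log2(tv / nv))
  }, 1)
  drvFreq <- if (is.null(driverSets)) NA_real_ else {
    sets <- lapply(driverSets, function(x)
      if (is(x, "DriverResult")) x@drivers else x)
    mean(vapply(sets, function(s) gene %in% s, TRUE))
  }
  mutFreq <- if (is.null(mutations) || !gene %in% rownames(mutations))
    NA_real_ else mean(mutations[gene, ] != 0)
  data.frame(gene = gene,
             driver_frequency = drvFreq,
             mean_abs_log2fc = mean(lfc, na.rm = TRUE),
             mean_degree = mean(degs[!is.na(degs) & degs > 0]),
             mutation_frequency = mutFreq,
             stringsAsFactors = FALSE)
}
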
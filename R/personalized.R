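# Per-patient state transition networks, three ways: the paired construction
# (tumor XOR normal significance), the plain single-sample tumor network,
# and the LIONESS linear interpolation.

#' Create a paired normal/tumor patient record
#'
#' @param patientId patient identifier.
#' @param normal,tumor named numeric expression vectors over the same genes.
#' @return a \linkS4class{PatientPair}.
#' @export
patientPair <- function(patientId, normal, tumor) {
  new("PatientPair", patientId = as.character(patientId),
      normal = normal, tumor = tumor[names(normal)])
}

#' Paired single-sample state transition network
#'
#' Builds the patient's state transition network: an edge of the reference
#' network is kept iff its correlation change is significant in exactly one
#' of the patient's two samples — p < alpha in the tumor sample but not in
#' the normal sample, or vice versa (XOR). Edges significant in both
#' samples reflect patient-specific but disease-unrelated co-expression
#' (shared germline and environment) and are removed; this is what cuts the
#' false-positive calls of the plain single-sample construction.
#'
#' @param exprRef genes-by-samples reference expression matrix (all normal
#'   samples of the cohort, in the standard design).
#' @param pair a \linkS4class{PatientPair}.
#' @param net the reference \linkS4class{GeneNetwork}; only its edges are
#'   tested.
#' @param alpha per-edge significance level (default 0.05).
#' @return a \linkS4class{StateTransitionNetwork} with per-edge
#'   \code{p_tumor} and \code{p_normal} in \code{edgeInfo}.
#' @export
pairedSSN <- function(exprRef, pair, net, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  stT <- edgeStats(exprRef, pair@tumor, net)
  stN <- edgeStats(exprRef, pair@normal, net)
  # align on the edge set defined for both samples
  kT <- paste(stT$gene_a, stT$gene_b, sep = "\r")
  kN <- paste(stN$gene_a, stN$gene_b, sep = "\r")
  common <- intersect(kT, kN)
  stT <- stT[match(common, kT), , drop = FALSE]
  stN <- stN[match(common, kN), , drop = FALSE]
  keep <- xor(stT$p < alpha, stN$p < alpha)
  buildSTN(pair@patientId, "paired_ssn",
           stT[keep, c("gene_a", "gene_b"), drop = FALSE],
           data.frame(p_tumor = stT$p[keep], p_normal = stN$p[keep]),
           net)
}

#' Single-sample (tumor-only) state transition network
#'
#' The plain single-sample baseline: the tumor sample's significant-edge
#' network is taken directly as the patient's state transition network.
#'
#' @param exprRef reference expression matrix.
#' @param tumor named numeric vector (the tumor sample), or a
#'   \linkS4class{PatientPair} whose tumor slot is used.
#' @param net the reference \linkS4class{GeneNetwork}.
#' @param alpha per-edge significance level.
#' @param patientId identifier for the output network.
#' @return a \linkS4class{StateTransitionNetwork} with per-edge
#'   \code{p_tumor}.
#' @export
ssnNetwork <- function(exprRef, tumor, net, alpha = 0.05,
                       patientId = "sample") {
  if (alpha < 0 || alpha >= 1) stop("alpha must lie in [0, 1)")
  if (is(tumor, "PatientPair")) {
    patientId <- tumor@patientId
    tumor <- tumor@tumor
  }
  st <- edgeStats(exprRef, tumor, net)
  keep <- st$p < alpha
  buildSTN(patientId, "ssn",
           st[keep, c("gene_a", "gene_b"), drop = FALSE],
           data.frame(p_tumor = st$p[keep]),
           net)
}

#' LIONESS single-sample network
#'
#' Linear interpolation to obtain a network estimate for one sample: for
#' every reference-network edge, with e_all the Pearson correlation over
#' all Ns tumor samples and e_minus the correlation with sample q left out,
#' the sample-specific edge weight is
#'   e_q = Ns (e_all - e_minus) + e_minus.
#' Edges are kept when |e_q| strictly exceeds w = mean(S) + 2 sd(S), where
#' S is the distribution of |e_q| over the reference-network edges of this
#' sample (sample standard deviation, n-1 denominator). e_q is an
#' interpolation estimate, not a correlation, and may lie outside [-1, 1];
#' it is used as-is.
#'
#' @param exprTumors genes-by-samples matrix of all tumor samples (Ns >= 3).
#' @param q column name or index of the sample of interest.
#' @param net the reference \linkS4class{GeneNetwork}.
#' @return a \linkS4class{StateTransitionNetwork} with per-edge
#'   \code{weight} (= e_q).
#' @export
lionessNetwork <- function(exprTumors, q, net) {
  Ns <- ncol(exprTumors)
  if (Ns < 3) stop("need at least 3 tumor samples")
  if (is.character(q)) {
    q <- match(q, colnames(exprTumors))
    if (is.na(q)) stop("sample not found among tumor columns")
  }
  e <- net@edges
  genes <- unique(c(e))
  miss <- setdiff(genes, rownames(exprTumors))
  if (length(miss)) stop("gene absent from tumor expression: ", miss[1])
  X <- exprTumors[genes, , drop = FALSE]
  ia <- match(e[, 1], genes); ib <- match(e[, 2], genes)
  eAll <- pairwisePCC(X, ia, ib)
  eMinus <- pairwisePCC(X[, -q, drop = FALSE], ia, ib)
  eq <- Ns * (eAll - eMinus) + eMinus
  ok <- is.finite(eq)
  nUndef <- sum(!ok)
  if (nUndef > 0)
    message(sprintf("lionessNetwork: %d edge(s) undefined, dropped", nUndef))
  aeq <- abs(eq[ok])
  w <- mean(aeq) + 2 * (if (length(aeq) > 1) sd(aeq) else 0)
  keep <- which(ok)[aeq > w]
  buildSTN(colnames(exprTumors)[q] %||% as.character(q), "lioness",
           e[keep, , drop = FALSE],
           data.frame(weight = eq[keep]),
           net)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# PCC for selected row pairs of a matrix (two-pass, vectorized)
pairwisePCC <- function(X, ia, ib) {
  n <- ncol(X)
  sx <- rowSums(X); sxx <- rowSums(X^2)
  sxy <- rowSums(X[ia, , drop = FALSE] * X[ib, , drop = FALSE])
  (sxy - sx[ia] * sx[ib] / n) /
    sqrt((sxx[ia] - sx[ia]^2 / n) * (sxx[ib] - sx[ib]^2 / n))
}

buildSTN <- function(patientId, method, edges, info, net) {
  e <- normalizeEdges(as.matrix(edges))
  stopifnot(nrow(e) == nrow(info))
  ord <- order(e[, 1], e[, 2])
  new("StateTransitionNetwork",
      nodes = sort(unique(c(e))),
      edges = e[ord, , drop = FALSE],
      patientId = as.character(patientId),
      method = method,
      edgeInfo = info[ord, , drop = FALSE])
}
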
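# Single-sample differential-correlation statistic.
#
# For an edge (i, j): PCC^n is the Pearson correlation over the n reference
# samples, PCC^{n+1} the correlation after appending the one new sample, and
#
#   Z = |PCC^{n+1} - PCC^n| / ((1 - (PCC^n)^2) / (n - 1))
#
# with a two-sided standard-normal p-value. The denominator is the
# asymptotic standard deviation of the correlation perturbation caused by a
# single appended observation.

# Z and p from the two correlations; the heart of the statistic, kept as a
# separate function so tests can hit it with hand-computed values.
ssnZ <- function(pccRef, pccPert, nRef) {
  delta <- abs(pccPert - pccRef)
  z <- delta * (nRef - 1) / (1 - pccRef^2)
  p <- 2 * pnorm(-z)
  # a zero perturbation must give p = 1 exactly
  list(delta = delta, z = z, p = pmin(p, 1))
}

#' Per-edge single-sample differential-correlation statistics
#'
#' For every edge of the network, computes the reference Pearson correlation
#' over the reference samples, the perturbed correlation after appending the
#' supplied single sample, their absolute difference, the Z-score and its
#' two-sided normal p-value. Edges with an undefined correlation
#' (zero-variance gene in the reference, or |PCC| = 1) are excluded and
#' counted in the \code{"excluded"} attribute.
#'
#' @param exprRef genes-by-samples reference expression matrix with at least
#'   3 columns (all normal samples of the cohort, in the standard design).
#' @param sample named numeric vector: the one new sample, covering every
#'   gene used by \code{edges}.
#' @param edges two-column character matrix (or data.frame) of gene pairs,
#'   or a \linkS4class{GeneNetwork} whose edges are used.
#' @return data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{pcc_ref}, \code{pcc_pert}, \code{delta}, \code{direction}
#'   (sign of pcc_pert - pcc_ref), \code{z}, \code{p}; attributes
#'   \code{n_ref} (reference sample count) and \code{excluded} (edge count
#'   dropped as undefined).
#' @examples
#' set.seed(1)
#' expr <- matrix(rnorm(40), 4, 10, dimnames = list(LETTERS[1:4], NULL))
#' s <- setNames(rnorm(4), LETTERS[1:4])
#' edgeStats(expr, s, cbind(c("A", "B"), c("B", "C")))
#' @export
edgeStats <- function(exprRef, sample, edges) {
  if (is(edges, "GeneNetwork")) edges <- networkEdges(edges)
  e <- normalizeEdges(edges)
  n <- ncol(exprRef)
  if (n < 3) stop("need at least 3 reference samples")
  genes <- unique(c(e))
  missingExpr <- setdiff(genes, rownames(exprRef))
  if (length(missingExpr))
    stop("gene absent from reference expression: ", missingExpr[1])
  missingSmp <- setdiff(genes, names(sample))
  if (length(missingSmp))
    stop("gene absent from the perturbing sample: ", missingSmp[1])

  X <- exprRef[genes, , drop = FALSE]
  s <- sample[genes]
  # per-gene reference moments
  sx <- rowSums(X)
  sxx <- rowSums(X^2)
  ia <- match(e[, 1], genes)
  ib <- match(e[, 2], genes)
  sxy <- rowSums(X[ia, , drop = FALSE] * X[ib, , drop = FALSE])

  covAB <- sxy - sx[ia] * sx[ib] / n
  varA <- sxx[ia] - sx[ia]^2 / n
  varB <- sxx[ib] - sx[ib]^2 / n
  pccRef <- covAB / sqrt(varA * varB)

  # appended-sample moments
  sx1a <- sx[ia] + s[ia]; sx1b <- sx[ib] + s[ib]
  sxx1a <- sxx[ia] + s[ia]^2; sxx1b <- sxx[ib] + s[ib]^2
  sxy1 <- sxy + s[ia] * s[ib]
  n1 <- n + 1
  cov1 <- sxy1 - sx1a * sx1b / n1
  var1a <- sxx1a - sx1a^2 / n1
  var1b <- sxx1b - sx1b^2 / n1
  pccPert <- cov1 / sqrt(var1a * var1b)

  ok <- is.finite(pccRef) & is.finite(pccPert) & abs(pccRef) < 1
  excluded <- sum(!ok)
  if (excluded > 0)
    message(sprintf("edgeStats: %d edge(s) with undefined correlation excluded",
                    excluded))
  st <- ssnZ(pccRef[ok], pccPert[ok], n)
  out <- data.frame(gene_a = e[ok, 1], gene_b = e[ok, 2],
                    pcc_ref = pccRef[ok], pcc_pert = pccPert[ok],
                    delta = st$delta,
                    direction = sign(pccPert[ok] - pccRef[ok]),
                    z = st$z, p = st$p,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_ref") <- n
  attr(out, "excluded") <- excluded
  out
}

#' Edges with a significant single-sample correlation change
#'
#' @param stats data.frame from \code{\link{edgeStats}}.
#' @param alpha significance level in (0, 1); edges with p strictly below
#'   alpha are kept.
#' @return two-column character matrix of significant edges, with the kept
#'   rows' p-values in attribute \code{"p"}.
#' @export
significantEdges <- function(stats, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  keep <- stats$p < alpha
  e <- as.matrix(stats[keep, c("gene_a", "gene_b"), drop = FALSE])
  dimnames(e) <- NULL
  if (length(e) == 0) e <- matrix(character(0), 0, 2)
  attr(e, "p") <- stats$p[keep]
  e
}

#' Null ("volcano") distribution of the single-sample correlation change
#'
#' Simulates the null of the single-sample statistic: two independent
#' standard-normal reference series of length \code{nRef} plus one appended
#' random observation pair, recording |PCC^{n+1} - PCC^n| each time. The
#' resulting sharply-peaked, heavy-shouldered distribution is the "volcano"
#' null; its two-tail 5% critical value closely tracks the closed-form
#' inversion 1.96 (1 - (PCC^n)^2) / (n - 1) of the Z statistic.
#'
#' @param nRef reference sample count (>= 3).
#' @param reps number of Monte-Carlo repetitions (>= 1e4).
#' @param seed RNG seed; the returned sample is a pure function of
#'   (nRef, reps, seed).
#' @param tailProb two-tail probability for the critical value (default
#'   0.05, i.e. the 95th percentile of |delta PCC|).
#' @return list with \code{sample} (sorted delta PCC values),
#'   \code{critical} (the two-tail critical value) and the call parameters.
#' @examples
#' v <- volcanoNull(20, 1e4, seed = 1)
#' v$critical            # close to 1.96 / 19
#' @export
volcanoNull <- function(nRef, reps, seed, tailProb = 0.05) {
  if (nRef < 3) stop("nRef must be at least 3")
  if (reps < 1e4) stop("reps must be at least 1e4")
  set.seed(seed)
  # vectorized across repetitions: rows are repetitions
  deltas <- numeric(reps)
  block <- 20000L
  done <- 0L
  while (done < reps) {
    b <- min(block, reps - done)
    X <- matrix(rnorm(b * nRef), b, nRef)
    Y <- matrix(rnorm(b * nRef), b, nRef)
    u <- rnorm(b); v <- rnorm(b)
    sx <- rowSums(X); sy <- rowSums(Y)
    sxx <- rowSums(X^2); syy <- rowSums(Y^2); sxy <- rowSums(X * Y)
    r0 <- (sxy - sx * sy / nRef) /
      sqrt((sxx - sx^2 / nRef) * (syy - sy^2 / nRef))
    n1 <- nRef + 1
    r1 <- ((sxy + u * v) - (sx + u) * (sy + v) / n1) /
      sqrt(((sxx + u^2) - (sx + u)^2 / n1) * ((syy + v^2) - (sy + v)^2 / n1))
    deltas[(done + 1):(done + b)] <- abs(r1 - r0)
    done <- done + b
  }
  deltas <- sort(deltas)
  list(sample = deltas,
       critical = unname(quantile(deltas, 1 - tailProb, type = 7)),
       nRef = nRef, reps = reps, seed = seed, tailProb = tailProb)
}
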
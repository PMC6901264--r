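# Structural diagnostics of personalized networks: connected components
# and the discrete power-law degree-exponent fit with a semiparametric
# bootstrap goodness-of-fit test.

#' Connected components of a network
#'
#' @param net a \linkS4class{GeneNetwork}.
#' @return data.frame sorted by decreasing component size: component index,
#'   node count, edge count, and average degree 2|E|/|V|; singleton
#'   (isolated) nodes are their own components.
#' @examples
#' tri2 <- geneNetwork(data.frame(a = c("A","B","C","X","Y","Z"),
#'                                b = c("B","C","A","Y","Z","X")))
#' componentsSummary(tri2)
#' @export
componentsSummary <- function(net) {
  g <- asIgraph(net)
  cmp <- igraph::components(g)
  edgeComp <- cmp$membership[net@edges[, 1]]
  nE <- tabulate(edgeComp, nbins = cmp$no)
  out <- data.frame(component = seq_len(cmp$no),
                    n_nodes = as.integer(cmp$csize),
                    n_edges = as.integer(nE))
  out$avg_degree <- 2 * out$n_edges / out$n_nodes
  out <- out[order(-out$n_nodes, out$component), , drop = FALSE]
  out$component <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Degree sequence of a network
#'
#' @param net a \linkS4class{GeneNetwork}.
#' @param component \code{"largest"} (default; degrees within the largest
#'   connected component, the convention for per-component power-law fits)
#'   or \code{"all"} (whole graph, connected nodes only).
#' @return integer vector of degrees.
#' @export
degreeSequence <- function(net, component = c("largest", "all")) {
  component <- match.arg(component)
  deg <- nodeDegrees(net)
  if (component == "all") return(unname(deg[deg > 0]))
  g <- asIgraph(net)
  cmp <- igraph::components(g)
  keep <- cmp$membership == which.max(cmp$csize)
  unname(deg[names(cmp$membership)[keep]])
}

#' Discrete power-law fit with bootstrap goodness of fit
#'
#' Fits P(k) ~ k^-gamma to a degree sequence by discrete maximum
#' likelihood, choosing the lower cutoff kmin that minimizes the
#' Kolmogorov-Smirnov distance between the tail data and the fitted model
#' (the standard Clauset-Shalizi-Newman recipe, via igraph's plfit). The
#' goodness-of-fit p-value is computed by a semiparametric bootstrap: each
#' replicate resamples the body (below kmin) empirically and draws the
#' tail from the fitted power law, refits, and records its KS distance;
#' p is the fraction of replicates whose KS distance reaches the observed
#' one. Fits with p > 0.05 are conventionally called plausible.
#'
#' @param degrees positive-integer degree observations (>= 20, with >= 2
#'   distinct values).
#' @param bootstrapReps bootstrap replicates (default 200; 0 skips the
#'   bootstrap and leaves p = NA).
#' @param seed RNG seed for the bootstrap.
#' @return a \linkS4class{PowerLawFit}.
#' @examples
#' set.seed(7)
#' k <- samplePowerLaw(500, gamma = 2.5, kmin = 1)
#' fitPowerLaw(k, bootstrapReps = 50, seed = 1)
#' @export
fitPowerLaw <- function(degrees, bootstrapReps = 200, seed = 1) {
  degrees <- as.integer(degrees)
  if (any(degrees < 1)) stop("degrees must be positive integers")
  if (length(degrees) < 20) stop("need at least 20 degree observations")
  if (length(unique(degrees)) < 2)
    stop("all degrees identical; no power-law fit is defined")
  fit <- igraph::fit_power_law(degrees, implementation = "plfit")
  ks <- fit$KS.stat
  kmin <- fit$xmin
  gam <- fit$alpha
  nTail <- sum(degrees >= kmin)
  p <- NA_real_
  if (bootstrapReps > 0) {
    set.seed(seed)
    body <- degrees[degrees < kmin]
    nAll <- length(degrees)
    exceed <- 0L
    for (b in seq_len(bootstrapReps)) {
      nT <- rbinom(1, nAll, nTail / nAll)
      synth <- c(if (nAll - nT > 0 && length(body) > 0)
                   sample(body, nAll - nT, replace = TRUE),
                 samplePowerLaw(max(nT, 1), gam, kmin))
      bf <- tryCatch(igraph::fit_power_law(synth, implementation = "plfit"),
                     error = function(e) NULL)
      if (!is.null(bf) && bf$KS.stat >= ks) exceed <- exceed + 1L
    }
    p <- exceed / bootstrapReps
  }
  new("PowerLawFit", gamma = gam, kmin = as.numeric(kmin), ks = ks,
      p = p, nTail = as.integer(nTail),
      bootstrapReps = as.integer(bootstrapReps))
}

#' Sample from a discrete power law
#'
#' Inverse-CDF sampling of P(k) proportional to k^-gamma for k >= kmin
#' (support truncated at a large finite maximum for normalization).
#'
#' @param n sample size.
#' @param gamma exponent (> 1).
#' @param kmin lower support bound.
#' @param kmax upper support truncation (default 1e6).
#' @return integer vector of length n.
#' @export
samplePowerLaw <- function(n, gamma, kmin = 1, kmax = 1e6) {
  if (gamma <= 1) stop("gamma must exceed 1")
  # continuous-relaxation inverse CDF with rounding correction, the
  # standard fast approximation for discrete power-law generation
  u <- runif(n)
  k <- floor((kmin - 0.5) * (1 - u)^(-1 / (gamma - 1)) + 0.5)
  as.integer(pmin(k, kmax))
}
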
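## NormFinder: model-based stability value separating intra-group variance
## from (shrunken) inter-group differences of candidate reference genes.

#' NormFinder stability analysis
#'
#' Fits the model-based decomposition of log-scale expression into
#' sample-specific, gene-specific and gene-by-group effects. Per group g,
#' each gene's values are centered by the per-sample mean over genes,
#' z[i,g,s] = y[i,g,s] - mean_i y[i,g,s], removing sample loading. The
#' intra-group variance of gene i is estimated from the sample variance
#' s2[i,g] of the centered values with the between-gene leakage removed:
#' \deqn{\hat\sigma^2_{ig} = \max(0, \frac{k}{k-2}(s2_{ig} - S_g/(k(k-1))))}
#' with S_g the sum of s2 over genes. With a single group the stability
#' value is \eqn{\rho_i = \hat\sigma_i}. With G >= 2 groups the per-group
#' deviations d[i,g] (centered over groups per gene) estimate differential
#' expression; their variance \eqn{\hat\gamma^2} (method of moments,
#' truncated at zero) shrinks each d toward zero, and
#' \deqn{\rho_i = \frac{1}{G}\sum_g |\tilde d_{ig}| +
#'   \sqrt{\frac{\hat\gamma^2 \hat\sigma^2_{ig}/n_g}
#'        {\hat\gamma^2 + \hat\sigma^2_{ig}/n_g}}}
#' so candidates pay for both instability flavors: noise and group-wise
#' regulation. Lower rho = more stable.
#'
#' The result is invariant to per-gene additive offsets of y, so y may be
#' -CqE or log2 of the relative quantities under any calibrator.
#'
#' @param y a \linkS4class{QuantityMatrix} (log2 quantities and the group
#'   labels in \code{colData} are used) or a genes x samples matrix of
#'   log2-scale expression.
#' @param groups sample group labels (required for the matrix method).
#' @return a \linkS4class{NormFinderResult}.
#' @export
normFinder <- function(y, groups = NULL) {
  if (is(y, "QuantityMatrix")) {
    if (is.null(groups)) groups <- sampleGroups(y)
    y <- log2(assay(y, "q"))
  }
  stopif(!is.matrix(y) || !is.numeric(y), "y must be a numeric matrix")
  stopif(is.null(groups), "groups are required")
  groups <- factor(groups, levels = unique(as.character(groups)))
  stopif(length(groups) != ncol(y), "one group label per sample required")
  k <- nrow(y)
  stopif(k < 3L, "NormFinder needs at least 3 genes")
  G <- nlevels(groups)
  nPer <- as.integer(table(groups))
  stopif(any(nPer < 2L), "every group needs at least 2 samples")
  genes <- rownames(y)

  dBar <- s2 <- matrix(NA_real_, k, G, dimnames = list(genes, levels(groups)))
  for (g in seq_len(G)) {
    z <- y[, groups == levels(groups)[g], drop = FALSE]
    z <- sweep(z, 2, colMeans(z))          # per-sample centering over genes
    dBar[, g] <- rowMeans(z)
    s2[, g] <- apply(z, 1, stats::var)
  }
  Sg <- colSums(s2)
  sigma2 <- pmax((k / (k - 2)) * sweep(s2, 2, Sg / (k * (k - 1))), 0)

  if (G == 1L) {
    rho <- sqrt(sigma2[, 1])
    dShrunk <- matrix(0, k, 1, dimnames = dimnames(dBar))
    gamma2 <- 0
  } else {
    d <- dBar - rowMeans(dBar)             # center over groups per gene
    varPerSample <- sweep(sigma2, 2, nPer, "/")
    ## method-of-moments gamma^2 on the (k-1)(G-1) free dimensions left by
    ## the two centering constraints
    gamma2 <- max(0, sum(d^2) / ((k - 1) * (G - 1)) - mean(varPerSample))
    shrink <- gamma2 / (gamma2 + varPerSample)
    shrink[is.nan(shrink)] <- 0            # gamma2 = 0 and zero variance
    dShrunk <- d * shrink
    condSD <- sqrt(gamma2 * varPerSample / (gamma2 + varPerSample))
    condSD[is.nan(condSD)] <- 0
    rho <- rowMeans(abs(dShrunk) + condSD)
  }
  new("NormFinderResult", genes = genes,
      rho = stats::setNames(as.numeric(rho), genes),
      dBar = dBar, s2 = s2, sigma2Hat = sigma2,
      gamma2Hat = as.numeric(gamma2), dShrunk = dShrunk,
      nPerGroup = stats::setNames(nPer, levels(groups)))
}

#' @rdname stabilityScores
#' @export
setMethod("stabilityScores", "NormFinderResult", function(x) x@rho)

#' @rdname stabilityRanks
#' @export
setMethod("stabilityRanks", "NormFinderResult", function(x) avgRank(x@rho))

#' @rdname scoreTable
#' @export
setMethod("scoreTable", "NormFinderResult", function(x, ...) {
  r <- avgRank(x@rho)
  data.frame(gene = x@genes, score = unname(x@rho),
             rank = unname(r))[order(r), ]
})

setMethod("show", "NormFinderResult", function(object) {
  cat("NormFinder stability (rho, lower = more stable), ",
      ncol(object@dBar), " group(s)\n", sep = "")
  print(round(sort(object@rho), 4))
})
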
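## consensus: RefFinder-style aggregation of the four method rankings and
## the optimal reference-gene count from the pairwise-variation series.

#' Per-method ranks from stability scores
#'
#' Ascending scores map to ranks 1..k; exact ties receive the average of
#' the tied positions. All methods must score the same gene set.
#'
#' @param scores named list of named numeric score vectors, one per
#'   method (lower = more stable).
#' @return method x gene matrix of ranks.
#' @export
methodRanks <- function(scores) {
  stopif(length(scores) == 0L, "no scores supplied")
  genes <- sort(names(scores[[1]]))
  for (m in names(scores)) {
    stopif(!setequal(names(scores[[m]]), genes) ||
             length(scores[[m]]) != length(genes),
           "method '", m, "' scored a different gene set")
  }
  t(vapply(scores, function(s) avgRank(s)[genes], numeric(length(genes))))
}

#' RefFinder-style consensus of the four stability rankings
#'
#' Aggregates the geNorm, NormFinder, BestKeeper and delta-Ct rankings
#' into a comprehensive weighed ranking: each gene's consensus score is
#' the geometric mean of its four per-method ranks, and genes are ordered
#' ascending by it (ties broken by arithmetic mean rank, then
#' lexicographically). The geNorm ranking used is its
#' iterative-elimination ranking.
#'
#' @param genorm,normfinder,bestkeeper,deltact the four results, or
#'   alternatively \code{ranks}: a method x gene matrix as from
#'   [methodRanks()] (four rows).
#' @param ranks optional pre-computed rank matrix overriding the result
#'   objects.
#' @return a \linkS4class{ConsensusRanking}.
#' @export
refFinderConsensus <- function(genorm = NULL, normfinder = NULL,
                               bestkeeper = NULL, deltact = NULL,
                               ranks = NULL) {
  if (is.null(ranks)) {
    res <- list(geNorm = genorm, NormFinder = normfinder,
                BestKeeper = bestkeeper, deltaCt = deltact)
    stopif(any(vapply(res, is.null, logical(1))),
           "all four method results (or a rank matrix) are required")
    genes <- sort(res[[1]]@genes)
    for (m in names(res))
      stopif(!setequal(res[[m]]@genes, genes),
             "method '", m, "' scored a different gene set")
    ranks <- t(vapply(res, function(r) stabilityRanks(r)[genes],
                      numeric(length(genes))))
  }
  stopif(nrow(ranks) != 4L, "consensus requires exactly four methods")
  genes <- colnames(ranks)
  geomean <- apply(ranks, 2, geoMean)
  ord <- genes[order(geomean, colMeans(ranks), genes)]
  new("ConsensusRanking", ranks = ranks,
      geomean = stats::setNames(geomean, genes), order = ord)
}

#' @rdname scoreTable
#' @export
setMethod("scoreTable", "ConsensusRanking", function(x, ...) {
  df <- data.frame(gene = colnames(x@ranks), t(x@ranks),
                   geomean = unname(x@geomean),
                   consensus_rank = match(colnames(x@ranks), x@order),
                   check.names = FALSE)
  df[order(df$consensus_rank), ]
})

setMethod("show", "ConsensusRanking", function(object) {
  cat("RefFinder-style consensus (geometric mean of method ranks)\n")
  df <- scoreTable(object)
  df$geomean <- round(df$geomean, 3)
  print(df, row.names = FALSE)
})

#' Optimal number of reference genes
#'
#' Builds the pairwise-variation series V_n/n+1 along the consensus order
#' and reports the first n whose V falls below the cutoff: adding the
#' (n+1)-th gene no longer improves the normalization factor, so n genes
#' are recommended. The classic cutoff 0.15 is a guideline, not a strict
#' rule, and is configurable.
#'
#' @param q a \linkS4class{QuantityMatrix} or quantity matrix.
#' @param consensus a \linkS4class{ConsensusRanking} (or a ranked gene
#'   character vector).
#' @param cutoff threshold on V (default 0.15).
#' @param nMax largest NF size (default all ranked genes).
#' @return a \linkS4class{PairwiseVariationSeries} with \code{optimalN}.
#' @export
optimalRgCount <- function(q, consensus, cutoff = 0.15, nMax = NULL) {
  ord <- if (is(consensus, "ConsensusRanking")) consensus@order
         else as.character(consensus)
  stopif(length(ord) < 3L, "need at least 3 ranked genes")
  geNormPairwiseVariation(q, order = ord, nMax = nMax, cutoff = cutoff)
}
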
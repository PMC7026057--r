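#' Stability scores of a stability-algorithm result
#'
#' Lower scores mean more stable expression in every algorithm.
#'
#' @param x a \linkS4class{StabilityResult}.
#' @return named numeric vector over genes.
#' @export
setGeneric("stabilityScores", function(x) standardGeneric("stabilityScores"))

#' Stability ranks of a stability-algorithm result
#'
#' Rank 1 is the most stable gene. Exact score ties receive the average of
#' the tied rank positions; the geNorm method returns its
#' iterative-elimination ranking instead of a re-ranking of M.
#'
#' @param x a \linkS4class{StabilityResult}.
#' @return named numeric vector over genes.
#' @export
setGeneric("stabilityRanks", function(x) standardGeneric("stabilityRanks"))

#' Per-gene PCR efficiencies
#' @param x a \linkS4class{CqExperiment}, \linkS4class{CqTable} or
#'   \linkS4class{QuantityMatrix}.
#' @return named numeric vector of amplification efficiencies E.
#' @export
setGeneric("efficiencies", function(x) standardGeneric("efficiencies"))

#' Sample group labels
#' @param x a container with per-sample metadata.
#' @return factor of group labels, named by sample.
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' Tabular summary of a result
#'
#' A plain data.frame suitable for writing as TSV: one row per gene with
#' score and rank for stability results, per-method ranks plus geometric
#' mean for a consensus, the V series for a pairwise-variation series.
#'
#' @param x a result object.
#' @param ... unused.
#' @return data.frame.
#' @export
setGeneric("scoreTable", function(x, ...) standardGeneric("scoreTable"))
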
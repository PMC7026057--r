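## normalization: normalization factors from the selected reference genes
## and fold-change quantification of a gene of interest.

#' Per-sample normalization factor
#'
#' The geometric mean over the selected reference genes of their relative
#' quantities, per sample.
#'
#' @param q a \linkS4class{QuantityMatrix} or quantity matrix.
#' @param rgs non-empty character vector of reference genes.
#' @return named numeric NF per sample.
#' @export
normalizationFactor <- function(q, rgs) {
  q <- .asQuantityMat(q)
  stopif(length(rgs) == 0L, "reference gene set must be non-empty")
  stopif(!all(rgs %in% rownames(q)),
         "unknown reference gene(s): ",
         paste(setdiff(rgs, rownames(q)), collapse = ", "))
  apply(q[rgs, , drop = FALSE], 2, geoMean)
}

#' Normalize a gene of interest by a normalization factor
#'
#' @param goiQ named numeric relative quantities of the GOI per sample.
#' @param nf named numeric normalization factor per sample.
#' @return named numeric normalized relative quantities.
#' @export
normalizeGoi <- function(goiQ, nf) {
  stopif(length(goiQ) != length(nf), "sample sets differ in length")
  if (!is.null(names(goiQ)) && !is.null(names(nf))) {
    stopif(!setequal(names(goiQ), names(nf)), "sample sets differ")
    nf <- nf[names(goiQ)]
  }
  stopif(any(nf <= 0), "normalization factors must be positive")
  goiQ / nf
}

#' Fold changes versus a calibrator group
#'
#' Expresses each sample's normalized quantity as a ratio to the
#' arithmetic mean of the calibrator group's normalized quantities, so the
#' calibrator group's folds average exactly 1. Per-group arithmetic means
#' and standard errors of the fold are reported alongside.
#'
#' @param rel named numeric normalized quantities.
#' @param groups group labels per sample.
#' @param calibratorGroup the baseline group label (e.g. "PM").
#' @return list with \code{fold} (per sample) and \code{summary}
#'   (data.frame group, n, mean_fold, se_fold).
#' @export
foldChangeVsGroup <- function(rel, groups, calibratorGroup) {
  groups <- factor(groups, levels = unique(as.character(groups)))
  stopif(length(rel) != length(groups), "one group label per sample required")
  stopif(!calibratorGroup %in% levels(groups),
         "calibrator group '", calibratorGroup, "' absent from the data")
  base <- mean(rel[groups == calibratorGroup])
  fold <- rel / base
  sds <- tapply(fold, groups, stats::sd)
  ns <- tapply(fold, groups, length)
  summary <- data.frame(group = levels(groups), n = as.integer(ns),
                        mean_fold = as.numeric(tapply(fold, groups, mean)),
                        se_fold = as.numeric(sds / sqrt(ns)))
  list(fold = fold, summary = summary)
}

#' Full normalization of a gene of interest
#'
#' Convenience wrapper: computes the NF from the chosen reference genes,
#' normalizes the GOI and expresses fold changes versus the calibrator
#' group.
#'
#' @param q a \linkS4class{QuantityMatrix} containing the reference genes
#'   and, unless \code{goiQ} is given, the GOI itself.
#' @param goi GOI gene name (must not be in \code{rgs}).
#' @param rgs ordered reference-gene set.
#' @param calibratorGroup baseline group label.
#' @param groups labels per sample; defaults to the \code{colData} groups.
#' @param goiQ optional explicit GOI quantities (overrides \code{goi}).
#' @return a \linkS4class{NormalizedExpression}.
#' @export
normalizeExpression <- function(q, goi, rgs, calibratorGroup,
                                groups = NULL, goiQ = NULL) {
  if (is.null(groups)) groups <- sampleGroups(q)
  qm <- .asQuantityMat(q)
  stopif(goi %in% rgs, "the gene of interest cannot normalize itself")
  if (is.null(goiQ)) {
    stopif(!goi %in% rownames(qm), "GOI '", goi, "' absent from the data")
    goiQ <- qm[goi, ]
  }
  nf <- normalizationFactor(qm, rgs)
  rel <- normalizeGoi(goiQ, nf)
  fc <- foldChangeVsGroup(rel, groups, calibratorGroup)
  new("NormalizedExpression", nf = nf, rel = rel, fold = fc$fold,
      groups = factor(groups, levels = unique(as.character(groups))),
      calibratorGroup = calibratorGroup, rgSet = rgs,
      groupSummary = fc$summary)
}

#' @rdname scoreTable
#' @export
setMethod("scoreTable", "NormalizedExpression", function(x, ...) {
  data.frame(sample = names(x@nf), group = as.character(x@groups),
             nf = unname(x@nf), rel = unname(x@rel), fold = unname(x@fold))
})

setMethod("show", "NormalizedExpression", function(object) {
  cat("Normalized expression vs group '", object@calibratorGroup,
      "' using NF(", paste(object@rgSet, collapse = ", "), ")\n", sep = "")
  df <- object@groupSummary
  df$mean_fold <- round(df$mean_fold, 3)
  df$se_fold <- round(df$se_fold, 3)
  print(df, row.names = FALSE)
})
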
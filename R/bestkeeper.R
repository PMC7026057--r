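## BestKeeper: descriptive dispersion of raw Cq plus correlation of each
## candidate with the BestKeeper index.

#' BestKeeper analysis of raw Cq values
#'
#' Works directly on raw quantitation cycles. Per gene it reports the
#' arithmetic and geometric mean, range, the dispersion \code{sd_cq}
#' (mean absolute deviation from the arithmetic mean, in cycles) and its
#' coefficient of variation; genes with \code{sd_cq} above 1 cycle are
#' flagged inconsistent. The BestKeeper index is the per-sample geometric
#' mean of Cq over all candidates; each gene's Cq is correlated with the
#' index (Pearson r, two-sided p). Genes with zero variance get \code{NA}
#' correlations with a warning. For consensus ranking, genes are ordered
#' by \code{sd_cq} ascending.
#'
#' @param x a \linkS4class{CqTable} on the raw Cq scale, or a genes x
#'   samples Cq matrix (>= 2 genes, >= 3 samples, complete).
#' @return a \linkS4class{BestKeeperResult}.
#' @export
bestKeeper <- function(x) {
  if (is(x, "CqTable")) {
    if (x@scale != "cq")
      warning("BestKeeper is defined on raw Cq; input is on the ",
              x@scale, " scale", call. = FALSE)
    x <- assay(x)
  }
  stopif(!is.matrix(x) || !is.numeric(x), "x must be a numeric matrix")
  stopif(any(is.na(x)), "complete matrix required")
  stopif(nrow(x) < 2L, "BestKeeper needs at least 2 genes")
  stopif(ncol(x) < 3L, "BestKeeper needs at least 3 samples")
  genes <- rownames(x)

  am <- rowMeans(x)
  sdcq <- rowMeans(abs(x - am))
  index <- apply(x, 2, geoMean)
  corOne <- function(v) {
    if (sampleSD(v) == 0) return(c(r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(v, index, method = "pearson",
                          alternative = "two.sided")
    c(r = unname(ct$estimate), p = ct$p.value)
  }
  rp <- t(apply(x, 1, corOne))
  if (any(is.na(rp[, "r"])))
    warning("zero-variance gene(s), correlation undefined: ",
            paste(genes[is.na(rp[, "r"])], collapse = ", "), call. = FALSE)
  stats <- data.frame(
    gene = genes,
    arith_mean = am,
    geo_mean = apply(x, 1, geoMean),
    min = apply(x, 1, min),
    max = apply(x, 1, max),
    sd_cq = sdcq,
    cv_pct = 100 * sdcq / am,
    r = rp[, "r"],
    p = rp[, "p"],
    inconsistent = sdcq > 1,
    row.names = genes)
  new("BestKeeperResult", genes = genes, stats = stats,
      index = stats::setNames(index, colnames(x)))
}

#' @rdname stabilityScores
#' @export
setMethod("stabilityScores", "BestKeeperResult", function(x)
  stats::setNames(x@stats$sd_cq, x@genes))

#' @rdname stabilityRanks
#' @export
setMethod("stabilityRanks", "BestKeeperResult", function(x)
  avgRank(stabilityScores(x)))

#' @rdname scoreTable
#' @export
setMethod("scoreTable", "BestKeeperResult", function(x, ...) {
  r <- stabilityRanks(x)
  data.frame(gene = x@genes, score = x@stats$sd_cq,
             rank = unname(r))[order(r), ]
})

setMethod("show", "BestKeeperResult", function(object) {
  cat("BestKeeper (sd_cq in cycles, lower = more stable)\n")
  print(round(object@stats[order(object@stats$sd_cq),
                           c("arith_mean", "sd_cq", "cv_pct", "r")], 4))
})
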
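## Comparative delta-Ct: stability from the SD of pairwise Cq differences.

#' Comparative delta-Ct stability analysis
#'
#' For every ordered gene pair (j, k) computes the standard deviation over
#' samples of the Cq difference \code{cq[j, s] - cq[k, s]}; a gene's score
#' is the mean of its pairwise SDs with all partner genes (cycles, lower =
#' more stable). On efficiency-corrected input this equals the full-set
#' geNorm M computed from the derived quantities, since the pairwise
#' delta-Cq is the negated pairwise log2 quantity ratio up to a constant.
#'
#' @param x a \linkS4class{CqTable} (corrected scale by default in the
#'   pipeline; raw Cq also accepted) or a genes x samples matrix (>= 2
#'   genes, >= 2 samples, complete).
#' @return a \linkS4class{DeltaCtResult}.
#' @export
deltaCt <- function(x) {
  if (is(x, "CqTable")) x <- assay(x)
  stopif(!is.matrix(x) || !is.numeric(x), "x must be a numeric matrix")
  stopif(any(is.na(x)), "complete matrix required")
  stopif(nrow(x) < 2L, "delta-Ct needs at least 2 genes")
  stopif(ncol(x) < 2L, "delta-Ct needs at least 2 samples")
  genes <- rownames(x)
  k <- nrow(x)
  V <- matrix(0, k, k, dimnames = list(genes, genes))
  for (j in seq_len(k - 1)) {
    for (l in (j + 1):k) {
      V[j, l] <- V[l, j] <- sampleSD(x[j, ] - x[l, ])
    }
  }
  score <- stats::setNames(rowSums(V) / (k - 1), genes)
  new("DeltaCtResult", genes = genes, score = score, pairSD = V)
}

#' @rdname stabilityScores
#' @export
setMethod("stabilityScores", "DeltaCtResult", function(x) x@score)

#' @rdname stabilityRanks
#' @export
setMethod("stabilityRanks", "DeltaCtResult", function(x) avgRank(x@score))

#' @rdname scoreTable
#' @export
setMethod("scoreTable", "DeltaCtResult", function(x, ...) {
  r <- avgRank(x@score)
  data.frame(gene = x@genes, score = unname(x@score),
             rank = unname(r))[order(r), ]
})

setMethod("show", "DeltaCtResult", function(object) {
  cat("Comparative delta-Ct (mean pairwise SD in cycles)\n")
  print(round(sort(object@score), 4))
})
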
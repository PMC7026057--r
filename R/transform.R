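## transform: efficiency correction of Cq and conversion to relative
## quantities, the common input to the stability algorithms and to
## normalization.

#' Efficiency-corrected quantitation cycle
#'
#' Rescales a Cq measured under amplification efficiency E to the
#' equivalent perfect-doubling cycle count:
#' \deqn{CqE = Cq \cdot \log(E) / \log(2) = Cq \cdot \log_2 E.}
#' At E = 2 the correction is the identity. The base of the logarithm is
#' irrelevant (a ratio of logs).
#'
#' @param x a numeric vector/matrix of Cq values, or a
#'   \linkS4class{CqTable} on the raw Cq scale (the per-gene efficiencies
#'   in its \code{rowData} are applied row-wise).
#' @param e amplification efficiency in (1, 2.2]; recycled over \code{x}
#'   for the numeric method, ignored for the CqTable method.
#' @return same shape as \code{x}; for a CqTable, a CqTable with scale
#'   \code{"cqe"}.
#' @examples
#' efficiencyCorrect(30, 2)    # 30
#' efficiencyCorrect(25, 1.9)  # 25 * log2(1.9)
#' @export
setGeneric("efficiencyCorrect", function(x, e) {
  standardGeneric("efficiencyCorrect")
})

#' @rdname efficiencyCorrect
#' @export
setMethod("efficiencyCorrect", "numeric", function(x, e) {
  stopif(any(!is.finite(e)) || any(e <= 1) || any(e > 2.2),
         "efficiency must lie in (1, 2.2]")
  x * log2(e)
})

#' @rdname efficiencyCorrect
#' @export
setMethod("efficiencyCorrect", "CqTable", function(x, e) {
  stopif(x@scale != "cq", "x is already efficiency-corrected")
  if (missing(e)) e <- efficiencies(x)
  stopif(any(!is.finite(e)) || any(e <= 1) || any(e > 2.2),
         "efficiency must lie in (1, 2.2]")
  m <- assay(x) * log2(e)  # row-wise recycling: one efficiency per gene
  se <- SummarizedExperiment(assays = list(cqe = m), rowData = rowData(x),
                             colData = colData(x))
  out <- new("CqTable", se, scale = "cqe")
  metadata(out) <- metadata(x)
  out
})

#' Relative quantities from corrected Cq
#'
#' Converts a complete matrix of efficiency-corrected Cq values into
#' relative quantities \code{q[g, s] = 2^(calibrator_cq[g] - cqe[g, s])}.
#' The default calibrator is the per-gene minimum CqE (the most abundant
#' sample), so each gene's largest quantity is exactly 1; any fixed
#' per-gene calibrator may be supplied instead. All downstream stability
#' statistics are invariant to this choice.
#'
#' @param x a \linkS4class{CqTable} with scale \code{"cqe"} (a raw-scale
#'   table is corrected first using its stored efficiencies).
#' @param calibratorCq optional named numeric vector of fixed per-gene
#'   calibrator CqE values.
#' @return a \linkS4class{QuantityMatrix}.
#' @export
relativeQuantities <- function(x, calibratorCq = NULL) {
  stopif(!is(x, "CqTable"), "x must be a CqTable")
  if (x@scale == "cq") x <- efficiencyCorrect(x)
  cqe <- assay(x)
  if (any(is.na(cqe)))
    stop("missing cells present; restrict with validateCompleteMatrix() first",
         call. = FALSE)
  cal <- if (is.null(calibratorCq)) {
    apply(cqe, 1, min)
  } else {
    stopif(!all(rownames(x) %in% names(calibratorCq)),
           "calibratorCq must cover every gene")
    calibratorCq[rownames(x)]
  }
  q <- 2^(cal - cqe)
  se <- SummarizedExperiment(
    assays = list(q = q, cqe = cqe),
    rowData = DataFrame(rowData(x), calibrator_cq = unname(cal)),
    colData = colData(x))
  new("QuantityMatrix", se)
}

setMethod("show", "QuantityMatrix", function(object) {
  cat("QuantityMatrix:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("quantity range:",
      paste(signif(range(assay(object, "q")), 4), collapse = " - "), "\n")
})

#' Export a QuantityMatrix as wide TSV (genes x samples)
#' @param x a \linkS4class{QuantityMatrix}.
#' @param path destination.
#' @export
writeQuantityTSV <- function(x, path) {
  writeTsv(data.frame(gene = rownames(x), assay(x, "q"),
                      check.names = FALSE), path)
}
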
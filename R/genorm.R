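## geNorm: gene stability value M and iterative elimination ranking, plus
## the pairwise variation V_n/n+1 of sequential normalization factors.

.asQuantityMat <- function(q) {
  if (is(q, "QuantityMatrix")) q <- assay(q, "q")
  stopif(!is.matrix(q) || !is.numeric(q), "q must be a numeric matrix")
  stopif(any(!is.finite(q)), "q must be complete and finite")
  stopif(any(q <= 0), "relative quantities must be strictly positive")
  stopif(is.null(rownames(q)), "q needs gene rownames")
  q
}

## Full pairwise log-ratio SD matrix V[j, k] = SD_s log2(q[j,s]/q[k,s])
## (n-1 sample SD) and M_j = mean over k != j of V[j, k].
.genormM <- function(lq) {
  k <- nrow(lq)
  V <- matrix(0, k, k, dimnames = list(rownames(lq), rownames(lq)))
  for (j in seq_len(k - 1)) {
    for (l in (j + 1):k) {
      V[j, l] <- V[l, j] <- sampleSD(lq[j, ] - lq[l, ])
    }
  }
  m <- rowSums(V) / (k - 1)
  list(V = V, m = m)
}

#' geNorm stability analysis
#'
#' Scores each candidate reference gene by its stability value M, the mean
#' standard deviation of its pairwise log2 expression ratios with every
#' other candidate, then ranks genes by iterative elimination: the gene
#' with the largest M on the surviving set is removed and M recomputed
#' until two genes remain. The final pair is jointly most stable; its
#' ranks 1 and 2 are assigned by the full-set M (lexicographic on exact
#' ties) so that downstream consensus input is deterministic.
#'
#' @param q a \linkS4class{QuantityMatrix} or a positive genes x samples
#'   matrix of relative quantities (at least 3 genes, 2 samples).
#' @return a \linkS4class{GeNormResult}.
#' @export
geNorm <- function(q) {
  q <- .asQuantityMat(q)
  stopif(nrow(q) < 3L, "geNorm needs at least 3 genes")
  stopif(ncol(q) < 2L, "geNorm needs at least 2 samples")
  lq <- log2(q)
  full <- .genormM(lq)

  surviving <- rownames(q)
  removal <- character(0)
  ranking <- stats::setNames(numeric(nrow(q)), rownames(q))
  while (length(surviving) > 2L) {
    m <- .genormM(lq[surviving, , drop = FALSE])$m
    ## largest M goes; on exact ties the lexicographically last gene
    idx <- order(m, surviving)
    worst <- surviving[idx[length(idx)]]
    ranking[worst] <- length(surviving)
    removal <- c(removal, worst)
    surviving <- setdiff(surviving, worst)
  }
  pair <- surviving[order(full$m[surviving], surviving)]
  ranking[pair] <- c(1, 2)
  removal <- c(removal, rev(pair))
  new("GeNormResult", genes = rownames(q), m = full$m,
      pairwiseSD = full$V, removalOrder = removal, ranking = ranking)
}

#' @rdname stabilityScores
#' @export
setMethod("stabilityScores", "GeNormResult", function(x) x@m)

#' @rdname stabilityRanks
#' @export
setMethod("stabilityRanks", "GeNormResult", function(x) x@ranking)

#' @rdname scoreTable
#' @export
setMethod("scoreTable", "GeNormResult", function(x, ...) {
  data.frame(gene = x@genes, score = unname(x@m),
             rank = unname(x@ranking))[order(x@ranking), ]
})

setMethod("show", "GeNormResult", function(object) {
  cat("geNorm stability (M, lower = more stable)\n")
  print(round(sort(object@m), 4))
  cat("most stable pair:",
      paste(names(sort(object@ranking))[1:2], collapse = " + "), "\n")
})

#' Pairwise variation of sequential normalization factors
#'
#' For n = 2 ... nMax-1 builds the normalization factor NF_n (per-sample
#' geometric mean of the n top-ranked genes' quantities in the supplied
#' order) and the pairwise variation
#' \deqn{V_{n/n+1} = SD_s\, \log_2(NF_n[s] / NF_{n+1}[s]),}
#' the classic criterion for how many reference genes the normalization
#' factor needs.
#'
#' @param q a \linkS4class{QuantityMatrix} or quantity matrix.
#' @param order ranked gene list, most stable first (defaults to all genes
#'   in row order).
#' @param nMax largest NF size to consider (default all of \code{order}).
#' @param cutoff V threshold under which adding gene n+1 is deemed
#'   unnecessary (default 0.15); determines the reported optimal n.
#' @return a \linkS4class{PairwiseVariationSeries}.
#' @export
geNormPairwiseVariation <- function(q, order = NULL, nMax = NULL,
                                    cutoff = 0.15) {
  q <- .asQuantityMat(q)
  if (is.null(order)) order <- rownames(q)
  stopif(!all(order %in% rownames(q)),
         "order contains unknown gene(s): ",
         paste(setdiff(order, rownames(q)), collapse = ", "))
  if (is.null(nMax)) nMax <- length(order)
  stopif(nMax < 3L, "pairwise variation needs nMax >= 3")
  stopif(nMax > length(order), "nMax exceeds the ranked gene list")
  stopif(cutoff <= 0, "cutoff must be positive")

  lq <- log2(q[order, , drop = FALSE])
  ## log2 NF_n per sample = running mean of the top-n genes' log2 q
  lnf <- apply(lq, 2, cumsum) / seq_len(nrow(lq))
  nf <- 2^lnf[2:nMax, , drop = FALSE]
  rownames(nf) <- paste0("NF", 2:nMax)
  ns <- 2:(nMax - 1)
  v <- vapply(ns, function(n) sampleSD(lnf[n, ] - lnf[n + 1, ]), numeric(1))
  names(v) <- paste0("V", ns, "/", ns + 1)
  below <- which(v < cutoff)
  optimalN <- if (length(below) > 0L) as.integer(ns[below[1]]) else {
    warning("no V_n/n+1 below the ", cutoff,
            " cutoff; consider using the full ranked set", call. = FALSE)
    NA_integer_
  }
  new("PairwiseVariationSeries", v = v, nf = nf, optimalN = optimalN,
      cutoff = cutoff, order = order[seq_len(nMax)])
}

#' @rdname scoreTable
#' @export
setMethod("scoreTable", "PairwiseVariationSeries", function(x, ...) {
  ns <- 2:(length(x@v) + 1)
  data.frame(n = ns, comparison = names(x@v), v = unname(x@v),
             below_cutoff = unname(x@v < x@cutoff),
             first_below = ns == (x@optimalN %||% -1L))
})

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

setMethod("show", "PairwiseVariationSeries", function(object) {
  cat("Pairwise variation V_n/n+1 (cutoff ", object@cutoff, ")\n", sep = "")
  print(round(object@v, 4))
  if (is.na(object@optimalN))
    cat("no V below cutoff; full set recommended\n")
  else
    cat("optimal number of reference genes:", object@optimalN, "\n")
})
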
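## cli_report: orchestration of the full workflow and report rendering.
## The exported functions are the interface; inst/scripts/rgnorm.R is a
## thin command-line wrapper over them.

#' Run all four stability algorithms and the consensus on a dataset
#'
#' Collapses technical replicates, applies the efficiency correction,
#' converts to relative quantities and runs geNorm, NormFinder,
#' BestKeeper and the comparative delta-Ct method, then aggregates their
#' rankings into the RefFinder-style consensus. BestKeeper receives raw
#' Cq and delta-Ct the corrected CqE by default; both are configurable.
#'
#' @param x a \linkS4class{CqExperiment}.
#' @param genes gene subset (default all).
#' @param missingPolicy \code{"strict"} or \code{"drop-gene"} for
#'   incomplete cells (see [validateCompleteMatrix()]).
#' @param bestkeeperScale,deltaCtScale \code{"cq"} or \code{"cqe"}.
#' @param methods which algorithms to run; the consensus needs all four.
#' @param discordance replicate-disagreement QC threshold, cycles.
#' @return list with \code{q} (the \linkS4class{QuantityMatrix}),
#'   the per-method results, and \code{consensus} (NULL unless all four
#'   methods ran).
#' @export
rankStability <- function(x, genes = rownames(x),
                          missingPolicy = c("strict", "drop-gene"),
                          bestkeeperScale = c("cq", "cqe"),
                          deltaCtScale = c("cqe", "cq"),
                          methods = c("genorm", "normfinder", "bestkeeper",
                                      "deltact"),
                          discordance = 0.5) {
  missingPolicy <- match.arg(missingPolicy)
  bestkeeperScale <- match.arg(bestkeeperScale)
  deltaCtScale <- match.arg(deltaCtScale)
  methods <- match.arg(methods, several.ok = TRUE)
  collapsed <- collapseTechnicalReplicates(x, discordance = discordance)
  collapsed <- validateCompleteMatrix(collapsed, genes, policy = missingPolicy)
  cqe <- efficiencyCorrect(collapsed)
  q <- relativeQuantities(cqe)
  res <- list(q = q)
  if ("genorm" %in% methods) res$genorm <- geNorm(q)
  if ("normfinder" %in% methods) res$normfinder <- normFinder(q)
  if ("bestkeeper" %in% methods)
    res$bestkeeper <- bestKeeper(
      if (bestkeeperScale == "cq") collapsed else cqe)
  if ("deltact" %in% methods)
    res$deltact <- deltaCt(if (deltaCtScale == "cqe") cqe else collapsed)
  res$consensus <- if (all(c("genorm", "normfinder", "bestkeeper",
                             "deltact") %in% methods)) {
    refFinderConsensus(res$genorm, res$normfinder, res$bestkeeper,
                       res$deltact)
  } else {
    warning("consensus skipped: it requires all four methods", call. = FALSE)
    NULL
  }
  res
}

#' Rank reference genes and write the report artifacts
#'
#' Reads the Cq, metadata and efficiency tables, runs [rankStability()]
#' and [optimalRgCount()], and writes: per-method score TSVs, the
#' consensus table (method ranks + geometric mean), the V series with the
#' first-below-cutoff flag, and a JSON log of all parameters. Outputs are
#' deterministic: rerunning with identical inputs is byte-identical.
#'
#' @param input,metaPath,efficiencyPath input file paths (see
#'   [parseCqTable()]).
#' @param outDir output directory (created if needed).
#' @param layout \code{"long"} or \code{"wide"}.
#' @param cutoff pairwise-variation cutoff (default 0.15).
#' @param ... passed to [rankStability()] (e.g. \code{missingPolicy},
#'   \code{methods}).
#' @return the [rankStability()] result, with \code{$vseries} appended,
#'   invisibly.
#' @export
runRank <- function(input, metaPath, efficiencyPath, outDir,
                    layout = c("long", "wide"), cutoff = 0.15, ...) {
  layout <- match.arg(layout)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  ds <- parseCqTable(input, layout, metaPath, efficiencyPath)
  res <- rankStability(ds, ...)
  for (m in intersect(names(res), c("genorm", "normfinder", "bestkeeper",
                                    "deltact")))
    writeTsv(scoreTable(res[[m]]), file.path(outDir, paste0(m, ".tsv")))
  if (!is.null(res$consensus)) {
    writeTsv(scoreTable(res$consensus), file.path(outDir, "consensus.tsv"))
    res$vseries <- optimalRgCount(res$q, res$consensus, cutoff = cutoff)
    writeTsv(scoreTable(res$vseries),
             file.path(outDir, "pairwise_variation.tsv"))
  }
  log <- list(input = input, meta = metaPath,
              efficiencies = efficiencyPath, layout = layout,
              cutoff = cutoff, genes = rownames(res$q),
              samples = colnames(res$q),
              optimal_n = if (!is.null(res$vseries))
                res$vseries@optimalN else NULL)
  writeLines(jsonlite::toJSON(log, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE),
             file.path(outDir, "run_log.json"))
  invisible(res)
}

#' Quantify a gene of interest and write the report artifacts
#'
#' Normalizes the GOI by the NF of the chosen reference genes (explicit,
#' or the consensus top n), runs the group significance tests and,
#' optionally, the stepwise reduction study; writes per-sample TSV and a
#' JSON summary with group means, standard errors, Tukey letters and
#' Dunnett stars.
#'
#' @param input,metaPath,efficiencyPath,layout input tables as in
#'   [runRank()]; the Cq table must contain the GOI row.
#' @param goi gene of interest.
#' @param calibratorGroup calibrator / Dunnett control group.
#' @param outDir output directory.
#' @param refs explicit reference-gene set; \code{NULL} selects the
#'   consensus top \code{nTop}.
#' @param nTop consensus genes used when \code{refs} is NULL (default the
#'   optimal n from the V series, else 3).
#' @param reduce also run [reductionStudy()] (default FALSE).
#' @param cutoff pairwise-variation cutoff.
#' @param alpha significance level.
#' @return list(expression, tests, reduction), invisibly.
#' @export
runQuantify <- function(input, metaPath, efficiencyPath, goi,
                        calibratorGroup, outDir,
                        layout = c("long", "wide"), refs = NULL,
                        nTop = NULL, reduce = FALSE, cutoff = 0.15,
                        alpha = 0.05) {
  layout <- match.arg(layout)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  ds <- parseCqTable(input, layout, metaPath, efficiencyPath)
  stopif(!goi %in% rownames(ds), "GOI '", goi, "' absent from the input")
  stopif(!calibratorGroup %in% sampleGroups(ds),
         "calibrator group '", calibratorGroup, "' absent from the input")
  candidates <- setdiff(rownames(ds), goi)
  rk <- rankStability(ds, genes = candidates)
  vs <- optimalRgCount(rk$q, rk$consensus, cutoff = cutoff)
  if (is.null(refs)) {
    n <- nTop %||% (if (is.na(vs@optimalN)) 3L else vs@optimalN)
    refs <- utils::head(rk$consensus@order, n)
  }
  collapsed <- validateCompleteMatrix(collapseTechnicalReplicates(ds),
                                      c(refs, goi))
  q <- relativeQuantities(efficiencyCorrect(collapsed))
  ne <- normalizeExpression(q, goi, refs, calibratorGroup)
  tests <- groupTests(ne@fold, ne@groups, calibratorGroup, alpha = alpha)
  red <- NULL
  if (reduce && length(refs) >= 2L)
    red <- reductionStudy(q, goi, refs, length(refs), calibratorGroup,
                          alpha = alpha)
  writeTsv(scoreTable(ne), file.path(outDir, "normalized_expression.tsv"))
  summary <- ne@groupSummary
  summary$letters <- tests@letters[summary$group]
  stars <- stats::setNames(tests@dunnett$stars, tests@dunnett$group)
  summary$dunnett <- ifelse(summary$group == calibratorGroup, "",
                            stars[summary$group])
  js <- list(goi = goi, refs = refs, calibrator_group = calibratorGroup,
             optimal_n = vs@optimalN, v = as.list(vs@v),
             groups = summary,
             anova = list(F = tests@anovaF, p = tests@anovaP),
             shapiro = tests@shapiro,
             reduction = if (!is.null(red)) list(
               minimal_safe_n = red@minimalSafeN,
               safe = as.list(red@safe),
               quant_shift = red@quantShift) else NULL)
  writeLines(jsonlite::toJSON(js, auto_unbox = TRUE, digits = NA,
                              null = "null", dataframe = "rows",
                              pretty = TRUE),
             file.path(outDir, "quantification.json"))
  invisible(list(expression = ne, tests = tests, reduction = red,
                 vseries = vs))
}
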
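#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

#' CqExperiment: raw quantitation-cycle measurements
#'
#' A \linkS4class{SummarizedExperiment} holding raw Cq values for candidate
#' reference genes across samples, with one assay matrix per technical
#' replicate (named \code{cq.rep1}, \code{cq.rep2}, ...). Rows are genes,
#' columns are samples. \code{rowData} carries the per-amplicon PCR
#' efficiency \code{efficiency} (per-cycle amplification factor E, 2 =
#' perfect doubling); \code{colData} carries \code{group}, \code{genotype},
#' \code{tissue} and \code{bio_rep} for every sample.
#'
#' Validity requires: at least one finite Cq per (gene, sample) unless the
#' cell is wholly missing; efficiencies strictly greater than 1 and at most
#' 2.2; no empty group labels.
#'
#' @seealso [CqExperiment()] for the constructor,
#'   [collapseTechnicalReplicates()] for the next pipeline step.
#' @export
setClass("CqExperiment", contains = "SummarizedExperiment")

#' CqTable: one Cq (or efficiency-corrected Cq) value per gene and sample
#'
#' A \linkS4class{SummarizedExperiment} with a single assay, produced by
#' [collapseTechnicalReplicates()] (scale \code{"cq"}) or
#' [efficiencyCorrect()] (scale \code{"cqe"}). Missing cells are \code{NA};
#' \code{metadata(x)$qc} records collapsing warnings and
#' \code{metadata(x)$provenance} the collapse rule used.
#'
#' @slot scale character, \code{"cq"} for raw cycles or \code{"cqe"} for
#'   efficiency-corrected cycles (equivalent perfect-doubling cycle count).
#' @export
setClass("CqTable", contains = "SummarizedExperiment",
         representation(scale = "character"),
         prototype(scale = "cq"))

setValidity("CqTable", function(object) {
  if (length(object@scale) != 1L || !object@scale %in% c("cq", "cqe"))
    return("scale must be one of 'cq', 'cqe'")
  if (length(assays(object)) != 1L)
    return("a CqTable has exactly one assay")
  TRUE
})

#' QuantityMatrix: efficiency-corrected relative quantities
#'
#' A \linkS4class{SummarizedExperiment} with assays \code{q} (relative
#' quantity, strictly positive) and \code{cqe} (the corrected Cq it was
#' derived from); \code{rowData} carries \code{calibrator_cq}, the per-gene
#' reference CqE so that \code{q = 2^(calibrator_cq - cqe)}. Under the
#' default per-gene-minimum calibrator the most abundant sample of each
#' gene has quantity 1.
#'
#' @export
setClass("QuantityMatrix", contains = "SummarizedExperiment")

setValidity("QuantityMatrix", function(object) {
  if (!all(c("q", "cqe") %in% assayNames(object)))
    return("assays 'q' and 'cqe' are required")
  q <- assay(object, "q")
  if (any(!is.finite(q)) || any(q <= 0))
    return("relative quantities must be finite and strictly positive")
  if (is.null(rowData(object)$calibrator_cq))
    return("rowData must carry calibrator_cq")
  TRUE
})

## ---- stability results -----------------------------------------------------

#' Virtual parent of the four stability-algorithm results
#'
#' All concrete results expose [stabilityScores()] (lower = more stable) and
#' [stabilityRanks()] (1 = most stable, average ranks on ties).
#'
#' @slot genes character, the gene set scored.
#' @export
setClass("StabilityResult", representation("VIRTUAL", genes = "character"))

#' geNorm result
#'
#' @slot m named numeric, gene stability value M: the mean, over all other
#'   candidates, of the standard deviation across samples of the pairwise
#'   log2 expression ratios (lower = more stable).
#' @slot pairwiseSD symmetric matrix of those pairwise log-ratio SDs.
#' @slot removalOrder genes in elimination order, least stable first.
#' @slot ranking named numeric, iterative-elimination ranks; the final pair
#'   takes ranks 1 and 2 by full-set M (lexicographic on ties).
#' @export
setClass("GeNormResult", contains = "StabilityResult",
         representation(m = "numeric", pairwiseSD = "matrix",
                        removalOrder = "character", ranking = "numeric"))

#' NormFinder result
#'
#' Model-based stability combining intra-group variance and (shrunken)
#' inter-group expression differences on the log2 scale.
#'
#' @slot rho named numeric stability value (lower = more stable).
#' @slot dBar gene x group matrix of mean per-sample-centered deviations.
#' @slot s2 gene x group sample variances of the centered values.
#' @slot sigma2Hat gene x group corrected intra-group variance estimates
#'   (truncated at zero).
#' @slot gamma2Hat estimated variance of the inter-group differences.
#' @slot dShrunk gene x group shrunken inter-group differences.
#' @slot nPerGroup samples per group.
#' @export
setClass("NormFinderResult", contains = "StabilityResult",
         representation(rho = "numeric", dBar = "matrix", s2 = "matrix",
                        sigma2Hat = "matrix", gamma2Hat = "numeric",
                        dShrunk = "matrix", nPerGroup = "integer"))

#' BestKeeper result
#'
#' Descriptive statistics of raw Cq plus Pearson correlation of each gene
#' with the BestKeeper index (per-sample geometric mean of Cq over genes).
#'
#' @slot stats data.frame with per-gene arith_mean, geo_mean, min, max,
#'   sd_cq (mean absolute deviation from the arithmetic mean, in cycles),
#'   cv_pct, r, p, and the inconsistent flag (sd_cq > 1 cycle).
#' @slot index named numeric, the BestKeeper index per sample.
#' @export
setClass("BestKeeperResult", contains = "StabilityResult",
         representation(stats = "data.frame", index = "numeric"))

#' Comparative delta-Ct result
#'
#' @slot score named numeric: mean over partner genes of the SD across
#'   samples of the pairwise Cq difference (cycles).
#' @slot pairSD symmetric matrix of the pairwise SDs.
#' @export
setClass("DeltaCtResult", contains = "StabilityResult",
         representation(score = "numeric", pairSD = "matrix"))

## ---- consensus -------------------------------------------------------------

#' RefFinder-style consensus ranking
#'
#' @slot ranks method x gene matrix of per-method ranks (average on ties).
#' @slot geomean named numeric, geometric mean of the per-method ranks.
#' @slot order genes sorted ascending by geomean (ties by arithmetic mean
#'   rank, then lexicographically).
#' @export
setClass("ConsensusRanking",
         representation(ranks = "matrix", geomean = "numeric",
                        order = "character"))

#' Pairwise-variation series V_n/n+1
#'
#' @slot v named numeric, \code{v[n]} = SD over samples of
#'   \code{log2(NF_n/NF_n+1)} for n = 2 ... nMax-1.
#' @slot nf matrix of normalization factors, one row per n.
#' @slot optimalN integer, first n with \code{v[n]} below the cutoff
#'   (adding gene n+1 is unnecessary); \code{NA} when never reached.
#' @slot cutoff numeric threshold (default 0.15).
#' @slot order the ranked gene order the NFs were built from.
#' @export
setClass("PairwiseVariationSeries",
         representation(v = "numeric", nf = "matrix", optimalN = "integer",
                        cutoff = "numeric", order = "character"))

## ---- normalization / evaluation -------------------------------------------

#' Normalized expression of a gene of interest
#'
#' @slot nf named numeric normalization factor per sample (geometric mean of
#'   the reference genes' relative quantities).
#' @slot rel named numeric normalized relative quantity of the GOI.
#' @slot fold named numeric expression ratio versus the calibrator-group
#'   mean; the calibrator group's folds average 1.
#' @slot groups factor of sample group labels.
#' @slot calibratorGroup character, e.g. "PM".
#' @slot rgSet ordered reference genes used.
#' @slot groupSummary data.frame of per-group mean fold and standard error.
#' @export
setClass("NormalizedExpression",
         representation(nf = "numeric", rel = "numeric", fold = "numeric",
                        groups = "factor", calibratorGroup = "character",
                        rgSet = "character", groupSummary = "data.frame"))

#' Group significance-test report
#'
#' Shapiro-Wilk normality per group, one-way ANOVA, Tukey HSD all-pairs
#' with a compact letter display, and two-sided Dunnett contrasts versus a
#' control group with star annotations ("*" p<0.05, "**" p<0.01).
#'
#' @slot shapiro data.frame (group, W, p).
#' @slot anovaF,anovaP one-way ANOVA F statistic and p-value.
#' @slot tukey data.frame of pairwise comparisons (diff, p_adj).
#' @slot letters named character compact letter display.
#' @slot dunnett data.frame (group, estimate, t, p_adj, stars).
#' @slot controlGroup,alpha test configuration.
#' @export
setClass("GroupTestReport",
         representation(shapiro = "data.frame", anovaF = "numeric",
                        anovaP = "numeric", tukey = "data.frame",
                        letters = "character", dunnett = "data.frame",
                        controlGroup = "character", alpha = "numeric"))

#' Stepwise reference-gene reduction report
#'
#' For each NF variant (n = nRec ... 2 genes, following the consensus
#' order) the GOI is re-normalized and re-tested; a level is safe when no
#' group shows a significant Tukey quantification shift against the
#' reference level (n = nRec) and its Dunnett star pattern is unchanged.
#'
#' @slot levels integer vector of n values, nRec first.
#' @slot foldLog2 per-level list of per-sample log2 fold values.
#' @slot quantShift data.frame (level, group, p_adj, flagged) of Tukey
#'   comparisons of each level against the reference level within a group.
#' @slot dunnettPattern per-level named character star patterns.
#' @slot safe named logical per level.
#' @slot minimalSafeN smallest n with all levels from nRec down to n safe.
#' @export
setClass("ReductionReport",
         representation(levels = "integer", foldLog2 = "list",
                        quantShift = "data.frame", dunnettPattern = "list",
                        safe = "logical", minimalSafeN = "integer",
                        controlGroup = "character"))

#' Synthetic-data configuration
#'
#' See [simConfig()] for field semantics and defaults.
#' @export
setClass("SimConfig", representation(params = "list"))
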
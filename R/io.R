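## io_model: the CqExperiment container, table readers/writers, technical
## replicate collapsing and completeness validation.

.MISSING_TOKENS <- c("NA", "NaN", "", "Undetermined", "undetermined")

#' Construct a CqExperiment
#'
#' @param cq a genes x samples x replicates numeric array, or a list of
#'   genes x samples matrices (one per technical replicate). \code{NA}
#'   marks a missing measurement.
#' @param efficiency named numeric vector of per-gene amplification
#'   efficiencies E, in (1, 2.2]; values above 2 are flagged as likely
#'   over-efficiency artifacts.
#' @param meta data.frame with one row per sample and columns
#'   \code{group}, \code{genotype}, \code{tissue}, \code{bio_rep}; row
#'   names (or a \code{sample} column) identify the samples.
#' @return a validated \linkS4class{CqExperiment}.
#' @examples
#' cq <- array(c(20, 25, 21, 26), dim = c(2, 2, 1),
#'             dimnames = list(c("G1", "G2"), c("S1", "S2"), NULL))
#' meta <- data.frame(group = c("PM", "PRO"), genotype = "CS",
#'                    tissue = "anther", bio_rep = c(1, 1),
#'                    row.names = c("S1", "S2"))
#' CqExperiment(cq, c(G1 = 1.92, G2 = 1.94), meta)
#' @export
CqExperiment <- function(cq, efficiency, meta) {
  if (is.list(cq)) {
    stopif(length(cq) == 0L, "cq needs at least one replicate matrix")
    cq <- array(unlist(cq), dim = c(dim(cq[[1]]), length(cq)),
                dimnames = c(dimnames(cq[[1]]), list(NULL)))
  }
  stopif(length(dim(cq)) != 3L, "cq must be genes x samples x replicates")
  genes <- dimnames(cq)[[1]]
  samples <- dimnames(cq)[[2]]
  stopif(is.null(genes) || is.null(samples),
         "cq must carry gene and sample dimnames")
  if (!is.null(meta$sample)) {
    rownames(meta) <- meta$sample
    meta$sample <- NULL
  }
  missingMeta <- setdiff(samples, rownames(meta))
  stopif(length(missingMeta) > 0L,
         "samples lacking metadata: ", paste(missingMeta, collapse = ", "))
  extra <- setdiff(rownames(meta), samples)
  if (length(extra) > 0L)
    warning("metadata for unknown samples ignored: ",
            paste(extra, collapse = ", "), call. = FALSE)
  meta <- meta[samples, , drop = FALSE]
  need <- c("group", "genotype", "tissue", "bio_rep")
  stopif(!all(need %in% colnames(meta)),
         "metadata must have columns ", paste(need, collapse = ", "))

  stopif(!all(genes %in% names(efficiency)),
         "missing efficiency for gene(s): ",
         paste(setdiff(genes, names(efficiency)), collapse = ", "))
  e <- efficiency[genes]
  stopif(any(!is.finite(e)) || any(e <= 1) || any(e > 2.2),
         "efficiencies must lie in (1, 2.2]")
  if (any(e > 2))
    warning("efficiency > 2 (over-efficiency artifact?) for: ",
            paste(genes[e > 2], collapse = ", "), call. = FALSE)

  vals <- cq[!is.na(cq)]
  stopif(any(!is.finite(vals)), "Cq values must be finite")
  stopif(any(vals <= 0), "Cq values must be positive")
  if (any(vals > 45))
    warning("Cq values above 45 cycles present (instrument ceiling?)",
            call. = FALSE)
  allMissing <- apply(is.na(cq), c(1, 2), all)
  if (any(allMissing))
    message(sum(allMissing), " (gene, sample) cell(s) wholly missing")

  assays <- lapply(seq_len(dim(cq)[3]), function(r) cq[, , r, drop = TRUE])
  assays <- lapply(assays, function(m) {
    dim(m) <- dim(cq)[1:2]; dimnames(m) <- dimnames(cq)[1:2]; m
  })
  names(assays) <- paste0("cq.rep", seq_along(assays))
  se <- SummarizedExperiment(
    assays = assays,
    rowData = DataFrame(efficiency = unname(e), row.names = genes),
    colData = DataFrame(meta))
  new("CqExperiment", se)
}

#' @rdname efficiencies
#' @export
setMethod("efficiencies", "SummarizedExperiment", function(x) {
  e <- rowData(x)$efficiency
  stopif(is.null(e), "no efficiencies recorded")
  stats::setNames(e, rownames(x))
})

#' @rdname sampleGroups
#' @export
setMethod("sampleGroups", "SummarizedExperiment", function(x) {
  g <- colData(x)$group
  stopif(is.null(g), "no group labels recorded")
  stats::setNames(factor(g, levels = unique(g)), colnames(x))
})

setMethod("show", "CqExperiment", function(object) {
  cat("CqExperiment:", nrow(object), "genes x", ncol(object), "samples,",
      length(assays(object)), "technical replicate(s)\n")
  cat("groups:", paste(levels(sampleGroups(object)), collapse = ", "), "\n")
  cat("efficiency range:",
      paste(signif(range(efficiencies(object)), 4), collapse = " - "), "\n")
})

setMethod("show", "CqTable", function(object) {
  cat("CqTable (", object@scale, "): ", nrow(object), " genes x ",
      ncol(object), " samples, ", sum(is.na(assay(object))),
      " missing cell(s)\n", sep = "")
})

## ---- parsing ---------------------------------------------------------------

.sniffSep <- function(path, sep) {
  if (!is.null(sep)) return(sep)
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

.readTable <- function(path, sep = NULL) {
  stopif(!file.exists(path), "file not found: ", path)
  utils::read.table(path, sep = .sniffSep(path, sep), header = TRUE,
                    colClasses = "character", check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = NULL)
}

## Parse a character column of Cq values: declared missing tokens -> NA,
## anything else non-numeric -> error locating the offending cell.
.parseNumeric <- function(x, what, rows) {
  x <- trimws(x)
  miss <- x %in% .MISSING_TOKENS
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !miss)
  stopif(length(bad) > 0L,
         "malformed numeric value in column '", what, "', data row ",
         rows[bad[1]], ": '", x[bad[1]], "'")
  v[miss] <- NA_real_
  v
}

#' Parse a Cq table with sample metadata and efficiencies
#'
#' Reads a long-format table (columns exactly \code{sample}, \code{gene},
#' \code{tech_rep}, \code{cq}) or a wide one (first column \code{gene},
#' remaining columns one per sample, a single technical replicate), plus a
#' metadata table (\code{sample}, \code{group}, \code{genotype},
#' \code{tissue}, \code{bio_rep}) and an efficiency table (\code{gene},
#' \code{efficiency}). Delimiters (tab or comma) are sniffed from the first
#' line unless \code{sep} is given. The missing-value tokens \code{NA},
#' \code{NaN}, empty cell and \code{Undetermined} mask a measurement.
#'
#' @param path Cq table path.
#' @param layout \code{"long"} or \code{"wide"}.
#' @param metaPath sample metadata path.
#' @param efficiencyPath per-gene efficiency table path; optional when
#'   \code{defaultEfficiency} is supplied.
#' @param defaultEfficiency efficiency assumed for genes absent from the
#'   efficiency table (e.g. 2 for perfect doubling); \code{NULL} makes a
#'   missing efficiency an error.
#' @param sep field delimiter override, applied to all three files.
#' @return a \linkS4class{CqExperiment}.
#' @export
parseCqTable <- function(path, layout = c("long", "wide"), metaPath,
                         efficiencyPath = NULL, defaultEfficiency = NULL,
                         sep = NULL) {
  layout <- match.arg(layout)
  tab <- .readTable(path, sep)

  if (layout == "long") {
    need <- c("sample", "gene", "tech_rep", "cq")
    stopif(!all(need %in% colnames(tab)),
           "long layout requires columns ", paste(need, collapse = ", "))
    tab$cq <- .parseNumeric(tab$cq, "cq", seq_len(nrow(tab)))
    key <- paste(tab$gene, tab$sample, tab$tech_rep, sep = "|")
    dup <- key[duplicated(key)]
    stopif(length(dup) > 0L,
           "duplicated (gene, sample, tech_rep): ", dup[1])
    genes <- unique(tab$gene)
    samples <- unique(tab$sample)
    reps <- sort(unique(tab$tech_rep))
    cq <- array(NA_real_, dim = c(length(genes), length(samples),
                                  length(reps)),
                dimnames = list(genes, samples, NULL))
    idx <- cbind(match(tab$gene, genes), match(tab$sample, samples),
                 match(tab$tech_rep, reps))
    cq[idx] <- tab$cq
  } else {
    stopif(colnames(tab)[1] != "gene", "wide layout: first column must be 'gene'")
    genes <- tab$gene
    samples <- colnames(tab)[-1]
    m <- vapply(samples, function(s) .parseNumeric(tab[[s]], s,
                                                   seq_len(nrow(tab))),
                numeric(nrow(tab)))
    m <- matrix(m, nrow = length(genes), dimnames = list(genes, samples))
    cq <- array(m, dim = c(dim(m), 1L), dimnames = c(dimnames(m), list(NULL)))
  }

  meta <- .readTable(metaPath, sep)
  stopif(is.null(meta$sample), "metadata requires a 'sample' column")

  eff <- if (!is.null(efficiencyPath)) {
    et <- .readTable(efficiencyPath, sep)
    stopif(!all(c("gene", "efficiency") %in% colnames(et)),
           "efficiency table requires columns gene, efficiency")
    stats::setNames(.parseNumeric(et$efficiency, "efficiency",
                                  seq_len(nrow(et))), et$gene)
  } else stats::setNames(numeric(0), character(0))
  missing <- setdiff(dimnames(cq)[[1]], names(eff))
  if (length(missing) > 0L) {
    stopif(is.null(defaultEfficiency),
           "missing efficiency for gene(s): ",
           paste(missing, collapse = ", "),
           " (supply defaultEfficiency to override)")
    eff[missing] <- defaultEfficiency
  }
  CqExperiment(cq, eff, meta)
}

#' Write a CqExperiment as canonical long TSV (+ metadata, + efficiencies)
#'
#' Values are written with enough precision to round-trip below 1e-9.
#'
#' @param x a \linkS4class{CqExperiment}.
#' @param path Cq table destination.
#' @param metaPath,efficiencyPath optional companion files.
#' @return \code{path}, invisibly.
#' @export
writeCqLong <- function(x, path, metaPath = NULL, efficiencyPath = NULL) {
  reps <- seq_along(assays(x))
  long <- do.call(rbind, lapply(reps, function(r) {
    m <- assay(x, r)
    data.frame(sample = rep(colnames(m), each = nrow(m)),
               gene = rep(rownames(m), times = ncol(m)),
               tech_rep = r, cq = as.vector(m))
  }))
  long <- long[!is.na(long$cq), ]
  writeTsv(long, path)
  if (!is.null(metaPath)) {
    cd <- as.data.frame(colData(x))
    writeTsv(cbind(sample = rownames(cd), cd), metaPath)
  }
  if (!is.null(efficiencyPath))
    writeTsv(data.frame(gene = rownames(x),
                        efficiency = efficiencies(x)), efficiencyPath)
  invisible(path)
}

#' JSON dump of a dataset and its QC notes
#'
#' @param x a \linkS4class{CqExperiment} or \linkS4class{CqTable}.
#' @param path destination; \code{NULL} returns the JSON string.
#' @export
writeDatasetJSON <- function(x, path = NULL) {
  obj <- list(genes = rownames(x), samples = colnames(x),
              efficiency = as.list(efficiencies(x)),
              meta = as.data.frame(colData(x)),
              assays = lapply(as.list(assays(x)), function(m)
                as.data.frame(m)),
              qc = metadata(x)$qc)
  js <- jsonlite::toJSON(obj, digits = NA, na = "null", auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

## ---- collapsing & completeness --------------------------------------------

#' Collapse technical replicates to one Cq per gene and sample
#'
#' Cells are the arithmetic mean of the available technical replicates
#' (means of Cq correspond to geometric means of quantities). Cells whose
#' replicates are all missing stay \code{NA}. Quality issues are warnings,
#' never errors: a cell left with a single replicate, and replicate
#' discordance, i.e. a within-cell Cq range above \code{discordance}
#' cycles. Details are kept in \code{metadata(result)$qc}.
#'
#' @param x a \linkS4class{CqExperiment}.
#' @param discordance replicate-disagreement threshold in cycles
#'   (default 0.5).
#' @return a \linkS4class{CqTable} on the raw Cq scale.
#' @export
collapseTechnicalReplicates <- function(x, discordance = 0.5) {
  stopif(!is(x, "CqExperiment"), "x must be a CqExperiment")
  arr <- simplify2array(as.list(assays(x)))
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  nOK <- apply(!is.na(arr), c(1, 2), sum)
  m <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  m[nOK == 0L] <- NA_real_
  rng <- suppressWarnings(
    apply(arr, c(1, 2), function(v) diff(range(v, na.rm = TRUE))))
  qc <- list()
  single <- which(nOK == 1L & dim(arr)[3] > 1L, arr.ind = TRUE)
  if (nrow(single) > 0L) {
    qc$single_replicate <- data.frame(gene = rownames(x)[single[, 1]],
                                      sample = colnames(x)[single[, 2]])
    warning(nrow(single), " cell(s) collapsed from a single replicate",
            call. = FALSE)
  }
  disc <- which(nOK >= 2L & rng > discordance, arr.ind = TRUE)
  if (nrow(disc) > 0L) {
    qc$discordant <- data.frame(gene = rownames(x)[disc[, 1]],
                                sample = colnames(x)[disc[, 2]],
                                range = rng[disc])
    warning(nrow(disc), " cell(s) with replicate disagreement > ",
            discordance, " cycles", call. = FALSE)
  }
  dimnames(m) <- dimnames(x)[1:2]
  out <- SummarizedExperiment(assays = list(cq = m), rowData = rowData(x),
                              colData = colData(x))
  out <- new("CqTable", out, scale = "cq")
  metadata(out)$provenance <- "arithmetic mean of technical replicates"
  metadata(out)$qc <- qc
  out
}

#' Restrict a CqTable to a complete gene x sample block
#'
#' With \code{policy = "strict"} any missing cell in the requested genes is
#' an error naming the offending (gene, sample) cells. With
#' \code{policy = "drop-gene"} genes carrying any missing cell are dropped
#' (the treatment needed when a candidate is not expressed in some
#' genotypes, as for a synaptonemal-complex gene absent from ph1 mutants).
#'
#' @param x a \linkS4class{CqTable}.
#' @param genes subset to keep (default all).
#' @param policy \code{"strict"} or \code{"drop-gene"}.
#' @return the complete \linkS4class{CqTable} sub-table.
#' @export
validateCompleteMatrix <- function(x, genes = rownames(x),
                                   policy = c("strict", "drop-gene")) {
  policy <- match.arg(policy)
  stopif(!all(genes %in% rownames(x)),
         "unknown gene(s): ", paste(setdiff(genes, rownames(x)), collapse = ", "))
  x <- x[genes, ]
  miss <- which(is.na(assay(x)), arr.ind = TRUE)
  if (nrow(miss) > 0L) {
    if (policy == "strict") {
      cells <- paste0("(", rownames(x)[miss[, 1]], ", ",
                      colnames(x)[miss[, 2]], ")")
      stop("missing cells: ", paste(utils::head(cells, 10), collapse = ", "),
           if (nrow(miss) > 10) " ...", call. = FALSE)
    }
    dropped <- unique(rownames(x)[miss[, 1]])
    message("dropping gene(s) with missing cells: ",
            paste(dropped, collapse = ", "))
    x <- x[setdiff(rownames(x), dropped), ]
  }
  stopif(nrow(x) == 0L, "no genes left after dropping incomplete ones")
  x
}
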
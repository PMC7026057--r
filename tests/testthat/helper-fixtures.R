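suppressPackageStartupMessages(library(SummarizedExperiment))

## Closed-form micro fixture: G1 and G2 co-vary perfectly (constant Cq
## offset), G3 is jittered. Hand-derived values:
## M1 = M2 = dCt1 = dCt2 = sqrt(2/3)/2 = 0.40825, M3 = sqrt(2/3) = 0.81650
microCq <- function() {
  m <- rbind(G1 = c(20, 21, 22, 23),
             G2 = c(25, 26, 27, 28),
             G3 = c(20, 22, 21, 23))
  colnames(m) <- paste0("S", 1:4)
  m
}

## quantities under the per-gene-minimum calibrator (E = 2)
microQ <- function() {
  cq <- microCq()
  2^(apply(cq, 1, min) - cq)
}

## small CqExperiment built in code
makeCqExperiment <- function(cq2d, efficiency = NULL, groups = NULL,
                             techReps = 1L) {
  if (is.null(efficiency))
    efficiency <- setNames(rep(2, nrow(cq2d)), rownames(cq2d))
  if (is.null(groups)) groups <- rep("A", ncol(cq2d))
  arr <- array(rep(cq2d, techReps), c(dim(cq2d), techReps),
               dimnames = c(dimnames(cq2d), list(NULL)))
  meta <- data.frame(group = groups, genotype = "CS", tissue = "anther",
                     bio_rep = seq_len(ncol(cq2d)),
                     row.names = colnames(cq2d))
  CqExperiment(arr, efficiency, meta)
}

## write a small long-format fixture set; returns the three paths
writeLongFixture <- function(dir, cq = microCq(), efficiency = NULL,
                             groups = NULL, techReps = 1L) {
  ds <- makeCqExperiment(cq, efficiency, groups, techReps)
  paths <- c(cq = file.path(dir, "cq.tsv"),
             meta = file.path(dir, "meta.tsv"),
             eff = file.path(dir, "eff.tsv"))
  writeCqLong(ds, paths["cq"], paths["meta"], paths["eff"])
  paths
}

## Independent two-loop geNorm elimination oracle: recompute every
## pairwise SD at each step with explicit loops, remove the largest-M
## gene (lexicographic ties), stop at two genes.
bruteForceGenormOrder <- function(q) {
  lq <- log2(q)
  surviving <- rownames(q)
  removed <- character(0)
  while (length(surviving) > 2) {
    m <- sapply(surviving, function(j) {
      ot <- setdiff(surviving, j)
      mean(sapply(ot, function(k) sd(lq[j, ] - lq[k, ])))
    })
    worst <- surviving[order(-m, surviving)][1]
    removed <- c(removed, worst)
    surviving <- setdiff(surviving, worst)
  }
  list(removed = removed, pair = sort(surviving))
}

## collapse -> correct -> quantities shortcut
pipelineQuantities <- function(ds) {
  relativeQuantities(efficiencyCorrect(
    suppressWarnings(collapseTechnicalReplicates(ds))))
}

## GOI quantities through the same pipeline
goiQuantities <- function(goiExperiment) {
  q <- pipelineQuantities(goiExperiment)
  assay(q, "q")[1, ]
}
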
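## synthetic_data: seeded generator of Cq datasets with known ground-truth
## stability structure, emulating a meiotic-anther RT-qPCR study design
## (4 stage groups x 3 biological x 2 technical replicates, 12 candidate
## reference genes, Cq 20-30, efficiencies 1.900-1.946).

#' Simulation configuration
#'
#' Defaults reproduce the emulated study design: 12 candidate reference
#' genes of which 9 are stable (biological noise SD 0.15 cycles) and 3
#' unstable — two with inflated noise (SD 1.0 cycles) and one carrying a
#' stage-specific shift of 1.5 cycles in one group; four meiotic stage
#' groups (PM premeiosis, PRO prophase I, TT telophase I-II, IP immature
#' pollen) with 3 biological and 2 technical replicates; baseline Cq
#' drawn uniformly in 20-30; per-sample loading factors with SD
#' \code{tau} = 0.5 cycles shared by all genes; technical-replicate SD
#' 0.1 cycles; amplification efficiencies drawn uniformly in
#' 1.900-1.946. The two unstable flavors are deliberate: pairwise methods
#' (geNorm, delta-Ct) are blind to coordinated group shifts that the
#' model-based method penalizes.
#'
#' @param kStable,kUnstable stable / unstable gene counts.
#' @param nShifted how many of the unstable genes are group-shifted
#'   rather than noisy (at most \code{kUnstable}).
#' @param groups named integer vector: biological replicates per group.
#' @param techReps technical replicates per biological sample.
#' @param muRange baseline Cq range (uniform draw), cycles.
#' @param tau SD of the per-sample loading factor, cycles.
#' @param sigmaStable,sigmaUnstable per-gene biological noise SDs, cycles.
#' @param shiftSize stage-specific shift of the shifted gene(s), cycles.
#' @param shiftGroup group receiving the shift (default the last group).
#' @param sigmaTech technical replicate SD, cycles.
#' @param efficiencyRange amplification-efficiency range (uniform draw).
#' @param goiProfile optional named per-group log2 fold profile for a
#'   gene of interest (e.g. \code{c(PM = 0, PRO = 0, TT = -1, IP = -2)}).
#' @param sigmaGoi GOI biological noise SD, cycles.
#' @param seed RNG seed; the whole dataset is deterministic given it.
#' @return a \linkS4class{SimConfig}.
#' @export
simConfig <- function(kStable = 9L, kUnstable = 3L, nShifted = 1L,
                      groups = c(PM = 3L, PRO = 3L, TT = 3L, IP = 3L),
                      techReps = 2L, muRange = c(20, 30), tau = 0.5,
                      sigmaStable = 0.15, sigmaUnstable = 1.0,
                      shiftSize = 1.5, shiftGroup = NULL, sigmaTech = 0.1,
                      efficiencyRange = c(1.900, 1.946),
                      goiProfile = NULL, sigmaGoi = 0.15, seed = 1L) {
  p <- list(kStable = as.integer(kStable), kUnstable = as.integer(kUnstable),
            nShifted = as.integer(nShifted), groups = groups,
            techReps = as.integer(techReps), muRange = muRange, tau = tau,
            sigmaStable = sigmaStable, sigmaUnstable = sigmaUnstable,
            shiftSize = shiftSize,
            shiftGroup = shiftGroup %||% names(groups)[length(groups)],
            sigmaTech = sigmaTech, efficiencyRange = efficiencyRange,
            goiProfile = goiProfile, sigmaGoi = sigmaGoi,
            seed = as.integer(seed))
  stopif(p$kStable + p$kUnstable < 1L, "need at least one gene")
  stopif(p$nShifted > p$kUnstable, "nShifted cannot exceed kUnstable")
  stopif(is.null(names(groups)) || any(groups < 1L),
         "groups must be a named vector of replicate counts")
  stopif(!p$shiftGroup %in% names(groups), "shiftGroup not among the groups")
  stopif(any(c(p$tau, p$sigmaStable, p$sigmaUnstable, p$sigmaTech,
               p$sigmaGoi) < 0), "SDs must be non-negative")
  stopif(efficiencyRange[1] <= 1 || efficiencyRange[2] > 2.2,
         "efficiencies must lie in (1, 2.2]")
  new("SimConfig", params = p)
}

setMethod("show", "SimConfig", function(object) {
  p <- object@params
  cat("SimConfig:", p$kStable, "stable +", p$kUnstable, "unstable genes (",
      p$nShifted, "group-shifted ),", sum(p$groups), "samples x",
      p$techReps, "tech reps, seed", p$seed, "\n")
})

#' Simulate a Cq dataset with known stability structure
#'
#' The latent model per gene g and sample s is
#' \code{CqE[g,s] = mu[g] + lambda[s] + shift[g, group(s)] + b[g,s]}
#' with loading factors \code{lambda ~ N(0, tau^2)} shared across genes,
#' biological noise \code{b ~ N(0, sigma_g^2)} and stage shifts only for
#' the shifted gene(s). Raw Cq follows by inverting the efficiency
#' correction, \code{Cq = CqE * log(2)/log(E_g)}, and each technical
#' replicate adds \code{N(0, sigmaTech^2)}. All draws happen in a fixed
#' documented order (efficiencies, baselines, loadings, biological noise,
#' technical noise, GOI sub-seed), so a seed fully determines the output.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @return list with \code{dataset} (a \linkS4class{CqExperiment}) and
#'   \code{truth}: per-gene parameters as drawn, the loading factors, the
#'   noise-free-of-technical-error CqE matrix, the true stability order
#'   (stable genes first, by increasing total instability
#'   \code{sqrt(sigma^2 + var_s(shift))}), and the sub-seed reserved for
#'   [simulateGoi()].
#' @export
simulateCqDataset <- function(cfg) {
  stopif(!is(cfg, "SimConfig"), "cfg must be a SimConfig")
  p <- cfg@params
  set.seed(p$seed)
  k <- p$kStable + p$kUnstable
  genes <- sprintf("RG%02d", seq_len(k))
  type <- c(rep("stable", p$kStable),
            rep("noisy", p$kUnstable - p$nShifted),
            rep("shifted", p$nShifted))
  sigma <- ifelse(type == "noisy", p$sigmaUnstable, p$sigmaStable)
  groupOf <- rep(names(p$groups), times = p$groups)
  samples <- unlist(lapply(names(p$groups), function(g)
    paste0(g, "_b", seq_len(p$groups[[g]]))))
  nS <- length(samples)

  eff <- stats::setNames(stats::runif(k, p$efficiencyRange[1],
                                      p$efficiencyRange[2]), genes)
  mu <- stats::setNames(stats::runif(k, p$muRange[1], p$muRange[2]), genes)
  lambda <- stats::setNames(p$tau * stats::rnorm(nS), samples)
  shift <- matrix(0, k, length(p$groups),
                  dimnames = list(genes, names(p$groups)))
  shift[type == "shifted", p$shiftGroup] <- p$shiftSize
  b <- matrix(stats::rnorm(k * nS), k, nS) * sigma
  cqe <- mu + shift[, groupOf, drop = FALSE] + b +
    rep(lambda, each = k)
  dimnames(cqe) <- list(genes, samples)
  rawCq <- cqe * log(2) / log(eff)          # invert the CqE rescaling
  tech <- array(stats::rnorm(k * nS * p$techReps), c(k, nS, p$techReps)) *
    p$sigmaTech
  cq <- array(rawCq, c(k, nS, p$techReps)) + tech
  dimnames(cq) <- list(genes, samples, NULL)
  goiSeed <- sample.int(.Machine$integer.max - 1L, 1L)

  tissue <- ifelse(groupOf %in% c("L", "R"),
                   c(L = "leaf", R = "root")[groupOf], "anther")
  meta <- data.frame(group = groupOf, genotype = "CS", tissue = tissue,
                     bio_rep = unlist(lapply(p$groups, seq_len)),
                     row.names = samples)
  dataset <- CqExperiment(cq, eff, meta)

  instability <- sqrt(sigma^2 + apply(shift[, groupOf, drop = FALSE], 1,
                                      function(z) mean((z - mean(z))^2)))
  truth <- list(genes = genes, type = type, sigma = sigma, mu = mu,
                lambda = lambda, efficiency = eff, shift = shift,
                cqe = cqe, samples = samples, groups = groupOf,
                instability = stats::setNames(instability, genes),
                trueStabilityOrder = genes[order(instability, genes)],
                goiSeed = goiSeed)
  list(dataset = dataset, truth = truth)
}

#' Simulate a gene of interest sharing the dataset's loading factors
#'
#' Generates a one-gene \linkS4class{CqExperiment} for a gene of interest
#' whose latent CqE uses the same per-sample loading factors as the
#' reference-gene dataset (so normalization can remove them) plus the
#' configured per-group log2 fold profile: a group at log2 fold f is
#' shifted by -f cycles on the CqE scale. Deterministic given the parent
#' dataset's seed (a dedicated sub-seed is drawn during
#' [simulateCqDataset()]).
#'
#' @param cfg the \linkS4class{SimConfig} used for the dataset (its
#'   \code{goiProfile} must be set).
#' @param truth the ground truth returned by [simulateCqDataset()].
#' @param name gene name (default "GOI").
#' @return a one-gene \linkS4class{CqExperiment} over the same samples.
#' @export
simulateGoi <- function(cfg, truth, name = "GOI") {
  stopif(!is(cfg, "SimConfig"), "cfg must be a SimConfig")
  p <- cfg@params
  stopif(is.null(p$goiProfile), "cfg has no goiProfile")
  stopif(!all(names(p$groups) %in% names(p$goiProfile)),
         "goiProfile must cover every group")
  set.seed(truth$goiSeed)
  nS <- length(truth$samples)
  mu <- stats::runif(1, p$muRange[1], p$muRange[2])
  eff <- stats::runif(1, p$efficiencyRange[1], p$efficiencyRange[2])
  b <- p$sigmaGoi * stats::rnorm(nS)
  cqe <- mu + truth$lambda - p$goiProfile[truth$groups] + b
  rawCq <- cqe * log(2) / log(eff)
  tech <- matrix(stats::rnorm(nS * p$techReps), nS) * p$sigmaTech
  cq <- array(rawCq + tech, c(1L, nS, p$techReps),
              dimnames = list(name, truth$samples, NULL))
  tissue <- ifelse(truth$groups %in% c("L", "R"),
                   c(L = "leaf", R = "root")[truth$groups], "anther")
  meta <- data.frame(group = truth$groups, genotype = "CS",
                     tissue = tissue,
                     bio_rep = sub(".*_b", "", truth$samples),
                     row.names = truth$samples)
  CqExperiment(cq, stats::setNames(eff, name), meta)
}

#' Write a simulated dataset as the standard input files
#'
#' Emits the long-format Cq TSV, the sample metadata TSV and the
#' efficiency TSV consumed by [parseCqTable()], plus the ground truth as
#' JSON. When the configuration defines a GOI profile, the GOI row is
#' appended to the Cq and efficiency tables.
#'
#' @param sim result of [simulateCqDataset()].
#' @param outDir destination directory (created if needed).
#' @param cfg the \linkS4class{SimConfig}; needed to append a GOI.
#' @return named character vector of the written paths, invisibly.
#' @export
writeSimulation <- function(sim, outDir, cfg = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cq = file.path(outDir, "cq_long.tsv"),
             meta = file.path(outDir, "samples.tsv"),
             efficiency = file.path(outDir, "efficiencies.tsv"),
             truth = file.path(outDir, "ground_truth.json"))
  ds <- sim$dataset
  if (!is.null(cfg) && !is.null(cfg@params$goiProfile)) {
    goi <- simulateGoi(cfg, sim$truth)
    arr <- simplify2array(as.list(assays(ds)))
    garr <- simplify2array(as.list(assays(goi)))
    if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
    if (length(dim(garr)) == 2L) dim(garr) <- c(dim(garr), 1L)
    comb <- array(NA_real_, dim = dim(arr) + c(1, 0, 0),
                  dimnames = list(c(rownames(ds), rownames(goi)),
                                  colnames(ds), NULL))
    comb[rownames(ds), , ] <- arr
    comb[rownames(goi), , ] <- garr
    ds <- CqExperiment(comb, c(efficiencies(ds), efficiencies(goi)),
                       as.data.frame(colData(ds)))
  }
  writeCqLong(ds, paths["cq"], paths["meta"], paths["efficiency"])
  truth <- sim$truth
  truth$shift <- as.data.frame(truth$shift)
  truth$cqe <- as.data.frame(truth$cqe)
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE),
             paths["truth"])
  invisible(paths)
}
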
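test_that("simulation is deterministic and respects its configuration", {
  cfg <- simConfig(seed = 5)
  a <- simulateCqDataset(cfg)
  b <- simulateCqDataset(cfg)
  expect_identical(assay(a$dataset, 1), assay(b$dataset, 1))
  expect_identical(a$truth$lambda, b$truth$lambda)
  expect_equal(dim(a$dataset), c(12L, 12L))
  expect_equal(length(assays(a$dataset)), 2L)
  expect_true(all(efficiencies(a$dataset) >= 1.900 &
                    efficiencies(a$dataset) <= 1.946))
  expect_equal(as.character(unique(sampleGroups(a$dataset))),
               c("PM", "PRO", "TT", "IP"))
  ## stable genes precede unstable in the true stability order
  unstable <- a$truth$genes[a$truth$type != "stable"]
  expect_true(all(match(unstable, a$truth$trueStabilityOrder) > 9))
  ## a different seed changes the data
  expect_false(identical(assay(simulateCqDataset(simConfig(seed = 6))$dataset, 1),
                         assay(a$dataset, 1)))
})

test_that("noise-free limit collapses to constant rows and zero scores", {
  cfg <- simConfig(tau = 0, sigmaStable = 0, sigmaUnstable = 0,
                   shiftSize = 0, sigmaTech = 0, seed = 2)
  sim <- simulateCqDataset(cfg)
  cq <- assay(sim$dataset, 1)
  expect_true(all(apply(cq, 1, function(r) diff(range(r))) < 1e-12))
  q <- pipelineQuantities(sim$dataset)
  expect_true(all(stabilityScores(geNorm(q)) < 1e-12))
  expect_true(all(stabilityScores(deltaCt(assay(q, "cqe"))) < 1e-12))
})

test_that("raw Cq inverts the efficiency correction back to the latent CqE", {
  cfg <- simConfig(sigmaTech = 0, seed = 9)
  sim <- simulateCqDataset(cfg)
  ct <- collapseTechnicalReplicates(sim$dataset)
  cqe <- efficiencyCorrect(ct)
  expect_equal(assay(cqe), sim$truth$cqe, tolerance = 1e-9)
})

test_that("normalization removes the loading factors exactly when noise-free", {
  profile <- c(PM = 0, PRO = 0, TT = -1, IP = -2)
  cfg <- simConfig(tau = 2, sigmaStable = 0, sigmaUnstable = 0,
                   shiftSize = 0, sigmaTech = 0, sigmaGoi = 0,
                   goiProfile = profile, seed = 3)
  sim <- simulateCqDataset(cfg)
  q <- pipelineQuantities(sim$dataset)
  goiQ <- goiQuantities(simulateGoi(cfg, sim$truth))
  ne <- normalizeExpression(q, "GOI", rownames(q)[1:3], "PM", goiQ = goiQ)
  expect_equal(unname(log2(ne@groupSummary$mean_fold)), unname(profile),
               tolerance = 1e-9)
  expect_true(all(abs(log2(ne@fold) -
                        profile[as.character(ne@groups)]) < 1e-9))
})

test_that("inflating a gene's noise degrades its rank in all four methods", {
  worseRank <- function(sigma, seed) {
    cfg <- simConfig(kStable = 7, kUnstable = 1, nShifted = 0,
                     sigmaUnstable = sigma, seed = seed)
    sim <- simulateCqDataset(cfg)
    rk <- suppressWarnings(rankStability(sim$dataset))
    noisy <- sim$truth$genes[sim$truth$type == "noisy"]
    vapply(c("genorm", "normfinder", "bestkeeper", "deltact"),
           function(m) unname(stabilityRanks(rk[[m]])[noisy]), numeric(1))
  }
  for (s in 1:3) {
    low <- worseRank(0.4, s)
    high <- worseRank(2.0, s)
    expect_true(all(high >= low),
                label = paste("seed", s, ": ranks",
                              paste(low, collapse = ","), "->",
                              paste(high, collapse = ",")))
  }
})

test_that("the GOI shares loading and answers to its profile", {
  cfg <- simConfig(goiProfile = c(PM = 0, PRO = 0, TT = -1, IP = -2),
                   seed = 4)
  sim <- simulateCqDataset(cfg)
  goi <- simulateGoi(cfg, sim$truth)
  expect_equal(colnames(goi), colnames(sim$dataset))
  expect_identical(assay(goi, 1), assay(simulateGoi(cfg, sim$truth), 1))
  expect_error(simulateGoi(simConfig(seed = 4), sim$truth), "goiProfile")
})

test_that("written simulation files parse back through the io layer", {
  d <- withr::local_tempdir()
  cfg <- simConfig(goiProfile = c(PM = 0, PRO = 0, TT = -1, IP = -2),
                   seed = 10)
  sim <- simulateCqDataset(cfg)
  paths <- writeSimulation(sim, d, cfg)
  expect_true(all(file.exists(paths)))
  back <- parseCqTable(paths["cq"], "long", paths["meta"],
                       paths["efficiency"])
  expect_true("GOI" %in% rownames(back))
  expect_equal(assay(back, 1)[rownames(sim$dataset), colnames(sim$dataset)],
               assay(sim$dataset, 1), tolerance = 1e-9)
  truth <- jsonlite::read_json(paths["truth"])
  expect_equal(unlist(truth$trueStabilityOrder),
               sim$truth$trueStabilityOrder, ignore_attr = TRUE)
})

test_that("configuration validation rejects impossible designs", {
  expect_error(simConfig(kStable = 2, kUnstable = 1, nShifted = 2),
               "nShifted")
  expect_error(simConfig(tau = -1), "non-negative")
  expect_error(simConfig(efficiencyRange = c(0.9, 1.9)), "efficienc")
  expect_error(simConfig(groups = c(3, 3)), "named")
})
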
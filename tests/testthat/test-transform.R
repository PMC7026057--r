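test_that("efficiency correction rescales Cq by log2(E)", {
  expect_identical(efficiencyCorrect(30, 2), 30)
  expect_equal(efficiencyCorrect(25, 1.9), 25 * log(1.9) / log(2),
               tolerance = 1e-12)
  expect_equal(efficiencyCorrect(25, 1.9), 23.14998, tolerance = 1e-5)
  expect_identical(efficiencyCorrect(0, 1.5), 0)
  expect_error(efficiencyCorrect(20, 1), "efficiency")
  expect_error(efficiencyCorrect(20, 0.9), "efficiency")
})

test_that("table-level correction applies per-gene efficiencies row-wise", {
  eff <- c(G1 = 2, G2 = 1.9, G3 = 1.95)
  ds <- makeCqExperiment(microCq(), efficiency = eff)
  ct <- collapseTechnicalReplicates(ds)
  cqe <- efficiencyCorrect(ct)
  expect_s4_class(cqe, "CqTable")
  expect_identical(cqe@scale, "cqe")
  expect_equal(assay(cqe)["G1", ], microCq()["G1", ])       # E = 2 identity
  expect_equal(assay(cqe)["G2", ], microCq()["G2", ] * log2(1.9))
  expect_error(efficiencyCorrect(cqe), "already")
})

test_that("relative quantities follow 2^(calibrator - cqe)", {
  cqe <- rbind(G1 = c(20, 21, 22, 23), G2 = c(25, 25, 25, 25))
  colnames(cqe) <- paste0("S", 1:4)
  ds <- makeCqExperiment(cqe)
  q <- relativeQuantities(efficiencyCorrect(collapseTechnicalReplicates(ds)))
  expect_equal(unname(assay(q, "q")["G1", ]), c(1, 0.5, 0.25, 0.125))
  expect_equal(unname(assay(q, "q")["G2", ]), rep(1, 4))
  expect_equal(unname(rowData(q)$calibrator_cq), c(20, 25))

  qfix <- relativeQuantities(
    efficiencyCorrect(collapseTechnicalReplicates(ds)),
    calibratorCq = c(G1 = 20, G2 = 24))
  expect_equal(unname(assay(qfix, "q")["G2", ]), rep(0.5, 4))
})

test_that("missing cells are rejected with a pointer to validation", {
  holed <- microCq()
  holed["G2", "S3"] <- NA
  arr <- array(holed, c(dim(holed), 1), dimnames = c(dimnames(holed),
                                                     list(NULL)))
  meta <- data.frame(group = "PM", genotype = "CS", tissue = "anther",
                     bio_rep = 1:4, row.names = colnames(holed))
  ds <- suppressMessages(
    CqExperiment(arr, setNames(rep(2, 3), rownames(holed)), meta))
  ct <- suppressWarnings(collapseTechnicalReplicates(ds))
  expect_error(relativeQuantities(efficiencyCorrect(ct)),
               "validateCompleteMatrix")
})

test_that("log2 quantity differences are calibrator-invariant", {
  set.seed(11)
  cqe <- matrix(runif(20, 20, 30), 4, 5,
                dimnames = list(paste0("G", 1:4), paste0("S", 1:5)))
  ds <- makeCqExperiment(cqe)
  ct <- efficiencyCorrect(collapseTechnicalReplicates(ds))
  qmin <- assay(relativeQuantities(ct), "q")
  qfix <- assay(relativeQuantities(ct, calibratorCq = setNames(
    runif(4, 15, 35), paste0("G", 1:4))), "q")
  for (g in 1:4) {
    dmin <- log2(qmin[g, 1]) - log2(qmin[g, -1])
    dfix <- log2(qfix[g, 1]) - log2(qfix[g, -1])
    expect_equal(dmin, dfix, tolerance = 1e-9)
    expect_equal(unname(dmin), unname(cqe[g, -1] - cqe[g, 1]),
                 tolerance = 1e-9)
  }
})

test_that("stability scores are invariant to the calibrator choice", {
  set.seed(12)
  cqe <- matrix(runif(24, 20, 30), 4, 6,
                dimnames = list(paste0("G", 1:4), paste0("S", 1:6)))
  ds <- makeCqExperiment(cqe, groups = rep(c("PM", "IP"), each = 3))
  ct <- efficiencyCorrect(collapseTechnicalReplicates(ds))
  q1 <- relativeQuantities(ct)
  q2 <- relativeQuantities(ct, calibratorCq = setNames(runif(4, 10, 40),
                                                       paste0("G", 1:4)))
  expect_equal(stabilityScores(geNorm(q1)), stabilityScores(geNorm(q2)),
               tolerance = 1e-9)
  expect_equal(stabilityScores(normFinder(q1)),
               stabilityScores(normFinder(q2)), tolerance = 1e-9)
})
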
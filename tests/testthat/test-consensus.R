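test_that("method ranks map ascending scores to 1..k with average ties", {
  r <- methodRanks(list(m1 = c(A = 0.1, B = 0.3, C = 0.2)))
  expect_equal(unname(r["m1", c("A", "B", "C")]), c(1, 3, 2))
  r2 <- methodRanks(list(m1 = c(A = 0.1, B = 0.1, C = 0.5)))
  expect_equal(unname(r2["m1", c("A", "B", "C")]), c(1.5, 1.5, 3))
  expect_error(methodRanks(list(m1 = c(A = 1, B = 2),
                                m2 = c(A = 1, C = 2))),
               "different gene set")
})

test_that("consensus geometric mean, ordering and tie-breaks", {
  ranks <- rbind(geNorm = c(A = 1, B = 2, C = 3),
                 NormFinder = c(A = 2, B = 1, C = 3),
                 BestKeeper = c(A = 1.5, B = 2, C = 3),
                 deltaCt = c(A = 1, B = 2, C = 3))
  cons <- refFinderConsensus(ranks = ranks)
  expect_equal(unname(cons@geomean["A"]), (1 * 2 * 1.5 * 1)^(1 / 4),
               tolerance = 1e-9)
  expect_equal(unname(cons@geomean["A"]), 1.3161, tolerance = 1e-4)
  expect_equal(cons@order, c("A", "B", "C"))

  ## identical rankings across methods -> consensus equals that ranking
  same <- matrix(rep(c(C = 1, A = 2, B = 3)[c("A", "B", "C")], 4),
                 4, 3, byrow = TRUE,
                 dimnames = list(paste0("m", 1:4), c("A", "B", "C")))
  conss <- refFinderConsensus(ranks = same)
  expect_equal(conss@order, c("C", "A", "B"))
  expect_equal(unname(conss@geomean), unname(same[1, ]))

  ## a gene ranked 1 everywhere is first; method order is irrelevant
  expect_equal(cons@geomean,
               refFinderConsensus(ranks = ranks[c(3, 1, 4, 2), ])@geomean)
  expect_error(refFinderConsensus(ranks = ranks[1:3, ]), "four methods")
})

test_that("consensus from the four result objects uses geNorm elimination ranks", {
  set.seed(13)
  cqe <- matrix(runif(60, 20, 30), 6, 10,
                dimnames = list(paste0("G", 1:6), paste0("S", 1:10)))
  ds <- makeCqExperiment(cqe, groups = rep(c("PM", "IP"), each = 5))
  rk <- rankStability(ds)
  expect_s4_class(rk$consensus, "ConsensusRanking")
  expect_equal(unname(rk$consensus@ranks["geNorm", ]),
               unname(stabilityRanks(rk$genorm)[colnames(rk$consensus@ranks)]))
  expect_setequal(rk$consensus@order, paste0("G", 1:6))
  tbl <- scoreTable(rk$consensus)
  expect_equal(tbl$consensus_rank, 1:6)
})

test_that("optimal reference-gene count follows the first V below cutoff", {
  ## all genes identical -> v all 0, optimal n = 2
  qi <- matrix(1, 4, 6, dimnames = list(paste0("G", 1:4), paste0("S", 1:6)))
  pv <- optimalRgCount(qi, paste0("G", 1:4))
  expect_identical(pv@optimalN, 2L)

  ## a series crossing the cutoff later: check first-below semantics
  set.seed(14)
  base <- rnorm(8)
  q <- rbind(G1 = base, G2 = base + rnorm(8, sd = 0.9),
             G3 = base + rnorm(8, sd = 0.05),
             G4 = base + rnorm(8, sd = 0.05))
  q <- 2^q; colnames(q) <- paste0("S", 1:8)
  pv2 <- optimalRgCount(q, c("G1", "G2", "G3", "G4"), cutoff = 0.15)
  firstBelow <- which(pv2@v < 0.15)[1]
  expect_equal(pv2@optimalN, c(2L, 3L)[firstBelow])

  ## cutoff never reached -> NA and a warning recommending the full set
  expect_warning(pv3 <- optimalRgCount(q, c("G1", "G2", "G3", "G4"),
                                       cutoff = 1e-9), "cutoff")
  expect_true(is.na(pv3@optimalN))
  expect_error(optimalRgCount(qi, c("G1", "G2")), "3 ranked genes")
})
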
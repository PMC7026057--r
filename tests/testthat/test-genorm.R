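test_that("micro example reproduces hand-computed M and removal order", {
  gn <- geNorm(microQ())
  expect_equal(unname(stabilityScores(gn)[c("G1", "G2")]),
               rep(sqrt(2 / 3) / 2, 2), tolerance = 1e-9)
  expect_equal(unname(stabilityScores(gn)["G3"]), sqrt(2 / 3),
               tolerance = 1e-9)
  expect_equal(gn@removalOrder[1], "G3")
  expect_equal(sort(names(which(gn@ranking <= 2))), c("G1", "G2"))
  ## co-varying pair has zero pairwise variation
  expect_equal(gn@pairwiseSD["G1", "G2"], 0)
  expect_true(all(diag(gn@pairwiseSD) == 0))
  expect_equal(gn@pairwiseSD, t(gn@pairwiseSD))
})

test_that("degenerate and invalid inputs are handled", {
  q <- matrix(1, 3, 4, dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
  gn <- geNorm(q)
  expect_true(all(stabilityScores(gn) == 0))
  expect_equal(gn@removalOrder, c("G3", "G2", "G1"))  # lexicographic ties
  expect_error(geNorm(q[1:2, ]), "3 genes")
  expect_error(geNorm(-q), "positive")
})

test_that("M is invariant to per-gene scaling and sample order", {
  set.seed(5)
  q <- matrix(2^rnorm(30), 5, 6,
              dimnames = list(paste0("G", 1:5), paste0("S", 1:6)))
  m0 <- stabilityScores(geNorm(q))
  qs <- q; qs[2, ] <- qs[2, ] * 37.5
  expect_equal(stabilityScores(geNorm(qs)), m0, tolerance = 1e-9)
  expect_equal(stabilityScores(geNorm(q[, sample(6)])), m0,
               tolerance = 1e-9)
})

test_that("iterative removal order matches the brute-force oracle", {
  set.seed(99)
  for (i in 1:10) {
    q <- matrix(2^rnorm(36, sd = runif(1, 0.2, 1.5)), 6, 6,
                dimnames = list(paste0("G", 1:6), paste0("S", 1:6)))
    gn <- geNorm(q)
    bf <- bruteForceGenormOrder(q)
    expect_equal(gn@removalOrder[1:4], bf$removed)
    expect_equal(sort(names(which(gn@ranking <= 2))), bf$pair)
  }
})

test_that("pairwise variation matches the closed forms", {
  ## duplicated top gene: log2(NF2/NF3) = (1/6) log2(q1/q2)
  q <- rbind(A = microQ()["G1", ], B = microQ()["G3", ],
             C = microQ()["G1", ])
  pv <- geNormPairwiseVariation(q, order = c("A", "B", "C"))
  expect_equal(unname(pv@v["V2/3"]), sqrt(2 / 3) / 6, tolerance = 1e-9)

  ## identical genes: every V is zero and optimal n is 2
  qi <- matrix(0.5, 4, 5, dimnames = list(paste0("G", 1:4),
                                          paste0("S", 1:5)))
  pvi <- geNormPairwiseVariation(qi)
  expect_true(all(pvi@v == 0))
  expect_identical(pvi@optimalN, 2L)

  ## NF_n is symmetric in the top-n genes
  set.seed(3)
  qr <- matrix(2^rnorm(24), 4, 6, dimnames = list(paste0("G", 1:4),
                                                  paste0("S", 1:6)))
  a <- suppressWarnings(
    geNormPairwiseVariation(qr, order = c("G1", "G2", "G3", "G4")))
  b <- suppressWarnings(
    geNormPairwiseVariation(qr, order = c("G2", "G1", "G3", "G4")))
  expect_equal(unname(a@nf["NF2", ]), unname(b@nf["NF2", ]),
               tolerance = 1e-12)
  expect_equal(unname(a@v["V3/4"]), unname(b@v["V3/4"]), tolerance = 1e-12)

  expect_error(geNormPairwiseVariation(qr, nMax = 2), "nMax")
  ## infinite cutoff always stops at n = 2
  expect_identical(geNormPairwiseVariation(qr, cutoff = Inf)@optimalN, 2L)
  ## cutoff never met -> undefined with a warning
  expect_warning(pvn <- geNormPairwiseVariation(qr, cutoff = 1e-6),
                 "cutoff")
  expect_true(is.na(pvn@optimalN))
})
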
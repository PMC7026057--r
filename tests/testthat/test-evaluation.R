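test_that("letter display agrees with the pairwise significance matrix", {
  letterDisplay <- CqStability:::letterDisplay
  set.seed(61)
  for (i in 1:20) {
    k <- sample(3:6, 1)
    groups <- LETTERS[1:k]
    sig <- matrix(FALSE, k, k, dimnames = list(groups, groups))
    for (a in 1:(k - 1)) for (b in (a + 1):k) {
      s <- runif(1) < 0.4
      sig[a, b] <- sig[b, a] <- s
    }
    ld <- letterDisplay(groups, sig)
    for (a in 1:(k - 1)) for (b in (a + 1):k) {
      shared <- length(intersect(strsplit(ld[a], "")[[1]],
                                 strsplit(ld[b], "")[[1]])) > 0
      expect_identical(shared, !sig[a, b],
                       label = paste("pair", groups[a], groups[b],
                                     "display", ld[a], ld[b]))
    }
  }
})

test_that("identical values across groups give the global-null report", {
  gt <- groupTests(rep(2, 12), rep(c("PM", "PRO", "TT", "IP"), each = 3),
                   "PM")
  expect_equal(gt@anovaP, 1)
  expect_true(all(gt@letters == "a"))
  expect_true(all(gt@dunnett$stars == ""))
  expect_true(all(is.na(gt@shapiro$W)))  # zero-range groups
})

test_that("widely separated groups earn Dunnett double stars", {
  set.seed(62)
  v <- c(rnorm(3, 10, 0.1), rnorm(3, 11, 0.1))  # 10 SDs apart
  gt <- groupTests(2^v, rep(c("PM", "IP"), each = 3), "PM")
  expect_equal(gt@dunnett$stars[gt@dunnett$group == "IP"], "**")
  expect_false(gt@letters["PM"] == gt@letters["IP"])
  expect_lt(gt@anovaP, 0.01)
})

test_that("group tests validate their inputs", {
  expect_error(groupTests(1:4, c("A", "A", "A", "B"), "A"),
               ">= 2 replicates")
  expect_error(groupTests(1:4, rep("A", 4), "A"), "2 groups")
  expect_error(groupTests(1:4, rep(c("A", "B"), 2), "C"), "absent")
  expect_error(groupTests(c(-1, 1, 2, 3), rep(c("A", "B"), 2), "A"),
               "positive")
})

test_that("Dunnett holds its nominal level under a simulated null", {
  set.seed(63)
  reps <- 300
  hits <- 0L
  for (i in seq_len(reps)) {
    v <- rnorm(12)
    gt <- CqStability:::.dunnettTest(v, rep(c("PM", "PRO", "TT", "IP"),
                                            each = 3), "PM")
    if (any(gt$p_adj < 0.05)) hits <- hits + 1L
  }
  ## family-wise error ~ 0.05; allow 3 binomial SDs
  expect_lte(hits / reps, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("reduction study: interchangeable stable RGs are all safe", {
  ## noise-free: GOI flat, RGs exact duplicates up to scale
  set.seed(65)
  base <- 2^rnorm(12)
  q <- rbind(R1 = base, R2 = base * 2, R3 = base / 3, R4 = base,
             GOI = base * 5)
  colnames(q) <- paste0("S", 1:12)
  groups <- rep(c("PM", "PRO", "TT", "IP"), each = 3)
  rr <- reductionStudy(q, "GOI", paste0("R", 1:4), 4, "PM",
                       groups = groups)
  expect_identical(rr@minimalSafeN, 2L)
  expect_true(all(rr@safe))
  expect_false(any(rr@quantShift$flagged))

  expect_error(reductionStudy(q, "GOI", c("GOI", "R1", "R2"), 3, "PM",
                              groups = groups), "self-normalization")
  ## nRec = 2 -> single level, trivially safe
  rr2 <- reductionStudy(q, "GOI", paste0("R", 1:4), 2, "PM",
                        groups = groups)
  expect_identical(rr2@minimalSafeN, 2L)
  expect_equal(rr2@levels, 2L)
})

test_that("dropping a group-shifted RG from the NF flags a quantification shift", {
  set.seed(64)
  groups <- rep(c("PM", "PRO", "TT", "IP"), each = 3)
  lgq <- rbind(R1 = rnorm(12, sd = 0.05), R2 = rnorm(12, sd = 0.05),
               R3 = rnorm(12, sd = 0.05) + 2 * (groups == "IP"),
               GOI = rnorm(12, sd = 0.05))
  q <- 2^lgq; colnames(q) <- paste0("S", 1:12)
  rr <- reductionStudy(q, "GOI", c("R1", "R2", "R3"), 3, "PM",
                       groups = groups)
  flagged <- rr@quantShift[rr@quantShift$flagged, ]
  expect_true(any(flagged$group == "IP" & flagged$level == 2))
  expect_identical(rr@minimalSafeN, 3L)
})
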
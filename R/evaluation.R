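## evaluation: normality/ANOVA/Tukey/Dunnett testing of normalized
## expression and the stepwise reference-gene reduction study.

.stars <- function(p) ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))

## Compact letter display by insert-absorb on the significance matrix:
## start from one set holding every group; for each significant pair,
## split every set containing both; absorb subsets. Two groups share a
## letter iff their comparison is non-significant.
letterDisplay <- function(groups, sig) {
  stopif(!is.matrix(sig) || !identical(rownames(sig), groups) ||
           !identical(colnames(sig), groups),
         "sig must be a square logical matrix over the groups")
  sets <- list(groups)
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (j <= i || !isTRUE(sig[i, j])) next
      a <- groups[i]; b <- groups[j]
      out <- list()
      for (s in sets) {
        if (a %in% s && b %in% s) {
          out <- c(out, list(setdiff(s, a)), list(setdiff(s, b)))
        } else out <- c(out, list(s))
      }
      out <- out[!duplicated(lapply(out, sort))]
      keep <- vapply(seq_along(out), function(m)
        !any(vapply(seq_along(out), function(l)
          l != m && all(out[[m]] %in% out[[l]]) &&
            !(all(out[[l]] %in% out[[m]])), logical(1))), logical(1))
      sets <- out[keep]
    }
  }
  ## order letters by the first group each set contains
  ord <- order(vapply(sets, function(s) min(match(s, groups)), numeric(1)))
  sets <- sets[ord]
  vapply(groups, function(g)
    paste(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
          collapse = ""), character(1))
}

## Two-sided Dunnett contrasts vs the control group (single-step adjusted
## p) via multcomp; a fixed local seed keeps the quasi-randomized
## multivariate-t integration reproducible.
.dunnettTest <- function(v, groups, control) {
  groups <- stats::relevel(factor(groups), ref = control)
  d <- data.frame(v = v, g = groups)
  if (stats::var(v) < 1e-20) {
    lev <- setdiff(levels(groups), control)
    return(data.frame(group = lev, estimate = 0, t = 0, p_adj = 1,
                      stars = "", row.names = NULL))
  }
  fit <- stats::aov(v ~ g, data = d)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  sm <- withLocalSeed(20240915L, summary(gl))
  lev <- sub(" - .*", "", names(sm$test$coefficients))
  data.frame(group = lev,
             estimate = unname(sm$test$coefficients),
             t = unname(sm$test$tstat),
             p_adj = unname(as.numeric(sm$test$pvalues)),
             stars = .stars(unname(as.numeric(sm$test$pvalues))),
             row.names = NULL)
}

#' Group significance tests on normalized expression
#'
#' Runs, on (by default) log2-transformed values: Shapiro-Wilk normality
#' per group, one-way ANOVA across groups, Tukey HSD on all pairs with a
#' compact letter display (groups share a letter iff not significantly
#' different at \code{alpha}), and two-sided Dunnett contrasts against the
#' control group with star annotations ("*" p < 0.05, "**" p < 0.01).
#' Fold-change ratios are log-normal under the generative model, hence the
#' log2 default; the Shapiro-Wilk results let users judge.
#'
#' @param values per-sample quantities (e.g. fold changes), positive when
#'   \code{log2Transform}.
#' @param groups group labels (>= 2 groups, >= 2 replicates each).
#' @param controlGroup the Dunnett control (e.g. the calibrator group).
#' @param log2Transform analyze log2(values) (default TRUE).
#' @param alpha significance level (default 0.05).
#' @return a \linkS4class{GroupTestReport}.
#' @export
groupTests <- function(values, groups, controlGroup, log2Transform = TRUE,
                       alpha = 0.05) {
  groups <- factor(groups, levels = unique(as.character(groups)))
  stopif(length(values) != length(groups), "one group label per value required")
  stopif(nlevels(groups) < 2L, "need at least 2 groups")
  stopif(any(table(groups) < 2L), "every group needs >= 2 replicates")
  stopif(!controlGroup %in% levels(groups),
         "control group '", controlGroup, "' absent")
  v <- if (log2Transform) {
    stopif(any(values <= 0), "log2 transform needs positive values")
    log2(values)
  } else values

  shapiro <- do.call(rbind, lapply(levels(groups), function(g) {
    x <- v[groups == g]
    res <- tryCatch(stats::shapiro.test(x),
                    error = function(e) NULL)
    data.frame(group = g, n = length(x),
               W = if (is.null(res)) NA_real_ else unname(res$statistic),
               p = if (is.null(res)) NA_real_ else res$p.value)
  }))

  lev <- levels(groups)
  if (stats::var(v) < 1e-20) {
    ## degenerate null: identical values everywhere
    pairs <- t(utils::combn(lev, 2))
    tukey <- data.frame(comparison = paste(pairs[, 2], pairs[, 1], sep = "-"),
                        diff = 0, p_adj = 1)
    sig <- matrix(FALSE, length(lev), length(lev), dimnames = list(lev, lev))
    return(new("GroupTestReport", shapiro = shapiro, anovaF = 0, anovaP = 1,
               tukey = tukey, letters = letterDisplay(lev, sig),
               dunnett = .dunnettTest(v, groups, controlGroup),
               controlGroup = controlGroup, alpha = alpha))
  }

  fit <- stats::aov(v ~ groups)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  sig <- matrix(FALSE, length(lev), length(lev), dimnames = list(lev, lev))
  for (r in seq_len(nrow(tukey))) {
    gg <- strsplit(tukey$comparison[r], "-", fixed = TRUE)[[1]]
    s <- isTRUE(tukey$p_adj[r] < alpha)
    sig[gg[1], gg[2]] <- sig[gg[2], gg[1]] <- s
  }
  new("GroupTestReport", shapiro = shapiro,
      anovaF = an[["F value"]][1], anovaP = an[["Pr(>F)"]][1],
      tukey = tukey, letters = letterDisplay(lev, sig),
      dunnett = .dunnettTest(v, groups, controlGroup),
      controlGroup = controlGroup, alpha = alpha)
}

setMethod("show", "GroupTestReport", function(object) {
  cat("One-way ANOVA: F =", signif(object@anovaF, 4),
      ", p =", signif(object@anovaP, 4), "\n")
  cat("Tukey letters:",
      paste(names(object@letters), object@letters, sep = ":",
            collapse = "  "), "\n")
  cat("Dunnett vs '", object@controlGroup, "':\n", sep = "")
  d <- object@dunnett
  d$p_adj <- signif(d$p_adj, 4)
  print(d[, c("group", "estimate", "p_adj", "stars")], row.names = FALSE)
})

#' Stepwise reference-gene reduction study
#'
#' Quantifies a gene of interest under normalization factors built from
#' the top n consensus-ranked reference genes for n = nRec down to 2, and
#' asks whether using fewer genes changes the result. Within each sample
#' group, the log2 fold values of the NF variants are compared by one-way
#' ANOVA + Tukey HSD (an unpaired layout); a variant is flagged when its
#' comparison against the reference variant (n = nRec) is significant —
#' a quantification shift. Within each variant, Dunnett contrasts versus
#' the control group give the significance pattern. A variant is safe when
#' it shows no flagged shift in any group and reproduces the reference
#' Dunnett star pattern; \code{minimalSafeN} is the smallest n such that
#' every variant from nRec down to n is safe.
#'
#' @param q a \linkS4class{QuantityMatrix} containing the reference genes
#'   (and the GOI unless \code{goiQ} is given).
#' @param goi gene of interest (error if among the top-nRec reference
#'   genes: self-normalization).
#' @param consensusOrder ranked gene list, most stable first.
#' @param nRec recommended reference-gene count (>= 2).
#' @param controlGroup calibrator/control group label.
#' @param groups labels per sample; defaults to \code{colData} groups.
#' @param alpha significance level (default 0.05).
#' @param goiQ optional explicit GOI quantities.
#' @return a \linkS4class{ReductionReport}.
#' @export
reductionStudy <- function(q, goi, consensusOrder, nRec, controlGroup,
                           groups = NULL, alpha = 0.05, goiQ = NULL) {
  if (is.null(groups)) groups <- sampleGroups(q)
  groups <- factor(groups, levels = unique(as.character(groups)))
  stopif(nRec < 2L, "nRec must be at least 2")
  stopif(length(consensusOrder) < nRec, "consensus order shorter than nRec")
  stopif(goi %in% utils::head(consensusOrder, nRec),
         "GOI '", goi, "' is in the reference set (self-normalization)")
  qm <- .asQuantityMat(q)
  if (is.null(goiQ)) {
    stopif(!goi %in% rownames(qm), "GOI '", goi, "' absent from the data")
    goiQ <- qm[goi, ]
  }
  lvls <- seq(nRec, 2L)
  foldLog2 <- list()
  pattern <- list()
  for (n in lvls) {
    rgs <- utils::head(consensusOrder, n)
    nf <- normalizationFactor(qm, rgs)
    rel <- normalizeGoi(goiQ, nf)
    fc <- foldChangeVsGroup(rel, groups, controlGroup)
    lf <- log2(fc$fold)
    foldLog2[[as.character(n)]] <- lf
    dn <- .dunnettTest(lf, groups, controlGroup)
    pattern[[as.character(n)]] <- stats::setNames(dn$stars, dn$group)
  }

  ## Tukey across NF variants, within each group, on log2 fold values
  quantShift <- data.frame(level = integer(0), group = character(0),
                           p_adj = numeric(0), flagged = logical(0))
  if (length(lvls) > 1L) {
    for (g in levels(groups)) {
      vals <- unlist(lapply(lvls, function(n)
        foldLog2[[as.character(n)]][groups == g]), use.names = FALSE)
      lvl <- factor(rep(lvls, each = sum(groups == g)))
      if (stats::var(vals) < 1e-20) {
        p <- stats::setNames(rep(1, length(lvls) - 1),
                             as.character(lvls[-1]))
      } else {
        tk <- stats::TukeyHSD(stats::aov(vals ~ lvl))$lvl
        ## comparisons of each reduced variant against the reference nRec
        ref <- as.character(nRec)
        rows <- rownames(tk)
        pick <- grepl(paste0("^", ref, "-"), rows) |
          grepl(paste0("-", ref, "$"), rows)
        other <- sub(paste0("^", ref, "-"), "",
                     sub(paste0("-", ref, "$"), "", rows[pick]))
        p <- stats::setNames(tk[pick, "p adj"], other)
      }
      quantShift <- rbind(quantShift, data.frame(
        level = as.integer(names(p)), group = g, p_adj = unname(p),
        flagged = unname(p < alpha)))
    }
  }

  refPat <- pattern[[as.character(nRec)]]
  safe <- vapply(lvls, function(n) {
    shifts <- quantShift$flagged[quantShift$level == n]
    noShift <- n == nRec || !any(shifts)
    noShift && identical(pattern[[as.character(n)]], refPat)
  }, logical(1))
  names(safe) <- as.character(lvls)
  ## contiguous run of safe variants from nRec downwards
  minimalSafeN <- nRec
  for (n in lvls) {
    if (safe[[as.character(n)]]) minimalSafeN <- n else break
  }
  new("ReductionReport", levels = as.integer(lvls), foldLog2 = foldLog2,
      quantShift = quantShift, dunnettPattern = pattern, safe = safe,
      minimalSafeN = as.integer(minimalSafeN), controlGroup = controlGroup)
}

setMethod("show", "ReductionReport", function(object) {
  cat("Reference-gene reduction study (levels n = ",
      paste(object@levels, collapse = ", "), ")\n", sep = "")
  cat("safe levels:", paste(names(object@safe)[object@safe],
                            collapse = ", "), "\n")
  cat("minimal safe n:", object@minimalSafeN, "\n")
  if (any(object@quantShift$flagged)) {
    cat("flagged quantification shifts:\n")
    print(object@quantShift[object@quantShift$flagged, ], row.names = FALSE)
  }
})
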
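---
title: "Validating reference genes and normalizing RT-qPCR data with CqStability"
author: "CqStability package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating reference genes and normalizing RT-qPCR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(CqStability)
  library(SummarizedExperiment)
})
```

## The problem

Relative quantification by RT-qPCR stands or falls with its internal
controls. A gene of interest (GOI) is quantified as a ratio to one or
more reference genes (RGs) assumed stably expressed across all samples;
if that assumption fails — and classic housekeeping genes such as
tubulins or GAPDH often do fail under specific developmental or stress
conditions — fold changes are biased and group differences can appear or
vanish artifactually. This is acute in hard-to-sample tissues such as
anthers staged through meiosis, where material per biological replicate
is limited and expression programs change drastically between stages.

CqStability implements the complete candidate-RG validation workflow:
the four standard stability algorithms, a consensus ranking, the
pairwise-variation criterion for how many RGs the normalization factor
needs, normalization-factor-based quantification of a GOI with the
standard significance tests, and a stepwise study of whether the RG set
can be reduced without changing the biological conclusions. A seeded
synthetic-data generator with known ground truth makes every stage
testable end to end.

## Data model and the efficiency-corrected Cq

Raw data are quantitation cycles Cq — the PCR cycle at which a
reaction's fluorescence crosses threshold, inversely log-proportional to
template abundance — organized as a `CqExperiment`
(a `SummarizedExperiment`: genes × samples, one assay per technical
replicate, per-gene amplification efficiencies in `rowData`, sample
group/genotype/tissue/replicate metadata in `colData`). Technical
replicates are collapsed by the arithmetic mean of Cq (equivalent to the
geometric mean of quantities, the qBase convention); within-cell
disagreement beyond 0.5 cycles and single-replicate cells raise QC
warnings, never errors. Cq values outside (0, 45] likewise warn, since
the usable ceiling is instrument-dependent.

An amplicon with per-cycle efficiency $E$ (2 = perfect doubling;
accepted range $(1, 2.2]$, with $E > 2$ flagged as a likely artifact)
yields the efficiency-corrected cycle count

$$Cq_E = Cq \cdot \frac{\log E}{\log 2},$$

the identity at $E = 2$; the log base is irrelevant. Relative quantities
follow as $q_{gs} = 2^{\,cal_g - Cq_{E,gs}}$ with the per-gene minimum
$Cq_E$ (the most abundant sample) as the default calibrator, so each
gene's maximal quantity is 1. Every downstream stability statistic is
provably invariant to the calibrator choice (the package tests this
explicitly), so the convention is cosmetic.

## The four stability algorithms

**geNorm.** For genes $j, k$ let $V_{jk}$ be the standard deviation
(throughout: the $n-1$ sample SD) over samples of
$\log_2(q_{js}/q_{ks})$. The stability value $M_j$ is the mean of
$V_{jk}$ over all partners $k \ne j$. Ranking is by iterative
elimination: the gene with the largest $M$ on the surviving set is
removed and $M$ recomputed until two genes remain; the final pair is
jointly most stable, with ranks 1 and 2 assigned from the full-set $M$
and lexicographic tie-breaks, so the output is deterministic. Because two
co-regulated genes have constant ratio regardless of their individual
stability, geNorm is blind to coordinated regulation — one reason to run
several algorithms.

**Comparative ΔCt.** The same pairwise construction applied directly to
(by default efficiency-corrected) Cq: a gene's score is the mean SD of
its pairwise Cq differences. On corrected input this is *identical* to
the full-set geNorm $M$, since
$\Delta Cq_{jk,s} = -\log_2(q_{js}/q_{ks}) + \text{const}$; the package
keeps both because they receive different inputs in practice and the
identity is a valuable cross-check (asserted to $10^{-9}$ in the tests).

**BestKeeper.** Operates on raw Cq. Per gene it reports descriptive
statistics, the dispersion `sd_cq` — the mean absolute deviation from
the arithmetic-mean Cq, in cycles, with `sd_cq > 1` flagged inconsistent
— and the Pearson correlation (two-sided p) of the gene's Cq with the
BestKeeper index, the per-sample geometric mean of Cq over all
candidates. For the consensus the genes are ranked by `sd_cq` ascending;
$r$ is reported but not used for ranking, since the index correlation
rewards genes that follow shared loading trends rather than penalizing
them. The deviation base (arithmetic vs geometric mean) is a genuinely
open convention; the arithmetic mean was chosen and documented here.

**NormFinder.** A model-based decomposition on the log2 scale. Within
each group, per-sample centering across the $k$ genes removes
sample-loading effects; the centered values give per-gene, per-group
mean deviations $\bar d_{ig}$ and sample variances $s^2_{ig}$. The
intra-group variance estimate removes the leakage the centering
introduces,
$\hat\sigma^2_{ig} = \max\!\big(0, \tfrac{k}{k-2}(s^2_{ig} -
S_g/(k(k-1)))\big)$ with $S_g = \sum_i s^2_{ig}$ — unbiased when all
genes share a variance (the package verifies recovery within 10% by
simulation) and truncated at zero because the moment estimator can go
negative; $k \ge 3$ genes and $\ge 2$ samples per group are required.
With one group the stability value is $\hat\sigma_i$. With $G \ge 2$
groups, the group-centered differences $d_{ig}$ estimate differential
expression; their dispersion $\hat\gamma^2$ — estimated by the sum of
$d^2_{ig}$ over the $(k-1)(G-1)$ degrees of freedom left by the two
centering constraints, minus the mean sampling variance, truncated at
zero — shrinks each $d_{ig}$ toward zero, and

$$\rho_i = \frac{1}{G}\sum_g \left(|\tilde d_{ig}| +
  \sqrt{\frac{\hat\gamma^2\,\hat\sigma^2_{ig}/n_g}
  {\hat\gamma^2 + \hat\sigma^2_{ig}/n_g}}\right).$$

This is the one method that penalizes coordinated group-specific
regulation that the pairwise methods cannot see. The score is invariant
to per-gene additive offsets of the input, so $-Cq_E$ and calibrated
$\log_2 q$ give identical results.

## Consensus and the optimal number of reference genes

Each method yields ranks 1..k (ascending scores; exact ties take average
ranks — the tie handling of the aggregating web tool is undocumented, so
average ranks were chosen to keep the aggregate well defined and
deterministic; geNorm contributes its elimination ranking, not a
re-ranking of $M$). The consensus score per gene is the geometric mean
of its four ranks; genes are ordered ascending, ties broken by
arithmetic mean rank and then lexicographically.

Along the consensus order, the normalization factor over the top $n$
genes is the per-sample geometric mean $NF_n[s]$ of their quantities,
and the pairwise variation is
$V_{n/n+1} = SD_s \log_2(NF_n[s]/NF_{n+1}[s])$. The first $n$ with
$V_{n/n+1}$ below the cutoff is reported as the optimal count: adding
gene $n+1$ no longer changes the NF materially. The conventional cutoff
0.15 is the default but deliberately configurable — it is a guideline,
not a hard rule, and the series is always reported in full so users can
judge borderline cases.

## Quantification and significance testing

A GOI (never a member of its own RG set; this is rejected) is normalized
as $rel_s = q^{GOI}_s / NF_s$ and expressed as fold change against the
arithmetic mean of a calibrator group, so that group's folds average
exactly 1. Folds are computed per biological replicate (not from group
means) because the replicate-level values feed the statistics. The
defining property — a per-sample loading factor multiplying every gene,
GOI included, cancels exactly from `rel` — is tested both algebraically
and through the simulation.

Tests run on log2 fold values by default (ratios are log-normal under
the generative model; Shapiro–Wilk per group is reported so users can
judge the normality assumption at their n): one-way ANOVA, Tukey HSD
all-pairs with a compact letter display (two groups share a letter iff
not significantly different at $\alpha = 0.05$; the insert–absorb
construction is property-tested against the brute-force definition), and
two-sided Dunnett contrasts versus the control group annotated "*"
(p < 0.05) / "**" (p < 0.01). The Dunnett adjustment integrates a
multivariate t quasi-randomly; a fixed internal seed (with the caller's
RNG state restored) keeps reports bit-reproducible.

**Stepwise reduction.** Using fewer RGs than recommended is tempting
when material is scarce. `reductionStudy()` rebuilds the NF for
$n = n_{rec}, \dots, 2$ along the consensus order and asks two
questions per variant: does any sample group show a significant Tukey
shift of its log2 folds against the reference variant (an unpaired
one-way layout across variants was chosen; a paired layout would share
GOI noise across variants and overstate sensitivity), and is the
Dunnett star pattern versus the control unchanged? The minimal safe $n$
is the smallest count such that every variant from $n_{rec}$ down to it
passes both — "safe" meaning the quantification and its biological
interpretation are preserved, not merely the ranking.

## The synthetic-data generator

`simulateCqDataset()` draws from the latent model
$Cq_E[g,s] = \mu_g + \lambda_s + \delta_{g,\text{group}(s)} + b_{gs}$,
with baselines $\mu_g \sim U(20, 30)$ cycles, shared loading
$\lambda_s \sim N(0, \tau^2)$ ($\tau = 0.5$ cycles by default,
emulating pipetting/input variation), biological noise
$b_{gs} \sim N(0, \sigma_g^2)$, and stage shifts $\delta$ only for
shifted genes. Raw Cq inverts the efficiency correction
($Cq = Cq_E \log 2 / \log E_g$, $E_g \sim U(1.900, 1.946)$) and each
technical replicate adds $N(0, 0.1^2)$ cycles. Defaults: 12 genes — 9
stable ($\sigma = 0.15$), two noisy ($\sigma = 1.0$), one shifted by
1.5 cycles in the last group — across PM/PRO/TT/IP × 3 biological × 2
technical replicates. All draws happen in one documented order from a
single seed, and a GOI generated by `simulateGoi()` re-uses the same
$\lambda_s$ (plus its per-group log2 fold profile entering as
$-$profile cycles) so that normalization has something real to remove.

What the generator does *not* emulate: amplification-curve artifacts,
inter-run batch effects, correlated co-regulated gene modules beyond the
single-shift flavor, missing-data mechanisms, and Cq-dependent
(heteroscedastic) technical error. Passing tests therefore demonstrate
algorithmic correctness and statistical behavior under a clean
log-normal generative model, not robustness to every pathology of real
instrument exports.

## Numerical and design choices

- SDs use the $n-1$ denominator everywhere.
- geNorm elimination removes the lexicographically last gene on exact
  $M$ ties; the final pair takes ranks 1/2 by full-set $M$ — pure
  determinism decisions with no scientific content.
- NormFinder's negative variance estimates truncate at 0; with
  $\hat\gamma^2 = 0$ the shrinkage factor is defined as 0.
- BestKeeper's correlation is dropped (with a warning) for
  zero-variance genes rather than failing.
- Degenerate test inputs (all values identical) short-circuit to the
  global-null report instead of propagating 0/0 F statistics.
- Technical replicates collapse by arithmetic mean of Cq; the
  discordance QC threshold is 0.5 cycles by default.
- BestKeeper receives raw Cq and ΔCt the corrected Cq by default; both
  are configurable in `rankStability()` because conventions differ
  between labs.

## Problem sizes used in the automated checks

The package's test suite and the acceptance script regenerate
everything from code: 100 random 5×8 matrices for the ΔCt/geNorm
identity, 50 random 6-gene instances against a brute-force elimination
oracle, 100 seeds of the default 12-gene design for consensus recovery
and of a 6+3-gene design for the $V$ series, 500 replicates per
variance level for the NormFinder estimator, and 50 seeds per arm of
the reduction study — sizes chosen to give Monte-Carlo margins well
inside the asserted bounds while keeping a full run in the order of a
minute.

## A worked example

```{r example}
cfg <- simConfig(goiProfile = c(PM = 0, PRO = 0, TT = -1, IP = -2),
                 seed = 7)
sim <- simulateCqDataset(cfg)
rk <- rankStability(sim$dataset)
rk$consensus

vs <- optimalRgCount(rk$q, rk$consensus)
vs

goi <- simulateGoi(cfg, sim$truth)
goiQ <- assay(relativeQuantities(efficiencyCorrect(
  collapseTechnicalReplicates(goi))), "q")[1, ]
ne <- normalizeExpression(rk$q, "GOI", head(rk$consensus@order, 3),
                          "PM", goiQ = goiQ)
ne
groupTests(ne@fold, ne@groups, "PM")
```

## Limitations

The pipeline validates candidates you give it; it cannot conjure a
stable gene out of an unstable panel, and a consensus of four methods
that all mis-rank a co-regulated pair is still wrong — NormFinder's
group term mitigates but does not abolish this. V-series decisions near
the cutoff deserve the reduction study rather than blind trust. The
statistics assume independent biological replicates; technical
replicates must be collapsed first (the package enforces this order).
No inter-run calibration is implemented, so all samples of a comparison
must come from one run or be pre-calibrated upstream.
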
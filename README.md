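# CqStability

Reference-gene validation and normalization for RT-qPCR experiments.

Relative quantification by RT-qPCR expresses a gene of interest (GOI) as
a ratio to internal reference genes (RGs) assumed stably expressed
across all samples. That assumption must be *validated per experiment*:
classic housekeeping genes drift under specific developmental or stress
conditions, and an unstable RG biases every fold change downstream.
CqStability implements the full validation and quantification workflow
for anyone running qPCR panels — originally motivated by staged meiotic
anther samples, but applicable to any grouped design:

- **Data model** — `CqExperiment` (a `SummarizedExperiment`) holding raw
  quantitation cycles (Cq) with technical replicates, per-amplicon PCR
  efficiencies and sample metadata; robust long/wide TSV–CSV readers,
  technical-replicate collapsing with QC warnings, completeness
  validation with a drop-gene policy for genes absent from some
  genotypes.
- **Efficiency correction** — `CqE = Cq · log(E)/log(2)` and relative
  quantities `q = 2^(calibrator − CqE)`.
- **Four stability algorithms** —
  *geNorm*: stability value M = mean SD of pairwise log2 expression
  ratios, with iterative elimination ranking and the pairwise variation
  `V_n/n+1 = SD log2(NF_n/NF_{n+1})` of sequential normalization
  factors;
  *NormFinder*: model-based intra-group variance + shrunken inter-group
  difference;
  *BestKeeper*: raw-Cq dispersion and Pearson correlation with the
  geometric-mean index;
  *comparative ΔCt*: mean SD of pairwise Cq differences.
- **Consensus** — RefFinder-style geometric mean of the four ranks, and
  the optimal RG count as the first n with `V_n/n+1` under the 0.15
  cutoff (configurable — the cutoff is a guideline, not a law).
- **Quantification** — per-sample normalization factor (geometric mean
  of the selected RGs' quantities), GOI fold changes versus a calibrator
  group, Shapiro–Wilk / one-way ANOVA / Tukey HSD with compact letter
  display / two-sided Dunnett versus control with `*`/`**` stars.
- **Stepwise reduction study** — would fewer RGs than recommended change
  the quantification or its statistical interpretation?
- **Synthetic data** — a seeded generator with known ground-truth
  stability structure (stable, noisy and group-shifted genes; shared
  per-sample loading factors; a GOI with a configurable fold profile),
  so the whole pipeline is testable without any instrument data.

## Worked example

Simulate the default study design (12 candidate RGs — 9 stable, 2
noisy, 1 stage-shifted — across 4 meiotic stage groups × 3 biological ×
2 technical replicates) plus a down-regulated GOI, then validate and
quantify:

```r
library(CqStability)
library(SummarizedExperiment)

cfg <- simConfig(goiProfile = c(PM = 0, PRO = 0, TT = -1, IP = -2),
                 seed = 7)
sim <- simulateCqDataset(cfg)
rk  <- rankStability(sim$dataset)
rk$consensus
#> RefFinder-style consensus (geometric mean of method ranks)
#>  gene geNorm NormFinder BestKeeper deltaCt geomean consensus_rank
#>  RG05      1          3          6       1   2.060              1
#>  RG02      2          2          9       3   3.224              2
#>  RG07      6          6          1       5   3.663              3
#>  ...
#>  RG11     10         10         10      10  10.000             10
#>  RG12     11         12         11      11  11.242             11
#>  RG10     12         11         12      12  11.742             12
```

The three truly unstable genes (RG10–RG12 in this draw) land at the
bottom of the consensus. The pairwise-variation series says two genes
already make a stable normalization factor here (every V is far below
the 0.15 cutoff because the top-ranked genes are genuinely stable):

```r
optimalRgCount(rk$q, rk$consensus)
#> Pairwise variation V_n/n+1 (cutoff 0.15)
#>   V2/3   V3/4   V4/5   V5/6   V6/7   V7/8   V8/9  V9/10 V10/11 V11/12
#> 0.0657 0.0290 0.0459 0.0247 0.0240 0.0228 0.0218 0.0580 0.0607 0.0655
#> optimal number of reference genes: 2
```

Normalize the GOI by the consensus top 3 and test the groups (the
simulated truth is fold 1, 1, 0.5, 0.25 across PM, PRO, TT, IP):

```r
goiQ <- assay(relativeQuantities(efficiencyCorrect(
  collapseTechnicalReplicates(simulateGoi(cfg, sim$truth)))), "q")[1, ]
ne <- normalizeExpression(rk$q, "GOI", head(rk$consensus@order, 3),
                          "PM", goiQ = goiQ)
ne
#> Normalized expression vs group 'PM' using NF(RG05, RG02, RG07)
#>  group n mean_fold se_fold
#>     PM 3     1.000   0.119
#>    PRO 3     1.054   0.060
#>     TT 3     0.499   0.031
#>     IP 3     0.245   0.020
groupTests(ne@fold, ne@groups, "PM")
#> One-way ANOVA: F = 67.29 , p = 5.116e-06
#> Tukey letters: PM:a  PRO:a  TT:b  IP:c
#> Dunnett vs 'PM':
#>  group    estimate     p_adj stars
#>    PRO  0.09261642 0.9046000
#>     TT -0.98712373 0.0011310    **
#>     IP -2.01514612 0.0000161    **
```

The recovered folds (1.05, 0.50, 0.25) match the simulated profile, the
letter display separates PM/PRO from TT from IP, and Dunnett flags the
regulated stages against premeiosis.

File-based workflows go through `runRank()` / `runQuantify()` (TSV +
JSON reports), or the thin CLI at `inst/scripts/rgnorm.R` with
subcommands `rank`, `optimal-n`, `quantify`, `reduce`, `simulate`.

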
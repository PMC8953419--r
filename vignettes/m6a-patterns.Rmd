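---
title: "Quantifying m6A modification patterns: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying m6A modification patterns: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6Ascore)
```

## The problem

N6-methyladenosine (m6A) is the most abundant internal mRNA modification.
Its cellular homeostasis is set jointly by "writer" methyltransferases,
"eraser" demethylases and "reader" proteins — 24 regulator genes in the
panel shipped with this package (9 writers, 2 erasers, 13 readers). In bulk
tumor cohorts, the joint expression repertoire of these regulators defines a
per-tumor *m6A modification pattern*. The package provides the full analysis
chain for studying such patterns in a cohort with expression and survival
data:

1. consensus clustering of samples on the z-scored regulator panel, with
   data-driven choice of the number of clusters k;
2. pairwise differential expression between clusters and extraction of
   *core DEGs* (significant in at least two of the three pairwise
   contrasts), treated as m6A phenotype-associated genes;
3. a univariate Cox screen of each core DEG, partitioning significant genes
   by hazard-ratio sign; and
4. the per-sample **m6Avalue**,
   $$\mathrm{m6Avalue}_j \;=\; \sum_{g \in \text{risk}} z_{gj} \;-\;
     \sum_{g \in \text{protective}} z_{gj},$$
   where risk genes have HR > 1, protective genes HR < 1, and $z_{gj}$ is
   gene g's z-scored expression in sample j.

A companion score, the *weighted regulator signature*, applies the same
signed-sum construction directly to the 24-gene panel with fixed weights:
the four regulators typically down-regulated in tumors (ALKBH5, FTO, ZC3H13,
IGF2BP2) carry weight −1, the other twenty +1.

Downstream, the m6Avalue feeds survival stratification (maximally selected
rank-statistic cutpoint, Kaplan–Meier + log-rank, multivariate Cox with
grade and stage, ROC/AUC), single-sample enrichment of immune and stromal
signatures (a 28-set TIL compendium, the 7-step cancer immunity cycle,
ImmuneScore/StromaScore), and a Spearman drug-sensitivity screen against
cell-line IC50 tables.

## Tunable parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_count`, `min_fraction` | 3, 1/3 | a gene is kept iff it has ≥ 3 reads in **more than** one-third of samples (strict) |
| `fdr_max`, `fc_min` | 0.05, 2 | DEG rule: BH q < 0.05 **and** linear fold change > 2 (pseudocount 1) |
| `p_max` (Cox screen) | 0.05 | two-sided Wald p for a core DEG to enter the model |
| `n_resamples`, `subsample_fraction` | 1000, 0.8 | consensus clustering resampling depth and per-draw sample fraction |
| `alpha` (enrichment) | 0.25 | rank-weight exponent of the single-sample running-sum score |
| `min_group_fraction` | 0.1 | smallest admissible group at the survival cutpoint |
| `r_min`, `p_max` (drugs) | 0.1, 0.05 | retain a compound iff \|Spearman r\| > 0.1 and p < 0.05 |

## Choosing k: why not argmin PAC

The proportion of ambiguous clustering (PAC — the fraction of off-diagonal
consensus entries in (0.1, 0.9)) is reported for every `ConsensusResult`,
but it is *not* sufficient to select k on its own. With a deterministic
agglomerative base clusterer, every partition into k ≤ K groups of K
well-separated clusters is perfectly stable: merging two true clusters is a
reproducible act, so PAC(k = 2) ≈ 0 on clearly 3-cluster data and the
minimizer degenerates to the smallest candidate. `select_k()` therefore
scans k in ascending order and accepts a larger k while (a) the relative
gain in area under the consensus CDF is appreciable (≥ 0.1, the classic
elbow diagnostic of consensus clustering) and (b) the k-cluster solution is
itself clean (PAC ≤ 0.1); it stops at the first k failing either test. When
even the smallest candidate is unclean the data carry little cluster
structure and the argmin-PAC k is returned with a low-confidence warning.
On the synthetic cohorts below this rule selects k = 3 in 10/10 seeds while
two-duplicate-group data still yield k = 2.

Cluster labels are, by convention, renumbered by ascending mean of a
caller-supplied severity score (the weighted regulator signature in the
pipeline), so "cluster 1 indolent, cluster 3 aggressive" is reproducible.

## What the synthetic cohort emulates

`simulate_cohort()` is first-class, tested code, not a fixture. Its
defaults state one fixed world:

* **three latent clusters** with proportions (0.42, 0.12, 0.46) — a large
  indolent cluster, a small intermediate one, a large aggressive one —
  mirroring the 139/39/155-type splits reported for curated prostate
  cohorts;
* a **planted aggressiveness score** per sample: cluster offsets
  (−1.5, 0, +1.5) plus N(0, 0.3) within-cluster noise;
* **regulator genes** (the real 24-gene panel symbols) whose log2 means
  shift by ±1 per cluster step — writers/readers up toward cluster 3,
  erasers down;
* **phenotype genes** — 50 risk, 30 protective, 84 immune, 40 stroma —
  whose log2 means move by ±1 per unit of the planted score (risk up,
  the rest down), plus 1000 noise genes;
* **negative-binomial counts** (dispersion φ = 0.2, var = μ + φμ²) with
  log-normal library sizes (σ = 0.3) so normalization is actually
  exercised;
* **exponential proportional-hazards survival** with log-hazard
  0.5 × score and a 60-month baseline median, censored administratively at
  the empirical 50% quantile;
* **ordinal grade/stage** drawn with cluster-shifted probabilities;
* **cell lines** reuse the same expression model; each compound's IC50 is
  `link × score + noise` with unit total variance.

The cluster offsets were set once so that adjacent clusters differ by
1.5 log2 units in phenotype-gene means — comfortably beyond the fold-change
2 cutoff at the default unit effect size — and are not revisited.

What it does **not** emulate: gene–gene correlation beyond the planted
factor, batch effects, cohort-specific marginal distributions, copy-number
or mutation structure, and microarray-style intensity noise. A green
recovery test therefore establishes that the pipeline recovers the planted
low-rank structure under realistic count noise — not that it reproduces any
particular real cohort's gene lists or counts.

## Numerical choices and degenerate inputs

* **Z-scores** use the sample (n−1) standard deviation; constant genes are
  dropped with a warning. `gene_zscore()` stores the fitted centers/sds so
  a trained m6Avalue model can be applied *frozen* to held-out data;
  the default is *refit* (re-standardize on the scored cohort), because the
  score is routinely applied to independent cohorts and cell-line panels
  where training means are meaningless.
* **CPM + log2(x+1)** stands in for upstream TPM when gene lengths are
  unavailable; this is a documented deviation and only affects the
  between-gene (not between-sample) scale.
* **DEG testing** uses a per-gene two-sided Wilcoxon rank-sum test with BH
  adjustment rather than a negative-binomial count model: self-contained,
  assumption-light, and adequate for the rank-based downstream use. The
  fold-change filter is computed on linear-scale group means with
  pseudocount 1. Significance is direction-agnostic when counting core-DEG
  contrasts.
* **Single-sample enrichment** breaks expression ties by a seeded, recorded
  shuffle of gene order (ties otherwise make the running sum ambiguous);
  scores are invariant to monotone transforms within a sample but *not* to
  across-sample normalization — both properties are asserted in tests.
* **Cox fitting** delegates to the survival package (Newton–Raphson on the
  partial likelihood, Efron ties); monotone-likelihood fits are flagged.
  Genes with HR exactly 1 belong to neither model list.
* **The maxstat cutpoint** scans midpoints of consecutive distinct score
  values, requires each group to hold ≥ 10% of the cohort, and breaks ties
  toward the lower cutoff. The selection-induced optimism of the downstream
  log-rank p is deliberately *not* corrected (matching common practice);
  treat those p-values as descriptive.
* **Determinism**: every stochastic operation takes an explicit seed; the
  pipeline fans one global seed out to per-stage sub-seeds with a
  counter-based scheme, so inserting a stage never perturbs the randomness
  of earlier stages. Two runs with the same config hash to identical
  outputs.

## Known limitations

* The Wilcoxon DEG route is less powerful than count models at small n;
  the strategy is isolated behind `pairwise_deg()` and can be swapped.
* ImmuneScore/StromaScore are signature-enrichment summaries, not the
  published ESTIMATE coefficients.
* The 28 TIL and 7 immunity-cycle sets ship only as synthetic fixtures
  (`fixture_gene_sets()`); real analyses must supply curated GMTs.
* PAC-gated elbow selection of k assumes candidate k values are scanned
  consecutively from the smallest.
* No batch correction, stratified Cox, time-dependent covariates or
  competing risks.
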
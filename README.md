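# m6Ascore

Quantify **N6-methyladenosine (m6A) modification patterns** in bulk tumor
expression cohorts and turn them into a prognostic per-sample score.

m6A homeostasis is governed by 24 regulator genes — 9 writers, 2 erasers,
13 readers. Their joint expression stratifies tumors into modification
patterns with distinct aggressiveness, microenvironment and drug-response
profiles. This package implements the full analysis chain for cohorts with
expression, survival and (optionally) drug-response data:

* **Consensus clustering** of samples on the z-scored regulator panel
  (Ward agglomerative base clusterer, item resampling, PAC-gated
  CDF-area elbow selection of k).
* **Core DEG extraction**: per-gene Wilcoxon tests between every cluster
  pair (BH FDR < 0.05, fold change > 2); core DEGs are significant in at
  least two of the three contrasts.
* **m6Avalue**: a univariate Cox screen partitions core DEGs by hazard
  ratio, and each sample is scored as

      m6Avalue = Σ z(risk genes, HR > 1) − Σ z(protective genes, HR < 1)

  The companion *weighted regulator signature* applies the same signed sum
  to the 24-gene panel itself (20 genes weighted +1; ALKBH5, FTO, ZC3H13
  and IGF2BP2 weighted −1).
* **Survival statistics**: Cox fits (Efron ties), Kaplan–Meier + log-rank,
  a maximally selected rank-statistic cutpoint, ROC/AUC.
* **Single-sample enrichment** (rank-weighted running sum, α = 0.25) for
  immune/stromal signatures: 28 TIL subpopulations, the 7-step cancer
  immunity cycle, ImmuneScore/StromaScore.
* **Drug-sensitivity screen**: Spearman correlation of cell-line m6Avalue
  with IC50 per compound (retained iff |r| > 0.1 and p < 0.05; r > 0 =
  resistant, r < 0 = sensitive).
* A **negative-binomial cohort simulator** with planted clusters,
  survival and microenvironment structure, so the whole pipeline is
  testable offline.

## Worked example

```r
library(m6Ascore)

sim <- simulate_cohort(simulation_params(seed = 1))   # 300 samples
lg  <- normalize_log(filter_low_count(sim$counts))
z   <- gene_zscore(lg)

sev <- weighted_regulator_signature(z)
res <- lapply(2:5, function(k)
  consensus_cluster(z, regulator_panel()$gene, k,
                    n_resamples = 200, seed = 2, severity = sev))
k <- select_k(res)            # -> 3
cl <- res[[k - 1]]$assignments
table(cl)
#>   1   2   3
#> 123  33 144

model <- build_m6avalue_model(lg, cl, sim$clinical$time_months,
                              sim$clinical$event)
model
#> M6AvalueModel: 72 risk + 155 protective genes (from 227 core DEGs)

sc <- apply_m6avalue(model, lg)
st <- stratify_by_cutpoint(sc, sim$clinical$time_months,
                           sim$clinical$event, clinical = sim$clinical)
#> cutpoint 92.85 | log-rank p 4.2e-13 | AUC 0.699
cor(sc$m6avalue, sim$truth$samples$score, method = "spearman")
#> 0.995
```

The three clusters recover the planted pattern (cluster 1 indolent,
cluster 3 aggressive, a small intermediate cluster 2 — labels are ordered
by the regulator-signature severity convention). The 227 core DEGs shrink
to a 227-gene screen from which 72 risk and 155 protective genes form the
model; the resulting m6Avalue tracks the planted aggressiveness score at
Spearman ρ = 0.995, and the maxstat cutpoint splits survival at log-rank
p ≈ 4 × 10⁻¹³ with AUC 0.699 against the event indicator.

Cell-line screening works the same way:

```r
cls   <- simulate_cell_lines(seed = 3)
cl_sc <- apply_m6avalue(model, normalize_log(cls$expr))
drugs <- drug_sensitivity_screen(setNames(cl_sc$m6avalue, cl_sc$sample_id),
                                 cls$drugs)
head(drugs[drugs$retained, ], 4)
#>   compound   n spearman_r p retained     label
#> 1  drug_01 200     -0.851 0     TRUE sensitive
#> 2  drug_02 200     -0.804 0     TRUE sensitive
#> 3  drug_03 200     -0.726 0     TRUE sensitive
#> 4  drug_04 200     -0.635 0     TRUE sensitive
```

The one-shot pipeline (`run_pipeline(config, out_dir)`, or the
`inst/cli/m6ascore.R` command-line entry point) chains all stages from a
JSON/YAML config and writes `clusters.tsv`, `degs.tsv`, `model.tsv`,
`scores.tsv`, `survival.tsv`, `enrichment.tsv`, `drugs.tsv` plus a
`manifest.json` with per-file hashes; identical config + seed reproduces
byte-identical outputs.

## Documentation

See the methods vignette (`vignettes/m6a-patterns.Rmd`) for the model,
the simulator's stated world and its limits, numerical choices, and known
limitations.
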
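# fibrodiff

Differential expression and differential co-expression analysis for
four-arm fibroblast transcriptome studies of collagen-VI-related muscular
dystrophy, with a synthetic-data generator that makes every stage
verifiable against planted ground truth.

## The problem

Ullrich congenital muscular dystrophy (UCMD) is caused by collagen VI gene
mutations; dermal fibroblasts — the cells that secrete collagen VI — are the
primary disease cell type, and ascorbic acid is required for collagen
processing. The canonical experiment compares patient (`P`) and control
(`C`) fibroblast lines, each with and without ascorbic-acid treatment
(`P_AA`, `C_AA`), on a normalized log2-scale expression array, six lines per
arm. The questions are: which genes separate patients from controls, how
does the gene–gene co-expression structure rewire in disease, and which
disease-regulated genes does the treatment push back toward control levels.

## What the package computes

* **Rank Products differential expression** per contrast: for all
  $n_1 n_2$ pairwise between-group log2 ratios, the statistic
  $\mathrm{RP}(g) = (\prod_k r_{gk})^{1/K}$ (geometric mean of the gene's
  per-comparison ranks), with the proportion of false positives (pfp,
  reported as FDR) estimated by within-gene permutation, signed fold
  changes in the negative-reciprocal convention, and probeset-to-gene
  collapsing — `rank_products()`, `call_significant()`,
  `collapse_probesets()`.
* **Differential co-expression networks**: per-group Pearson correlations
  over a gene panel with $t$-based p-values; edges significant at
  $|R| > 0.8,\ p < 0.005$ classified `patient_only`, `control_only`,
  `shared_concordant` or `shared_discordant`; SIF/GraphML export for
  Cytoscape — `build_group_network()`, `write_network()`.
* **Ascorbic-acid reversion genes**: significant in both `P-C` and
  `P_AA-P` with opposite fold-change signs — `reversion_genes()`.
* **ΔΔCT fold changes** for qPCR/miRNA with housekeeping normalization and
  the strict ±1.5 screening rule — `ddct_fold_changes()`,
  `call_fc_significant()`.
* **Phenotype correlation screen** ($|R| > 0.7,\ p < 0.05$) —
  `phenotype_correlation_screen()`.
* **Over-representation** (Fisher / EASE with BH adjustment) against GMT
  collections — `overrepresentation_test()`.
* **Synthetic studies with planted truth** (DE genes, reversion genes,
  latent-factor co-expression modules) — `simulate_expression_study()` —
  plus readers/writers for TSV matrices, the GEO series-matrix dialect,
  annotation tables and GMT.

`run_analysis()` orchestrates the full study from a YAML manifest;
`run_synthetic_study()` is a one-command synthetic end-to-end run.

## Worked example

```r
library(fibrodiff)

sim <- simulate_expression_study(sim_config(
  n_genes = 1000, seed = 11, de_fraction = 0.05, de_log2fc = 2,
  noise_sd = 0.5, n_reversion_genes = 20,
  module_specs = list(module_spec(10, 0.95, active = "P"))))
sim$study
#> expression_study: 1000 genes x 24 samples
#> groups: C (n=6), C_AA (n=6), P (n=6), P_AA (n=6)

fit <- rank_products(sim$study, "P-C", n_permutations = 1000, seed = 7)
fit
#> Rank Products fit: contrast P-C, 1000 probes, 1000 permutations (seed 7)
#> probes with pfp < 0.05 in either direction: 64

head(summary(fit), 3)
#>    probe    rp_up  rp_down pfp_up pfp_down fc_signed
#> 1 g00006 7.394613 985.3291  0.006        1  6.008638
#> 2 g00009 7.437838 986.6402  0.006        1  5.918856
#> 3 g00013 8.307544 987.9228  0.006        1  5.661416
```

All 64 probes called at pfp < 0.05 are planted signal genes (of 70 planted:
50 DE plus 20 reversion genes, which are also shifted in `P-C`) — zero
false positives. Fold changes near +6 on the top rows are draws around the
planted linear fold change of 4 (log2 shift 2) plus noise. Downstream:

```r
calls <- call_significant(fit, 0.05)
cr <- collapse_probesets(calls, setNames(rownames(sim$study$values),
                                         rownames(sim$study$values)), "P-C")
cr
#> contrast P-C: 31 up, 33 down, 64 total unique genes

net <- build_group_network(sim$study,
         unique(c(sim$truth$module_edges$gene_a,
                  sim$truth$module_edges$gene_b)))
summary(net)
#>      patient_only      control_only shared_concordant shared_discordant
#>                11                 0                 0                 0
```

Only 11 of the 45 planted patient-only module pairs pass the stringent
$(|R| > 0.8,\ p < 0.005)$ screen in this particular draw, and none is
misclassified. That is expected behaviour at $n = 6$: the screen's per-pair
detection probability tops out near 0.66 even at a planted correlation of
0.95, and because all pairs share one latent factor the per-study fraction
scatters widely around it (see the methods vignette's power analysis).

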
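# patternxfer

Cross-species transfer learning of non-negative expression patterns, for
computational biologists studying treatment-induced immune cell states.

Tumor immunotherapy changes what immune cells *do*, not only which cells
are present — and activation programs confined to one lineage (such as
NK-cell activation under anti-CTLA-4) are easy to miss with
cluster-then-compare workflows. `patternxfer` implements the alternative:

1. **Learn** K non-negative latent patterns from a gene-by-cell matrix
   `X ≈ A P` (`A`: genes × K gene weights, `P`: K × cells usages) by a
   sparse, box-constrained alternating non-negative least squares with a
   subset/consensus procedure for large data,
2. **Characterize** each pattern by its marker genes (distance-to-basis
   statistic) and permutation gene-set enrichment with BH FDR,
3. **Transfer** the patterns into independent data — another species via
   one-to-one homologs, bulk RNA-seq, or a reduced protein panel — by
   regressing expression onto the fixed gene weights,
4. **Associate** projected pattern usages with treatment groups
   (rank-sum + stars), binary response (Mann–Whitney ROC/AUC),
   overall survival (age-adjusted Cox, Breslow ties), and pseudotime
   along a kNN-geodesic trajectory rooted in the low-activation region.

A synthetic-data module plants ground-truth programs, homolog tables
with dropout, and outcome models with known coefficients, so every stage
is validated by parameter recovery. The fitted objective is

```
min  ||X − A·P||²_F + λ·||P||₁    s.t.  0 ≤ A ≤ 1,  P ≥ 0
```

solved by exact HALS updates with screen-and-refit support selection
(see the vignette in `vignettes/pattern-transfer-learning.Rmd` for why
the scale constraint and the debiased refit matter).

## Worked example

```r
library(patternxfer)
library(dplyr)

truth <- simulate_truth(seed = 42)      # plants 4 programs; #4 = NK activation
expr  <- simulate_expression(truth)
expr
#> <expression_matrix> 200 genes x 300 samples [log2 space]
#> sample_meta: cell_type, treatment, true_activation_weight

fit <- consensus_factorize(preprocess(expr), n_patterns = 4, n_sets = 3,
                           sparsity_penalty = 0.6, seed = 42)
fit
#> <factorization_result> 200 genes x 300 samples, K_final=4 (520 sweeps, seed 42)
```

Patterns are ordered by reproducibility across subsets; in this run
`pattern_1` is the treatment-associated program (its weights separate
treated from control NK cells):

```r
tidy(fit) |>
  filter(pattern == "pattern_1", cell_type == "NK") |>
  compare_groups(weight, treatment) |>
  select(group1, group2, median1, median2, p_adj, stars)
#> # A tibble: 1 × 6
#>   group1      group2  median1 median2    p_adj stars
#> 1 anti-CTLA-4 control    1.40   0.461 7.50e-18 ***
```

The planted treatment shift (+1 in treated NK cells) is recovered:
median usage 1.40 in anti-CTLA-4 cells versus 0.46 in controls, with a
BH-adjusted rank-sum p of 7.5e-18 (three stars). Transfer the patterns
into the second "species" (30% of homologs missing) and into a
simulated patient cohort:

```r
tg  <- simulate_target_species(truth, homolog_dropout = 0.3)
project(fit$A, tg$expr, homologs = tg$homolog_map)
#> <projection_result> 4 patterns x 300 samples (ols, 140 genes used, 60 dropped)

cl <- simulate_clinical(truth, n_patients = 500)   # generative AUC 0.75
roc_auc(cl, activation_weight, response)
#> <roc_result> AUC = 0.746 (259 positives, 241 negatives)

tidy(cox_fit(cl, c("activation_weight", "age")))
#> # A tibble: 2 × 8
#>   term                 coef    hr      se        p conf_low conf_high significant
#> 1 activation_weight -0.546  0.580 0.0573  1.64e-21 -0.658     -0.433  TRUE
#> 2 age                0.0130 1.01  0.00504 9.90e- 3  0.00312    0.0229 TRUE
```

The empirical AUC (0.746) reproduces the configured generative AUC of
0.75, and the Cox fit recovers the planted log-hazard of −0.5 per unit
activation weight (estimate −0.546, HR 0.58: higher activation, longer
survival) with age correctly adjusted. `run_pipeline(pipeline_config(seed
= 7), "out/")` chains all stages and writes TSV/JSON artifacts plus
provenance; reruns with the same seed are byte-identical.

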
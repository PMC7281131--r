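# tnhf

Genetic-ancestry-associated gene expression and heterogenic molecular
subtyping for triple-negative breast cancer (TNBC) cohorts.

Self-reported race is a coarse proxy for the genetic background that
regulates tumor gene expression: African American and European American
patients both carry substantial admixture. `tnhf` is for researchers who want
to replace the categorical race contrast with **quantified genetic ancestry**
— continuous per-individual admixture proportions estimated from SNVs — and
to characterize TNBC subtype heterogeneity beyond single hard labels. It
provides:

- **Supervised admixture estimation.** Per-individual ancestry proportions
  `q` over K reference populations, by EM on the binomial likelihood
  `sum_j [ g_j log p_j + (2 - g_j) log(1 - p_j) ]` with
  `p_j = sum_k q_k f_kj`, where `g_j` is the alternate-allele dosage and
  `f_kj` the fixed reference-panel frequency. Includes the standard variant
  filters (biallelic SNVs only, panel harmonization, pooled minor-allele
  frequency ≥ 5%).
- **A continuous-ancestry expression screen.** Gene-by-gene OLS of log2 CPM
  on an ancestry proportion (`2^slope` = fold change at full ancestry
  contrast), Benjamini–Hochberg FDR control, a Welch two-group contrast for
  the self-reported-race comparison, and overlap/fold-change summaries
  between screens.
- **TNHF subtyping.** Rank-based signature scores (minimum-rank ties; median
  or mean summarized rank per signature), Spearman correlation scores against
  ±1 signature templates for the four valid TNBC subtypes (BL1, BL2, LAR, M),
  reassignment of the retired IM/MSL categories to the best valid subtype,
  and Ward clustering of the sample × (method, subtype) correlation-score
  matrix into heterogenic category nodes labelled `BL2+/BL1-`, `M-`, `IND`, …
- **A synthetic-cohort generator** (Balding–Nichols panels, Dirichlet
  admixture, planted ancestry-effect genes, planted subtype signatures,
  negative-binomial counts) so every stage can be validated against known
  ground truth.

## Worked example

Simulate a cohort with known truth, estimate ancestry, screen for
ancestry-associated genes, and subtype the tumors:

```r
library(tnhf)

cfg <- sim_config(J = 2000, n = 40, G = 1500, n_effect_genes = 60, seed = 42)
cohort <- simulate_cohort(cfg)

flt <- filter_variants(cohort$genotypes, cohort$panel, maf_min = 0.05)
ancestry <- cohort_ancestry(flt$genotypes, flt$panel)
ancestry
#> # A tibble: 40 × 7
#>   sample_id  q_AFR q_EUR  q_EAS loglik n_iter converged
#>   <chr>      <dbl> <dbl>  <dbl>  <dbl>  <int> <lgl>
#> 1 S1        0.780  0.206 0.0144 -2046.    925 TRUE
#> 2 S2        0.281  0.615 0.104  -2145.    243 TRUE
#> 3 S3        0.0341 0.635 0.331  -2163.    496 TRUE
#> # ℹ 37 more rows
```

Each row is one individual's estimated admixture (rows sum to 1), with the
final log-likelihood and EM iteration count. Screen every gene against the
African proportion:

```r
screen <- screen_ancestry_genes(cohort$expression, ancestry, component = "AFR")
screen
#> <ancestry_screen> AFR: 1500 genes tested, 57 significant at q < 0.05
head(tidy(screen), 3)
#> # A tibble: 3 × 7
#>   gene_id  slope    se t_stat       p_value n_used    q_value
#>   <chr>    <dbl> <dbl>  <dbl>         <dbl>  <int>      <dbl>
#> 1 gene0397  1.59 0.202   7.85 0.00000000179     40 0.00000269
#> 2 gene0612  1.92 0.252   7.59 0.00000000394     40 0.00000295
#> 3 gene1428  1.65 0.236   6.99 0.0000000250      40 0.0000125
```

The slope is log2 expression change per unit African proportion — a slope of
1.59 means a ~3-fold difference contrasting a fully African against a fully
European genome. Of the 60 planted effect genes, 53 are recovered here
(recall 0.88 at n = 40; `autoplot(screen)` draws the volcano). Subtype calls
and heterogenic nodes:

```r
calls <- call_with_reassignment(cohort$expression, cohort$signatures)
table(primary = calls$primary, reassigned = calls$reassigned)
#>        reassigned
#> primary BL1 BL2 LAR  M
#>     BL1  12   0   0  0
#>     BL2   0  15   0  0
#>     LAR   0   0   5  0
#>     M     0   0   0  8

cs <- build_cs_matrix(cohort$expression, normalize_log(cohort$expression),
                      cohort$signatures)
het <- cluster_heterogenic(cs, k = 4)
status_labels(cs, het$clusters)[, 1:6]
#> # A tibble: 4 × 6
#>   cluster label             status_BL1 status_BL2 status_LAR status_M
#>     <int> <chr>             <chr>      <chr>      <chr>      <chr>
#> 1       1 M+/BL2-/BL1-/LAR- -          -          -          +
#> 2       2 BL2+/BL1-/LAR-/M- -          +          -          -
#> 3       3 LAR+/BL2-/BL1-/M- -          -          +          -
#> 4       4 BL1+/BL2-/M-/LAR- +          -          -          -
```

Every reassigned call is one of the four valid subtypes, and the four
clusters recover the four planted identities exactly (accuracy 1.0 against
the simulation truth; this cohort plants single-subtype tumors, so each node
is one subtype present and the rest absent — real cohorts produce mixed
nodes such as `BL2+/BL1-` alongside `IND`). `run_pipeline(run_config(...))`
runs all stages from files (VCF genotypes, panel/expression TSV, GMT
signatures) and writes per-stage tables plus a checksum manifest.

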
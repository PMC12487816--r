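# recalvg

Recalibrating differential-expression fold changes by genetic dosage
variance.

## The problem

A differential-expression (DE) analysis ranks genes by how much their
expression changes between conditions. But genes differ enormously in how
much their expression *naturally* varies between individuals: a 1.5-fold
change is unremarkable for a gene whose expression swings widely across the
population, and dramatic for a tightly constrained dosage-sensitive gene.
Nominal fold-change rankings are therefore dominated by highly variable
"responder" genes, while constrained regulators with small but meaningful
shifts sink down the list.

`recalvg` rescales each gene's log fold change by the standard deviation of
its genetically regulated expression — the gene's dosage variance V^G, in
squared log-fold-change units, estimated from population allelic-expression
data — so that changes are expressed in units of natural genetic dosage
variation:

```
FC̄_g = FC_g / sqrt(V_g)
```

The package is aimed at transcriptomics analysts who already have a
DESeq2-style result table and per-gene (or per-tissue) V^G estimates, and
want to re-prioritise their DE genes by biological significance rather than
raw effect size.

## What the package does

* **Recalibration** — `recalibrate()` joins a DE table with a V^G map,
  computes FC̄ for the significant genes, and ranks genes by both nominal
  and recalibrated absolute fold change; `select_top_n()` /
  `select_top_half_rounded()` implement the selection rules used in
  enrichment comparisons, and `abs_pearson()`, `spearman_bootstrap_ci()`,
  `compare_gene_sets_mwu()`, `filter_by_tpm()` the accompanying statistics.
* **Cross-tissue V^G inference** — `infer_vg()` imputes missing
  tissue-specific V^G cells: measured estimates are first adjusted to each
  gene's mean expression level through a per-tissue log–log fit of
  expression on variance, then a similarity-weighted mean over the (up to
  five) most-correlated tissues is re-adjusted to the target tissue's
  expression. `weighted_harmonic_mean_vg()` aggregates tissue estimates into
  one value per gene with TPM weights; `lowest_vg_tissue()` reports each
  gene's most constrained tissue.
* **Enrichment comparison** — `hypergeometric_ora()` (one-sided
  hypergeometric with Benjamini–Hochberg correction),
  `compare_selections()` (adjusted p of 1 imputed on the non-enriched
  side), `keyword_group_logmean()`, `assign_rarest_label()`, and
  `binomial_lowest_tissue_test()`.
* **Synthetic studies** — `simulate_vg_study()` generates expression and
  V^G matrices linked by the assumed log–log model, with correlated tissue
  blocks, missing-not-at-random V^G entries concentrated in lowly expressed
  genes, and a DE table with designated low-variance *driver* and
  high-variance *responder* genes, so the whole pipeline is testable
  without any external data. `mask_additional()` + `evaluate_recovery()`
  quantify held-out imputation accuracy.
* **I/O and CLI** — readers/writers for DESeq2-dialect DE tables,
  gene × tissue TSV matrices, and GMT gene-set files; a `recal` command
  line (`inst/scripts/recal`) with `simulate`, `recalibrate`, `infer-vg`,
  `aggregate-vg`, `enrich-compare`, and `evaluate` subcommands.

All user-facing functions take and return tibbles, and the main result
types have `tidy()`, `glance()`, and `autoplot()` methods.

## Worked example

```r
library(recalvg)

truth <- simulate_vg_study(sim_config(seed = 1))

# impute the 20% missing V^G cells from correlated tissues
inference <- infer_vg(truth$vg_observed, truth$expression, k = 5)
inference
#> V^G inference: 2000 genes x 10 tissues; 16000 measured cells, 4000 inferred (k = 5)

# aggregate across tissues (TPM-weighted harmonic mean) and recalibrate
vg_mean <- weighted_harmonic_mean_vg(inference$v_hi, truth$expression)
recal <- recalibrate(truth$de, vg_mean, fdr_cutoff = 0.05)
recal
#> # Recalibrated fold changes: 400 genes
#> # A tibble: 400 × 6
#>   gene_id nominal_fc       vg recal_fc rank_nominal rank_recal
#>   <chr>        <dbl>    <dbl>    <dbl>        <int>      <int>
#> 1 g01165      -0.270 0.000167    -20.9          111          1
#> 2 g01771       0.437 0.000730     16.2           15          2
#> 3 g00975       0.341 0.000446     16.1           55          3
#> ...

abs_pearson(recal$nominal_fc, recal$recal_fc)$estimate
#> [1] 0.6155003
```

The top recalibrated gene (`g01165`) sits at rank 111 nominally: its fold
change of −0.27 is modest in absolute terms, but enormous relative to its
tiny dosage variance (V^G ≈ 1.7 × 10⁻⁴, i.e. a shift of ~21 population
standard deviations). The moderate correlation (0.62) between absolute
nominal and recalibrated fold changes shows that recalibration genuinely
reorders the list rather than rescaling it.

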
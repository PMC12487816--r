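---
title: "Recalibrating fold changes by genetic dosage variance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recalibrating fold changes by genetic dosage variance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(recalvg)
```

## The model

A gene's dosage variance V^G estimates the variance in its expression that
is attributable to genetic *cis*-regulatory differences between individuals
in a population. It is measured in squared log-fold-change units, so
`sqrt(V^G)` is directly comparable to a log fold change from a DE
analysis. Recalibration expresses each significant gene's change in those
units:

$$\bar{FC}_g = \frac{FC_g}{\sqrt{V_g}}.$$

Two assumptions matter. First, the fold changes and V^G must share one log
base; the package never converts bases, because the recalibrated ranking is
invariant to a common base and any mismatch is undetectable from the
numbers alone — it is the user's contract. Second, V^G values are
variances, hence strictly positive; zero or negative inputs are rejected,
never silently clamped. Genes without a V^G estimate cannot be recalibrated
and are excluded; genes with a missing adjusted p-value are treated as
non-significant.

Recalibration preserves the sign of regulation, is exactly equivariant
under rescaling of V^G (`V -> c^2 V` divides every recalibrated fold change
by `c`), and for a constant V^G leaves the ranking untouched. These
identities are asserted exactly in the test suite, not approximately.

## Cross-tissue inference of missing V^G

Tissue-specific V^G estimates are missing wherever allelic expression data
were too sparse to fit, and the missingness is not at random: lowly
expressed genes are harder to estimate. The inference pipeline
(`infer_vg()`) imputes a cell from the tissues whose V^G profiles correlate
best with the target tissue, with an expression-level correction on both
ends:

1. **Pseudocount.** Expression E (TPM) is shifted by the smallest positive
   value observed anywhere in the matrix, so logs are defined at zero
   expression. The pseudocount is computed over present cells only and
   missing cells stay missing.
2. **Per-tissue fit.** For each tissue, ordinary least squares of
   `log(E)` on `log(V)` over the genes with both values gives
   `(beta0_t, beta1_t)`. Natural logarithms are used throughout; `beta1`
   and the adjustment factors below are invariant to the common log base,
   so this is a documented convention rather than an option. At least three
   shared genes and non-constant `log(V)` are required; otherwise the fit
   errors rather than returning a degenerate slope.
3. **Adjustment to mean expression.**
   `v_hat[g,t] = V[g,t] * (mean_r E[g,r] / E[g,t])^beta1_t`, the estimate
   expected if the tissue expressed the gene at its cross-tissue mean
   level. The mean is taken over tissues with a present expression value
   for that gene, so incomplete expression matrices divide by the number of
   observed tissues, not the total.
4. **Tissue similarity.** Spearman correlation of raw V^G between tissue
   pairs over their pairwise-complete genes. Pairs sharing fewer than three
   genes get a missing similarity and are never used as neighbors. The
   similarity is computed on raw V rather than on the adjusted `v_hat`,
   matching the definition of the procedure being implemented; since
   Spearman is rank-based and the adjustment is monotone per tissue only
   through the expression term, the two are not interchangeable.
5. **Neighbor selection.** For each cell, the up-to-`k` (default 5) tissues
   other than the target with the highest similarity, among tissues where
   the gene's estimate is defined and the similarity is present and
   strictly positive. If fewer qualify, all of them are used. Negative
   similarities are excluded as weights because a weighted mean with
   mixed-sign weights can leave the convex hull of its inputs and produce a
   non-positive variance.
6. **Weighted mean.** `v_dot[g,t]` is the similarity-weighted mean of the
   *neighbor* adjusted estimates `v_hat[g,s]`. (A weighted mean of the
   target's own value would be vacuous; the neighbor form is the only
   self-consistent reading and is the one implemented.)
7. **Re-adjustment.** `v_tilde[g,t] = (E[g,t] / mean_r E[g,r])^beta1_t *
   v_dot[g,t]` — the exact multiplicative inverse of step 3 at the target
   tissue, so composing the two at one tissue is the identity (asserted to
   1e-12). Cells with missing expression cannot be re-adjusted and stay
   missing; symmetrically, a cell whose expression is missing cannot be
   *adjusted* in step 3 either, so such tissues never serve as neighbors.

The combined matrix `v_hi` keeps measured values wherever they exist and
falls back to `v_tilde` elsewhere.

One structural point deserves a note. The per-tissue fit regresses
`log(E)` on `log(V)`, yet steps 3 and 7 reuse that slope `beta1` directly
as the exponent mapping expression ratios to variance ratios (rather than
its reciprocal, which a formal inversion of the regression would suggest).
The pipeline is implemented exactly in this printed form: the adjustment is
deliberately attenuated — with the default slope near −0.5 it moves
estimates by the square root of the expression ratio — and the held-out
recovery results below are obtained under it. "Fixing" the exponent would
change the procedure being implemented, so it is documented instead.

Inference is fully deterministic: identical inputs give bit-identical
outputs, and the whole pipeline is checked cell-by-cell against an
independent straight-line re-implementation (normal-equation fits,
rank-then-correlate Spearman, explicit per-cell loops) to a relative 1e-10
on a 500-gene × 8-tissue instance.

### Aggregation and per-gene summaries

The per-gene V^G used for recalibrating a bulk experiment is the weighted
harmonic mean over tissues, `sum_t w / sum_t (w / V)`, with per-tissue TPM
as the weight. The harmonic mean is the natural aggregate for variances
that act as denominators — it is dominated by the small, constrained values
rather than the large ones — and it provably stays within the min–max range
of the tissue values (property-tested). `lowest_vg_tissue()` reports each
gene's most constrained tissue, with ties broken by ascending tissue id for
determinism.

## Enrichment comparison

Selections by nominal and by recalibrated absolute fold change are compared
with a one-sided hypergeometric over-representation test per term,
Benjamini–Hochberg adjusted across the tested terms. Term membership is
intersected with the analysis universe (all genes with expression and V^G)
before term sizes are computed. The comparison keeps the union of terms
enriched in either selection and imputes an adjusted p of 1, with a flag,
on the side where a term is not enriched — making the comparison exactly
symmetric under swapping the selections. Keyword grouping is
case-insensitive substring matching on the term name, first match wins in
the user-given keyword order (the natural convention when a term name
contains several keywords), and group summaries are geometric means of the
adjusted p-values.

The BH correction is the one deliberate methodological substitution in the
package: web enrichment services use proprietary multiple-testing schemes
whose internals are not reproducible offline, and the comparison logic
(imputation, grouping, selection rules) is independent of which correction
is applied to both sides.

Two selection rules are exposed rather than one, because both are standard:
a fixed top-N (`select_top_n()`), and the top ~50% of significant genes
rounded to the nearest 100 (`select_top_half_rounded()`, round-half-up:
722 → 700, 750 → 800) with the count floored at 100 — a literal 50% of a
small study would select almost nothing — and capped at the table size.
All rankings break ties by ascending gene id so selections are
deterministic.

## Statistical conventions

* **Correlation between nominal and recalibrated fold changes** uses
  Pearson on absolute values: the sign of a fold change is unchanged by
  recalibration, and correlating signed values would inflate the estimate
  through shared directionality.
* **Bootstrap Spearman CIs** use the percentile method with paired
  resampling, default 1000 resamples at the 95% level, seeded for
  reproducibility. Resamples in which a vector degenerates to constant are
  dropped rather than counted as zero correlation.
* **Mann–Whitney U** comparisons are two-sided; the exact distribution is
  used when the combined sample size is at most 20 without ties (where it
  is verified against full enumeration of all rank arrangements), the
  normal approximation with tie correction otherwise.
* **Binomial focal-tissue test** is the upper tail `P[X >= k]`, so `k = 0`
  gives p = 1 and `k = n` gives `p0^n` exactly.

## The synthetic-data generator

`simulate_vg_study()` generates the structure the method assumes, with
defaults chosen once as a realistic desk-scale study and used unchanged
throughout the tests:

| parameter | default | what it encodes |
|---|---|---|
| `n_genes` × `n_tissues` | 2000 × 10 | desk-scale analogue of a transcriptome × tissue panel |
| `log_vg_mean`, `log_vg_sd` | ln 0.01, 1.0 | lognormal V^G: strictly positive, heavy right tail, median 0.01 in squared log-FC units |
| `tissue_block_count`, `tissue_effect_sd` | 2, 0.3 | blocks of related tissues sharing gene-level effects, giving higher within-block than between-block similarity |
| `cell_noise_sd` | 0.3 | independent cell-level noise on log V^G |
| `beta0`, `beta1`, `expr_noise_sd` | 2.0, −0.5, 0.3 | expression model `log E = 2 − 0.5 log V + eps`: lowly expressed genes are more variable |
| `missing_rate`, `low_expr_missing_boost` | 0.2, 2.0 | 20% missing V^G cells overall, concentrated 2× in the bottom expression quartile (missing-not-at-random) |
| `frac_drivers`, `frac_responders` | 0.05, 0.15 | designated gene sets for the DE table |
| `fc_scale` | 1.0 | scale of responder fold changes |

Driver genes are drawn from the bottom quartile of gene-level V^G and get
small but consistent fold changes (`|N(0.3, 0.1)|`); responders are drawn
from the top quartile — the generator's one free design choice, made so the
two sets differ in variance as sharply as in the biological dichotomy they
model — with `|FC| = fc_scale * sqrt(vg_g) * |N(1, 0.3)|`, tying fold
change to dosage variance exactly as the recalibration removes; null genes
get `N(0, 0.05)`. Adjusted p-values are *assigned* (< 0.001 for
drivers/responders, uniform on (0.1, 1) for null genes), not computed from
a test: the package consumes DE tables and must not re-derive significance.
The gene-level `vg_g` used for the DE construction is the
expression-weighted harmonic mean of the true tissue values, i.e. the same
aggregate the pipeline itself computes.

Everything is driven by a single integer seed through one RNG stream with
draws in a fixed order (genes outer, tissues inner), so runs are
bit-reproducible across platforms.

What the generator does *not* emulate: read-count noise and
mean–variance coupling of counts (expression is drawn directly in TPM),
realistic gene-gene correlation within pathways, uncertainty in the V^G
estimates themselves, and real tissue identities. Passing tests therefore
demonstrate that the algorithms implement their definitions and that the
pipeline recovers structure *of the kind it assumes*; they do not certify
performance on real GTEx-derived matrices, where the log–log relationship
is noisier and similarity structure is richer.

## Reference problem sizes and observed behaviour

The test suite and the acceptance script run the full pipeline at
2000 genes × 10 tissues (the generator defaults), with inference oracles
checked at 500 × 8 and 200 × 6, exact-enumeration oracles at universes of
at most 12 genes and rank tests of at most 20 observations. At the default
scale, masking a further 20% of observed cells and re-inferring them yields
a Spearman correlation between inferred and held-out true values of about
0.94, consistently above the ~0.92 of the copy-the-most-similar-tissue
baseline — the qualitative claim (weighted multi-tissue inference beats the
best single tissue) that motivates the pipeline. Per-tissue fits on the
generated data recover the expression-model slope to within 0.05 of the
generating −0.5 (attenuated slightly by the non-random missingness), the
Mann–Whitney difference between two sets constructed with 4-fold different
median V^G and `|FC| ∝ sqrt(V)` vanishes after recalibration (p ≈ 0.8
versus < 1e-50 before), and the driver term's enrichment strengthens by
>20 orders of magnitude of adjusted p under the recalibrated selection
while the responder term's weakens. All of these numbers are recomputed
from scratch — never stored — by `scripts/acceptance.R` and the test suite.

## Numerical and degenerate-input conventions

* Missing values in files are the literal string `NA` (empty accepted on
  read); parsing never coerces missing to zero, and all writers round-trip
  tables bit-identically.
* Gene identifiers are opaque strings; an optional flag strips trailing
  `.N` version suffixes for Ensembl-style ids, default off, covering both
  versioned and unversioned supplements.
* All rankings and tissue selections break ties lexicographically; no
  result depends on hash or input order.
* Degenerate inputs error early with the offending gene/tissue/row named:
  non-positive V^G, negative TPM, all-zero expression, constant vectors in
  correlations, empty significant-gene intersections, fewer than three
  genes for a fit.
* Equality-sensitive filters keep the boundary: `filter_by_tpm()` retains
  TPM exactly 1 at the default threshold, and the enrichment flag uses
  `adj_p <= alpha`.

## Limitations

* V^G uncertainty is not propagated into recalibration; point estimates
  are treated as known. Incorporating estimate noise would shrink extreme
  recalibrated values for poorly estimated genes.
* The expression adjustment inherits the attenuated exponent discussed
  above; inference accuracy at expression levels far from a gene's mean is
  correspondingly conservative.
* Model fitting for V^G itself (from allelic counts or eQTLs) is out of
  scope: V^G matrices are inputs.
* The enrichment engine is a standard hypergeometric/BH ORA; it does not
  model term overlap or gene-set dependence.
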
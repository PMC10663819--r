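---
title: "Screening focal-cluster-specific cell-cell communication channels"
author: "CCCscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening focal-cluster-specific cell-cell communication channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CCCscreen)
```

# The problem and the model

Tumors are tissues: malignant cells sit among immune, stromal and vascular
populations and exchange signals through ligand–receptor pairs. Given an
annotated single-cell dataset — every cell carries a cluster, a tissue
(`tumor` / `juxtatumor`), a patient and a dataset label — and a curated
dictionary of directed ligand→receptor interactions, this package asks
which channels a focal population (for us, a malignant cluster) uses
*specifically*, i.e. more than any other population in the same tissue.

The quantitative core is deliberately simple. Per cluster `C` and gene `g`
we compute the arithmetic mean `l_g^C` of log-normalized expression and the
fraction of the cluster's cells with a nonzero raw count. Communication
between an emitter `C1` and receiver `C2` is the sum over the `N` database
interactions of ligand mean times receptor mean,

$$ S_{C_1 \to C_2} \;=\; \sum_{(i,j)=1}^{N} l_i^{C_1} \, r_j^{C_2}, $$

and the per-interaction score of an emitter `C` aggregates that
interaction's products over all `K` receiving clusters,

$$ S_C(i,j) \;=\; l_i^{C} \sum_{k=1}^{K} r_j^{k}. $$

The incoming-direction mirror, $(\sum_k l_i^k)\, r_j^C$, is an explicit
construction in this package: the screen reports both directions, and the
receiver-summed form is the natural dual of the emitter-summed one. Both
sums include the focal cluster itself by default — autocrine loops are
biologically meaningful hits — with `includeFocal = FALSE` available for
sensitivity analysis.

A channel is called focal-specific when the focal cluster's score is at
least `ratio` (default 1.5, inclusive) times the best competing cluster's
score, and when the focal-side molecule — every subunit of the ligand
complex for outgoing channels, of the receptor complex for incoming ones —
is up-regulated in the focal cluster relative to a *reference* cluster
(the presumed cell of origin, taken from the adjacent tissue) by a Wilcoxon
rank-sum test with Bonferroni correction, log2FC ≥ 0.25 and adjusted
p < 0.05. Hits from several datasets can be intersected, keeping channels
found in at least two.

## Assumptions

* Cluster labels are trusted inputs; the method never re-clusters.
* Mean log-normalized expression is an adequate cluster summary; the
  minimum-percent filter (below) guards the means against rare-cell noise.
* The interaction database is directed and curated; the scores inherit its
  coverage and its errors.
* Specificity is relative: a channel used equally by two clusters is not a
  hit for either, however strong.

# Tunable parameters

| parameter | default | units / range | why this value |
|---|---|---|---|
| QC: min genes per cell | 200 | genes | standard droplet QC gate |
| QC: min UMI per cell | 1000 | counts | standard droplet QC gate |
| QC: max mitochondrial fraction | 0.20 | fraction, exclusive | dying-cell marker |
| normalization scale | 10^4 | counts | dominant single-cell convention |
| normalization pseudocount | 1 | counts | keeps `0 -> 0` and sparsity |
| min pct expressed | 0.10 | fraction, strict `<` | excludes communication genes rarely expressed in a cluster from that cluster's scores only |
| complex rule | minimum | {minimum, mean} | limiting-subunit semantics for heterodimers |
| specificity ratio | 1.5 | fold, inclusive `>=` | the screen's specificity margin |
| DE gate | log2FC 0.25, adj. p 0.05 | Bonferroni | conventional single-cell DE thresholds |
| family contrast | alpha 0.001, abs log2FC 0.25 | BH-FDR | strict two-gate family-level call |
| bulk validation | adj. p 0.001, log2FC 1 | Bonferroni | strict validation gate on products |

The normalization scale and pseudocount are not dictated by the method and
are therefore recorded in the object metadata and in every run manifest.
The heterodimer aggregation rule is likewise a genuine design choice:
`minimum` encodes that a complex cannot signal beyond its scarcest subunit,
`mean` is available because curated pipelines differ here, and the choice
is echoed in the outputs.

# Numerical and edge-case choices

* **Strict 10 % bound.** A gene expressed by exactly 10 % of a cluster's
  cells is kept (the exclusion is "less than 10 %"); the filter zeroes the
  *mean* of the gene in that cluster only, never the gene globally.
* **All-competitors-zero.** When every competing cluster scores 0 for an
  interaction, the specificity ratio is undefined; the interaction passes
  iff the focal score is positive, and the realized ratio is reported as
  `Inf`.
* **Zero-variance families.** If all cluster means of a family coincide,
  z-scores are set to 0 with a warning rather than dividing by zero.
* **Fold-change guard.** The family contrast uses
  `log2((mean_T + 1e-9)/(mean_J + 1e-9))`; the single-cell DE fold change
  follows the de-log/average/re-log convention with a +1 shift on both
  means.
* **DE pre-filter.** Genes are tested only when `|log2FC|` reaches the
  threshold; Bonferroni is applied over the tested genes.
* **Ties.** Wilcoxon tests run through `stats::wilcox.test`, which uses the
  exact distribution for small untied samples and the tie-corrected normal
  approximation otherwise; all-tied genes are assigned p = 1.
* **Degenerate inputs.** Empty databases score 0 with a warning; empty cell
  groups, missing focal/reference clusters, and all-zero-count cells are
  errors with the offending group named.

# The synthetic data generator

`simulateSCDataset()` draws genes × cells counts from a negative binomial
with gene-level baseline means log-normal around `mu` (dispersion `theta`)
and independent Bernoulli dropout. Cluster structure exists only where a
planted channel puts it: the channel's ligand (and/or receptor) subunits
are multiplied by a configured fold in the focal cluster's tumor cells.
The focal cluster exists only in tumor tissue; a reference cluster at
baseline exists only in the adjacent tissue (mirroring a malignant
population and its cell of origin); all other clusters live in both
tissues.

The reference scenario — 6 tumor clusters × 400 cells, `mu = 2`,
`theta = 2`, dropout 0.3, ligand fold 8, gene universe 1000 — is what the
recovery and null-calibration suites run on. The gene universe size is a
modeling constraint, not a free dial: with far fewer genes, per-cell totals
fall below the 1000-UMI gate the pipeline's own QC imposes, and the
library-size scale factor then inflates all log values so much that an
8-fold count difference compresses to less than 1.5× on log-mean profiles.
One thousand genes keeps simulated cells inside the QC-valid regime while
remaining desk-scale.

What the generator does *not* emulate: batch effects, trajectories,
gene–gene correlation, UMI saturation, or compositional shifts between
tissues. Passing tests therefore demonstrate the correctness and
calibration of the scoring and screening logic under a faithful null and a
planted alternative — not robustness to every artifact of real scRNA-seq.

`simulateBulkDataset()` is the bulk counterpart: negative-binomial counts,
log-normal per-sample library factors, and a tumor-only fold on the
ligand and receptor genes of planted pairs.

# The bulk validation and a symmetry caveat

The bulk step normalizes counts by median-of-ratios size factors
(`DESeq2::estimateSizeFactorsForMatrix`), centers and reduces each gene
across samples, forms the per-sample product of ligand and receptor
complex values on that scaled layer, and compares tumor versus normal
products by Wilcoxon with Bonferroni correction. Because products of
centered values can be negative, the fold-change gate is computed on the
normalized, non-centered layer with a +1 shift; both layers are emitted.

One property of this construction deserves emphasis. With per-gene
centering, a symmetric up-shift of both partners in *exactly balanced*
groups puts tumor values near `+m` and normal values near `-m` — and the
products `(+m)(+m)` and `(-m)(-m)` are nearly exchangeable, so the test
has almost no power in a balanced design (the acceptance script reports
this measured power honestly). In a cohort-like unbalanced design
(e.g. 538 tumors vs 72 normals, as in public tumor cohorts) the pooled
mean sits close to the tumor group, the symmetry breaks, and the measured
power at a planted 2-fold is 100 %. Users validating against balanced
cohorts should be aware that the scaled-product test is design-sensitive.
A related non-property: Wilcoxon on *products* is not invariant to
monotone per-gene transforms, so no such invariance is asserted anywhere.

# Problem sizes used by the test and acceptance suites

Oracle-equivalence and additivity checks run 50 random instances of up to
25 genes × 6 clusters × 20 interactions under both complex rules, against
an independently coded brute-force double loop, at 1e-10 relative
tolerance. Screen recovery and null calibration each run the reference
scenario over 100 seeds. The family-contrast null uses 200 tissue-label
shuffles; the bulk suites use 50 planted replicates per design and 100
condition permutations. These sizes are the package's own choices for a
thorough desk-scale audit.

# Known limitations

* Scores are products of log-scale means: they are unitless, comparable
  within a dataset, and deliberately rescalable to 0–100
  (`rescaleTo100()`) rather than interpretable absolutely.
* The DE gate requires *every* subunit of the gated side by default
  (`deGate`, configurable): a conservative reading of complex function.
* The specificity rule compares emitter-summed scores (the per-pair
  variant is available via `perPair = TRUE`); the two can disagree when a
  channel is strong toward one receiver but weak in aggregate.
* Cross-dataset intersection matches interactions by identifier; database
  versions must be harmonized upstream.
* The cluster-label input contract means mis-clustering propagates
  directly into the screen.
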
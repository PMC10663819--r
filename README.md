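# CCCscreen

Screening of cell–cell communication channels used *specifically* by a
focal cell population — typically malignant cells in a tumor
microenvironment — from annotated single-cell RNA-seq data, with a bulk
RNA-seq validation step.

## Who this is for

Computational biologists with an annotated single-cell dataset (cluster,
tissue, patient and dataset labels per cell), a curated ligand–receptor
interaction dictionary, and a question of the form *"through which
ligand–receptor channels does this cell population talk to the rest of the
tissue, and which of those channels are specific to it?"*. Clustering,
integration and doublet removal are upstream of this package: cluster
labels are inputs.

## The model

Given a database of `N` directed ligand→receptor interactions (heterodimeric
complexes of up to 2 ligand and 3 receptor subunits are supported), and
per-cluster mean expression profiles `l_i^C`, `r_j^C` (means of
log-normalized expression, with communication genes expressed by < 10 % of
a cluster's cells zeroed for that cluster), the package computes:

* **Communication score** between an emitting cluster `C1` and a receiving
  cluster `C2` (self-pairs included, so autocrine loops are scored):

  `S(C1→C2) = Σ_{(i,j) = 1..N}  l_i^C1 · r_j^C2`

* **Per-interaction emitter-summed score** for one interaction `(i, j)` and
  an emitter `C`, over all `K` clusters:

  `S_C(i,j) = l_i^C · Σ_{k = 1..K} r_j^k`

  and its mirror for incoming communication,
  `(Σ_k l_i^k) · r_j^C`.

* **Specificity rule**: an interaction is focal-specific when the focal
  cluster's per-interaction score is at least 1.5× the score of every
  competing cluster.

* **Differential-expression gate**: the focal-side molecule (every subunit)
  must additionally be up-regulated in the focal cluster versus a reference
  cluster (e.g. the presumed cell of origin in adjacent tissue), by a
  Wilcoxon rank-sum test with Bonferroni correction (log2FC ≥ 0.25,
  adjusted p < 0.05). Hits can be intersected across datasets.

* **Family scores**: per-cell sums of normalized expression over
  communication-molecule families (cytokines, chemokines, immune
  checkpoints, growth factors, cell adhesion molecules), centered-reduced
  to z-scores across clusters and contrasted between tumor and adjacent
  tissue (Wilcoxon + BH-FDR, |log2FC| > 0.25).

* **Bulk validation**: median-of-ratios normalization, per-gene scaling,
  per-sample ligand×receptor expression products, Wilcoxon tumor vs normal
  with Bonferroni correction (p_adj < 0.001, log2FC ≥ 1).

A negative-binomial simulator with planted channels
(`simulateSCDataset()` / `simulateBulkDataset()`) provides ground-truth
data for every stage.

## Worked example

```r
library(CCCscreen)

db  <- syntheticInteractionDB()              # 21 interactions, 5 families
id  <- interactionIds(db)[1]                 # "LG01 / RC01"

# plant one outgoing channel: ligand 8x up in the focal cluster
cfg <- simConfig(plantedChannels = list(list(interaction_id = id, f_L = 8)),
                 seed = 7)
sim <- simulateSCDataset(cfg, db)
sce <- normalizeLog(sim$sce)

scr <- screenDataset(db, sce, focal = "cancer", reference = "PT")
subset(scr, final)
```

```
   dataset interaction_id direction focal_score max_competitor    ratio passes_specificity passes_de final
1 dataset1    LG01 / RC01  outgoing    66.08724       40.64675 1.625892               TRUE      TRUE  TRUE
```

The planted channel — and nothing else — is recovered: its emitter-summed
score at the focal cluster (66.1) is 1.63× the best competing cluster's
score, clearing the 1.5× specificity bound, and its ligand passes the DE
gate versus the reference cluster. The same objects feed
`allPairScores()` (the K×K communication matrix, rescalable to 0–100 with
`rescaleTo100()`), `perCellFamilyScores()` / `tissueContrast()` for the
family-level analyses, and `intersectScreens()` to tier hits found in
several datasets. `runScreen()` wraps the whole chain behind a YAML/list
config and writes TSV tables plus a JSON manifest of all thresholds.

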
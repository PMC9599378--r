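---
title: "ACAM: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ACAM: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the method it implements:
the model and its assumptions, the parameters that matter, what the
synthetic generator does and does not emulate, and the choices made where
the design was genuinely open.

# The annotation model

ACAM annotates cells from marker knowledge alone. Its central premise is
the defining property of a marker gene: high expression in its own cell
type, comparatively low expression elsewhere. Three consequences shape
the three stages.

**Consensus before annotation.** Any single clustering method makes
characteristic mistakes; cells grouped together by *every* method are
far more likely to be of one type. ACAM therefore runs five backends,
drops the one whose adjusted Rand index (ARI) profile against the others
has minimum variance (it agrees most uniformly with everyone, so it
contributes the least diversity to the ensemble), and intersects the
co-clustering relations of the rest. The intersection of equivalence
relations is an equivalence relation, so the unanimous co-clustering
graph is a disjoint union of cliques; Louvain community detection on it
recovers these cliques robustly, and only communities larger than a size
threshold become representative clusters. The strictness of unanimity is
the point: the intersection can split, but never merge, groups that some
method separates, so representative clusters are biased toward purity at
the cost of coverage — exactly the right trade-off when their labels
will be propagated to everything else.

**Stumps match the marker model.** A depth-1 gradient-boosted tree is a
single expression threshold on a single gene. If a cluster is a real
cell type, its markers are precisely the genes on which one threshold
separates it from the rest, so the total gain a stump ensemble assigns
to each gene is a direct measurement of "marker-ness" for that cluster.
Summing gains over each type's marker set (`Score_t`) and taking the
argmax converts importances into a label. Two guards keep the fit
honest: genes whose mean inside the cluster does not strictly exceed the
mean outside are excluded (a marker of the cluster cannot be
down-regulated in it), and the cluster is oversampled to the size of its
complement so the hinge loss does not ignore the minority class.

**Propagation is deliberately simple.** Leftover cells — those outside
every representative cluster — get the label of their nearest annotated
cell (k = 1) in a 2-D UMAP embedding of the marker matrix. With
representative clusters that are large, pure and well-spread, the
nearest labelled neighbour is almost always of the right type, and a
single neighbour avoids the smoothing that a larger k would apply across
type boundaries.

# Parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `threshold` | 10 | minimum representative-cluster size, strictly exceeded. Small communities are too thin to support a one-vs-rest fit; 10 cells is the conventional floor. Lower it for very small datasets. |
| `k` | 1 | neighbours in label propagation; see above. |
| `resolution` | 1.0 | Louvain resolution. On a near-disjoint-clique graph the communities barely depend on it. |
| booster | depth 1, hinge loss, 100 rounds, eta 0.3 | depth and objective are the model (stumps + margin loss); rounds and learning rate follow the boosting tool's defaults, since the fit is used only for importances, not prediction. |
| UMAP | 15 neighbours, min_dist 0.1 | standard defaults; the embedding only needs to keep types locally coherent. The embedding runs on the marker matrix itself — the matrix the whole method is defined on — not a PCA of it. |
| normalization | median size factor, then log1p | the simplest size-factor reading; a `passthrough` mode accepts pre-normalized input, and the mode is recorded in the object so runs are reproducible. |
| backends | 5 self-contained | SNN-graph Louvain, t-SNE + k-means, PCA k-means, PCA Gaussian mixture, PCA Ward; each with its own k selection (BIC for the mixture, a silhouette scan for the k-based methods). Any backend can be replaced, or partitions injected from files — diversity matters more than the specific algorithms. |

# Numerical and degenerate-input choices

* **Ties are never silent.** Minimum ARI variance: the earliest backend
  is removed, and the tie is logged. Equal `Score_t`: the
  lexicographically smallest type name wins, logged with the margin.
  Equidistant neighbours in propagation: the labelled cell with the
  smallest index wins.
* **Row variance excludes the diagonal.** Every diagonal ARI entry is
  exactly 1; with only five methods, including it would shift variances
  enough to change removal decisions, while the quantity of interest is
  disagreement among *peers*. The matrix is small enough that both
  variants are trivially computable; the off-diagonal one is used
  throughout.
* **Importance = total gain.** Gain measures the loss reduction of each
  split, which for stumps is exactly the quality of the one-threshold
  separation a marker provides. Split frequency would reward genes split
  on often but weakly.
* **Prefilter means use the original cluster**, not the oversampled
  multiset: uniform duplication leaves expected means unchanged, and
  using the originals removes any seed dependence from a deterministic
  filter.
* **`unknown` vs `unassigned`.** A cell with zero expression across all
  marker genes is `unknown` (the input carries no usable information); a
  representative cluster whose prefilter or fit yields no importance
  mass is `unassigned` (the marker database has nothing matching this
  group). The two are distinct outputs and both count as errors in
  evaluation unless the truth says otherwise.
* **Macro F1** is computed as the harmonic mean of macro-averaged
  precision and macro-averaged recall. This is not the more common mean
  of per-class F1 scores; the latter is available behind
  `macroF1 = "mean_of_f1"`. Zero-denominator classes contribute 0 to
  the averages, and an MCC with zero denominator is reported as 0 — all
  logged.
* Zero-total cells are dropped at normalization (size factor undefined)
  and resurface in the output as `unknown`.

# The synthetic generator

`simulateCellTypes()` plants `T` cell types: each gets a dedicated set
of marker genes whose negative-binomial mean is `foldChange` times the
baseline in its own cells, on top of log-normal per-cell library sizes
and independent dropout. An optional fraction of each type's markers is
shared with the adjacent type, mimicking the overlapping marker sets of
real databases. The defaults — 3 types × 150 cells, 10 markers/type, 60
background genes, fold change 10, dispersion 2, 20% dropout — describe a
moderately sparse, overdispersed dataset in which the types are
recoverable but the per-gene signal is noisy.

What the generator does *not* emulate: batch effects, continuous
trajectories, doublets, ambient RNA, or cell types defined by marker
*absence*. Passing the end-to-end tests therefore shows the machinery is
correct under the marker model's own assumptions; it does not certify
performance on tissues where those assumptions fail (closely related
subtypes sharing most markers, markers expressed in gradients rather
than blocks).

Test and benchmark sizes were chosen to exercise each property at the
smallest informative scale: oracle-equivalence checks run on hundreds of
random instances of n ≤ 30–500 (pair counting and exhaustive AND are
quadratic), the end-to-end recovery benchmark uses 450 cells across 3
types, and the fold-change degradation sweep uses 300 cells per run over
fold changes 2, 4 and 8 with three seeds each.

# Known limitations

* Every cell receives a known type (or `unknown`/`unassigned`); there is
  no novel-type discovery, and rare types below the size threshold can
  only be labelled by propagation from a neighbouring cluster.
* Gene symbols are matched case-sensitively by default (a `caseFold`
  flag exists); there is no identifier translation or ortholog mapping.
* The diversity-removal step always removes exactly one method,
  whatever the ensemble's actual redundancy.
* Louvain on a weighted or near-clique-violating graph can in principle
  split a clique; with the unanimous intersection this regime
  essentially never arises, but the seed is exposed for reproducibility.

# Session info

```{r}
sessionInfo()
```
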
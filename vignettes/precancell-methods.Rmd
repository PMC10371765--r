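---
title: "Methods: consensus markers and ensemble k-NN for malignant-cell calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus markers and ensemble k-NN for malignant-cell calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`precancell` labels single cells as malignant or non-malignant by combining
two ideas: marker genes that behave consistently across several cancer types,
and an ensemble of simple k-nearest-neighbor classifiers, one per labeled
reference dataset. This vignette explains the model, its tunable parameters,
the numerical conventions, and what the simulation-based tests do and do not
establish.

## Normalization

Two dialects of log-normalization are supported, matching the two dominant
scRNA-seq quantification styles:

* **Full-length (TPM) data**: `E = log2(TPM/10 + 1)`. The divisor 10 rescales
  transcripts-per-million toward the ~100k transcripts a full-length
  single-cell library actually samples, so that the pseudocount 1 sits at a
  sensible depth.
* **UMI counts**: each cell is scaled to a total of `size_factor` (default
  10,000) counts and transformed by the natural `log(x + 1)`. Cells with zero
  total count are kept as all-zero columns rather than dropped: quality
  control is upstream of this package, which never silently removes cells.

Before classification, every gene is min–max scaled to `[0, 1]`:
`x_scaled = (x − min x)/(max x − min x)`, with the minimum and maximum taken
per gene *across the cells of one dataset*. A reference and a query are each
scaled with their own statistics; no statistic leaks between datasets. Genes
constant within a dataset map to all-zero rows, which makes them inert in any
distance computation. Scaling is applied per gene, so scaling all genes and
scaling only the classifier's feature genes are equivalent on the feature
subspace; the implementation scales the aligned feature rows after feature
alignment.

## Marker discovery

Within one labeled dataset, each gene is tested malignant vs non-malignant
with a two-sided Wilcoxon rank-sum test. The test uses the exact null
distribution when both groups have at most 8 observations and no ties (the
regime where enumeration is cheap and the test's own oracle can be checked
exhaustively), and the normal approximation with tie and continuity
corrections otherwise. P-values are Bonferroni-adjusted by the **total**
number of genes present in the dataset — not just the genes actually tested —
which is the conservative convention and keeps the adjustment independent of
any speed-motivated pre-filtering.

A gene is called up in malignant cells when all three hold:

| filter | default | meaning |
|---|---|---|
| `p_adj_threshold` | 0.05 | Bonferroni-adjusted rank-sum p-value |
| `min_pct` | 0.10 | detected (normalized value > 0) in ≥ 10% of the favored class |
| `min_log_fc` | 0.25 | mean log-expression difference in favor of the called class |

and up in non-malignant cells symmetrically. The detection filter is applied
to the favored class only. `log_fc` is by default the difference of class
means of log-normalized expression; a `log_fc_method = "seurat"` switch
offers the alternative convention (log2 ratio of expm1-backtransformed class
means with pseudocount 1) for parity comparisons with pipelines that use it.
The two conventions order genes similarly but are not numerically identical;
the simple mean difference is the package default because it is exactly the
quantity the threshold is applied to in the log domain.

Genes that cannot pass the detection-and-fold-change filters in either
direction are skipped before testing. This is purely a speed optimization:
since those filters enter every call conjunctively, the skipped genes would
be called `none` regardless of their p-value, and the Bonferroni multiplier
counts all genes either way, so the output is identical to testing
everything. Skipped genes carry `NA` p-values.

Consensus sets are the intersection across datasets: a tumor marker gene
(TMG) must be up in malignant cells in *every* reference, a non-tumor marker
gene (NMG) up in non-malignant cells in every reference. Intersection is
deliberately strict — unanimity, not a majority — because the marker set is
meant to transfer across cancer types. The bundled set (73 TMGs, 186 NMGs)
came from five references covering renal cell carcinoma, head and neck
squamous cell carcinoma, melanoma, lung adenocarcinoma and breast cancer.

## The ensemble classifier

Each labeled reference backs one base classifier: k-NN with `k = 5` on the
marker features shared by that reference and the query (feature alignment
reports coverage of the marker set and fails only at zero overlap; below 50%
coverage it warns but proceeds). For a query cell, the base vote is the
majority label among the k nearest reference cells, and the
malignant-neighbor fraction is retained as a continuous signal. The final
label is the majority vote across base classifiers; `vote_frequency` is the
fraction voting malignant and `score` the mean malignant-neighbor fraction.

Numerical conventions, chosen where the method itself is agnostic:

* **Distance**: Euclidean on the min–max-scaled features, the plain k-NN
  convention; cosine distance is available via `metric = "cosine"`.
* **Distance ties** at the k-th neighbor break by ascending reference cell
  index. This is stable and deterministic; random tie-breaking would make
  repeated runs disagree on degenerate data.
* **Odd counts**: `k` must be odd, so a base vote is never tied. With an odd
  number of references the ensemble label is equivalent to
  `vote_frequency > 0.5`. An even reference count (only possible when the
  user supplies one) is accepted with a warning; a split vote then falls
  back on `score > 0.5`, and a score of exactly 0.5 resolves to
  non-malignant with a warning.
* **Parallelism**: query cells are classified independently, so the
  `workers` option shards cells across forked workers with bit-identical
  results to sequential evaluation.

A known degree of freedom versus other implementations of the same recipe:
the distance metric and the decision to scale reference and query separately
(rather than jointly) are not dictated by the method description; both are
explicit options here and potential sources of small parity differences.

## Evaluation

Malignant is the positive class. `confusion_metrics()` reports accuracy,
sensitivity, specificity, balanced accuracy (exactly the mean of sensitivity
and specificity), and the false-negative/false-positive rates; with a
single-class truth the undefined rates are `NA` with a warning. `auroc()` is
the rank-based Mann–Whitney statistic — the probability a random malignant
cell outscores a random non-malignant one, ties counted half — computed from
midranks, so it agrees with all-pairs enumeration exactly and is invariant
under monotone transforms of the score. The ensemble's `score` (mean
malignant-neighbor fraction) is used as the AUROC input because it is finer
grained than the vote frequency, whose resolution with five references is
only six levels; this choice is configurable by passing any other score
vector.

`cross_validate()` runs the within-dataset protocol: class-stratified,
seeded 10-fold assignment; each fold predicted by a *single* base classifier
trained on the remaining folds (no ensemble — within one training set there
is only one reference); held-out predictions pooled into one confusion table
and AUROC. Stratification avoids folds that lose a class on imbalanced data,
which would make sensitivity or specificity undefined in some folds.

## The simulator

`simulate_dataset()` generates the statistical structure the pipeline
assumes, with no attempt to copy any particular real dataset:

* counts are gamma-Poisson (negative binomial): gene baseline abundances are
  lognormal (sdlog 1), per-cell library sizes lognormal (sdlog 0.3) around
  `library_size_mean`, and per-entry gamma noise with `dispersion` = 1/size
  gives variance `mu + dispersion*mu^2`;
* planted tumor markers have their mean multiplied by `exp(effect_size)` in
  malignant cells (planted non-tumor markers symmetrically), i.e.
  `effect_size` is a natural-log mean shift;
* independent multiplicative dropout zeroes each observed count with
  probability `dropout_rate`;
* the counts are then passed through the package's own UMI normalization.

Defaults — 300 cells per class, 2,000 genes, 50 planted markers per
direction, effect size 2, 20% dropout, dispersion 0.4, ~5,000 counts per
cell — describe a moderately deep droplet experiment with a strong,
biologically plausible class signal; they are the conditions under which the
package's own recovery properties are stated and tested. Panels of
references derive member seeds as `seed + i`, and a `shared_marker_fraction`
controls how many planted markers are common to all members (the rest are
panel-private and disjoint across members), so the consensus intersection
has both true positives and true negatives to find.

What the simulator does *not* emulate: batch effects, cell-cycle and subtype
structure, doublets, gene-gene correlation, and realistic mean-variance or
dropout-expression coupling. Passing the planted-marker and end-to-end
recovery tests therefore shows the pipeline is correct and powerful under
its own model assumptions — it does not certify accuracy on real tumors,
where the bundled marker set and real labeled references carry that burden.

## Problem sizes and determinism

The test suite and the acceptance script run the full pipeline at the
default simulation scale (five references of 600 cells × 2,000 genes plus a
600-cell query, a few seeds each), which completes in well under a minute on
one core — large enough to exercise every filter, small enough to iterate
on. All generators take explicit seeds, restore the caller's RNG state, and
are bit-reproducible given a seed; the command-line interface reproduces
byte-identical output files for identical inputs and seed.

## Limitations

* Binary output only: the package does not subtype non-malignant cells, emit
  an "unknown" class, or calibrate probabilities; `score` is a ranking
  signal, not a calibrated posterior.
* The bundled marker set is defined on human gene symbols; queries quantified
  against other identifier schemes must be mapped before use.
* Marker discovery assumes two well-populated classes (≥ 2 cells each to run,
  far more for power) and log-normalized input; it will refuse raw matrices.
* k-NN prediction is O(reference cells × query cells) per reference; very
  large queries should use the `workers` option.
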
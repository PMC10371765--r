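# precancell

Classify single cells as **malignant** or **non-malignant** from their
transcriptomes.

A recurring task in cancer single-cell RNA-seq analysis is separating tumor
cells from the immune, stromal and other normal cells captured alongside
them. `precancell` does this with a deliberately simple supervised recipe:

1. **Consensus marker discovery.** In each labeled reference dataset, every
   gene is tested for differential expression between malignant and
   non-malignant cells with a Wilcoxon rank-sum test. A gene is called *up in
   malignant cells* when the Bonferroni-adjusted p-value is `< 0.05`, it is
   detected (normalized expression `> 0`) in at least 10% of malignant cells,
   and the mean log-expression difference (malignant − non-malignant) exceeds
   0.25; *up in non-malignant cells* symmetrically. Genes called in **every**
   reference form the tumor marker genes (TMGs) and non-tumor marker genes
   (NMGs). The package bundles a consensus set of 73 TMGs and 186 NMGs
   derived from five labeled cancer datasets (renal cell carcinoma, head and
   neck squamous cell carcinoma, melanoma, lung adenocarcinoma, breast
   cancer); `load_bundled_markers()` returns it.

2. **Ensemble k-NN classification.** With the marker genes as features, each
   reference dataset backs one k-nearest-neighbor base classifier (`k = 5`,
   Euclidean distance). Expression is first min–max scaled per gene,
   `x_scaled = (x − min x) / (max x − min x)`, within each dataset
   (reference and query each use their own statistics). A query cell's base
   vote is the majority label of its 5 nearest reference cells; the final
   label is the **majority vote across references**. Each cell also gets a
   `vote_frequency` (fraction of base classifiers voting malignant) and a
   continuous `score` (mean malignant-neighbor fraction) used for ROC
   analysis.

Inputs are log-normalized expression matrices: `log2(TPM/10 + 1)` for
full-length protocols (`normalize_full_length()`) or size-factor-10,000
`log(x + 1)` for UMI counts (`normalize_umi()`). Dense CSV/TSV and Matrix
Market sparse matrices are supported (`read_expression_matrix()`).

The package also provides the evaluation stack (accuracy, sensitivity,
specificity, balanced accuracy, Mann–Whitney AUROC, stratified 10-fold
cross-validation), a negative-binomial simulator with planted marker genes
for testing the whole pipeline without downloads, and a command-line
interface (`exec/precancell`).

## Worked example

Simulate five labeled references, discover consensus markers, and classify a
fresh simulated query:

```r
library(precancell)

cfg <- simulation_config(seed = 42)              # 300 cells/class, 2000 genes
panel <- simulate_reference_panel(cfg, n_references = 5)
tables <- lapply(panel, function(s) find_markers(s$dataset))
consensus <- intersect_markers(tables)
consensus
#> <marker_gene_set> 50 TMGs + 50 NMGs (ref1+ref2+ref3+ref4+ref5)

query <- simulate_dataset(simulation_config(seed = 4242), name = "query")
preds <- ensemble_predict(lapply(panel, `[[`, "dataset"),
                          query$dataset$expr, consensus)
head(preds[, 1:4])
#>           cell_id     label vote_frequency score
#> 1 query_cell00001 malignant              1     1

report <- confusion_metrics(query$dataset$labels, preds$label)
report$auroc <- auroc(preds$score, query$dataset$labels)
report
#> <performance_report>
#>   confusion: tp=300 fp=0 tn=300 fn=0
#>   accuracy          1.0000
#>   sensitivity       1.0000
#>   specificity       1.0000
#>   balanced_accuracy 1.0000
#>   auroc             1.0000
```

All 100 planted markers are recovered with no false calls, and the ensemble
separates the two planted classes perfectly — the simulator's default effect
size (2 natural-log units) is a strong, clearly detectable signal. `score`
is the mean malignant-neighbor fraction over the five base classifiers;
`vote_frequency` is the fraction of base classifiers voting malignant.

The same pipeline is available from the shell:

```sh
exec/precancell simulate --sim-config sim.json --n-references 5 --out-dir refs/
exec/precancell predict --query query.csv --references refs/ \
    --markers bundled --k 5 --out predictions.csv
exec/precancell evaluate --predictions predictions.csv --truth labels.csv --out report.json
```

`--markers bundled` selects the packaged 73 + 186 consensus marker set for
real data; marker ids then have to be gene symbols.

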
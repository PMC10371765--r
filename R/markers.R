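#' Two-sided Wilcoxon rank-sum p-value
#'
#' The per-gene test behind marker discovery. Uses the exact null distribution
#' when both groups have at most 8 observations and there are no ties, and the
#' normal approximation with tie and continuity corrections otherwise (the
#' same switch `stats::wilcox.test()` applies, pinned here so results do not
#' depend on that function's size heuristics).
#'
#' @param group_a,group_b numeric vectors, both non-empty.
#' @return two-sided p-value in `[0, 1]`.
#' @export
wilcoxon_rank_sum <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be non-empty")
  }
  ties <- anyDuplicated(c(group_a, group_b)) > 0L
  exact <- !ties && length(group_a) <= 8L && length(group_b) <= 8L
  suppressWarnings(
    stats::wilcox.test(group_a, group_b, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value
  )
}

#' Per-gene marker statistics for one labeled dataset
#'
#' Tests every gene for differential expression between malignant and
#' non-malignant cells with the Wilcoxon rank-sum test, Bonferroni-adjusted by
#' the total number of genes in the dataset. A gene is called up in malignant
#' cells when the adjusted p-value is below `p_adj_threshold`, it is detected
#' (normalized value > 0) in at least `min_pct` of malignant cells, and the
#' mean log-expression difference (malignant minus non-malignant) exceeds
#' `min_log_fc`; up in non-malignant cells symmetrically. Genes that cannot
#' pass the detection and fold-change filters in either direction are skipped
#' for speed (their p-values are `NA`); the skip cannot change any call
#' because the filters are part of every call, and the Bonferroni multiplier
#' still counts all genes.
#'
#' @param ds a [reference_dataset()] with log-normalized expression.
#' @param p_adj_threshold adjusted p-value cutoff (default 0.05).
#' @param min_pct minimum detected fraction in the favored class (default
#'   0.10).
#' @param min_log_fc minimum log fold change in favor of the called class
#'   (default 0.25).
#' @param log_fc_method `"mean_diff"` (default): difference of class means of
#'   log-normalized expression. `"seurat"`: log2 ratio of class means of
#'   expm1-backtransformed expression with pseudocount 1, the Seurat v4
#'   FindMarkers convention, offered for parity comparisons.
#' @return data.frame with one row per gene: `gene_id`, `p_value`,
#'   `p_adjusted`, `log_fc`, `pct_malignant`, `pct_non_malignant`,
#'   `direction` (`"up_malignant"`, `"up_non_malignant"` or `"none"`).
#' @export
find_markers <- function(ds, p_adj_threshold = 0.05, min_pct = 0.10,
                         min_log_fc = 0.25,
                         log_fc_method = c("mean_diff", "seurat")) {
  stopifnot(inherits(ds, "reference_dataset"))
  log_fc_method <- match.arg(log_fc_method)
  if (!is_lognormalized(ds$expr)) {
    stop("find_markers needs log-normalized expression (tpm_log2 or ",
         "umi_lognorm), got '", ds$expr$normalization, "'")
  }
  mal <- ds$labels == "malignant"
  if (sum(mal) < 2L || sum(!mal) < 2L) {
    stop("each class needs at least 2 cells")
  }
  v <- ds$expr$values
  n_genes <- nrow(v)
  pct_mal <- rowMeans(v[, mal, drop = FALSE] > 0)
  pct_non <- rowMeans(v[, !mal, drop = FALSE] > 0)
  mean_mal <- rowMeans(v[, mal, drop = FALSE])
  mean_non <- rowMeans(v[, !mal, drop = FALSE])
  log_fc <- if (log_fc_method == "mean_diff") {
    mean_mal - mean_non
  } else {
    log2((rowMeans(expm1(v[, mal, drop = FALSE])) + 1) /
           (rowMeans(expm1(v[, !mal, drop = FALSE])) + 1))
  }

  # a gene can only be called in a direction where both non-p filters pass
  could_up_mal <- pct_mal >= min_pct & log_fc > min_log_fc
  could_up_non <- pct_non >= min_pct & -log_fc > min_log_fc
  test_idx <- which(could_up_mal | could_up_non)

  p_value <- rep(NA_real_, n_genes)
  for (i in test_idx) {
    p_value[i] <- wilcoxon_rank_sum(v[i, mal], v[i, !mal])
  }
  p_adjusted <- pmin(1, p_value * n_genes)  # Bonferroni over all genes present

  sig <- !is.na(p_adjusted) & p_adjusted < p_adj_threshold
  direction <- rep("none", n_genes)
  direction[sig & could_up_mal] <- "up_malignant"
  direction[sig & could_up_non] <- "up_non_malignant"

  data.frame(gene_id = ds$expr$gene_ids, p_value = p_value,
             p_adjusted = p_adjusted, log_fc = log_fc,
             pct_malignant = pct_mal, pct_non_malignant = pct_non,
             direction = direction, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Consensus marker set
#'
#' Constructor/validator for a marker gene set: an ordered list of tumor
#' marker genes (TMGs, up in malignant cells) and non-tumor marker genes
#' (NMGs, up in non-malignant cells). The union is the classifier's feature
#' space.
#'
#' @param tmg,nmg character vectors of gene ids, disjoint and duplicate-free.
#' @param provenance string recording where the set came from.
#' @return object of class `marker_gene_set`.
#' @export
marker_gene_set <- function(tmg, nmg, provenance = "user") {
  tmg <- as.character(tmg); nmg <- as.character(nmg)
  if (anyDuplicated(tmg)) stop("duplicate gene ids in tmg")
  if (anyDuplicated(nmg)) stop("duplicate gene ids in nmg")
  if (length(intersect(tmg, nmg))) {
    stop("tmg and nmg must be disjoint; overlap: ",
         paste(utils::head(intersect(tmg, nmg), 5), collapse = ", "))
  }
  structure(list(tmg = tmg, nmg = nmg, provenance = provenance),
            class = "marker_gene_set")
}

#' @export
print.marker_gene_set <- function(x, ...) {
  cat(sprintf("<marker_gene_set> %d TMGs + %d NMGs (%s)\n",
              length(x$tmg), length(x$nmg), x$provenance))
  invisible(x)
}

#' Intersect per-dataset marker calls into a consensus set
#'
#' A gene is a consensus TMG only if it is called up in malignant cells in
#' every supplied marker table, and a consensus NMG only if called up in
#' non-malignant cells in every table. Output order follows the first table.
#'
#' @param tables named list of marker tables as returned by [find_markers()];
#'   names record the source datasets.
#' @return a [marker_gene_set()] whose provenance lists the source names.
#' @export
intersect_markers <- function(tables) {
  if (!is.list(tables) || length(tables) == 0L) {
    stop("need at least one marker table")
  }
  nm <- names(tables)
  if (is.null(nm)) nm <- paste0("dataset", seq_along(tables))
  up_mal <- lapply(tables, function(t) t$gene_id[t$direction == "up_malignant"])
  up_non <- lapply(tables, function(t) t$gene_id[t$direction == "up_non_malignant"])
  tmg <- Reduce(intersect, up_mal)
  nmg <- Reduce(intersect, up_non)
  # keep the first table's order of appearance
  first <- tables[[1L]]$gene_id
  marker_gene_set(first[first %in% tmg], first[first %in% nmg],
                  provenance = paste(nm, collapse = "+"))
}

#' Bundled consensus marker genes
#'
#' The package ships the consensus marker set discovered by intersecting
#' per-dataset differential expression across five labeled cancer single-cell
#' transcriptome datasets (renal cell carcinoma, head and neck squamous cell
#' carcinoma, melanoma, lung adenocarcinoma, breast cancer): 73 tumor marker
#' genes and 186 non-tumor marker genes.
#'
#' @return a [marker_gene_set()] with provenance `"bundled"`.
#' @export
load_bundled_markers <- function() {
  path <- system.file("extdata", "bundled_markers.tsv", package = "precancell",
                      mustWork = TRUE)
  read_marker_set(path, provenance = "bundled")
}

#' Read / write a marker gene set as two-column TSV
#'
#' The on-disk form is a TSV with columns `gene_id` and `class`
#' (`TMG`/`NMG`). [write_marker_set()] can also emit JSON
#' (`{"tmg": [...], "nmg": [...], "provenance": ...}`) when `path` ends in
#' `.json`.
#'
#' @param path file path.
#' @param provenance provenance string to attach on read.
#' @return [read_marker_set()]: a [marker_gene_set()];
#'   [write_marker_set()]: `path`, invisibly.
#' @export
read_marker_set <- function(path, provenance = path) {
  if (grepl("\\.json$", path)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(marker_gene_set(j$tmg, j$nmg,
                           provenance = j$provenance %||% provenance))
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("gene_id", "class") %in% colnames(df))) {
    stop("marker set file must have columns gene_id, class: ", path)
  }
  marker_gene_set(df$gene_id[df$class == "TMG"],
                  df$gene_id[df$class == "NMG"], provenance = provenance)
}

#' @rdname read_marker_set
#' @param markers a [marker_gene_set()].
#' @export
write_marker_set <- function(markers, path) {
  stopifnot(inherits(markers, "marker_gene_set"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(tmg = markers$tmg, nmg = markers$nmg,
                              provenance = markers$provenance),
                         path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    df <- data.frame(gene_id = c(markers$tmg, markers$nmg),
                     class = rep(c("TMG", "NMG"),
                                 c(length(markers$tmg), length(markers$nmg))))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
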
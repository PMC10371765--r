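#' Confusion counts and threshold metrics
#'
#' Tabulates predictions against truth with malignant as the positive class
#' and derives accuracy, sensitivity, specificity, balanced accuracy (the
#' mean of sensitivity and specificity), and the false negative / false
#' positive rates. When the truth contains a single class the undefined rates
#' are `NA` with a warning.
#'
#' @param truth,predicted character vectors of `"malignant"` /
#'   `"non_malignant"`, equal length.
#' @return object of class `performance_report`: list with integer counts
#'   `tp`, `fp`, `tn`, `fn` and metrics `accuracy`, `sensitivity`,
#'   `specificity`, `balanced_accuracy`, `fnr`, `fpr` (`auroc` is `NA` here;
#'   see [auroc()]).
#' @export
confusion_metrics <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length")
  }
  ok <- c("malignant", "non_malignant")
  if (!all(truth %in% ok) || !all(predicted %in% ok)) {
    stop("labels must be 'malignant' or 'non_malignant'")
  }
  tp <- sum(truth == "malignant" & predicted == "malignant")
  fn <- sum(truth == "malignant" & predicted == "non_malignant")
  tn <- sum(truth == "non_malignant" & predicted == "non_malignant")
  fp <- sum(truth == "non_malignant" & predicted == "malignant")
  n_pos <- tp + fn; n_neg <- tn + fp
  if (n_pos == 0L) warning("no truly malignant cells: sensitivity/FNR undefined")
  if (n_neg == 0L) warning("no truly non-malignant cells: specificity/FPR undefined")
  sens <- if (n_pos > 0L) tp / n_pos else NA_real_
  spec <- if (n_neg > 0L) tn / n_neg else NA_real_
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = (tp + tn) / length(truth),
    sensitivity = sens,
    specificity = spec,
    balanced_accuracy = (sens + spec) / 2,
    fnr = if (n_pos > 0L) fn / n_pos else NA_real_,
    fpr = if (n_neg > 0L) fp / n_neg else NA_real_,
    auroc = NA_real_
  ), class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat("<performance_report>\n")
  cat(sprintf("  confusion: tp=%d fp=%d tn=%d fn=%d\n", x$tp, x$fp, x$tn, x$fn))
  for (m in c("accuracy", "sensitivity", "specificity", "balanced_accuracy",
              "auroc")) {
    cat(sprintf("  %-17s %s\n", m,
                ifelse(is.na(x[[m]]), "NA", sprintf("%.4f", x[[m]]))))
  }
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC: the probability that a randomly chosen
#' malignant cell scores higher than a randomly chosen non-malignant cell,
#' with ties counted 1/2. Equivalent to exhaustive enumeration of all
#' malignant x non-malignant pairs; invariant under strictly monotone score
#' transforms.
#'
#' @param scores numeric malignancy scores (higher = more malignant), e.g.
#'   the `score` column of [ensemble_predict()] output.
#' @param truth labels, both classes present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, truth) {
  truth <- as.character(truth)
  if (length(scores) != length(truth)) stop("scores and truth must match")
  pos <- truth == "malignant"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUROC needs both classes present in truth")
  }
  r <- rank(scores)  # midranks handle ties as 1/2 wins
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Stratified k-fold cross-validation of a single base classifier
#'
#' Within one labeled dataset, cells are split into class-stratified folds;
#' each fold is predicted by a k-NN base classifier whose reference is the
#' remaining folds (reference and held-out cells each min-max scaled with
#' their own statistics on the aligned marker features). Held-out predictions
#' are pooled into one confusion table and AUROC (scored by the
#' malignant-neighbor fraction).
#'
#' @param ds a [reference_dataset()] with at least `folds` cells per class.
#' @param markers a [marker_gene_set()].
#' @param folds number of folds, default 10.
#' @param k odd neighbor count, default 5.
#' @param seed integer seed controlling the fold assignment.
#' @param metric distance metric, see [knn_base_classify()].
#' @return a `performance_report` (including `auroc`); the pooled per-cell
#'   predictions are attached as attribute `"predictions"`.
#' @export
cross_validate <- function(ds, markers = load_bundled_markers(), folds = 10,
                           k = 5, seed = 1,
                           metric = c("euclidean", "cosine")) {
  stopifnot(inherits(ds, "reference_dataset"))
  metric <- match.arg(metric)
  folds <- as.integer(folds)
  if (folds < 2L) stop("folds must be at least 2")
  class_sizes <- table(factor(ds$labels, c("malignant", "non_malignant")))
  if (any(class_sizes < folds)) {
    stop("each class needs at least ", folds, " cells for ", folds,
         "-fold stratified CV (got ", paste(class_sizes, collapse = ", "), ")")
  }

  n <- length(ds$expr$cell_ids)
  fold_id <- integer(n)
  with_seed(seed, {
    for (cls in c("malignant", "non_malignant")) {
      idx <- which(ds$labels == cls)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })

  truth <- character(n); pred <- character(n); score <- numeric(n)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    train_expr <- expression_matrix(ds$expr$values[, !test, drop = FALSE],
                                    ds$expr$gene_ids,
                                    ds$expr$cell_ids[!test],
                                    normalization = ds$expr$normalization)
    ref <- reference_dataset(train_expr, ds$labels[!test],
                             name = paste0(ds$name, "_train"))
    test_expr <- expression_matrix(ds$expr$values[, test, drop = FALSE],
                                   ds$expr$gene_ids, ds$expr$cell_ids[test],
                                   normalization = ds$expr$normalization)
    al <- align_features(markers, ref, test_expr)
    ref$expr <- minmax_scale(subset_genes(ref$expr, al$features))
    q_scaled <- minmax_scale(subset_genes(test_expr, al$features))
    votes <- knn_base_classify(ref, q_scaled, al$features, k = k,
                               metric = metric)
    truth[test] <- ds$labels[test]
    pred[test] <- votes$label
    score[test] <- votes$malignant_neighbor_fraction
  }

  report <- confusion_metrics(truth, pred)
  report$auroc <- auroc(score, truth)
  attr(report, "predictions") <- data.frame(
    cell_id = ds$expr$cell_ids, fold = fold_id, truth = truth,
    predicted = pred, score = score, stringsAsFactors = FALSE)
  report
}

# run code with a temporary RNG state; the caller's stream is untouched
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
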
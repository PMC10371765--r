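#' Align marker features between a reference and a query
#'
#' The usable features of one base classifier are the marker genes (TMG union
#' NMG) present in both the reference and the query, kept in marker-set order.
#' Coverage is the retained fraction of the full marker set; alignment fails
#' when no marker gene is shared, and warns below 50% coverage.
#'
#' @param markers a [marker_gene_set()].
#' @param reference a [reference_dataset()].
#' @param query an [expression_matrix()].
#' @return list with `features` (ordered gene ids) and `coverage` in `[0,1]`.
#' @export
align_features <- function(markers, reference, query) {
  stopifnot(inherits(markers, "marker_gene_set"),
            inherits(reference, "reference_dataset"),
            inherits(query, "expression_matrix"))
  all_markers <- c(markers$tmg, markers$nmg)
  features <- all_markers[all_markers %in% reference$expr$gene_ids &
                            all_markers %in% query$gene_ids]
  coverage <- length(features) / length(all_markers)
  if (length(features) == 0L) {
    stop("reference '", reference$name,
         "' shares no marker genes with the query")
  }
  if (coverage < 0.5) {
    warning(sprintf("reference '%s': only %.0f%% of marker genes usable",
                    reference$name, 100 * coverage))
  }
  list(features = features, coverage = coverage)
}

# cross-distance between scaled query (cells x features) and reference rows;
# returns cells_query x cells_ref
cross_distance <- function(q, r, metric) {
  if (metric == "euclidean") {
    d2 <- outer(rowSums(q^2), rowSums(r^2), `+`) - 2 * tcrossprod(q, r)
    sqrt(pmax(d2, 0))
  } else {  # cosine distance; all-zero vectors get similarity 0
    qn <- sqrt(rowSums(q^2)); rn <- sqrt(rowSums(r^2))
    sim <- tcrossprod(q, r) / outer(pmax(qn, .Machine$double.eps),
                                    pmax(rn, .Machine$double.eps))
    sim[qn == 0, ] <- 0
    if (any(rn == 0)) sim[, rn == 0] <- 0
    1 - sim
  }
}

#' k-NN base classification against one reference
#'
#' For each query cell, finds the `k` reference cells nearest in Euclidean
#' (default) or cosine distance over the given feature genes and votes: the
#' cell is labeled malignant when more than half of the neighbors are
#' malignant. Distance ties at the k-th neighbor are broken by ascending
#' reference cell index, so results are deterministic.
#'
#' Both matrices are expected min-max scaled on the feature rows, each within
#' its own dataset ([ensemble_predict()] does this for you).
#'
#' @param reference a [reference_dataset()] with at least `k` cells.
#' @param query an [expression_matrix()].
#' @param features ordered gene ids to use; must be present in both.
#' @param k odd positive integer, default 5.
#' @param metric `"euclidean"` (default) or `"cosine"`.
#' @param workers number of parallel workers over query cells (forked;
#'   results are identical to sequential evaluation).
#' @return data.frame with one row per query cell: `cell_id`, `label`,
#'   `malignant_neighbor_fraction`; the reference name is attached as
#'   attribute `"reference_name"`.
#' @export
knn_base_classify <- function(reference, query, features, k = 5,
                              metric = c("euclidean", "cosine"), workers = 1L) {
  stopifnot(inherits(reference, "reference_dataset"),
            inherits(query, "expression_matrix"))
  metric <- match.arg(metric)
  k <- as.integer(k)
  if (k < 1L || k %% 2L == 0L) stop("k must be an odd positive integer, got ", k)
  n_ref <- length(reference$expr$cell_ids)
  if (k > n_ref) stop("k = ", k, " exceeds reference size ", n_ref)
  miss <- setdiff(features, reference$expr$gene_ids)
  if (length(miss)) stop("features missing from reference: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  miss <- setdiff(features, query$gene_ids)
  if (length(miss)) stop("features missing from query: ",
                         paste(utils::head(miss, 5), collapse = ", "))

  r <- t(reference$expr$values[features, , drop = FALSE])  # cells x features
  q <- t(query$values[features, , drop = FALSE])
  is_mal <- reference$labels == "malignant"

  classify_chunk <- function(rows) {
    d <- cross_distance(q[rows, , drop = FALSE], r, metric)
    vapply(seq_along(rows), function(i) {
      # radix order is stable: distance ties resolve by reference index
      nn <- order(d[i, ], method = "radix")[seq_len(k)]
      mean(is_mal[nn])
    }, numeric(1))
  }

  n_q <- nrow(q)
  workers <- max(1L, as.integer(workers))
  if (workers > 1L && n_q > 1L && .Platform$OS.type == "unix") {
    chunks <- split(seq_len(n_q), cut(seq_len(n_q), workers, labels = FALSE))
    frac <- unlist(parallel::mclapply(chunks, classify_chunk,
                                      mc.cores = workers), use.names = FALSE)
  } else {
    frac <- classify_chunk(seq_len(n_q))
  }

  out <- data.frame(cell_id = query$cell_ids,
                    label = ifelse(frac > 0.5, "malignant", "non_malignant"),
                    malignant_neighbor_fraction = frac,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "reference_name") <- reference$name
  out
}

# majority vote over base-classifier neighbor fractions for one cell set.
# fractions: cells x references matrix. Even vote splits fall back on the
# mean neighbor fraction (> 0.5 malignant; exactly 0.5 -> non_malignant with
# a warning).
combine_votes <- function(fractions) {
  votes_mal <- fractions > 0.5
  vote_frequency <- rowMeans(votes_mal)
  score <- rowMeans(fractions)
  label <- ifelse(vote_frequency > 0.5, "malignant", "non_malignant")
  split <- which(vote_frequency == 0.5)
  if (length(split)) {
    label[split] <- ifelse(score[split] > 0.5, "malignant", "non_malignant")
    if (any(score[split] == 0.5)) {
      warning(sum(score[split] == 0.5),
              " cell(s) with an even vote split and score exactly 0.5 ",
              "assigned non_malignant")
    }
  }
  data.frame(label = label, vote_frequency = vote_frequency, score = score,
             stringsAsFactors = FALSE)
}

#' Ensemble malignancy prediction
#'
#' The full predictor: for each labeled reference, marker features are aligned
#' with the query, reference and query are min-max scaled on those features
#' (each with its own per-gene statistics), and a k-NN base classifier votes;
#' the final label is the majority vote across references. With an even,
#' user-supplied number of references a split vote is broken by the continuous
#' score (the mean malignant-neighbor fraction).
#'
#' @param references list of [reference_dataset()] objects (an odd count is
#'   recommended; the standard configuration uses five).
#' @param query a log-normalized [expression_matrix()].
#' @param markers a [marker_gene_set()]; defaults to the bundled consensus
#'   set.
#' @inheritParams knn_base_classify
#' @return data.frame with one row per query cell: `cell_id`, `label`,
#'   `vote_frequency` (fraction of base classifiers voting malignant), `score`
#'   (mean malignant-neighbor fraction), then one `vote_<reference>` label
#'   column per reference. The per-reference neighbor-fraction matrix is
#'   attached as attribute `"neighbor_fractions"`.
#' @export
ensemble_predict <- function(references, query, markers = load_bundled_markers(),
                             k = 5, metric = c("euclidean", "cosine"),
                             workers = 1L) {
  if (inherits(references, "reference_dataset")) references <- list(references)
  stopifnot(length(references) >= 1L,
            all(vapply(references, inherits, logical(1), "reference_dataset")),
            inherits(query, "expression_matrix"))
  metric <- match.arg(metric)
  if (query$normalization == "raw") {
    stop("query must be log-normalized (see normalize_full_length / normalize_umi)")
  }
  ref_names <- vapply(references, function(r) r$name, character(1))
  if (anyDuplicated(ref_names)) stop("reference names must be unique")
  if (length(references) %% 2L == 0L) {
    warning("even number of references (", length(references),
            "): split votes are broken by the continuous score")
  }

  votes <- list()
  for (ref in references) {
    al <- tryCatch(align_features(markers, ref, query), error = identity)
    if (inherits(al, "error")) {
      warning("skipping reference '", ref$name, "': ", conditionMessage(al))
      next
    }
    r_scaled <- ref
    r_scaled$expr <- minmax_scale(subset_genes(ref$expr, al$features))
    q_scaled <- minmax_scale(subset_genes(query, al$features))
    votes[[ref$name]] <- knn_base_classify(r_scaled, q_scaled, al$features,
                                           k = k, metric = metric,
                                           workers = workers)
  }
  if (length(votes) == 0L) {
    stop("no reference shares marker genes with the query")
  }

  fractions <- vapply(votes, function(v) v$malignant_neighbor_fraction,
                      numeric(length(query$cell_ids)))
  fractions <- matrix(fractions, nrow = length(query$cell_ids),
                      dimnames = list(query$cell_ids, names(votes)))
  combined <- combine_votes(fractions)
  out <- data.frame(cell_id = query$cell_ids, combined,
                    row.names = NULL, stringsAsFactors = FALSE)
  for (nm in names(votes)) out[[paste0("vote_", nm)]] <- votes[[nm]]$label
  attr(out, "neighbor_fractions") <- fractions
  out
}

subset_genes <- function(m, genes) {
  out <- expression_matrix(m$values[genes, , drop = FALSE], genes, m$cell_ids,
                           normalization = m$normalization)
  out
}
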
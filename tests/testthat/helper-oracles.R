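# Independent brute-force oracles used to check the fast implementations.

# exact two-sided rank-sum p by enumerating every assignment of group labels
oracle_wilcoxon <- function(a, b) {
  pooled <- c(a, b)
  m <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(length(pooled), m)
  w_null <- apply(combos, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  lower <- mean(w_null <= w_obs)
  upper <- mean(w_null >= w_obs)
  min(1, 2 * min(lower, upper))
}

# all-pairs AUROC: wins + half-ties over malignant x non-malignant pairs
oracle_auroc <- function(scores, truth) {
  pos <- scores[truth == "malignant"]
  neg <- scores[truth != "malignant"]
  total <- 0
  for (p in pos) for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# exhaustive k-NN: explicit per-pair distances, full stable sort
oracle_knn_fractions <- function(ref_values, ref_labels, query_values, k) {
  vapply(seq_len(ncol(query_values)), function(j) {
    d <- vapply(seq_len(ncol(ref_values)), function(i) {
      sqrt(sum((ref_values[, i] - query_values[, j])^2))
    }, numeric(1))
    nn <- sort.list(d, method = "radix")[seq_len(k)]
    mean(ref_labels[nn] == "malignant")
  }, numeric(1))
}

make_expr <- function(values, normalization = "umi_lognorm",
                      gene_prefix = "g", cell_prefix = "c") {
  values <- as.matrix(values)
  expression_matrix(values,
                    gene_ids = paste0(gene_prefix, seq_len(nrow(values))),
                    cell_ids = paste0(cell_prefix, seq_len(ncol(values))),
                    normalization = normalization)
}

# tiny reference where the two classes sit on distinct constant vectors
make_constant_reference <- function(n_per_class = 10, n_genes = 5,
                                    name = "const") {
  v <- cbind(matrix(1, n_genes, n_per_class), matrix(0, n_genes, n_per_class))
  labels <- rep(c("malignant", "non_malignant"), each = n_per_class)
  reference_dataset(make_expr(v, cell_prefix = paste0(name, "_c")),
                    labels, name = name)
}
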
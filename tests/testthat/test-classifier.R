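scale_pair <- function(ref, query, features) {
  ref$expr <- minmax_scale(precancell:::subset_genes(ref$expr, features))
  list(ref = ref,
       query = minmax_scale(precancell:::subset_genes(query, features)))
}

test_that("feature alignment reports coverage and guards empty overlap", {
  ms <- marker_gene_set(paste0("t", 1:4), paste0("n", 1:4))
  all_genes <- c(paste0("t", 1:4), paste0("n", 1:4))
  ref <- reference_dataset(
    expression_matrix(matrix(runif(32), 8, 4), all_genes, paste0("rc", 1:4),
                      normalization = "umi_lognorm"),
    c("malignant", "malignant", "non_malignant", "non_malignant"), "r1")
  q_full <- expression_matrix(matrix(runif(16), 8, 2), all_genes,
                              c("q1", "q2"), normalization = "umi_lognorm")
  al <- align_features(ms, ref, q_full)
  expect_equal(al$coverage, 1)
  expect_identical(al$features, all_genes)

  q_half <- expression_matrix(matrix(runif(8), 4, 2), all_genes[1:4],
                              c("q1", "q2"), normalization = "umi_lognorm")
  al2 <- align_features(ms, ref, q_half)  # exactly half retained: no warning
  expect_equal(al2$coverage, 0.5)
  expect_identical(al2$features, all_genes[1:4])

  q_low <- expression_matrix(matrix(runif(6), 3, 2), all_genes[1:3],
                             c("q1", "q2"), normalization = "umi_lognorm")
  expect_warning(al3 <- align_features(ms, ref, q_low), "usable")
  expect_equal(al3$coverage, 3 / 8)

  q_none <- expression_matrix(matrix(runif(4), 2, 2), c("x1", "x2"),
                              c("q1", "q2"), normalization = "umi_lognorm")
  expect_error(align_features(ms, ref, q_none), "no marker genes")
})

test_that("k-NN votes follow the nearest labeled neighbors", {
  ref <- make_constant_reference(n_per_class = 6, n_genes = 4)
  q <- make_expr(cbind(rep(1, 4), rep(0, 4)), normalization = "minmax_scaled",
                 cell_prefix = "q")
  votes <- knn_base_classify(ref, q, ref$expr$gene_ids, k = 5)
  expect_identical(votes$label, c("malignant", "non_malignant"))
  expect_equal(votes$malignant_neighbor_fraction, c(1, 0))
  expect_identical(attr(votes, "reference_name"), "const")

  # k = 1 returns the label of the unique coincident reference cell
  set.seed(8)
  rv <- matrix(runif(30), 3, 10)
  ref2 <- reference_dataset(
    make_expr(rv, normalization = "minmax_scaled", cell_prefix = "r"),
    rep(c("malignant", "non_malignant"), 5), "r2")
  q2 <- make_expr(rv[, 4, drop = FALSE], normalization = "minmax_scaled",
                  cell_prefix = "q")
  v2 <- knn_base_classify(ref2, q2, ref2$expr$gene_ids, k = 1)
  expect_identical(v2$label, ref2$labels[4])

  expect_error(knn_base_classify(ref2, q2, ref2$expr$gene_ids, k = 4), "odd")
  expect_error(knn_base_classify(ref2, q2, ref2$expr$gene_ids, k = 11),
               "exceeds reference size")
})

test_that("k-NN matches an exhaustive-distance oracle on random references", {
  for (seed in c(2, 13, 77)) {
    set.seed(seed)
    rv <- matrix(runif(30), 3, 10)
    labels <- sample(rep(c("malignant", "non_malignant"), 5))
    qv <- matrix(runif(18), 3, 6)
    ref <- reference_dataset(
      make_expr(rv, normalization = "minmax_scaled", cell_prefix = "r"),
      labels, paste0("rand", seed))
    q <- make_expr(qv, normalization = "minmax_scaled", cell_prefix = "q")
    votes <- knn_base_classify(ref, q, ref$expr$gene_ids, k = 5)
    expect_equal(votes$malignant_neighbor_fraction,
                 oracle_knn_fractions(rv, labels, qv, k = 5),
                 tolerance = 1e-12)
  }
})

test_that("parallel evaluation over query cells is identical to sequential", {
  skip_on_os("windows")
  set.seed(4)
  ref <- make_constant_reference(8, 6)
  qv <- matrix(runif(60), 6, 10)
  q <- make_expr(qv, normalization = "minmax_scaled", cell_prefix = "q")
  seq_votes <- knn_base_classify(ref, q, ref$expr$gene_ids, k = 5, workers = 1)
  par_votes <- knn_base_classify(ref, q, ref$expr$gene_ids, k = 5, workers = 3)
  expect_identical(par_votes, seq_votes)
})

test_that("majority vote, vote frequency and score follow their definitions", {
  # votes (M, M, M, N, N): fractions above/below 0.5
  fr <- matrix(c(0.8, 1.0, 0.6, 0.2, 0.4), 1,
               dimnames = list("cell", paste0("r", 1:5)))
  out <- precancell:::combine_votes(fr)
  expect_identical(out$label, "malignant")
  expect_equal(out$vote_frequency, 0.6)
  expect_equal(out$score, 0.6)

  # even split (M, M, N, N) falls back on the mean neighbor fraction 0.55
  fr4 <- matrix(c(0.8, 0.8, 0.4, 0.2), 1)
  out4 <- precancell:::combine_votes(fr4)
  expect_equal(out4$vote_frequency, 0.5)
  expect_equal(out4$score, 0.55)
  expect_identical(out4$label, "malignant")

  # even split with score exactly 0.5: non_malignant plus a warning
  fr5 <- matrix(c(0.8, 0.2), 1)
  expect_warning(out5 <- precancell:::combine_votes(fr5), "exactly 0.5")
  expect_identical(out5$label, "non_malignant")
})

test_that("ensemble over identical references equals the single base classifier", {
  set.seed(14)
  sim <- simulate_dataset(simulation_config(
    n_malignant = 40, n_non_malignant = 40, n_genes = 150,
    n_tmg_planted = 10, n_nmg_planted = 10, seed = 31))
  ms <- marker_gene_set(sim$planted_tmg, sim$planted_nmg)
  q <- simulate_dataset(simulation_config(
    n_malignant = 20, n_non_malignant = 20, n_genes = 150,
    n_tmg_planted = 10, n_nmg_planted = 10, seed = 32), name = "query")
  refs <- lapply(1:5, function(i) {
    r <- sim$dataset; r$name <- paste0("copy", i); r
  })
  ens <- ensemble_predict(refs, q$dataset$expr, ms)
  single <- ensemble_predict(refs[1], q$dataset$expr, ms)
  expect_identical(ens$label, single$label)
  expect_true(all(ens$vote_frequency %in% c(0, 1)))
  expect_equal(ens$score, single$score)
})

test_that("predictions are invariant to reference order and follow query order", {
  sims <- simulate_reference_panel(simulation_config(
    n_malignant = 40, n_non_malignant = 40, n_genes = 150,
    n_tmg_planted = 10, n_nmg_planted = 10, seed = 41), n_references = 3)
  refs <- lapply(sims, `[[`, "dataset")
  ms <- marker_gene_set(sims[[1]]$planted_tmg, sims[[1]]$planted_nmg)
  q <- simulate_dataset(simulation_config(
    n_malignant = 15, n_non_malignant = 15, n_genes = 150,
    n_tmg_planted = 10, n_nmg_planted = 10, seed = 43), name = "query")$dataset$expr

  base <- ensemble_predict(refs, q, ms)
  perm <- ensemble_predict(refs[c(3, 1, 2)], q, ms)
  expect_identical(perm$label, base$label)
  expect_equal(perm$vote_frequency, base$vote_frequency)
  expect_equal(perm$score, base$score)
  # odd reference count: majority label is determined by vote frequency
  expect_identical(base$label,
                   ifelse(base$vote_frequency > 0.5, "malignant",
                          "non_malignant"))
  expect_true(all(base$vote_frequency %in% ((0:3) / 3)))

  # permuting query cells permutes predictions with no cross-cell leakage
  set.seed(6)
  ord <- sample(length(q$cell_ids))
  q_perm <- expression_matrix(q$values[, ord], q$gene_ids, q$cell_ids[ord],
                              normalization = q$normalization)
  p_perm <- ensemble_predict(refs, q_perm, ms)
  expect_identical(p_perm$label, base$label[ord])
  expect_equal(p_perm$score, base$score[ord])
})

test_that("a gene constant in both reference and query changes no prediction", {
  sims <- simulate_reference_panel(simulation_config(
    n_malignant = 30, n_non_malignant = 30, n_genes = 120,
    n_tmg_planted = 8, n_nmg_planted = 8, seed = 51), n_references = 3)
  refs <- lapply(sims, `[[`, "dataset")
  ms <- marker_gene_set(sims[[1]]$planted_tmg, sims[[1]]$planted_nmg)
  q <- simulate_dataset(simulation_config(
    n_malignant = 10, n_non_malignant = 10, n_genes = 120,
    n_tmg_planted = 8, n_nmg_planted = 8, seed = 52), name = "query")$dataset$expr
  base <- ensemble_predict(refs, q, ms)

  add_const <- function(m, value) {
    expression_matrix(rbind(m$values, dummy = value),
                      c(m$gene_ids, "dummy"), m$cell_ids,
                      normalization = m$normalization)
  }
  refs2 <- lapply(refs, function(r) { r$expr <- add_const(r$expr, 2); r })
  q2 <- add_const(q, 5)
  ms2 <- marker_gene_set(c(ms$tmg, "dummy"), ms$nmg)
  with_dummy <- ensemble_predict(refs2, q2, ms2)
  expect_identical(with_dummy$label, base$label)
  expect_equal(with_dummy$score, base$score)
})
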
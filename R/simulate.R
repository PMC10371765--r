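#' Simulation configuration
#'
#' Parameters of the synthetic scRNA-seq generator. Counts are gamma-Poisson
#' (negative binomial) with lognormal per-cell library sizes and independent
#' multiplicative dropout; a small set of planted marker genes gets a
#' class-specific log-mean shift. Defaults describe a moderately deep UMI
#' experiment with clearly separated classes: 300 cells per class, 2,000
#' genes, 50 planted markers per direction, a shift of 2 natural-log units,
#' 20% dropout, negative-binomial dispersion 0.4 and ~5,000 counts per cell.
#'
#' @param n_malignant,n_non_malignant cells per class.
#' @param n_genes total genes.
#' @param n_tmg_planted,n_nmg_planted planted markers up in malignant /
#'   non-malignant cells; the planted genes occupy the first
#'   `n_tmg_planted + n_nmg_planted` gene ids, in that order.
#' @param effect_size natural-log mean shift of planted markers in their
#'   favored class (counts multiplied by `exp(effect_size)`).
#' @param dropout_rate probability that any observed count is zeroed,
#'   in `[0, 1)`.
#' @param dispersion negative-binomial dispersion (1/size); variance is
#'   `mu + dispersion * mu^2`.
#' @param library_size_mean mean total raw count per cell.
#' @param seed integer seed; generation is bit-reproducible given the config.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_malignant = 300, n_non_malignant = 300,
                              n_genes = 2000, n_tmg_planted = 50,
                              n_nmg_planted = 50, effect_size = 2,
                              dropout_rate = 0.2, dispersion = 0.4,
                              library_size_mean = 5000, seed = 1) {
  cfg <- list(n_malignant = as.integer(n_malignant),
              n_non_malignant = as.integer(n_non_malignant),
              n_genes = as.integer(n_genes),
              n_tmg_planted = as.integer(n_tmg_planted),
              n_nmg_planted = as.integer(n_nmg_planted),
              effect_size = as.numeric(effect_size),
              dropout_rate = as.numeric(dropout_rate),
              dispersion = as.numeric(dispersion),
              library_size_mean = as.numeric(library_size_mean),
              seed = as.integer(seed))
  if (cfg$n_malignant < 1L || cfg$n_non_malignant < 1L || cfg$n_genes < 1L) {
    stop("cell and gene counts must be positive")
  }
  if (cfg$n_tmg_planted < 0L || cfg$n_nmg_planted < 0L ||
      cfg$n_tmg_planted + cfg$n_nmg_planted > cfg$n_genes) {
    stop("planted marker counts must be non-negative and fit within n_genes")
  }
  if (cfg$effect_size < 0) stop("effect_size must be non-negative")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1) {
    stop("dropout_rate must be in [0, 1)")
  }
  if (cfg$dispersion <= 0 || cfg$library_size_mean <= 0) {
    stop("dispersion and library_size_mean must be positive")
  }
  structure(cfg, class = "simulation_config")
}

#' Simulate one labeled scRNA-seq dataset
#'
#' Draws a genes x cells UMI count matrix from a gamma-Poisson model with
#' lognormal gene baseline abundances (sdlog 1) and lognormal library sizes
#' (sdlog 0.3 around `library_size_mean`). Planted tumor markers have their
#' mean multiplied by `exp(effect_size)` in malignant cells; planted
#' non-tumor markers symmetrically in non-malignant cells. Each count is then
#' zeroed independently with probability `dropout_rate`, and the matrix is
#' depth-normalized with [normalize_umi()]. Malignant cells come first in
#' column order.
#'
#' @param cfg a [simulation_config()].
#' @param name dataset name.
#' @param planted_tmg,planted_nmg optional explicit gene ids to plant
#'   (defaults: the first `n_tmg_planted` gene ids, then the next
#'   `n_nmg_planted`).
#' @return object of class `synthetic_dataset`: list with `dataset` (a
#'   [reference_dataset()], log-normalized), `planted_tmg`, `planted_nmg`.
#' @export
simulate_dataset <- function(cfg, name = "sim", planted_tmg = NULL,
                             planted_nmg = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  g <- cfg$n_genes
  n_mal <- cfg$n_malignant; n_non <- cfg$n_non_malignant
  n <- n_mal + n_non
  gene_ids <- sprintf("gene%04d", seq_len(g))
  cell_ids <- sprintf("%s_cell%05d", name, seq_len(n))
  if (is.null(planted_tmg)) planted_tmg <- gene_ids[seq_len(cfg$n_tmg_planted)]
  if (is.null(planted_nmg)) {
    planted_nmg <- gene_ids[cfg$n_tmg_planted + seq_len(cfg$n_nmg_planted)]
  }
  stopifnot(all(planted_tmg %in% gene_ids), all(planted_nmg %in% gene_ids),
            !any(planted_tmg %in% planted_nmg))
  labels <- rep(c("malignant", "non_malignant"), c(n_mal, n_non))
  mal <- labels == "malignant"

  counts <- with_seed(cfg$seed, {
    w <- exp(stats::rnorm(g, mean = 0, sd = 1))        # baseline abundance
    lib <- cfg$library_size_mean *
      exp(stats::rnorm(n, mean = -0.3^2 / 2, sd = 0.3))  # per-cell depth
    mu <- outer(w / sum(w), lib)                        # genes x cells means
    if (cfg$effect_size > 0) {
      fc <- exp(cfg$effect_size)
      mu[match(planted_tmg, gene_ids), mal] <-
        mu[match(planted_tmg, gene_ids), mal] * fc
      mu[match(planted_nmg, gene_ids), !mal] <-
        mu[match(planted_nmg, gene_ids), !mal] * fc
    }
    shape <- 1 / cfg$dispersion
    lambda <- matrix(stats::rgamma(g * n, shape = shape, scale = 1 / shape),
                     g, n) * mu
    x <- matrix(stats::rpois(g * n, lambda), g, n)
    if (cfg$dropout_rate > 0) {
      keep <- matrix(stats::rbinom(g * n, 1L, 1 - cfg$dropout_rate), g, n)
      x <- x * keep
    }
    x
  })

  raw <- expression_matrix(counts, gene_ids, cell_ids, normalization = "raw")
  ds <- reference_dataset(normalize_umi(raw), labels, name = name)
  structure(list(dataset = ds, planted_tmg = planted_tmg,
                 planted_nmg = planted_nmg),
            class = "synthetic_dataset")
}

#' Simulate a panel of reference datasets
#'
#' Draws `n_references` datasets from independent seeds derived as
#' `cfg$seed + i` for panel member `i`. A fraction `shared_marker_fraction`
#' of each direction's planted markers is common to every panel member; the
#' remainder are panel-private, drawn disjointly across members from the
#' non-planted gene pool, so consensus intersection has both true positives
#' (shared markers) and true negatives (private ones).
#'
#' @param cfg a [simulation_config()].
#' @param n_references panel size, default 5.
#' @param shared_marker_fraction fraction of planted markers shared by all
#'   panel members, in `[0, 1]` (default 1).
#' @return list of `synthetic_dataset` objects named `ref1..refN`.
#' @export
simulate_reference_panel <- function(cfg, n_references = 5,
                                     shared_marker_fraction = 1.0) {
  stopifnot(inherits(cfg, "simulation_config"))
  n_references <- as.integer(n_references)
  if (n_references < 1L) stop("n_references must be at least 1")
  if (shared_marker_fraction < 0 || shared_marker_fraction > 1) {
    stop("shared_marker_fraction must be in [0, 1]")
  }
  gene_ids <- sprintf("gene%04d", seq_len(cfg$n_genes))
  base_tmg <- gene_ids[seq_len(cfg$n_tmg_planted)]
  base_nmg <- gene_ids[cfg$n_tmg_planted + seq_len(cfg$n_nmg_planted)]
  n_shared_t <- round(shared_marker_fraction * cfg$n_tmg_planted)
  n_shared_n <- round(shared_marker_fraction * cfg$n_nmg_planted)
  shared_tmg <- base_tmg[seq_len(n_shared_t)]
  shared_nmg <- base_nmg[seq_len(n_shared_n)]
  n_priv_t <- cfg$n_tmg_planted - n_shared_t
  n_priv_n <- cfg$n_nmg_planted - n_shared_n
  pool <- gene_ids[-seq_len(cfg$n_tmg_planted + cfg$n_nmg_planted)]
  need <- n_references * (n_priv_t + n_priv_n)
  if (need > length(pool)) {
    stop("not enough non-planted genes for disjoint panel-private markers")
  }
  panel <- lapply(seq_len(n_references), function(i) {
    off <- (i - 1L) * (n_priv_t + n_priv_n)
    priv <- pool[off + seq_len(n_priv_t + n_priv_n)]
    sub <- simulation_config(
      n_malignant = cfg$n_malignant, n_non_malignant = cfg$n_non_malignant,
      n_genes = cfg$n_genes, n_tmg_planted = cfg$n_tmg_planted,
      n_nmg_planted = cfg$n_nmg_planted, effect_size = cfg$effect_size,
      dropout_rate = cfg$dropout_rate, dispersion = cfg$dispersion,
      library_size_mean = cfg$library_size_mean, seed = cfg$seed + i)
    simulate_dataset(sub, name = paste0("ref", i),
                     planted_tmg = c(shared_tmg, utils::head(priv, n_priv_t)),
                     planted_nmg = c(shared_nmg,
                                     utils::tail(priv, n_priv_n)))
  })
  stats::setNames(panel, paste0("ref", seq_len(n_references)))
}
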
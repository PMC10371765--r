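#' Log-normalize full-length (TPM) expression
#'
#' For full-length protocols expression quantified as transcripts per million
#' is transformed gene-wise as `log2(TPM/10 + 1)`. The divisor 10 reflects the
#' convention that full-length single-cell libraries capture on the order of
#' 100,000 transcripts, so TPM/10 approximates counts per 100k.
#'
#' @param tpm an [expression_matrix()] of raw TPM values
#'   (`normalization = "raw"`).
#' @return the matrix with values `log2(v/10 + 1)` and
#'   `normalization = "tpm_log2"`.
#' @export
normalize_full_length <- function(tpm) {
  stopifnot(inherits(tpm, "expression_matrix"))
  if (tpm$normalization != "raw") {
    stop("input must be raw TPM (normalization = 'raw'), got '",
         tpm$normalization, "'")
  }
  if (any(tpm$values < 0)) stop("TPM values must be non-negative")
  expression_matrix(log2(tpm$values / 10 + 1), tpm$gene_ids, tpm$cell_ids,
                    normalization = "tpm_log2")
}

#' Log-normalize UMI counts
#'
#' Standard depth normalization for UMI protocols: each cell's counts are
#' scaled to a fixed total (`size_factor`, default 10,000) and transformed by
#' `log(x + 1)` (natural log). Cells with zero total count are kept and map to
#' all-zero columns.
#'
#' @param counts an [expression_matrix()] of raw UMI counts.
#' @param size_factor positive target total per cell; default 10000.
#' @return the matrix with `normalization = "umi_lognorm"`.
#' @export
normalize_umi <- function(counts, size_factor = 10000) {
  stopifnot(inherits(counts, "expression_matrix"))
  if (counts$normalization != "raw") {
    stop("input must be raw counts (normalization = 'raw'), got '",
         counts$normalization, "'")
  }
  if (any(counts$values < 0)) stop("counts must be non-negative")
  if (!is.numeric(size_factor) || length(size_factor) != 1L || size_factor <= 0) {
    stop("size_factor must be a positive number")
  }
  totals <- colSums(counts$values)
  scale <- ifelse(totals > 0, size_factor / totals, 0)
  v <- log1p(sweep(counts$values, 2L, scale, `*`))
  expression_matrix(v, counts$gene_ids, counts$cell_ids,
                    normalization = "umi_lognorm")
}

#' Min-max scale expression per gene
#'
#' Rescales each gene to `[0, 1]` across all cells of the matrix:
#' `x_scaled = (x - min(x)) / (max(x) - min(x))`, with min and max taken per
#' gene within this dataset. Genes constant across cells map to all-zero rows.
#' Scaling is always computed within one dataset; a reference and a query are
#' each scaled by their own statistics.
#'
#' @param m a log-normalized [expression_matrix()].
#' @return the scaled matrix (`normalization = "minmax_scaled"`) with an
#'   attribute `scaling_stats`: a two-column matrix of the per-gene (min, max)
#'   used.
#' @export
minmax_scale <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  if (!is_lognormalized(m) && m$normalization != "minmax_scaled") {
    stop("minmax_scale expects a log-normalized matrix (tpm_log2 or ",
         "umi_lognorm), got '", m$normalization, "'")
  }
  mins <- apply(m$values, 1L, min)
  maxs <- apply(m$values, 1L, max)
  rng <- maxs - mins
  denom <- ifelse(rng > 0, rng, 1)  # constant genes: (x - min) is 0 anyway
  v <- (m$values - mins) / denom
  out <- expression_matrix(v, m$gene_ids, m$cell_ids,
                           normalization = "minmax_scaled")
  attr(out, "scaling_stats") <- cbind(min = mins, max = maxs)
  out
}
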
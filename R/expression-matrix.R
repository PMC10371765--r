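#' Expression matrix container
#'
#' A thin S3 container for a genes x cells expression matrix. Values are held
#' as a dense base matrix; gene and cell identifiers must be unique, and the
#' `normalization` field records which transform the values have been through
#' (`"raw"`, `"tpm_log2"`, `"umi_lognorm"`, or `"minmax_scaled"`).
#'
#' @param values numeric matrix, genes in rows and cells in columns.
#' @param gene_ids character vector of unique gene identifiers (one per row).
#'   Defaults to `rownames(values)`.
#' @param cell_ids character vector of unique cell identifiers (one per
#'   column). Defaults to `colnames(values)`.
#' @param normalization one of `"raw"`, `"tpm_log2"`, `"umi_lognorm"`,
#'   `"minmax_scaled"`.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `gene_ids`, `cell_ids`, `normalization`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              cell_ids = colnames(values),
                              normalization = "raw") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop("gene_ids and cell_ids are required (or supply a matrix with dimnames)")
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values)) {
    stop(sprintf("gene_ids has length %d but the matrix has %d rows",
                 length(gene_ids), nrow(values)))
  }
  if (length(cell_ids) != ncol(values)) {
    stop(sprintf("cell_ids has length %d but the matrix has %d columns",
                 length(cell_ids), ncol(values)))
  }
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g)) {
    stop("duplicate gene ids: ", paste(utils::head(dup_g, 10), collapse = ", "))
  }
  dup_c <- unique(cell_ids[duplicated(cell_ids)])
  if (length(dup_c)) {
    stop("duplicate cell ids: ", paste(utils::head(dup_c, 10), collapse = ", "))
  }
  normalization <- match.arg(normalization,
                             c("raw", "tpm_log2", "umi_lognorm", "minmax_scaled"))
  if (any(!is.finite(values))) stop("expression values must be finite")
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 normalization = normalization),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d cells [%s]\n",
              length(x$gene_ids), length(x$cell_ids), x$normalization))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

is_lognormalized <- function(m) {
  m$normalization %in% c("tpm_log2", "umi_lognorm")
}

#' Labeled reference dataset
#'
#' Bundles an expression matrix with a per-cell binary malignancy label and a
#' dataset name. References are the training units of the ensemble: each one
#' backs a single k-NN base classifier.
#'
#' @param expr an [expression_matrix()], log-normalized.
#' @param labels character vector, one of `"malignant"` / `"non_malignant"`
#'   per cell, in `expr` cell order (a named vector is reordered by cell id).
#' @param name non-empty dataset name.
#' @return An object of class `reference_dataset`.
#' @export
reference_dataset <- function(expr, labels, name) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("name must be a non-empty string")
  }
  labels <- as.character(labels)
  if (!is.null(names(labels)) && all(expr$cell_ids %in% names(labels))) {
    labels <- labels[expr$cell_ids]
  }
  if (length(labels) != length(expr$cell_ids)) {
    stop("need exactly one label per cell")
  }
  bad <- setdiff(unique(labels), c("malignant", "non_malignant"))
  if (length(bad)) {
    stop("labels must be 'malignant' or 'non_malignant'; found: ",
         paste(bad, collapse = ", "))
  }
  counts <- table(factor(labels, c("malignant", "non_malignant")))
  if (any(counts < 2)) {
    stop("each class needs at least 2 cells (got ",
         counts[["malignant"]], " malignant, ",
         counts[["non_malignant"]], " non-malignant)")
  }
  structure(list(expr = expr, labels = unname(labels), name = name),
            class = "reference_dataset")
}

#' @export
print.reference_dataset <- function(x, ...) {
  cat(sprintf("<reference_dataset> '%s': %d genes x %d cells (%d malignant, %d non-malignant)\n",
              x$name, length(x$expr$gene_ids), length(x$expr$cell_ids),
              sum(x$labels == "malignant"), sum(x$labels == "non_malignant")))
  invisible(x)
}

#' Read an expression matrix from disk
#'
#' Reads dense CSV/TSV (gene ids in the first column, cell ids in the header)
#' or Matrix Market sparse triplets (with `genes.tsv` / `barcodes.tsv`
#' sidecars alongside, CellRanger style). The result is always oriented genes
#' x cells and marked as raw.
#'
#' @param path file path. For `format = "mtx"` this is the `.mtx` file; gene
#'   and barcode sidecars are looked up in the same directory (`genes.tsv` or
#'   `features.tsv`, and `barcodes.tsv`).
#' @param format `"csv"`, `"tsv"` or `"mtx"`. Default guesses from the file
#'   extension.
#' @param genes_as for dense formats, whether genes are on `"rows"` (default)
#'   or `"columns"` of the file as stored.
#' @return An [expression_matrix()] with `normalization = "raw"`.
#' @export
read_expression_matrix <- function(path, format = c("auto", "csv", "tsv", "mtx"),
                                   genes_as = c("rows", "columns")) {
  format <- match.arg(format)
  genes_as <- match.arg(genes_as)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mtx = "mtx", tsv = "tsv", txt = "tsv", csv = "csv",
                     stop("cannot guess format from extension '", ext,
                          "'; pass format= explicitly"))
  }
  if (format == "mtx") {
    m <- read_mtx_with_sidecars(path)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- tryCatch(
      utils::read.table(path, sep = sep, header = TRUE, row.names = NULL,
                        check.names = FALSE, stringsAsFactors = FALSE,
                        comment.char = ""),
      error = function(e) stop("malformed ", format, " file '", path, "': ",
                               conditionMessage(e)))
    if (ncol(df) < 2) stop("malformed ", format, " file '", path,
                           "': need an id column plus at least one data column")
    ids <- as.character(df[[1]])
    vals <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(vals)) {
      bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1] + 1L
      stop("malformed ", format, " file '", path, "': column ", bad,
           " is not numeric")
    }
    m <- expression_matrix(vals, gene_ids = ids, cell_ids = colnames(df)[-1])
    if (genes_as == "columns") {
      m <- expression_matrix(t(m$values), gene_ids = m$cell_ids,
                             cell_ids = m$gene_ids)
    }
  }
  m
}

read_mtx_with_sidecars <- function(path) {
  dir <- dirname(path)
  gene_file <- NULL
  for (cand in c("genes.tsv", "features.tsv", "genes.txt")) {
    if (file.exists(file.path(dir, cand))) { gene_file <- file.path(dir, cand); break }
  }
  bc_file <- file.path(dir, "barcodes.tsv")
  if (is.null(gene_file)) stop("mtx sidecar genes.tsv/features.tsv not found next to ", path)
  if (!file.exists(bc_file)) stop("mtx sidecar barcodes.tsv not found next to ", path)
  sm <- tryCatch(Matrix::readMM(path),
                 error = function(e) stop("malformed mtx file '", path, "': ",
                                          conditionMessage(e)))
  genes <- utils::read.table(gene_file, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
  # CellRanger sidecars carry (ensembl id, symbol); prefer the symbol column
  gene_ids <- if (ncol(genes) >= 2) as.character(genes[[2]]) else as.character(genes[[1]])
  barcodes <- utils::read.table(bc_file, sep = "\t", header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  if (nrow(sm) != length(gene_ids)) {
    stop(sprintf("mtx declares %d rows but gene sidecar has %d entries",
                 nrow(sm), length(gene_ids)))
  }
  if (ncol(sm) != length(barcodes)) {
    stop(sprintf("mtx declares %d columns but barcode sidecar has %d entries",
                 ncol(sm), length(barcodes)))
  }
  expression_matrix(as.matrix(sm), gene_ids = gene_ids,
                    cell_ids = as.character(barcodes))
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_expression_matrix()]. For `"mtx"`, `path` names the
#' `.mtx` file and `genes.tsv` / `barcodes.tsv` sidecars are written next to
#' it.
#'
#' @inheritParams read_expression_matrix
#' @param m an [expression_matrix()].
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, format = c("csv", "tsv", "mtx")) {
  stopifnot(inherits(m, "expression_matrix"))
  format <- match.arg(format)
  if (format == "mtx") {
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(m$values, sparse = TRUE),
                                            "CsparseMatrix"), "generalMatrix"), path)
    utils::write.table(data.frame(m$gene_ids, m$gene_ids),
                       file.path(dirname(path), "genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    utils::write.table(data.frame(m$cell_ids),
                       file.path(dirname(path), "barcodes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(gene_id = m$gene_ids, m$values, check.names = FALSE,
                     row.names = NULL)
    colnames(df) <- c("gene_id", m$cell_ids)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read per-cell labels from a two-column CSV
#'
#' @param path CSV with columns `cell_id,label`.
#' @return named character vector of labels, named by cell id.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "label") %in% colnames(df))) {
    stop("labels file must have columns cell_id,label: ", path)
  }
  stats::setNames(as.character(df$label), as.character(df$cell_id))
}
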
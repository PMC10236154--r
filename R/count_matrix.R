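#' Sparse gene-by-cell UMI count container
#'
#' `CountMatrix` bundles a sparse genes x cells matrix of non-negative
#' integer UMI counts with per-gene and per-cell metadata. It is the
#' exchange object used by every stage of the pipeline.
#'
#' @param counts A genes x cells matrix coercible to
#'   [Matrix::dgCMatrix-class]; entries must be non-negative integers.
#' @param gene_meta A data.frame with at least `gene_id` (unique) and
#'   `symbol` columns; an `is_mito` logical column is added from the
#'   symbol prefix `"MT-"` (case-insensitive) when absent.
#' @param cell_meta A data.frame with at least a unique `cell_id` column;
#'   typical columns are `sample_id`, `subject_id`, `tissue`, `condition`,
#'   and for simulated data `true_label` and the mixture truth columns
#'   `mix_type_a`, `mix_type_b`, `mix_alpha`.
#' @return An object of class `CountMatrix`.
#' @export
CountMatrix <- function(counts, gene_meta, cell_meta) {
  counts <- if (is.matrix(counts)) {
    methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  } else {
    methods::as(methods::as(methods::as(counts, "dMatrix"),
                            "generalMatrix"), "CsparseMatrix")
  }
  gene_meta <- as.data.frame(gene_meta, stringsAsFactors = FALSE)
  cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
  if (is.null(gene_meta$gene_id) || is.null(cell_meta$cell_id))
    stop("gene_meta needs a 'gene_id' column and cell_meta a 'cell_id' column")
  if (nrow(gene_meta) != nrow(counts) || nrow(cell_meta) != ncol(counts))
    stop(sprintf("metadata dimensions (%d genes, %d cells) do not match counts (%d x %d)",
                 nrow(gene_meta), nrow(cell_meta), nrow(counts), ncol(counts)))
  if (anyDuplicated(gene_meta$gene_id)) stop("gene_ids are not unique")
  if (anyDuplicated(cell_meta$cell_id)) stop("cell_ids are not unique")
  if (length(counts@x) && (any(counts@x < 0) || any(counts@x != round(counts@x))))
    stop("counts must be non-negative integers")
  if (is.null(gene_meta$symbol)) gene_meta$symbol <- gene_meta$gene_id
  if (is.null(gene_meta$is_mito))
    gene_meta$is_mito <- grepl("^MT-", gene_meta$symbol, ignore.case = TRUE)
  gene_meta$is_mito <- as.logical(gene_meta$is_mito)
  dimnames(counts) <- list(gene_meta$gene_id, cell_meta$cell_id)
  rownames(gene_meta) <- NULL
  rownames(cell_meta) <- NULL
  structure(list(counts = counts, gene_meta = gene_meta, cell_meta = cell_meta),
            class = "CountMatrix")
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d cells (%d non-zero entries)\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  extra <- setdiff(names(x$cell_meta), "cell_id")
  if (length(extra)) cat("cell metadata:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

open_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

#' Read a sparse count matrix with TSV metadata sidecars
#'
#' Reads a Matrix Market coordinate file (1-based indices, genes as rows,
#' cells as columns, the 10x convention) together with tab-separated
#' gene and cell metadata sidecars. Gzipped files are handled
#' transparently. Extra sidecar columns are preserved verbatim.
#'
#' @param matrix_path Path to the `.mtx` (optionally `.mtx.gz`) file.
#' @param genes_path,cells_path Paths to the TSV sidecars; both must have
#'   a header row, with `gene_id` / `cell_id` as first columns.
#' @return A [CountMatrix].
#' @export
read_counts <- function(matrix_path, genes_path, cells_path) {
  con <- open_maybe_gz(matrix_path)
  on.exit(close(con), add = TRUE)
  mm <- Matrix::readMM(con)
  gene_meta <- utils::read.delim(genes_path, stringsAsFactors = FALSE,
                                 colClasses = NA, check.names = FALSE)
  cell_meta <- utils::read.delim(cells_path, stringsAsFactors = FALSE,
                                 colClasses = NA, check.names = FALSE)
  if (nrow(gene_meta) != nrow(mm) || nrow(cell_meta) != ncol(mm))
    stop(sprintf("matrix header declares %d x %d but sidecars have %d genes and %d cells",
                 nrow(mm), ncol(mm), nrow(gene_meta), nrow(cell_meta)))
  CountMatrix(mm, gene_meta, cell_meta)
}

#' Write a CountMatrix to Matrix Market + TSV sidecars
#'
#' Inverse of [read_counts()]: `read_counts()` on the written files
#' reproduces the object element-wise and in metadata.
#'
#' @param m A [CountMatrix].
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of the three written paths.
#' @export
write_counts <- function(m, out_dir) {
  stopifnot(inherits(m, "CountMatrix"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  paths <- c(matrix = file.path(out_dir, "matrix.mtx"),
             genes = file.path(out_dir, "genes.tsv"),
             cells = file.path(out_dir, "cells.tsv"))
  cm <- methods::as(m$counts, "TsparseMatrix")
  hdr <- c("%%MatrixMarket matrix coordinate integer general",
           sprintf("%d %d %d", nrow(cm), ncol(cm), length(cm@x)))
  body <- sprintf("%d %d %d", cm@i + 1L, cm@j + 1L, as.integer(cm@x))
  writeLines(c(hdr, body), paths[["matrix"]])
  utils::write.table(m$gene_meta, paths[["genes"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(m$cell_meta, paths[["cells"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths
}

#' Subset a CountMatrix by gene and cell masks
#'
#' @param x A [CountMatrix].
#' @param gene_mask,cell_mask Logical vectors matching the matrix
#'   dimensions; `NULL` keeps everything.
#' @param ... Ignored.
#' @return A [CountMatrix] restricted to the selected genes and cells,
#'   metadata subset in the original order.
#' @export
subset.CountMatrix <- function(x, gene_mask = NULL, cell_mask = NULL, ...) {
  if (is.null(gene_mask)) gene_mask <- rep(TRUE, nrow(x$counts))
  if (is.null(cell_mask)) cell_mask <- rep(TRUE, ncol(x$counts))
  if (length(gene_mask) != nrow(x$counts) || length(cell_mask) != ncol(x$counts))
    stop("mask lengths must match matrix dimensions")
  CountMatrix(x$counts[gene_mask, cell_mask, drop = FALSE],
              x$gene_meta[gene_mask, , drop = FALSE],
              x$cell_meta[cell_mask, , drop = FALSE])
}
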
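#' Build a multi-subject reference signature model
#'
#' For every cell type, each subject's cells are pooled into a relative
#' expression profile (summed counts normalized to sum 1); the per-type
#' signature `theta` is the average of these profiles across subjects and
#' `V` their cross-subject variance. Genes expressed in no type are
#' dropped; the remaining informative genes are ranked by the
#' between-type variance of `theta` divided by the mean cross-subject
#' variance plus `eps`, so genes that separate phenotypes consistently
#' across donors rank highest.
#'
#' @param m A [CountMatrix] of annotated reference cells.
#' @param label_key,subject_key Names of the `cell_meta` columns holding
#'   the cell-type label and subject (donor) id.
#' @param group_map Named character vector mapping each cell type to a
#'   tissue group (e.g. Squamous/SMG/Gastric/Intestinal/Colon). `NULL`
#'   maps each type to itself.
#' @param min_cells Minimum cells a subject must contribute to a type for
#'   its profile to enter the average (default 3); exclusions recorded.
#' @param n_informative Keep at most this many top-ranked informative
#'   genes (default all qualifying genes).
#' @param eps Stabilizer in the informative-gene ranking.
#' @return A list of class `ReferenceModel` with `theta` (genes x types,
#'   columns sum to 1), `V`, `S` (mean cell size per type), `cell_types`,
#'   `group_map`, `informative_genes` and `excluded` bookkeeping.
#' @export
build_reference <- function(m, label_key = "true_label",
                            subject_key = "subject_id", group_map = NULL,
                            min_cells = 3, n_informative = Inf, eps = 1e-6) {
  stopifnot(inherits(m, "CountMatrix"))
  labels <- m$cell_meta[[label_key]]
  subjects <- m$cell_meta[[subject_key]]
  if (is.null(labels) || is.null(subjects))
    stop("label/subject columns not found in cell_meta")
  if (anyNA(labels)) stop("every cell must be labeled")
  types <- unique(labels)
  n_genes <- nrow(m$counts)
  theta <- matrix(0, n_genes, length(types),
                  dimnames = list(m$gene_meta$gene_id, types))
  V <- theta
  S <- stats::setNames(numeric(length(types)), types)
  excluded <- list()
  for (k in seq_along(types)) {
    profs <- list(); sizes <- numeric(0)
    for (s in unique(subjects)) {
      cells <- which(labels == types[k] & subjects == s)
      if (length(cells) == 0) next
      if (length(cells) < min_cells) {
        excluded[[length(excluded) + 1L]] <- data.frame(
          cell_type = types[k], subject = s, n_cells = length(cells),
          stringsAsFactors = FALSE)
        next
      }
      tot <- Matrix::rowSums(m$counts[, cells, drop = FALSE])
      profs[[s]] <- as.numeric(tot / sum(tot))
      sizes <- c(sizes, mean(Matrix::colSums(m$counts[, cells, drop = FALSE])))
    }
    if (length(profs) == 0)
      stop("cell type has no subject with >= min_cells cells: ", types[k])
    P <- do.call(cbind, profs)
    theta[, k] <- rowMeans(P)
    if (ncol(P) >= 2) {
      V[, k] <- apply(P, 1, stats::var)
    } else {
      warning("cell type '", types[k],
              "' present in a single subject; cross-subject variance set to 0")
    }
    S[k] <- mean(sizes)
  }
  if (is.null(group_map)) group_map <- stats::setNames(types, types)
  if (!all(types %in% names(group_map)))
    stop("group_map missing cell types: ",
         paste(setdiff(types, names(group_map)), collapse = ", "))
  informative <- which(rowSums(theta > 0) > 0)
  score <- apply(theta[informative, , drop = FALSE], 1, stats::var) /
    (rowMeans(V[informative, , drop = FALSE]) + eps)
  ord <- informative[order(-score)]
  keep <- ord[seq_len(min(n_informative, length(ord)))]
  keep <- sort(keep)  # fixed gene order for deterministic fits
  structure(list(theta = theta, V = V, S = S, cell_types = types,
                 group_map = group_map[types],
                 informative_genes = m$gene_meta$gene_id[keep],
                 excluded = if (length(excluded)) do.call(rbind, excluded) else NULL),
            class = "ReferenceModel")
}

#' @export
print.ReferenceModel <- function(x, ...) {
  cat(sprintf("ReferenceModel: %d cell types, %d informative genes\n",
              length(x$cell_types), length(x$informative_genes)))
  cat("groups:", paste(unique(x$group_map), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize / load a ReferenceModel as plain text
#'
#' Writes the signatures, variances, cell sizes and group map as TSV
#' files in one directory.
#'
#' @param ref A `ReferenceModel`.
#' @param dir Directory to write to / read from.
#' @return `write_reference` the directory (invisibly); `read_reference`
#'   a `ReferenceModel`.
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f) utils::write.table(d, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  wt(data.frame(gene_id = rownames(ref$theta), ref$theta, check.names = FALSE), "theta.tsv")
  wt(data.frame(gene_id = rownames(ref$V), ref$V, check.names = FALSE), "variance.tsv")
  wt(data.frame(cell_type = ref$cell_types, size = ref$S,
                group = ref$group_map[ref$cell_types]), "types.tsv")
  writeLines(ref$informative_genes, file.path(dir, "informative_genes.txt"))
  invisible(dir)
}

#' @rdname write_reference
#' @export
read_reference <- function(dir) {
  th <- utils::read.delim(file.path(dir, "theta.tsv"), check.names = FALSE)
  vv <- utils::read.delim(file.path(dir, "variance.tsv"), check.names = FALSE)
  ty <- utils::read.delim(file.path(dir, "types.tsv"))
  theta <- as.matrix(th[, -1, drop = FALSE]); rownames(theta) <- th$gene_id
  V <- as.matrix(vv[, -1, drop = FALSE]); rownames(V) <- vv$gene_id
  structure(list(theta = theta, V = V,
                 S = stats::setNames(ty$size, ty$cell_type),
                 cell_types = ty$cell_type,
                 group_map = stats::setNames(ty$group, ty$cell_type),
                 informative_genes = readLines(file.path(dir, "informative_genes.txt")),
                 excluded = NULL),
            class = "ReferenceModel")
}
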
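#' Aggregate single cells into pseudo-bulk samples
#'
#' Raw UMI counts are summed over all cells sharing a combination of the
#' key columns (typically cell type, patient and condition), yielding
#' bulk-like samples suitable for negative-binomial GLM testing with
#' patient-level replication.
#'
#' @param m A [CountMatrix].
#' @param keys `cell_meta` columns defining a pseudo-bulk sample
#'   (default `true_label`, `subject_id`, `condition`).
#' @param min_cells Samples pooled from fewer cells are flagged
#'   (`flagged` column), not dropped (default 10).
#' @return A list of class `PseudobulkTable` with integer `counts`
#'   (genes x samples), `sample_meta` (`cell_type`, `patient`,
#'   `condition`, `n_cells`, `flagged`) and `norm_factors` (all 1 until
#'   [tmm_norm_factors()] is applied).
#' @export
aggregate_pseudobulk <- function(m, keys = c("true_label", "subject_id",
                                             "condition"),
                                 min_cells = 10) {
  stopifnot(inherits(m, "CountMatrix"))
  missing <- setdiff(keys, names(m$cell_meta))
  if (length(missing))
    stop("key column(s) not found in cell_meta: ", paste(missing, collapse = ", "))
  key_df <- m$cell_meta[keys]
  grp <- interaction(key_df, drop = TRUE, sep = "|", lex.order = TRUE)
  ind <- Matrix::sparseMatrix(i = seq_along(grp), j = as.integer(grp), x = 1,
                              dims = c(length(grp), nlevels(grp)))
  counts <- as.matrix(m$counts %*% ind)
  storage.mode(counts) <- "integer"
  meta <- unique(data.frame(key_df, grp = as.character(grp),
                            stringsAsFactors = FALSE))
  meta <- meta[match(levels(grp), meta$grp), , drop = FALSE]
  names(meta)[seq_along(keys)] <- c("cell_type", "patient", "condition")[seq_along(keys)]
  meta$n_cells <- as.integer(table(grp)[levels(grp)])
  meta$flagged <- meta$n_cells < min_cells
  rownames(meta) <- NULL
  colnames(counts) <- meta$grp
  rownames(counts) <- m$gene_meta$gene_id
  structure(list(counts = counts, sample_meta = meta,
                 norm_factors = stats::setNames(rep(1, ncol(counts)), meta$grp)),
            class = "PseudobulkTable")
}

#' @export
print.PseudobulkTable <- function(x, ...) {
  cat(sprintf("PseudobulkTable: %d genes x %d samples (%d flagged as < min cells)\n",
              nrow(x$counts), ncol(x$counts), sum(x$sample_meta$flagged)))
  invisible(x)
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' Computes TMM composition-bias factors across pseudo-bulk samples
#' (trim 30\% of M-value tails, 5\% of A-value tails, precision-weighted
#' mean, reference chosen by upper-quartile ratio), rescaled to geometric
#' mean 1. Pure depth differences are absorbed by library-size offsets,
#' so a sample that is an exact multiple of another gets factor 1.
#'
#' @param t A `PseudobulkTable`.
#' @return The table with `norm_factors` filled in.
#' @export
tmm_norm_factors <- function(t) {
  stopifnot(inherits(t, "PseudobulkTable"))
  if (sum(colSums(t$counts) > 0) < 2)
    stop("need at least 2 samples with positive totals")
  f <- edgeR::calcNormFactors(edgeR::DGEList(counts = t$counts),
                              method = "TMM")$samples$norm.factors
  t$norm_factors <- stats::setNames(f, colnames(t$counts))
  t
}

#' Estimate per-gene negative-binomial dispersions
#'
#' Maximum (adjusted profile) likelihood dispersion estimation across the
#' pseudo-bulk samples given a design matrix, with empirical-Bayes
#' shrinkage toward a mean-dispersion trend.
#'
#' @param t A `PseudobulkTable` (normalization factors applied if
#'   present).
#' @param design Design matrix (rows = samples).
#' @return Named numeric vector of per-gene dispersions (floored at
#'   1e-8).
#' @export
estimate_dispersion <- function(t, design) {
  stopifnot(inherits(t, "PseudobulkTable"))
  if (nrow(design) != ncol(t$counts))
    stop("design rows must match pseudo-bulk samples")
  if (nrow(design) - qr(design)$rank < 1)
    stop("no residual degrees of freedom for dispersion estimation")
  d <- edgeR::DGEList(counts = t$counts, norm.factors = t$norm_factors)
  d <- edgeR::estimateDisp(d, design)
  stats::setNames(pmax(d$tagwise.dispersion, 1e-8), rownames(t$counts))
}

#' Threshold differential-expression test on pseudo-bulk samples
#'
#' Fits a negative-binomial generalized log-linear model per gene (log
#' link, offsets log(library size x normalization factor)) and tests the
#' null that the absolute log2 fold-change of the chosen coefficient is
#' at most `lfc` (TREAT-style shifted test), so that significance implies
#' a fold-change beyond the threshold rather than mere non-zero change.
#' With `lfc = 0` the test reduces to the ordinary two-sided test.
#'
#' @param t A `PseudobulkTable`.
#' @param design Design matrix (rows = samples), e.g.
#'   `model.matrix(~ patient + condition, t$sample_meta)`.
#' @param coef Column index or name of the tested coefficient.
#' @param lfc Log2 fold-change threshold under the null (default 0.5).
#' @param use_flagged Include samples flagged as too small (default
#'   FALSE drops them along with matching design rows).
#' @return A data.frame of class `DEResult`: `gene_id`, `logFC`,
#'   `unshrunk_logFC`, `logCPM`, `p`, `fdr`, `direction`.
#' @export
de_test_treat <- function(t, design, coef = ncol(design), lfc = 0.5,
                          use_flagged = FALSE) {
  stopifnot(inherits(t, "PseudobulkTable"))
  keep <- if (use_flagged) rep(TRUE, ncol(t$counts)) else !t$sample_meta$flagged
  counts <- t$counts[, keep, drop = FALSE]
  design2 <- design[keep, , drop = FALSE]
  if (qr(design2)$rank < ncol(design2)) stop("design matrix is not full rank")
  nf <- t$norm_factors[keep]
  nf <- nf / exp(mean(log(nf)))  # re-center after any subsetting
  d <- edgeR::DGEList(counts = counts, norm.factors = nf)
  d <- edgeR::estimateDisp(d, design2)
  fit <- edgeR::glmQLFit(d, design2)
  tr <- if (lfc > 0) edgeR::glmTreat(fit, coef = coef, lfc = lfc)
  else suppressWarnings(edgeR::glmTreat(fit, coef = coef, lfc = 0))
  tab <- tr$table
  unshrunk <- if (!is.null(tab$unshrunk.logFC)) tab$unshrunk.logFC else tab$logFC
  res <- data.frame(gene_id = rownames(counts), logFC = tab$logFC,
                    unshrunk_logFC = unshrunk, logCPM = tab$logCPM,
                    p = tab$PValue, fdr = bh_fdr(tab$PValue),
                    direction = ifelse(tab$logFC > 0, "up",
                                       ifelse(tab$logFC < 0, "down", "none")),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("DEResult", "data.frame")
  res
}

#' Simes combination of p-values
#'
#' Returns `min_i ( n * p_(i) / i )` over the ascending sorted p-values,
#' capped at 1 — valid for the intersection null without requiring every
#' individual comparison to reject.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return The combined p-value.
#' @export
combine_simes <- function(pvals) {
  if (length(pvals) == 0) stop("empty p-value list")
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  n <- length(pvals)
  sp <- sort(pvals)
  min(1, min(n * sp / seq_len(n)))
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjusted p-values, monotone non-decreasing in p, capped at 1.
#'
#' @param pvals Numeric vector of p-values.
#' @return Adjusted p-values (same order as input).
#' @export
bh_fdr <- function(pvals) stats::p.adjust(pvals, method = "BH")

#' Cell-type marker genes by all-pairwise threshold tests
#'
#' Within one tissue, every pair of cell types is tested with
#' [de_test_treat()] (patient as a blocking factor whenever both types
#' share at least two patients); per cell type, each gene's p-values
#' across all comparisons involving that type (oriented so positive
#' logFC means up in the type) are combined by Simes and BH-adjusted
#' over genes.
#'
#' @param t A `PseudobulkTable` whose `cell_type` column has >= 2 levels.
#' @param lfc Log2 fold-change threshold (default 0.5).
#' @return A list with `pairwise` (named list of `DEResult`, names
#'   `"A|B"`) and `combined` (named list per type: data.frame `gene_id`,
#'   `min_p`, `p_simes`, `fdr`, `n_up`).
#' @export
marker_genes_per_type <- function(t, lfc = 0.5) {
  stopifnot(inherits(t, "PseudobulkTable"))
  types <- unique(t$sample_meta$cell_type)
  if (length(types) < 2) stop("need at least 2 cell types")
  pairwise <- list()
  for (i in seq_along(types)) {
    for (j in seq_along(types)) {
      if (j <= i) next
      A <- types[i]; B <- types[j]
      sel <- t$sample_meta$cell_type %in% c(A, B)
      sub <- t
      sub$counts <- t$counts[, sel, drop = FALSE]
      sub$sample_meta <- t$sample_meta[sel, , drop = FALSE]
      sub$norm_factors <- t$norm_factors[sel]
      meta <- sub$sample_meta
      grp <- factor(meta$cell_type, levels = c(B, A))  # coef: up in A
      shared <- intersect(meta$patient[meta$cell_type == A],
                          meta$patient[meta$cell_type == B])
      design <- if (length(shared) >= 2 && length(unique(meta$patient)) >= 2)
        stats::model.matrix(~ factor(meta$patient) + grp)
      else stats::model.matrix(~ grp)
      pairwise[[paste(A, B, sep = "|")]] <-
        de_test_treat(sub, design, coef = ncol(design), lfc = lfc)
    }
  }
  combined <- list()
  for (A in types) {
    keys <- names(pairwise)[vapply(strsplit(names(pairwise), "\\|"),
                                   function(v) A %in% v, TRUE)]
    P <- sapply(keys, function(k) pairwise[[k]]$p)
    FC <- sapply(keys, function(k) {
      sgn <- if (startsWith(k, paste0(A, "|"))) 1 else -1
      sgn * pairwise[[k]]$logFC
    })
    P <- matrix(P, ncol = length(keys)); FC <- matrix(FC, ncol = length(keys))
    p_simes <- apply(P, 1, combine_simes)
    combined[[A]] <- data.frame(gene_id = rownames(t$counts),
                                min_p = apply(P, 1, min),
                                p_simes = p_simes, fdr = bh_fdr(p_simes),
                                n_up = rowSums(FC > 0),
                                stringsAsFactors = FALSE, row.names = NULL)
  }
  list(pairwise = pairwise, combined = combined)
}
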
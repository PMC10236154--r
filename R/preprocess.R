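#' Quality-control bounds for cell-level filtering
#'
#' Cells are retained when total UMIs, detected genes and the percentage
#' of mitochondrial UMIs all lie within the given closed intervals. The
#' default mitochondrial bounds are 0.5\% (lower) and 25\% (upper), the
#' filter applied to metabolically active upper-GI tissue where high
#' mitochondrial content is common.
#'
#' @param min_umi,max_umi Bounds on the per-cell UMI total.
#' @param min_genes,max_genes Bounds on detected genes per cell.
#' @param mito_low,mito_high Bounds on the mitochondrial UMI percentage
#'   (0-100 scale).
#' @return A list of class `qc_bounds`.
#' @export
qc_bounds <- function(min_umi = 0, max_umi = Inf,
                      min_genes = 0, max_genes = Inf,
                      mito_low = 0.5, mito_high = 25) {
  if (min_umi > max_umi || min_genes > max_genes || mito_low > mito_high)
    stop("each lower bound must not exceed its upper bound")
  if (mito_low < 0 || mito_high > 100)
    stop("mitochondrial percentages must lie in [0, 100]")
  structure(list(min_umi = min_umi, max_umi = max_umi,
                 min_genes = min_genes, max_genes = max_genes,
                 mito_low = mito_low, mito_high = mito_high),
            class = "qc_bounds")
}

#' Cell-level quality-control filter
#'
#' Computes per-cell UMI totals, detected-gene counts and mitochondrial
#' UMI percentages and removes cells outside the bounds. The report
#' records every removed cell with the offending metric and its value,
#' so filtering decisions are auditable.
#'
#' @param m A [CountMatrix] with `is_mito` populated in `gene_meta`.
#' @param bounds A [qc_bounds()], or when `per_sample = TRUE` optionally
#'   a named list of [qc_bounds()] keyed by `sample_id` (samples without
#'   an entry fall back to `default`, or to the package defaults).
#' @param per_sample Apply (possibly sample-specific) bounds per sample.
#' @return A list with `counts` (the filtered [CountMatrix]) and
#'   `report`, a data.frame (`cell_id`, `sample_id`, `metric`, `value`,
#'   `action`) listing removals and any skipped filters.
#' @export
qc_filter <- function(m, bounds = qc_bounds(), per_sample = FALSE) {
  stopifnot(inherits(m, "CountMatrix"))
  umi <- Matrix::colSums(m$counts)
  ngene <- Matrix::colSums(m$counts > 0)
  mito_genes <- which(m$gene_meta$is_mito)
  have_mito <- length(mito_genes) > 0
  mito_pct <- if (have_mito)
    100 * Matrix::colSums(m$counts[mito_genes, , drop = FALSE]) / pmax(umi, 1)
  else rep(NA_real_, ncol(m$counts))

  sample_of <- if (per_sample) m$cell_meta$sample_id else rep("all", ncol(m$counts))
  bounds_for <- function(s) {
    if (inherits(bounds, "qc_bounds")) return(bounds)
    if (!is.null(bounds[[s]])) return(bounds[[s]])
    if (!is.null(bounds$default)) return(bounds$default)
    qc_bounds()
  }

  report <- list()
  keep <- rep(TRUE, ncol(m$counts))
  mito_active <- FALSE
  for (j in seq_len(ncol(m$counts))) {
    b <- bounds_for(sample_of[j])
    fail <- character(0); val <- numeric(0)
    if (umi[j] < b$min_umi || umi[j] > b$max_umi) {
      fail <- c(fail, "umi"); val <- c(val, umi[j])
    }
    if (ngene[j] < b$min_genes || ngene[j] > b$max_genes) {
      fail <- c(fail, "detected_genes"); val <- c(val, ngene[j])
    }
    if (b$mito_low > 0 || is.finite(b$mito_high) && b$mito_high < 100)
      mito_active <- TRUE
    if (have_mito && !is.na(mito_pct[j]) &&
        (mito_pct[j] < b$mito_low || mito_pct[j] > b$mito_high)) {
      fail <- c(fail, "mito_pct"); val <- c(val, mito_pct[j])
    }
    if (length(fail)) {
      keep[j] <- FALSE
      report[[length(report) + 1L]] <- data.frame(
        cell_id = m$cell_meta$cell_id[j], sample_id = m$cell_meta$sample_id[j],
        metric = fail, value = val, action = "removed",
        stringsAsFactors = FALSE)
    }
  }
  if (!have_mito && mito_active) {
    warning("no mitochondrial genes present; mitochondrial filter skipped")
    report[[length(report) + 1L]] <- data.frame(
      cell_id = NA_character_, sample_id = NA_character_, metric = "mito_pct",
      value = NA_real_, action = "filter_skipped_no_mito_genes",
      stringsAsFactors = FALSE)
  }
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(cell_id = character(0), sample_id = character(0),
               metric = character(0), value = numeric(0),
               action = character(0), stringsAsFactors = FALSE)
  list(counts = subset(m, cell_mask = keep), report = report)
}

#' Remove genes not detected in any cell
#'
#' @param m A [CountMatrix].
#' @return The [CountMatrix] restricted to genes with a positive total
#'   count, in the original order.
#' @export
drop_undetected_genes <- function(m) {
  stopifnot(inherits(m, "CountMatrix"))
  subset(m, gene_mask = Matrix::rowSums(m$counts) > 0)
}

#' Cross-batch scaling normalization to log2 expression
#'
#' Per-cell size factors are the cell's library size divided by the
#' geometric mean library size of its batch; factors are then rescaled
#' by (batch mean library)/(minimum batch mean library) so that the
#' effective coverage of every batch matches the lowest-coverage batch.
#' Values are `log2(count / size_factor + 1)`.
#'
#' @param m A [CountMatrix]; all cells must have positive totals.
#' @param batch_key Name of the `cell_meta` column holding batch labels.
#' @return A `NormalizedMatrix`: list with sparse `values`,
#'   `size_factors`, `batch`, and the gene/cell metadata.
#' @export
normalize_counts <- function(m, batch_key = "sample_id") {
  stopifnot(inherits(m, "CountMatrix"))
  batch <- m$cell_meta[[batch_key]]
  if (is.null(batch)) stop("batch column not found in cell_meta: ", batch_key)
  lib <- Matrix::colSums(m$counts)
  if (any(lib <= 0))
    stop("cells with zero total counts present; run qc_filter/drop first")
  geo <- tapply(lib, batch, function(v) exp(mean(log(v))))
  bmean <- tapply(lib, batch, mean)
  sf <- lib / geo[batch] * (bmean[batch] / min(bmean))
  sf <- as.numeric(sf)
  values <- m$counts
  if (length(values@x)) {
    col_of <- rep(seq_len(ncol(values)), diff(values@p))
    values@x <- log2(values@x / sf[col_of] + 1)
  }
  structure(list(values = values, size_factors = sf, batch = batch,
                 gene_meta = m$gene_meta, cell_meta = m$cell_meta),
            class = "NormalizedMatrix")
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat(sprintf("NormalizedMatrix: %d genes x %d cells, %d batches\n",
              nrow(x$values), ncol(x$values), length(unique(x$batch))))
  invisible(x)
}

#' Highly-variable-gene selection by mean-variance trend decomposition
#'
#' Per-gene means and variances of the log2-normalized values are
#' computed; a smooth trend of variance against mean captures the
#' technical mean-variance relationship, and genes are ranked by the
#' biological variance (total minus trend), descending. The trend is a
#' local regression (span 0.3) with a degree-2 polynomial fallback for
#' small gene sets; ties in rank are broken by input gene order.
#'
#' @param nm A `NormalizedMatrix` from [normalize_counts()].
#' @param n Number of genes to flag as highly variable (default 2000).
#' @return A data.frame with per-gene `mean`, `total`, `trend`, `bio`
#'   (= total - trend), `rank` and `selected`.
#' @export
select_hvg <- function(nm, n = 2000) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  if (n <= 0) stop("n must be positive")
  v <- nm$values
  if (nrow(v) < 10) stop("need at least 10 genes")
  nc <- ncol(v)
  mu <- Matrix::rowSums(v) / nc
  total <- (Matrix::rowSums(v^2) - nc * mu^2) / (nc - 1)
  trend <- if (length(unique(mu)) < 4) {
    rep(mean(total), length(mu))  # degenerate mean spread: flat trend
  } else if (nrow(v) >= 50) {
    fit <- stats::loess(total ~ mu, span = 0.3,
                        control = stats::loess.control(surface = "direct"))
    stats::predict(fit, mu)
  } else {
    stats::predict(stats::lm(total ~ stats::poly(mu, 2)))
  }
  trend <- pmax(as.numeric(trend), 0)
  bio <- total - trend
  ord <- order(-bio)            # stable: ties keep input gene order
  rank <- integer(length(bio)); rank[ord] <- seq_along(ord)
  data.frame(gene_id = nm$gene_meta$gene_id, mean = mu, total = total,
             trend = trend, bio = bio, rank = rank,
             selected = rank <= min(n, length(bio)),
             stringsAsFactors = FALSE, row.names = NULL)
}
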
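#' Deconvolve one cell against reference signatures
#'
#' Treats the cell's relative expression `x = y / sum(y)` as a bulk
#' mixture of the reference signatures and solves the weighted
#' non-negative least-squares problem
#' \deqn{\hat c = \arg\min_{c \ge 0} \sum_g w_g (x_g - \sum_k c_k \theta_{gk})^2}
#' by iteratively re-weighted NNLS. Weights start at 1; after each solve
#' \eqn{w_g = 1 / (\nu + \bar r^2 + \sum_k c_k^2 V_{gk})} with
#' \eqn{\bar r^2} the current mean squared residual and \eqn{\nu = 10^{-8}},
#' so genes with high cross-subject variance are down-weighted. Iteration
#' stops when \eqn{\max_k |\Delta c_k| / (\sum_k c_k + \nu) < } `tol`.
#'
#' Contributions `e = c / sum(c)` are RNA fractions; a cell-count-scale
#' alternative `e_size = (c/S) / sum(c/S)` (cell-size corrected) is also
#' returned for bulk use.
#'
#' @param y Named numeric vector of per-gene counts for one cell (names
#'   are gene ids); only the reference's informative genes are used.
#' @param ref A `ReferenceModel` from [build_reference()].
#' @param tol Relative convergence tolerance on the coefficients.
#' @param max_iter Maximum IRLS iterations.
#' @return A list of class `EGICResult`: `coefficients`, `contributions`
#'   (`NA` when the cell has no signal on informative genes, with
#'   `defined = FALSE`), `contributions_size`, `group_scores`,
#'   `mosaicism`, `n_iterations`, `converged`, `wrss`.
#' @export
deconvolve_cell <- function(y, ref, tol = 1e-6, max_iter = 100) {
  stopifnot(inherits(ref, "ReferenceModel"))
  genes <- intersect(ref$informative_genes, names(y))
  theta <- ref$theta[genes, , drop = FALSE]
  V <- ref$V[genes, , drop = FALSE]
  K <- ncol(theta)
  nu <- 1e-8
  yy <- as.numeric(y[genes])
  tot <- sum(yy)
  groups <- unique(ref$group_map)
  empty <- function() structure(list(
    coefficients = stats::setNames(rep(NA_real_, K), colnames(theta)),
    contributions = stats::setNames(rep(NA_real_, K), colnames(theta)),
    contributions_size = stats::setNames(rep(NA_real_, K), colnames(theta)),
    group_scores = stats::setNames(rep(NA_real_, length(groups)), groups),
    mosaicism = NA_real_, n_iterations = 0L, converged = FALSE,
    wrss = NA_real_, defined = FALSE), class = "EGICResult")
  if (tot <= 0) return(empty())
  x <- yy / tot

  w <- rep(1, length(x))
  cc <- rep(0, K)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    sw <- sqrt(w)
    fit <- pracma::lsqnonneg(theta * sw, x * sw)
    cnew <- fit$x
    if (max(abs(cnew - cc)) / (sum(cnew) + nu) < tol) {
      cc <- cnew; converged <- TRUE; break
    }
    cc <- cnew
    if (it >= max_iter) break
    r <- x - as.numeric(theta %*% cc)
    w <- 1 / (nu + mean(r^2) + as.numeric(V %*% cc^2))
  }
  names(cc) <- colnames(theta)
  if (sum(cc) <= 0) {
    res <- empty(); res$n_iterations <- it
    return(res)
  }
  e <- cc / sum(cc)
  cs <- cc / ref$S[colnames(theta)]
  e_size <- cs / sum(cs)
  gs <- tapply(e, ref$group_map[names(e)], sum)
  gs <- stats::setNames(as.numeric(gs[groups]), groups)
  gs[is.na(gs)] <- 0
  r <- x - as.numeric(theta %*% cc)
  mos <- if (all(c("Gastric", "Intestinal") %in% names(gs)))
    mosaicism_index(gs)
  else {  # no canonical pair in this group map: evenness of the top two
    o <- sort(gs, decreasing = TRUE)
    if (length(o) < 2 || o[1] + o[2] == 0) 0 else 2 * o[2] / (o[1] + o[2])
  }
  structure(list(coefficients = cc, contributions = e,
                 contributions_size = e_size, group_scores = gs,
                 mosaicism = mos,
                 n_iterations = it, converged = converged,
                 wrss = sum(w * r^2), defined = TRUE),
            class = "EGICResult")
}

#' @export
print.EGICResult <- function(x, ...) {
  cat("EGIC deconvolution:",
      if (!x$defined) "undefined (no signal on informative genes)\n" else "\n")
  if (x$defined) {
    print(round(x$group_scores, 4))
    cat(sprintf("mosaicism %.3f, %d iterations, converged: %s\n",
                x$mosaicism, x$n_iterations, x$converged))
  }
  invisible(x)
}

#' Per-cell EGIC phenotype scores for a whole count matrix
#'
#' Applies [deconvolve_cell()] to every cell and tabulates the per-type
#' contributions, tissue-group scores, mosaicism index and convergence
#' diagnostics.
#'
#' @param m A [CountMatrix].
#' @param ref A `ReferenceModel`.
#' @param tol,max_iter Passed to [deconvolve_cell()].
#' @param min_overlap Minimum number of shared informative genes required
#'   between `m` and the reference (default 50).
#' @return A data.frame keyed by `cell_id` with one column per cell type
#'   (contributions), one per tissue group (prefixed `group_`),
#'   `argmax_type`, `argmax_group`, `mosaicism`, `n_iterations`,
#'   `converged`, `defined`.
#' @export
egic_scores <- function(m, ref, tol = 1e-6, max_iter = 100, min_overlap = 50) {
  stopifnot(inherits(m, "CountMatrix"), inherits(ref, "ReferenceModel"))
  shared <- intersect(ref$informative_genes, m$gene_meta$gene_id)
  if (length(shared) < min_overlap)
    stop(sprintf("only %d informative genes shared with the reference (need >= %d)",
                 length(shared), min_overlap))
  counts <- as.matrix(m$counts[shared, , drop = FALSE])
  groups <- unique(ref$group_map)
  K <- length(ref$cell_types)
  out <- vector("list", ncol(counts))
  for (j in seq_len(ncol(counts))) {
    y <- counts[, j]
    names(y) <- shared
    r <- deconvolve_cell(y, ref, tol = tol, max_iter = max_iter)
    row <- c(as.list(r$contributions),
             stats::setNames(as.list(r$group_scores), paste0("group_", groups)))
    row$argmax_type <- if (r$defined)
      names(r$contributions)[which.max(r$contributions)] else NA_character_
    row$argmax_group <- if (r$defined)
      groups[which.max(r$group_scores)] else NA_character_
    row$mosaicism <- r$mosaicism
    row$n_iterations <- r$n_iterations
    row$converged <- r$converged
    row$defined <- r$defined
    out[[j]] <- row
  }
  res <- do.call(rbind, lapply(out, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  res <- data.frame(cell_id = m$cell_meta$cell_id, res,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(res) <- NULL
  res
}

#' Mosaicism index of two tissue-group scores
#'
#' Quantifies how evenly a cell's phenotype is split between two groups
#' (by default Gastric and Intestinal): with scores `a` and `b`, returns
#' `2 * min(a, b) / (a + b)`, i.e. 0 for a pure phenotype and 1 for an
#' even mosaic; 0 when both scores are 0.
#'
#' @param g Named numeric vector of group scores.
#' @param group_a,group_b Names of the two groups to compare.
#' @return A number in `[0, 1]`.
#' @export
mosaicism_index <- function(g, group_a = "Gastric", group_b = "Intestinal") {
  if (!group_a %in% names(g) || !group_b %in% names(g))
    stop("unknown group name(s): ", group_a, ", ", group_b)
  a <- g[[group_a]]; b <- g[[group_b]]
  if (a + b == 0) return(0)
  2 * min(a, b) / (a + b)
}

#' Fraction of cells co-expressing two marker genes
#'
#' Reports the share of cells whose log-normalized expression of both
#' genes exceeds a threshold — the per-cell co-expression statistic used
#' to demonstrate simultaneous gastric and intestinal marker expression
#' (e.g. MUC5AC with GPA33).
#'
#' @param nm A `NormalizedMatrix`.
#' @param gene_a,gene_b Gene symbols (or ids) to compare.
#' @param threshold Expression threshold (default 0: any detection).
#' @return A list with `fraction` and `table` (per-cell value pairs for
#'   plotting).
#' @export
coexpression_fraction <- function(nm, gene_a, gene_b, threshold = 0) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  find <- function(g) {
    i <- which(nm$gene_meta$symbol == g | nm$gene_meta$gene_id == g)
    if (length(i) == 0) stop("gene not found: ", g)
    i[1]
  }
  ia <- find(gene_a); ib <- find(gene_b)
  va <- as.numeric(nm$values[ia, ]); vb <- as.numeric(nm$values[ib, ])
  list(fraction = mean(va > threshold & vb > threshold),
       table = data.frame(cell_id = nm$cell_meta$cell_id,
                          gene_a = va, gene_b = vb,
                          stringsAsFactors = FALSE))
}
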
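#' Two-sample Wilcoxon rank-sum test per gene
#'
#' Thin wrapper around [stats::wilcox.test()] used for marker selection;
#' exact p-values are used when both groups are small and tie-free, the
#' normal approximation with tie correction otherwise.
#'
#' @param x,y Numeric vectors (expression of one gene in two label
#'   groups).
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or
#'   `"less"`.
#' @return The p-value.
#' @export
rank_sum_test <- function(x, y, alternative = "two.sided") {
  suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                      exact = NULL)$p.value)
}

# Vectorized two-sided Mann-Whitney over the rows of two matrices
# (genes x cells), normal approximation with tie correction.
rank_sum_p_rows <- function(A, B) {
  nA <- ncol(A); nB <- ncol(B); n <- nA + nB
  p <- numeric(nrow(A))
  mu <- nA * nB / 2
  for (g in seq_len(nrow(A))) {
    v <- c(A[g, ], B[g, ])
    r <- rank(v)
    U <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
    ties <- table(v)
    sig2 <- nA * nB / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) { p[g] <- 1; next }
    z <- (abs(U - mu) - 0.5) / sqrt(sig2)
    p[g] <- min(1, 2 * stats::pnorm(-z))
  }
  p
}

#' Train a reference-based cell classifier
#'
#' For every ordered pair of labels (A, B), genes are tested with a
#' two-sided rank-sum test between the two groups; the `m` genes most
#' significantly higher in A (ties broken by larger median difference,
#' then input gene order) become that pair's marker set. Reference
#' profiles are the median log-normalized profile per label per subject.
#'
#' @param nm A `NormalizedMatrix` of annotated reference cells.
#' @param labels Per-cell labels (or the name of a `cell_meta` column).
#' @param subject_key `cell_meta` column with the subject id.
#' @param m Markers retained per ordered label pair (default 20).
#' @param score_quantile Quantile of per-profile correlations used as the
#'   label score (default 0.8).
#' @param finetune_delta Labels within this margin of the best score are
#'   retained during fine-tuning (default 0.05).
#' @return A list of class `ClassifierModel`.
#' @export
train_classifier <- function(nm, labels = "true_label",
                             subject_key = "subject_id", m = 20,
                             score_quantile = 0.8, finetune_delta = 0.05) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  if (length(labels) == 1) labels <- nm$cell_meta[[labels]]
  if (m < 1) stop("m must be >= 1")
  tab <- table(labels)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("labels with < 2 cells excluded: ", paste(small, collapse = ", "))
    keep <- !labels %in% small
    nm <- list(values = nm$values[, keep, drop = FALSE],
               gene_meta = nm$gene_meta,
               cell_meta = nm$cell_meta[keep, , drop = FALSE],
               batch = nm$batch[keep], size_factors = nm$size_factors[keep])
    class(nm) <- "NormalizedMatrix"
    labels <- labels[keep]
  }
  lab_levels <- unique(labels)
  if (length(lab_levels) < 2) stop("need at least 2 labels with >= 2 cells")
  X <- as.matrix(nm$values)
  gene_ids <- nm$gene_meta$gene_id
  rownames(X) <- gene_ids

  # the two-sided test is symmetric: compute once per unordered pair,
  # pick markers directionally per ordered pair
  markers <- list()
  pcache <- new.env(parent = emptyenv())
  medians <- vapply(lab_levels, function(A)
    apply(X[, labels == A, drop = FALSE], 1, stats::median),
    numeric(nrow(X)))
  for (i in seq_along(lab_levels)) {
    for (j in seq_along(lab_levels)) {
      if (i == j) next
      A <- lab_levels[i]; B <- lab_levels[j]
      ukey <- paste(sort(c(A, B)), collapse = "|")
      if (is.null(pcache[[ukey]])) {
        XA <- X[, labels == A, drop = FALSE]
        XB <- X[, labels == B, drop = FALSE]
        pcache[[ukey]] <- if (ncol(XA) + ncol(XB) < 50) {
          vapply(seq_len(nrow(X)), function(g)
            rank_sum_test(XA[g, ], XB[g, ]), numeric(1))
        } else rank_sum_p_rows(XA, XB)
      }
      pv <- pcache[[ukey]]
      dmed <- medians[, A] - medians[, B]
      cls <- ifelse(dmed > 0, 0L, ifelse(dmed == 0, 1L, 2L))
      ord <- order(cls, pv, -dmed, seq_along(pv))
      ord <- ord[cls[ord] < 2L]  # genes strictly lower in A are never A-markers
      markers[[paste(A, B, sep = "|")]] <-
        gene_ids[ord[seq_len(min(m, length(ord)))]]
    }
  }

  profiles <- list(); prof_label <- character(0)
  subjects <- nm$cell_meta[[subject_key]]
  if (is.null(subjects)) subjects <- rep("s1", length(labels))
  for (A in lab_levels) {
    for (s in unique(subjects[labels == A])) {
      cells <- which(labels == A & subjects == s)
      profiles[[length(profiles) + 1L]] <-
        apply(X[, cells, drop = FALSE], 1, stats::median)
      prof_label <- c(prof_label, A)
    }
  }
  structure(list(labels = lab_levels, markers = markers,
                 profiles = do.call(cbind, profiles),
                 profile_label = prof_label, m = m,
                 score_quantile = score_quantile,
                 finetune_delta = finetune_delta,
                 gene_ids = gene_ids),
            class = "ClassifierModel")
}

#' @export
print.ClassifierModel <- function(x, ...) {
  cat(sprintf("ClassifierModel: %d labels, %d markers/pair, %d reference profiles\n",
              length(x$labels), x$m, ncol(x$profiles)))
  invisible(x)
}

spearman_scores <- function(x, model, active) {
  pairs <- expand.grid(A = active, B = active, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$A != pairs$B, , drop = FALSE]
  genes <- unique(unlist(model$markers[paste(pairs$A, pairs$B, sep = "|")]))
  genes <- intersect(genes, names(x))
  scores <- stats::setNames(rep(NA_real_, length(active)), active)
  if (length(genes) < 2) return(list(scores = scores, undefined = TRUE))
  xv <- x[genes]
  if (stats::sd(xv) == 0) return(list(scores = scores, undefined = TRUE))
  rx <- rank(xv)
  cors <- suppressWarnings(
    stats::cor(rx, apply(model$profiles[genes, , drop = FALSE], 2, rank)))
  cors[is.na(cors)] <- 0
  for (A in active)
    scores[A] <- stats::quantile(cors[model$profile_label == A],
                                 model$score_quantile, names = FALSE)
  list(scores = scores, undefined = FALSE)
}

#' Classify one cell against a trained reference model
#'
#' Round 1 scores every label by the `score_quantile` quantile of the
#' Spearman correlations between the cell and that label's reference
#' profiles, computed over the union of all pairwise marker genes.
#' Fine-tuning then repeatedly restricts to labels within
#' `finetune_delta` of the best score and re-scores using only markers
#' of the retained label pairs, until a single label remains or the set
#' stops shrinking.
#'
#' @param x Named numeric vector of log-normalized values for one cell.
#' @param model A `ClassifierModel`.
#' @return A list of class `AnnotationResult`: `label`, `scores` (round-1
#'   per-label scores), `rounds`, `pruned`, `delta` (top minus median
#'   score).
#' @export
classify_cell <- function(x, model) {
  stopifnot(inherits(model, "ClassifierModel"))
  genes0 <- unique(unlist(model$markers))
  if (length(intersect(genes0, names(x))) < 20)
    stop("fewer than 20 marker genes overlap the input cell")
  r1 <- spearman_scores(x, model, model$labels)
  if (r1$undefined) {
    return(structure(list(label = model$labels[1],
                          scores = stats::setNames(rep(0, length(model$labels)),
                                                   model$labels),
                          rounds = 0L, pruned = TRUE, delta = 0),
                     class = "AnnotationResult"))
  }
  scores1 <- r1$scores
  active <- model$labels[scores1 >= max(scores1) - model$finetune_delta]
  scores <- scores1
  rounds <- 0L
  while (length(active) > 1) {
    rounds <- rounds + 1L
    rr <- spearman_scores(x, model, active)
    if (rr$undefined) break
    scores_ft <- rr$scores
    new_active <- active[scores_ft >= max(scores_ft) - model$finetune_delta]
    scores <- scores_ft
    if (length(new_active) == length(active)) { active <- new_active; break }
    active <- new_active
  }
  label <- active[which.max(scores[active])]
  structure(list(label = label, scores = scores1, rounds = rounds,
                 pruned = max(scores1) - min(scores1) < 1e-12,
                 delta = max(scores1) - stats::median(scores1)),
            class = "AnnotationResult")
}

#' Classify every cell of a normalized matrix
#'
#' Applies [classify_cell()] per cell and flags low-confidence calls:
#' a cell is `pruned` when its score margin `delta` falls more than 3
#' median absolute deviations below the cohort's median `delta` (or when
#' its correlations were undefined). Pruned cells keep their label; the
#' flag only marks them.
#'
#' @param nm A `NormalizedMatrix`.
#' @param model A `ClassifierModel`.
#' @return A data.frame (`cell_id`, `label`, `delta`, `rounds`, `pruned`,
#'   one score column per label).
#' @export
classify_cells <- function(nm, model) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  X <- as.matrix(nm$values)
  rownames(X) <- nm$gene_meta$gene_id
  res <- vector("list", ncol(X))
  for (j in seq_len(ncol(X))) res[[j]] <- classify_cell(X[, j], model)
  delta <- vapply(res, `[[`, numeric(1), "delta")
  mad3 <- stats::median(delta) - 3 * stats::mad(delta)
  out <- data.frame(cell_id = nm$cell_meta$cell_id,
                    label = vapply(res, `[[`, character(1), "label"),
                    delta = delta,
                    rounds = vapply(res, `[[`, integer(1), "rounds"),
                    pruned = vapply(res, `[[`, logical(1), "pruned") |
                      delta < mad3,
                    stringsAsFactors = FALSE)
  sc <- t(vapply(res, function(r) r$scores[model$labels],
                 numeric(length(model$labels))))
  colnames(sc) <- paste0("score_", model$labels)
  cbind(out, as.data.frame(sc))
}

#' Cross-tabulate two annotations of the same cells
#'
#' @param a,b Label vectors over the same cells (same order).
#' @return A list with the contingency `table` and the overall
#'   `agreement` fraction.
#' @export
crosstab_annotations <- function(a, b) {
  if (length(a) != length(b))
    stop("annotations cover different numbers of cells")
  list(table = table(a, b), agreement = mean(a == b))
}
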
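#' Pipeline configuration
#'
#' One auditable home for every stage parameter of the end-to-end run:
#' simulate -> qc -> normalize -> hvg -> reference -> egic -> annotate
#' -> de -> report. Stages communicate only through files in the run
#' directory, so any stage can be re-run in isolation.
#'
#' @param out_dir Run directory.
#' @param seed Global seed governing all stochastic stages.
#' @param sim A [sim_config()] (its seed is overridden by `seed`).
#' @param mosaic_pairs List of `c(type_A, type_B)` pairs for planted
#'   mosaic cells; `n_mosaic` cells are drawn with uniform alpha.
#' @param n_mosaic Number of mosaic cells to simulate.
#' @param stages Character vector of stages to run.
#' @param qc A [qc_bounds()].
#' @param hvg_n Number of highly variable genes.
#' @param egic_tol,egic_max_iter Deconvolution settings.
#' @param markers_per_type,score_quantile,finetune_delta Classifier
#'   settings.
#' @param de_lfc,de_min_cells DE settings.
#' @param coexpr_genes Optional pair of gene ids/symbols for the
#'   co-expression report panel; defaults to the top planted marker of
#'   each mosaic pair type.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, sim = sim_config(),
                            mosaic_pairs = list(c("enterocyte", "foveolar")),
                            n_mosaic = 100,
                            stages = c("simulate", "qc", "normalize", "hvg",
                                       "reference", "egic", "annotate", "de",
                                       "report"),
                            qc = qc_bounds(), hvg_n = 2000,
                            egic_tol = 1e-6, egic_max_iter = 100,
                            markers_per_type = 20, score_quantile = 0.8,
                            finetune_delta = 0.05,
                            de_lfc = 0.5, de_min_cells = 10,
                            coexpr_genes = NULL) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 mosaic_pairs = mosaic_pairs, n_mosaic = n_mosaic,
                 stages = stages, qc = qc, hvg_n = hvg_n,
                 egic_tol = egic_tol, egic_max_iter = egic_max_iter,
                 markers_per_type = markers_per_type,
                 score_quantile = score_quantile,
                 finetune_delta = finetune_delta,
                 de_lfc = de_lfc, de_min_cells = de_min_cells,
                 coexpr_genes = coexpr_genes),
            class = "pipeline_config")
}

write_tsv <- function(d, path)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)

manifest_add <- function(run_dir, stage, status, params = list(),
                         inputs = character(0), seed = NA) {
  path <- file.path(run_dir, "manifest.json")
  man <- if (file.exists(path)) jsonlite::read_json(path) else list()
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  man[[stage]] <- list(stage = stage, status = status, seed = seed,
                       params = params, input_md5 = hashes)
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
}

#' Run the end-to-end synthetic analysis pipeline
#'
#' Executes the enabled stages in order inside `cfg$out_dir`, writing
#' every stage output as TSV/Matrix Market files plus a JSON manifest
#' recording stage status, parameters, the seed and input file hashes.
#' Reruns with the same configuration produce byte-identical tabular
#' outputs.
#'
#' @param cfg A [pipeline_config()].
#' @return The run directory, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  run <- cfg$out_dir
  dir.create(run, recursive = TRUE, showWarnings = FALSE)
  on_stage <- function(stage) stage %in% cfg$stages
  step <- function(stage, inputs, fun, params = list()) {
    if (!on_stage(stage)) {
      manifest_add(run, stage, "skipped", params, seed = cfg$seed)
      return(invisible(NULL))
    }
    ok <- tryCatch({ fun(); TRUE }, error = function(e) e)
    if (!isTRUE(ok)) {
      manifest_add(run, stage, paste("failed:", conditionMessage(ok)),
                   params, inputs[file.exists(inputs)], seed = cfg$seed)
      stop("stage '", stage, "' failed: ", conditionMessage(ok))
    }
    manifest_add(run, stage, "ok", params, inputs[file.exists(inputs)],
                 seed = cfg$seed)
  }
  counts_dir <- file.path(run, "counts")
  filt_dir <- file.path(run, "counts_qc")
  sim <- cfg$sim
  sim$seed <- cfg$seed

  step("simulate", character(0), function() {
    ref <- simulate_reference(sim)
    write_counts(ref$counts, counts_dir)
    write_tsv(ref$truth$markers, file.path(run, "truth_markers.tsv"))
    truth_cells <- data.frame(cell_id = ref$counts$cell_meta$cell_id,
                              true_label = ref$counts$cell_meta$true_label,
                              type_a = NA, type_b = NA, alpha = NA)
    if (cfg$n_mosaic > 0) {
      mos <- simulate_mosaic(sim, ref$truth, cfg$mosaic_pairs, cfg$n_mosaic,
                             seed = cfg$seed + 1L)
      both <- CountMatrix(
        cbind(ref$counts$counts, mos$counts$counts),
        ref$counts$gene_meta,
        merge_cell_meta(ref$counts$cell_meta, mos$counts$cell_meta))
      write_counts(both, counts_dir)
      truth_cells <- rbind(truth_cells, data.frame(
        cell_id = mos$truth$cell_id, true_label = "mosaic",
        type_a = mos$truth$mix_type_a, type_b = mos$truth$mix_type_b,
        alpha = mos$truth$mix_alpha))
    }
    write_tsv(truth_cells, file.path(run, "truth_cells.tsv"))
    write_tsv(data.frame(cell_type = names(ref$truth$group_map),
                         group = unname(ref$truth$group_map)),
              file.path(run, "group_map.tsv"))
  }, params = list(n_mosaic = cfg$n_mosaic))

  step("qc", file.path(counts_dir, "matrix.mtx"), function() {
    m <- read_counts(file.path(counts_dir, "matrix.mtx"),
                     file.path(counts_dir, "genes.tsv"),
                     file.path(counts_dir, "cells.tsv"))
    res <- qc_filter(m, cfg$qc)
    filtered <- drop_undetected_genes(res$counts)
    write_counts(filtered, filt_dir)
    write_tsv(res$report, file.path(run, "qc_report.tsv"))
  }, params = unclass(cfg$qc))

  step("normalize", file.path(filt_dir, "matrix.mtx"), function() {
    m <- read_counts(file.path(filt_dir, "matrix.mtx"),
                     file.path(filt_dir, "genes.tsv"),
                     file.path(filt_dir, "cells.tsv"))
    nm <- normalize_counts(m)
    write_tsv(data.frame(cell_id = nm$cell_meta$cell_id,
                         size_factor = nm$size_factors, batch = nm$batch),
              file.path(run, "size_factors.tsv"))
  })

  step("hvg", file.path(filt_dir, "matrix.mtx"), function() {
    nm <- normalize_counts(read_qc(run))
    write_tsv(select_hvg(nm, cfg$hvg_n), file.path(run, "hvg.tsv"))
  }, params = list(n = cfg$hvg_n))

  ref_dir <- file.path(run, "reference")
  step("reference", file.path(filt_dir, "matrix.mtx"), function() {
    m <- read_qc(run)
    gm <- utils::read.delim(file.path(run, "group_map.tsv"))
    pure <- subset(m, cell_mask = m$cell_meta$true_label != "mosaic")
    ref <- build_reference(pure, group_map = stats::setNames(gm$group, gm$cell_type))
    write_reference(ref, ref_dir)
  })

  step("egic", c(file.path(filt_dir, "matrix.mtx"),
                 file.path(ref_dir, "theta.tsv")), function() {
    m <- read_qc(run)
    ref <- read_reference(ref_dir)
    sc <- egic_scores(m, ref, tol = cfg$egic_tol, max_iter = cfg$egic_max_iter)
    write_tsv(sc, file.path(run, "egic.tsv"))
  }, params = list(tol = cfg$egic_tol, max_iter = cfg$egic_max_iter))

  step("annotate", file.path(filt_dir, "matrix.mtx"), function() {
    m <- read_qc(run)
    nm <- normalize_counts(m)
    pure <- m$cell_meta$true_label != "mosaic"
    nm_pure <- normalize_counts(subset(m, cell_mask = pure))
    model <- train_classifier(nm_pure, m = cfg$markers_per_type,
                              score_quantile = cfg$score_quantile,
                              finetune_delta = cfg$finetune_delta)
    write_tsv(classify_cells(nm, model), file.path(run, "annotations.tsv"))
  }, params = list(m = cfg$markers_per_type))

  step("de", file.path(filt_dir, "matrix.mtx"), function() {
    m <- read_qc(run)
    pure <- subset(m, cell_mask = m$cell_meta$true_label != "mosaic")
    pb <- aggregate_pseudobulk(pure, keys = c("true_label", "subject_id"),
                               min_cells = cfg$de_min_cells)
    pb <- tmm_norm_factors(pb)
    mk <- marker_genes_per_type(pb, lfc = cfg$de_lfc)
    for (ct in names(mk$combined))
      write_tsv(mk$combined[[ct]],
                file.path(run, sprintf("markers_%s.tsv", ct)))
  }, params = list(lfc = cfg$de_lfc, min_cells = cfg$de_min_cells))

  step("report", file.path(run, "egic.tsv"), function()
    build_report(run, cfg), params = list())

  invisible(run)
}

merge_cell_meta <- function(a, b) {
  for (col in setdiff(names(b), names(a))) a[[col]] <- NA
  for (col in setdiff(names(a), names(b))) b[[col]] <- NA
  rbind(a, b[names(a)])
}

read_qc <- function(run) {
  read_counts(file.path(run, "counts_qc", "matrix.mtx"),
              file.path(run, "counts_qc", "genes.tsv"),
              file.path(run, "counts_qc", "cells.tsv"))
}

#' Per-tissue cell-type composition summary
#'
#' @param labels Per-cell labels.
#' @param tissue Per-cell tissue assignment (same order).
#' @return A data.frame (`tissue`, `label`, `n`, `proportion`);
#'   proportions sum to 1 within each tissue. Empty tissues are omitted
#'   with a warning.
#' @export
composition_summary <- function(labels, tissue) {
  if (length(labels) != length(tissue))
    stop("labels and tissue cover different numbers of cells")
  keep <- !is.na(tissue)
  if (any(!keep)) warning("cells with missing tissue omitted")
  tb <- table(tissue[keep], labels[keep])
  out <- as.data.frame(tb, stringsAsFactors = FALSE)
  names(out) <- c("tissue", "label", "n")
  out <- out[out$n > 0 | TRUE, ]
  tot <- tapply(out$n, out$tissue, sum)
  empty <- names(tot)[tot == 0]
  if (length(empty)) {
    warning("empty tissue(s) omitted: ", paste(empty, collapse = ", "))
    out <- out[!out$tissue %in% empty, ]
    tot <- tot[!names(tot) %in% empty]
  }
  out$proportion <- out$n / as.numeric(tot[out$tissue])
  out[order(out$tissue, out$label), c("tissue", "label", "n", "proportion")]
}

#' Build report tables and figures for a completed run
#'
#' Writes (when the corresponding stage outputs exist, otherwise the
#' section is skipped with a notice): per-tissue composition bars,
#' EGIC group-score distributions by condition, the two-marker
#' co-expression scatter, and the alpha-recovery diagnostic (estimated
#' vs true mixture weight, with its Pearson correlation).
#'
#' @param run Run directory of [run_pipeline()].
#' @param cfg The [pipeline_config()] used (for the co-expression gene
#'   pair).
#' @return Character vector of written report files, invisibly.
#' @export
build_report <- function(run, cfg = NULL) {
  rep_dir <- file.path(run, "report")
  dir.create(rep_dir, showWarnings = FALSE)
  written <- character(0)
  notice <- function(msg) message("report: ", msg)

  ann_path <- file.path(run, "annotations.tsv")
  cells_path <- file.path(run, "counts_qc", "cells.tsv")
  if (file.exists(ann_path) && file.exists(cells_path)) {
    ann <- utils::read.delim(ann_path)
    cells <- utils::read.delim(cells_path)
    comp <- composition_summary(ann$label, cells$tissue[match(ann$cell_id, cells$cell_id)])
    write_tsv(comp, file.path(rep_dir, "composition.tsv"))
    grDevices::png(file.path(rep_dir, "composition.png"), 900, 600)
    graphics::barplot(t(stats::xtabs(proportion ~ tissue + label, comp)),
                      legend.text = TRUE, las = 2,
                      main = "Cell-type composition per tissue",
                      ylab = "proportion")
    grDevices::dev.off()
    written <- c(written, file.path(rep_dir, c("composition.tsv", "composition.png")))
  } else notice("composition section skipped (missing annotations)")

  egic_path <- file.path(run, "egic.tsv")
  if (file.exists(egic_path) && file.exists(cells_path)) {
    eg <- utils::read.delim(egic_path, check.names = FALSE)
    cells <- utils::read.delim(cells_path)
    cond <- cells$condition[match(eg$cell_id, cells$cell_id)]
    gcols <- grep("^group_", names(eg), value = TRUE)
    grDevices::png(file.path(rep_dir, "group_scores.png"), 1200, 500)
    graphics::par(mfrow = c(1, length(gcols)))
    for (g in gcols)
      graphics::boxplot(eg[[g]] ~ cond, main = sub("group_", "", g),
                        xlab = "", ylab = "phenotype contribution", las = 2)
    grDevices::dev.off()
    written <- c(written, file.path(rep_dir, "group_scores.png"))

    truth_path <- file.path(run, "truth_cells.tsv")
    if (file.exists(truth_path)) {
      tr <- utils::read.delim(truth_path)
      tr <- tr[!is.na(tr$alpha), ]
      if (nrow(tr) > 1 && "group_Intestinal" %in% names(eg)) {
        idx <- match(tr$cell_id, eg$cell_id)
        est <- eg$group_Intestinal[idx]
        # orient alpha toward the intestinal component of each pair
        int_types <- c("enterocyte", "goblet", "intestinal_stem")
        a_true <- ifelse(tr$type_a %in% int_types, tr$alpha, 1 - tr$alpha)
        r <- stats::cor(a_true, est, use = "complete.obs")
        rec <- data.frame(cell_id = tr$cell_id, alpha_true = a_true,
                          alpha_est = est)
        write_tsv(rec, file.path(rep_dir, "alpha_recovery.tsv"))
        write_tsv(data.frame(statistic = c("pearson_r", "mean_abs_error"),
                             value = c(r, mean(abs(est - a_true), na.rm = TRUE))),
                  file.path(rep_dir, "alpha_recovery_stats.tsv"))
        grDevices::png(file.path(rep_dir, "alpha_recovery.png"), 600, 600)
        graphics::plot(a_true, est, xlab = "true alpha (intestinal fraction)",
                       ylab = "estimated intestinal contribution",
                       main = sprintf("alpha recovery (r = %.3f)", r))
        graphics::abline(0, 1, lty = 2)
        grDevices::dev.off()
        written <- c(written, file.path(rep_dir, c("alpha_recovery.tsv",
                                                   "alpha_recovery_stats.tsv",
                                                   "alpha_recovery.png")))
      } else notice("alpha-recovery section skipped (no mosaic cells)")
    } else notice("alpha-recovery section skipped (no truth table)")
  } else notice("EGIC sections skipped (missing egic.tsv)")

  if (file.exists(cells_path)) {
    m <- read_qc(run)
    nm <- normalize_counts(m)
    pair <- if (!is.null(cfg) && !is.null(cfg$coexpr_genes)) cfg$coexpr_genes
    else {
      mk_path <- file.path(run, "truth_markers.tsv")
      if (file.exists(mk_path)) {
        mk <- utils::read.delim(mk_path)
        g1 <- mk$gene_id[mk$marker_of == "foveolar"][1]
        g2 <- mk$gene_id[mk$marker_of == "enterocyte"][1]
        if (!is.na(g1) && !is.na(g2)) c(g1, g2) else NULL
      } else NULL
    }
    if (!is.null(pair)) {
      cx <- coexpression_fraction(nm, pair[1], pair[2])
      write_tsv(cx$table, file.path(rep_dir, "coexpression.tsv"))
      grDevices::png(file.path(rep_dir, "coexpression.png"), 600, 600)
      graphics::plot(cx$table$gene_a, cx$table$gene_b,
                     xlab = paste("log2 expr", pair[1]),
                     ylab = paste("log2 expr", pair[2]),
                     main = sprintf("co-expression (fraction both > 0: %.3f)",
                                    cx$fraction))
      grDevices::dev.off()
      written <- c(written, file.path(rep_dir, c("coexpression.tsv", "coexpression.png")))
    } else notice("co-expression section skipped (no gene pair available)")
  }
  invisible(written)
}
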
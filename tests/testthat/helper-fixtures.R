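# Shared fixtures. Simulations are cached per helper so repeated use
# across test files does not redo the sampling.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# two-tissue, four-type cohort used by most recovery tests
small_cfg <- function(seed = 7) {
  sim_config(n_genes = 400,
             tissues = list(Gastric = c("foveolar", "chief"),
                            Intestinal = c("enterocyte", "goblet")),
             n_subjects = 2, cells_per_type_per_subject = 20,
             markers_per_type = 10, seed = seed)
}

small_sim <- function() cached("small_sim", simulate_reference(small_cfg()))

# tiny hand-built CountMatrix
toy_counts <- function(mat, mito = NULL) {
  ng <- nrow(mat); nc <- ncol(mat)
  gm <- data.frame(gene_id = sprintf("g%d", seq_len(ng)),
                   symbol = sprintf("S%d", seq_len(ng)))
  if (!is.null(mito)) gm$is_mito <- seq_len(ng) %in% mito
  CountMatrix(mat, gm,
              data.frame(cell_id = sprintf("c%d", seq_len(nc)),
                         sample_id = "s1", subject_id = "p1",
                         tissue = "t", condition = "x"))
}

# reference model with explicit signatures (V defaults to zero)
manual_ref <- function(theta, V = NULL, groups = NULL) {
  if (is.null(V)) V <- theta * 0
  if (is.null(groups))
    groups <- stats::setNames(colnames(theta), colnames(theta))
  structure(list(theta = theta, V = V,
                 S = stats::setNames(rep(1, ncol(theta)), colnames(theta)),
                 cell_types = colnames(theta), group_map = groups,
                 informative_genes = rownames(theta), excluded = NULL),
            class = "ReferenceModel")
}

# fresh cells drawn from the same truth profiles as a reference sim
holdout_pure <- function(cfg, truth, types, n_per_type, seed_base = 1000) {
  parts <- lapply(seq_along(types), function(i)
    simulate_mosaic(cfg, truth, c(types[i], types[i]), n_per_type,
                    alpha_dist = 1, seed = cfg$seed + seed_base + i))
  counts <- do.call(cbind, lapply(parts, function(p) p$counts$counts))
  meta <- do.call(rbind, lapply(seq_along(parts), function(i) {
    cm <- parts[[i]]$counts$cell_meta
    cm$cell_id <- paste0(types[i], "_", cm$cell_id)
    cm$true_label <- types[i]
    cm
  }))
  CountMatrix(as.matrix(counts), parts[[1]]$counts$gene_meta, meta)
}
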
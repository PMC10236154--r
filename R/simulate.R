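#' Configuration for the synthetic single-cell count generator
#'
#' The generator emulates a multi-tissue, multi-subject epithelial atlas:
#' each cell type has a heavy-tailed baseline expression profile with a
#' block of up-regulated marker genes, subjects perturb every gene
#' log-normally, per-cell library sizes are log-normal, and counts are
#' negative binomial with a shared dispersion. A configurable share of
#' baseline expression mass sits on mitochondrial genes so that QC on the
#' mitochondrial UMI percentage is exercised.
#'
#' @param n_genes Number of genes.
#' @param tissues Named list: tissue group -> character vector of cell
#'   type names. The default spans the five gastrointestinal phenotype
#'   groups (Squamous, SMG, Gastric, Intestinal, Colon).
#' @param n_subjects Subjects (donors) per tissue.
#' @param cells_per_type_per_subject Cells simulated per type per subject.
#' @param markers_per_type Marker genes planted per cell type.
#' @param marker_log2_fc Log2 fold-change of a marker in its own type.
#' @param subject_sd Log-scale SD of per-subject, per-gene effects.
#' @param libsize_log_mean,libsize_log_sd Log-normal library size
#'   parameters (defaults give a median depth of about 5000 UMIs).
#' @param nb_dispersion Negative-binomial dispersion phi (variance
#'   mu + phi mu^2); `0` gives Poisson counts.
#' @param mito_fraction Share of baseline expression mass on
#'   mitochondrial genes.
#' @param n_mito_genes Number of genes given `MT-` symbols.
#' @param n_qc_outliers Cells (per call to [simulate_reference()]) whose
#'   mitochondrial share is planted outside the default QC bounds
#'   (half above 25\%, half below 0.5\%); recorded in the truth table.
#' @param seed Integer seed; the generator is a pure function of the
#'   configuration including the seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       tissues = list(
                         Squamous   = c("squamous_basal", "squamous_differentiated"),
                         SMG        = c("smg_duct", "smg_mucous"),
                         Gastric    = c("foveolar", "gastric_neck", "chief"),
                         Intestinal = c("enterocyte", "goblet", "intestinal_stem"),
                         Colon      = c("colonocyte", "colon_goblet")),
                       n_subjects = 3,
                       cells_per_type_per_subject = 30,
                       markers_per_type = 20,
                       marker_log2_fc = 3,
                       subject_sd = 0.2,
                       libsize_log_mean = log(5000),
                       libsize_log_sd = 0.3,
                       nb_dispersion = 0.3,
                       mito_fraction = 0.05,
                       n_mito_genes = 13,
                       n_qc_outliers = 0,
                       seed = 1L) {
  cfg <- list(n_genes = n_genes, tissues = tissues, n_subjects = n_subjects,
              cells_per_type_per_subject = cells_per_type_per_subject,
              markers_per_type = markers_per_type,
              marker_log2_fc = marker_log2_fc, subject_sd = subject_sd,
              libsize_log_mean = libsize_log_mean,
              libsize_log_sd = libsize_log_sd,
              nb_dispersion = nb_dispersion, mito_fraction = mito_fraction,
              n_mito_genes = n_mito_genes, n_qc_outliers = n_qc_outliers,
              seed = as.integer(seed))
  all_types <- unlist(tissues, use.names = FALSE)
  if (anyDuplicated(all_types)) stop("cell type names must be unique across tissues")
  if (n_genes < 10 || n_subjects < 1 || cells_per_type_per_subject < 1)
    stop("n_genes, n_subjects and cells_per_type_per_subject must be positive")
  if (markers_per_type * length(all_types) > n_genes - n_mito_genes)
    stop("infeasible marker allocation: markers_per_type x n_types exceeds available genes")
  if (mito_fraction < 0 || mito_fraction >= 1)
    stop("mito_fraction must be in [0, 1)")
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

# counts ~ NB(mu, phi); phi = 0 is the Poisson limit
rcounts <- function(n, mu, phi) {
  if (phi <= 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / phi)
}

sim_gene_meta <- function(cfg) {
  n_mito <- cfg$n_mito_genes
  symbol <- c(sprintf("MT-SIM%d", seq_len(n_mito)),
              sprintf("GENE%05d", seq_len(cfg$n_genes - n_mito)))
  data.frame(gene_id = sprintf("G%05d", seq_len(cfg$n_genes)),
             symbol = symbol, is_mito = seq_len(cfg$n_genes) <= n_mito,
             stringsAsFactors = FALSE)
}

# Baseline relative expression: LogNormal(0, 1) draws, mitochondrial genes
# rescaled to hold mito_fraction of the total mass, then normalized to sum 1.
sim_baseline <- function(cfg) {
  base <- stats::rlnorm(cfg$n_genes, 0, 1)
  mito <- seq_len(cfg$n_genes) <= cfg$n_mito_genes
  if (cfg$n_mito_genes > 0 && cfg$mito_fraction > 0) {
    base[mito] <- base[mito] / sum(base[mito]) *
      cfg$mito_fraction / (1 - cfg$mito_fraction) * sum(base[!mito])
  } else base[mito] <- 0
  base / sum(base)
}

sample_cells <- function(lambda, n_cells, cfg) {
  p <- lambda / sum(lambda)
  L <- stats::rlnorm(n_cells, cfg$libsize_log_mean, cfg$libsize_log_sd)
  counts <- matrix(0L, nrow = length(p), ncol = n_cells)
  for (i in seq_len(n_cells))
    counts[, i] <- rcounts(length(p), L[i] * p, cfg$nb_dispersion)
  list(counts = counts, libsize = L)
}

#' Simulate a multi-subject, multi-tissue reference atlas
#'
#' For every tissue, subject and cell type, gene means are
#' `baseline * 2^(marker_log2_fc * is_marker) * subject_effect`, with
#' subject effects drawn LogNormal(0, `subject_sd`) per gene and subject;
#' cells draw a log-normal library size and negative-binomial counts.
#'
#' @param cfg A [sim_config()].
#' @return A list with `counts` (a [CountMatrix] whose `cell_meta`
#'   carries `true_label`) and `truth`, a list holding the marker table,
#'   baseline means, per-subject normalized type profiles, drawn library
#'   sizes, the cell-type to tissue-group map, and ids of planted QC
#'   outlier cells.
#' @export
simulate_reference <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  gene_meta <- sim_gene_meta(cfg)
  baseline <- sim_baseline(cfg)
  types <- unlist(cfg$tissues, use.names = FALSE)
  group_map <- stats::setNames(
    rep(names(cfg$tissues), lengths(cfg$tissues)), types)

  non_mito <- which(!gene_meta$is_mito)
  marker_idx <- matrix(sample(non_mito, cfg$markers_per_type * length(types)),
                       ncol = length(types))
  colnames(marker_idx) <- types
  markers <- data.frame(gene_id = gene_meta$gene_id[as.vector(marker_idx)],
                        marker_of = rep(types, each = cfg$markers_per_type),
                        stringsAsFactors = FALSE)

  blocks <- list(); meta <- list(); libs <- list()
  profiles <- list()  # normalized mean profile per subject x type
  for (tis in names(cfg$tissues)) {
    for (s in seq_len(cfg$n_subjects)) {
      subject <- sprintf("%s_subj%d", tis, s)
      eff <- stats::rlnorm(cfg$n_genes, 0, cfg$subject_sd)
      for (ct in cfg$tissues[[tis]]) {
        lam <- baseline * eff
        lam[marker_idx[, ct]] <- lam[marker_idx[, ct]] * 2^cfg$marker_log2_fc
        lam <- lam / sum(lam)
        profiles[[paste(subject, ct, sep = "|")]] <- lam
        sm <- sample_cells(lam, cfg$cells_per_type_per_subject, cfg)
        blocks[[length(blocks) + 1L]] <- sm$counts
        libs[[length(libs) + 1L]] <- sm$libsize
        meta[[length(meta) + 1L]] <- data.frame(
          tissue = tis, subject_id = subject, sample_id = subject,
          condition = "reference", true_label = ct,
          n = cfg$cells_per_type_per_subject, stringsAsFactors = FALSE)
      }
    }
  }
  counts <- do.call(cbind, blocks)
  meta <- do.call(rbind, meta)
  cell_meta <- meta[rep(seq_len(nrow(meta)), meta$n), ]
  cell_meta$n <- NULL
  cell_meta <- data.frame(cell_id = sprintf("cell%05d", seq_len(ncol(counts))),
                          cell_meta, stringsAsFactors = FALSE)
  libsize <- unlist(libs, use.names = FALSE)

  qc_outliers <- character(0)
  if (cfg$n_qc_outliers > 0) {
    out <- sample(ncol(counts), cfg$n_qc_outliers)
    hi <- out[seq_len(ceiling(length(out) / 2))]
    lo <- setdiff(out, hi)
    target <- stats::setNames(
      c(stats::runif(length(hi), 0.30, 0.60), stats::runif(length(lo), 0, 0.003)),
      c(hi, lo))
    mito <- gene_meta$is_mito
    w_mito <- baseline[mito] / sum(baseline[mito])
    for (j in out) {
      # replace the mitochondrial block so the realized share hits the target
      f <- target[[as.character(j)]]
      nm <- sum(counts[!mito, j])
      need <- round(f / (1 - f) * nm)
      counts[mito, j] <- as.integer(round(need * w_mito))
      qc_outliers <- c(qc_outliers, cell_meta$cell_id[j])
    }
  }

  cm <- CountMatrix(counts, gene_meta, cell_meta)
  truth <- list(markers = markers, baseline = baseline, profiles = profiles,
                libsize = libsize, group_map = group_map,
                qc_outliers = qc_outliers, cfg = cfg)
  list(counts = cm, truth = truth)
}

draw_alpha <- function(n, alpha_dist) {
  if (is.numeric(alpha_dist)) return(rep_len(alpha_dist, n))
  switch(alpha_dist$dist,
         uniform = stats::runif(n),
         beta = stats::rbeta(n, alpha_dist$shape1, alpha_dist$shape2),
         fixed = rep_len(alpha_dist$value, n),
         stop("unknown alpha distribution: ", alpha_dist$dist))
}

#' Simulate mosaic cells mixing two cell-type profiles
#'
#' Each mosaic cell draws a mixture weight `alpha` and has expected
#' relative expression `alpha * lambda_A + (1 - alpha) * lambda_B`, where
#' `lambda_A`, `lambda_B` are the subject-level normalized profiles from
#' [simulate_reference()]. Mixing acts on normalized profiles, so `alpha`
#' is an RNA fraction — the quantity per-cell deconvolution estimates.
#'
#' @param cfg The [sim_config()] used for the reference.
#' @param ref_truth `truth` component returned by [simulate_reference()].
#' @param pairs List of `c(type_A, type_B)` character pairs; cells cycle
#'   through them.
#' @param n_cells Number of mosaic cells.
#' @param alpha_dist Either a number (fixed alpha), or a list such as
#'   `list(dist = "uniform")`, `list(dist = "beta", shape1=, shape2=)`,
#'   `list(dist = "fixed", value=)`.
#' @param seed Seed for this draw (default `cfg$seed + 1`).
#' @return A list with `counts` (a [CountMatrix]; `cell_meta` carries
#'   `mix_type_a`, `mix_type_b`, `mix_alpha`) and a `truth` data.frame.
#' @export
simulate_mosaic <- function(cfg, ref_truth, pairs, n_cells,
                            alpha_dist = list(dist = "uniform"),
                            seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.character(pairs)) pairs <- list(pairs)
  types <- unlist(cfg$tissues, use.names = FALSE)
  for (p in pairs)
    if (!all(p %in% types))
      stop("unknown cell type in mosaic pair: ", paste(p, collapse = "/"))
  set.seed(seed)
  gene_meta <- sim_gene_meta(cfg)
  alpha <- draw_alpha(n_cells, alpha_dist)
  pair_idx <- rep_len(seq_along(pairs), n_cells)
  subj_names <- names(ref_truth$profiles)
  counts <- matrix(0L, cfg$n_genes, n_cells)
  meta <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    pa <- pairs[[pair_idx[i]]]
    tis_a <- names(which(vapply(cfg$tissues, function(v) pa[1] %in% v, TRUE)))
    tis_b <- names(which(vapply(cfg$tissues, function(v) pa[2] %in% v, TRUE)))
    s <- sample.int(cfg$n_subjects, 1)
    lam_a <- ref_truth$profiles[[sprintf("%s_subj%d|%s", tis_a, s, pa[1])]]
    lam_b <- ref_truth$profiles[[sprintf("%s_subj%d|%s", tis_b, s, pa[2])]]
    lam <- alpha[i] * lam_a + (1 - alpha[i]) * lam_b
    sm <- sample_cells(lam, 1L, cfg)
    counts[, i] <- sm$counts[, 1]
    meta[[i]] <- data.frame(
      cell_id = sprintf("mosaic%05d", i), sample_id = sprintf("mosaic_subj%d", s),
      subject_id = sprintf("mosaic_subj%d", s), tissue = "mosaic",
      condition = "mosaic", true_label = "mosaic",
      mix_type_a = pa[1], mix_type_b = pa[2], mix_alpha = alpha[i],
      stringsAsFactors = FALSE)
  }
  cell_meta <- do.call(rbind, meta)
  cm <- CountMatrix(counts, gene_meta, cell_meta)
  list(counts = cm,
       truth = cell_meta[, c("cell_id", "mix_type_a", "mix_type_b", "mix_alpha")])
}

#' Simulate a two-condition pseudo-bulk cohort with planted DE genes
#'
#' A single cell population measured in `n_patients` patients under two
#' conditions (paired design: each patient contributes cells to both).
#' `n_true_de` genes are shifted by `de_log2_fc` in condition 2; patient
#' effects act as log-normal subject effects shared across conditions.
#'
#' @param cfg A [sim_config()] (its tissue list is ignored; one
#'   population is simulated).
#' @param n_true_de Number of genes with a true condition effect.
#' @param de_log2_fc Log2 fold-change planted in condition 2.
#' @param n_patients Patients, each observed under both conditions.
#' @return A list with `counts` (a [CountMatrix] with `condition` and
#'   `subject_id` metadata) and `truth` (character vector of DE gene ids).
#' @export
simulate_de_cohort <- function(cfg, n_true_de, de_log2_fc, n_patients = 4) {
  stopifnot(inherits(cfg, "sim_config"))
  if (n_true_de > cfg$n_genes) stop("n_true_de exceeds n_genes")
  set.seed(cfg$seed)
  gene_meta <- sim_gene_meta(cfg)
  baseline <- sim_baseline(cfg)
  de_idx <- if (n_true_de > 0)
    sample(which(!gene_meta$is_mito), n_true_de) else integer(0)
  blocks <- list(); meta <- list()
  for (p in seq_len(n_patients)) {
    eff <- stats::rlnorm(cfg$n_genes, 0, cfg$subject_sd)
    for (cond in 1:2) {
      lam <- baseline * eff
      if (cond == 2 && length(de_idx)) lam[de_idx] <- lam[de_idx] * 2^de_log2_fc
      sm <- sample_cells(lam / sum(lam), cfg$cells_per_type_per_subject, cfg)
      blocks[[length(blocks) + 1L]] <- sm$counts
      meta[[length(meta) + 1L]] <- data.frame(
        subject_id = sprintf("patient%d", p),
        sample_id = sprintf("patient%d_cond%d", p, cond),
        tissue = "cohort", condition = sprintf("cond%d", cond),
        true_label = "epithelial", n = cfg$cells_per_type_per_subject,
        stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, blocks)
  meta <- do.call(rbind, meta)
  cell_meta <- meta[rep(seq_len(nrow(meta)), meta$n), ]
  cell_meta$n <- NULL
  cell_meta <- data.frame(cell_id = sprintf("cell%05d", seq_len(ncol(counts))),
                          cell_meta, stringsAsFactors = FALSE)
  cm <- CountMatrix(counts, gene_meta, cell_meta)
  list(counts = cm, truth = gene_meta$gene_id[de_idx])
}
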
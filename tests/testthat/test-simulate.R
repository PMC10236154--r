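test_that("generator is a pure function of its configuration", {
  cfg <- small_cfg(seed = 3)
  a <- simulate_reference(cfg)
  b <- simulate_reference(cfg)
  expect_true(all(a$counts$counts == b$counts$counts))
  expect_equal(a$truth$markers, b$truth$markers)
  m1 <- simulate_mosaic(cfg, a$truth, c("enterocyte", "foveolar"), 10)
  m2 <- simulate_mosaic(cfg, b$truth, c("enterocyte", "foveolar"), 10)
  expect_true(all(m1$counts$counts == m2$counts$counts))
})

test_that("Poisson-limit cell means match the analytic profile", {
  cfg <- sim_config(n_genes = 30, tissues = list(T = "t1"), n_subjects = 1,
                    cells_per_type_per_subject = 10000, markers_per_type = 3,
                    nb_dispersion = 0, subject_sd = 0, mito_fraction = 0.05,
                    seed = 21)
  sim <- simulate_reference(cfg)
  lam <- sim$truth$profiles[[1]]
  Lbar <- mean(sim$truth$libsize)
  mu_hat <- Matrix::rowMeans(sim$counts$counts)
  se <- apply(as.matrix(sim$counts$counts), 1, stats::sd) / sqrt(10000)
  expect_true(all(abs(mu_hat - Lbar * lam) <= 3 * se + 1e-9))
})

test_that("marker genes carry the configured fold-change", {
  cfg <- sim_config(n_genes = 500, tissues = list(T = c("t1", "t2")),
                    n_subjects = 1, cells_per_type_per_subject = 1500,
                    markers_per_type = 5, marker_log2_fc = 3,
                    subject_sd = 0, nb_dispersion = 0.05, seed = 33)
  sim <- simulate_reference(cfg)
  mk <- sim$truth$markers
  g1 <- match(mk$gene_id[mk$marker_of == "t1"], sim$counts$gene_meta$gene_id)
  cells1 <- sim$counts$cell_meta$true_label == "t1"
  cells2 <- !cells1
  # compare library-normalized means so depth variation cancels
  norm <- sweep(as.matrix(sim$counts$counts), 2,
                Matrix::colSums(sim$counts$counts), "/")
  ratio <- rowMeans(norm[g1, cells1]) / rowMeans(norm[g1, cells2])
  expect_true(all(abs(log2(ratio) - cfg$marker_log2_fc) < 0.3))
})

test_that("per-cell totals track the drawn library sizes", {
  sim <- small_sim()
  rho <- stats::cor(Matrix::colSums(sim$counts$counts), sim$truth$libsize,
                    method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("alpha = 1 mosaics are distributionally pure type A", {
  cfg <- small_cfg()
  sim <- small_sim()
  mos <- simulate_mosaic(cfg, sim$truth, c("enterocyte", "foveolar"), 200,
                         alpha_dist = 1, seed = 99)
  pure <- holdout_pure(cfg, sim$truth, "enterocyte", 200, seed_base = 500)
  pm <- function(m) Matrix::rowMeans(sweep(as.matrix(m$counts), 2,
                                           Matrix::colSums(m$counts), "/"))
  expect_gt(stats::cor(pm(mos$counts), pm(pure)), 0.98)
  expect_true(all(mos$truth$mix_alpha == 1))
})

test_that("noiseless alpha = 0.5 mosaics sit at the profile midpoint", {
  cfg <- sim_config(n_genes = 200, tissues = list(G = "a", I = "b"),
                    n_subjects = 1, cells_per_type_per_subject = 5,
                    markers_per_type = 10, nb_dispersion = 0, subject_sd = 0,
                    libsize_log_mean = log(2e6), libsize_log_sd = 0, seed = 4)
  sim <- simulate_reference(cfg)
  mos <- simulate_mosaic(cfg, sim$truth, c("a", "b"), 5, alpha_dist = 0.5)
  lam_mid <- 0.5 * sim$truth$profiles[["G_subj1|a"]] +
    0.5 * sim$truth$profiles[["I_subj1|b"]]
  prof <- Matrix::rowMeans(sweep(as.matrix(mos$counts$counts), 2,
                                 Matrix::colSums(mos$counts$counts), "/"))
  expect_lt(max(abs(prof - lam_mid)), 1e-3)
})

test_that("uniform alpha draws average near 0.5", {
  cfg <- small_cfg()
  sim <- small_sim()
  mos <- simulate_mosaic(cfg, sim$truth, c("enterocyte", "foveolar"), 500,
                         alpha_dist = list(dist = "uniform"), seed = 11)
  se <- sqrt(1 / 12) / sqrt(500)
  expect_lt(abs(mean(mos$truth$mix_alpha) - 0.5), 3 * se)
  expect_true(all(mos$truth$mix_alpha >= 0 & mos$truth$mix_alpha <= 1))
})

test_that("mosaic simulation validates type names", {
  sim <- small_sim()
  expect_error(simulate_mosaic(small_cfg(), sim$truth, c("enterocyte", "nope"), 5),
               "unknown cell type")
})

test_that("DE cohort truth bookkeeping and degenerate cases", {
  cfg <- sim_config(n_genes = 300, cells_per_type_per_subject = 10, seed = 6)
  alt <- simulate_de_cohort(cfg, n_true_de = 40, de_log2_fc = 2, n_patients = 3)
  expect_length(alt$truth, 40)
  expect_true(all(alt$truth %in% alt$counts$gene_meta$gene_id))
  expect_setequal(unique(alt$counts$cell_meta$condition), c("cond1", "cond2"))
  null <- simulate_de_cohort(cfg, n_true_de = 0, de_log2_fc = 2, n_patients = 3)
  expect_length(null$truth, 0)
  # zero fold-change planted genes leave the two conditions exchangeable
  flat <- simulate_de_cohort(cfg, n_true_de = 40, de_log2_fc = 0, n_patients = 3)
  g <- match(flat$truth, flat$counts$gene_meta$gene_id)
  c1 <- flat$counts$cell_meta$condition == "cond1"
  m1 <- Matrix::rowSums(flat$counts$counts[g, c1]) / sum(flat$counts$counts[, c1])
  m2 <- Matrix::rowSums(flat$counts$counts[g, !c1]) / sum(flat$counts$counts[, !c1])
  expect_lt(median(abs(log2(m1 / m2))), 0.2)
  expect_error(simulate_de_cohort(cfg, n_true_de = 301, de_log2_fc = 1), "exceeds")
})

test_that("infeasible marker allocation is rejected at configuration", {
  expect_error(sim_config(n_genes = 50, markers_per_type = 20), "infeasible")
})

test_that("planted QC outliers have mitochondrial shares outside bounds", {
  cfg <- small_cfg(seed = 17)
  cfg$n_qc_outliers <- 6
  sim <- simulate_reference(cfg)
  expect_length(sim$truth$qc_outliers, 6)
  mito <- sim$counts$gene_meta$is_mito
  share <- Matrix::colSums(sim$counts$counts[mito, ]) /
    Matrix::colSums(sim$counts$counts)
  names(share) <- sim$counts$cell_meta$cell_id
  out <- share[sim$truth$qc_outliers]
  expect_true(all(out > 0.25 | out < 0.005))
  expect_true(all(share[setdiff(names(share), sim$truth$qc_outliers)] >= 0.005 &
                    share[setdiff(names(share), sim$truth$qc_outliers)] <= 0.25))
})
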
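pb_from <- function(mat, cell_type, patient, condition = NULL, min_cells = 1) {
  nc <- ncol(mat)
  cm <- data.frame(cell_id = sprintf("c%d", seq_len(nc)), sample_id = "s",
                   subject_id = patient, tissue = "t",
                   condition = if (is.null(condition)) "x" else condition,
                   true_label = cell_type)
  gm <- data.frame(gene_id = sprintf("g%d", seq_len(nrow(mat))),
                   symbol = sprintf("g%d", seq_len(nrow(mat))))
  keys <- if (is.null(condition)) c("true_label", "subject_id") else
    c("true_label", "subject_id", "condition")
  aggregate_pseudobulk(CountMatrix(mat, gm, cm), keys = keys,
                       min_cells = min_cells)
}

test_that("pseudo-bulk aggregation is exact integer summation", {
  mat <- cbind(c(1, 2), c(3, 4))
  pb <- pb_from(mat, c("t1", "t1"), c("p1", "p1"))
  expect_equal(unname(pb$counts[, 1]), c(4L, 6L))
  expect_true(is.integer(pb$counts))
  # permuting cells leaves the table unchanged
  pb2 <- pb_from(mat[, 2:1], c("t1", "t1"), c("p1", "p1"))
  expect_equal(pb$counts, pb2$counts)
  # empty groups emit no column; small groups are flagged
  pb3 <- pb_from(cbind(c(5, 5), c(2, 0)), c("t1", "t2"), c("p1", "p1"),
                 min_cells = 10)
  expect_equal(ncol(pb3$counts), 2)
  expect_true(all(pb3$sample_meta$flagged))
  expect_error(aggregate_pseudobulk(toy_counts(mat), keys = "nope"),
               "not found")
})

test_that("TMM factors: symmetric, pure-depth and composition-shift cases", {
  set.seed(2)
  base <- matrix(rpois(400, 50) + 1L, ncol = 2)
  same <- pb_from(cbind(base[, 1], base[, 1]), c("t1", "t2"), "p1")
  expect_equal(unname(tmm_norm_factors(same)$norm_factors), c(1, 1),
               tolerance = 1e-9)
  depth <- pb_from(cbind(base[, 1], base[, 1] * 2L), c("t1", "t2"), "p1")
  expect_equal(unname(tmm_norm_factors(depth)$norm_factors), c(1, 1),
               tolerance = 1e-9)
  # half the genes 4x up in sample 2: the 30%/5% trimmed precision-weighted
  # mean M is negative (hand computation), so sample 2's factor is < 1
  shift <- base
  shift[1:100, 2] <- shift[1:100, 2] * 4L
  pbs <- pb_from(shift, c("t1", "t2"), "p1")
  f <- tmm_norm_factors(pbs)$norm_factors
  expect_lt(f[2], 1)
  expect_gt(f[1], 1)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-9)
})

test_that("dispersion estimates recover the simulated truth", {
  set.seed(3)
  ng <- 800; ns <- 8
  pois <- matrix(rpois(ng * ns, rep(exp(runif(ng, 2, 6)), ns)), ng)
  pbp <- pb_from(pois, rep("t1", ns), sprintf("p%d", seq_len(ns)))
  design <- matrix(1, ns, 1)
  expect_lte(median(estimate_dispersion(pbp, design)), 0.05)
  nb <- matrix(rnbinom(ng * ns, mu = rep(exp(runif(ng, 2, 6)), ns),
                       size = 1 / 0.4), ng)
  pbn <- pb_from(nb, rep("t1", ns), sprintf("p%d", seq_len(ns)))
  dn <- median(estimate_dispersion(pbn, design))
  expect_gte(dn, 0.2); expect_lte(dn, 0.6)
  # a constant gene is shrunk below the cohort's typical dispersion
  nb2 <- nb
  nb2[1, ] <- 150L
  pbc <- pb_from(nb2, rep("t1", ns), sprintf("p%d", seq_len(ns)))
  dd <- estimate_dispersion(pbc, design)
  expect_lt(dd[1], median(dd[-1]))
  expect_true(all(dd >= 1e-8))
  expect_error(estimate_dispersion(pbp, diag(ns)), "degrees of freedom")
})

test_that("threshold test: null genes, closed-form logFC, lfc = 0 equivalence", {
  set.seed(4)
  ng <- 300; ns <- 6
  mu <- exp(runif(ng, 3, 6))
  cnt <- matrix(rnbinom(ng * ns, mu = rep(mu, ns), size = 1 / 0.1), ng)
  grp <- rep(c("a", "b"), each = 3)
  pb <- pb_from(cnt, rep("t1", ns), sprintf("p%d", 1:ns), condition = grp)
  pb <- tmm_norm_factors(pb)
  design <- stats::model.matrix(~ grp)
  de <- de_test_treat(pb, design, coef = 2, lfc = 0.5)
  expect_true(all(de$p >= 0 & de$p <= 1))
  expect_gt(min(de$p), 0.001)          # nothing clears a 0.5 lfc threshold
  expect_lt(median(abs(de$logFC)), 0.3)

  # two-group design with equal offsets: the NB MLE of each group mean is
  # the arithmetic mean, so unshrunk logFC equals the log2 group-mean ratio
  cnt_eq <- cnt
  cnt_eq[1, ] <- cnt_eq[1, ] + max(colSums(cnt)) - colSums(cnt)  # equalize depth
  pbe <- pb_from(cnt_eq, rep("t1", ns), sprintf("p%d", 1:ns), condition = grp)
  dee <- de_test_treat(pbe, design, coef = 2, lfc = 0.5)
  g <- 5
  closed <- log2(mean(cnt_eq[g, 4:6]) / mean(cnt_eq[g, 1:3]))
  expect_equal(dee$unshrunk_logFC[g], closed, tolerance = 1e-4)

  de0 <- de_test_treat(pb, design, coef = 2, lfc = 0)
  ref <- local({
    d <- edgeR::DGEList(counts = pb$counts, norm.factors = pb$norm_factors)
    d <- edgeR::estimateDisp(d, design)
    fit <- edgeR::glmQLFit(d, design)
    edgeR::glmQLFTest(fit, coef = 2)$table$PValue
  })
  expect_equal(de0$p, ref, tolerance = 1e-9)
})

test_that("Simes combination follows its closed form and is permutation-invariant", {
  expect_equal(combine_simes(c(0.01, 0.04, 0.5)), 0.03)
  expect_equal(combine_simes(0.2), 0.2)
  expect_equal(combine_simes(c(1, 1, 1)), 1)
  expect_equal(combine_simes(c(0.5, 0.04, 0.01)), 0.03)
  expect_gte(combine_simes(c(0.2, 0.8)), min(0.2, 0.8))
  expect_equal(combine_simes(rep(0.07, 5)), 0.07)
  expect_error(combine_simes(numeric(0)), "empty")
  expect_error(combine_simes(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH adjustment matches an independent step-up implementation", {
  step_up <- function(p) {
    n <- length(p)
    o <- order(p, decreasing = TRUE)
    adj <- numeric(n)
    run <- 1
    for (i in seq_along(o)) {
      k <- n - i + 1
      run <- min(run, n * p[o[i]] / k)
      adj[o[i]] <- run
    }
    adj
  }
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.42), 0.42)
  set.seed(6)
  p <- runif(100)
  expect_equal(bh_fdr(p), step_up(p))
})

test_that("marker extraction finds planted markers and passes the null", {
  sim <- small_sim()
  pure <- sim$counts
  pb <- aggregate_pseudobulk(pure, keys = c("true_label", "subject_id"),
                             min_cells = 5)
  pb <- tmm_norm_factors(pb)
  mk <- marker_genes_per_type(pb, lfc = 0.5)
  expect_equal(length(mk$pairwise), choose(4, 2))
  # Simes over a single comparison returns the raw p unchanged
  two <- sim$counts
  keep <- two$cell_meta$true_label %in% c("foveolar", "enterocyte")
  pb2 <- tmm_norm_factors(aggregate_pseudobulk(
    subset(two, cell_mask = keep), keys = c("true_label", "subject_id"),
    min_cells = 5))
  mk2 <- marker_genes_per_type(pb2, lfc = 0.5)
  expect_equal(mk2$combined[["foveolar"]]$p_simes, mk2$pairwise[[1]]$p)
  # planted markers of each type are recovered at FDR 0.05
  planted <- sim$truth$markers
  sens <- sapply(unique(planted$marker_of), function(ct) {
    res <- mk$combined[[ct]]
    mean(planted$gene_id[planted$marker_of == ct] %in%
           res$gene_id[res$fdr < 0.05 & res$n_up == length(mk$pairwise) / 2])
  })
  expect_gte(mean(sens), 0.8)
})
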
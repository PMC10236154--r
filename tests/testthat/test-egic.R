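# unweighted residual objective on the simplex grid (step 0.01); with
# V = 0 the IRLS weights are constant so this is the solver's objective
# up to a positive scalar
grid_objective_min <- function(theta, x, step = 0.01) {
  g <- seq(0, 1, by = step)
  cand <- expand.grid(c1 = g, c2 = g)
  cand$c3 <- 1 - cand$c1 - cand$c2
  cand <- cand[cand$c3 >= -1e-12, ]
  P <- theta %*% t(as.matrix(cand))
  min(colSums((x - P)^2))
}

test_that("orthogonal signatures are read off directly", {
  ref <- manual_ref(matrix(c(1, 0, 0, 1), 2,
                           dimnames = list(c("g1", "g2"), c("A", "B"))),
                    groups = c(A = "Gastric", B = "Intestinal"))
  r <- deconvolve_cell(c(g1 = 60, g2 = 40), ref)
  expect_equal(unname(r$contributions), c(0.6, 0.4), tolerance = 1e-9)
  expect_equal(unname(r$group_scores), c(0.6, 0.4), tolerance = 1e-9)
  expect_true(r$converged)
})

test_that("interior least-squares solutions are found exactly", {
  theta <- matrix(c(0.5, 0.5, 0.9, 0.1), 2,
                  dimnames = list(c("g1", "g2"), c("A", "B")))
  r <- deconvolve_cell(c(g1 = 70, g2 = 30), manual_ref(theta))
  expect_equal(unname(r$contributions), c(0.5, 0.5), tolerance = 1e-9)
})

test_that("solver never loses to a dense simplex-grid search", {
  set.seed(20)
  worst <- 0
  for (i in 1:30) {
    theta <- apply(matrix(stats::rexp(60), 20, 3), 2, function(v) v / sum(v))
    dimnames(theta) <- list(sprintf("g%d", 1:20), c("A", "B", "C"))
    w_true <- stats::rexp(3); w_true <- w_true / sum(w_true)
    x <- as.numeric(theta %*% w_true) + abs(stats::rnorm(20, 0, 0.01))
    x <- x / sum(x)
    names(x) <- rownames(theta)
    r <- deconvolve_cell(x * 1e4, manual_ref(theta))
    obj <- sum((x - as.numeric(theta %*% r$coefficients))^2)
    worst <- max(worst, obj - grid_objective_min(theta, x))
  }
  expect_lte(worst, 1e-8)
})

test_that("contributions are invariant to input scale", {
  sim <- small_sim()
  ref <- build_reference(sim$counts, group_map = sim$truth$group_map)
  y <- as.numeric(sim$counts$counts[, 1])
  names(y) <- sim$counts$gene_meta$gene_id
  r1 <- deconvolve_cell(y, ref)
  r10 <- deconvolve_cell(10 * y, ref)
  expect_equal(r1$contributions, r10$contributions, tolerance = 1e-12)
})

test_that("zero-variance references reduce to plain NNLS", {
  sim <- small_sim()
  ref <- build_reference(sim$counts, group_map = sim$truth$group_map)
  ref0 <- ref
  ref0$V[] <- 0
  y <- as.numeric(sim$counts$counts[, 10])
  names(y) <- sim$counts$gene_meta$gene_id
  r <- deconvolve_cell(y, ref0)
  x <- y[ref0$informative_genes] / sum(y[ref0$informative_genes])
  nnls <- pracma::lsqnonneg(ref0$theta[ref0$informative_genes, ], x)$x
  expect_equal(unname(r$coefficients), nnls, tolerance = 1e-9)
})

test_that("undefined cells are flagged, not errors", {
  ref <- manual_ref(matrix(c(1, 0, 0, 1), 2,
                           dimnames = list(c("g1", "g2"), c("A", "B"))))
  r <- deconvolve_cell(c(g1 = 0, g2 = 0), ref)
  expect_false(r$defined)
  expect_true(is.na(r$mosaicism))
})

test_that("group scores partition the contributions", {
  sim <- small_sim()
  ref <- build_reference(sim$counts, group_map = sim$truth$group_map)
  sc <- egic_scores(subset(sim$counts, cell_mask = seq_len(ncol(sim$counts$counts)) <= 40),
                    ref)
  gcols <- paste0("group_", unique(sim$truth$group_map))
  expect_true(all(abs(rowSums(sc[, gcols]) - 1) < 1e-9))
  tcols <- unique(sim$counts$cell_meta$true_label)
  expect_true(all(abs(rowSums(sc[, tcols]) - 1) < 1e-9))
  expect_true(all(sc$mosaicism >= 0 & sc$mosaicism <= 1))
})

test_that("insufficient gene overlap with the reference is an error", {
  sim <- small_sim()
  ref <- build_reference(sim$counts, group_map = sim$truth$group_map)
  tiny <- subset(sim$counts,
                 gene_mask = seq_len(nrow(sim$counts$counts)) <= 20)
  expect_error(egic_scores(tiny, ref), "20 informative genes")
})

test_that("pure cells at signature means recover their group almost exactly", {
  sim <- small_sim()
  ref <- build_reference(sim$counts, group_map = sim$truth$group_map)
  for (ct in ref$cell_types) {
    y <- ref$theta[, ct] * 5000
    r <- deconvolve_cell(y, ref)
    expect_gte(r$group_scores[[ref$group_map[[ct]]]], 1 - 1e-6)
  }
})

test_that("intestinal score rises monotonically with the true mixture weight", {
  cfg <- small_cfg()
  sim <- small_sim()
  ref <- build_reference(sim$counts, group_map = sim$truth$group_map)
  mos <- simulate_mosaic(cfg, sim$truth, c("enterocyte", "foveolar"), 500,
                         seed = 123)
  sc <- egic_scores(mos$counts, ref)
  bins <- cut(mos$truth$mix_alpha, breaks = seq(0, 1, by = 0.2),
              include.lowest = TRUE)
  means <- tapply(sc$group_Intestinal, bins, mean)
  expect_true(all(diff(means) > 0))
})

test_that("mosaicism index follows its closed form", {
  expect_equal(mosaicism_index(c(Gastric = 0.5, Intestinal = 0.5)), 1)
  expect_equal(mosaicism_index(c(Gastric = 1, Intestinal = 0)), 0)
  expect_equal(mosaicism_index(c(Gastric = 0.3, Intestinal = 0.1)), 0.5)
  expect_equal(mosaicism_index(c(Gastric = 0, Intestinal = 0)), 0)
  expect_error(mosaicism_index(c(Gastric = 1), "Gastric", "Colon"), "unknown group")
})

test_that("co-expression fraction matches its definition and rises in mosaics", {
  # disjoint and complete co-expression
  m <- toy_counts(rbind(c(2, 0, 3), c(0, 4, 0)))
  nm <- normalize_counts(m)
  expect_equal(coexpression_fraction(nm, "S1", "S2")$fraction, 0)
  m2 <- toy_counts(rbind(c(2, 1, 3), c(5, 4, 1)))
  expect_equal(coexpression_fraction(normalize_counts(m2), "S1", "S2")$fraction, 1)
  expect_error(coexpression_fraction(nm, "S1", "NOPE"), "not found")

  cfg <- small_cfg()
  sim <- small_sim()
  mk <- sim$truth$markers
  ga <- mk$gene_id[mk$marker_of == "foveolar"][1]
  gi <- mk$gene_id[mk$marker_of == "enterocyte"][1]
  mos <- simulate_mosaic(cfg, sim$truth, c("enterocyte", "foveolar"), 150,
                         alpha_dist = 0.5, seed = 8)
  pure <- subset(sim$counts,
                 cell_mask = sim$counts$cell_meta$true_label %in%
                   c("enterocyte", "foveolar"))
  f_mos <- coexpression_fraction(normalize_counts(mos$counts), ga, gi)$fraction
  f_pure <- coexpression_fraction(normalize_counts(pure), ga, gi)$fraction
  expect_gt(f_mos, f_pure)
})
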
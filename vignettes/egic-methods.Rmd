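---
title: "Methods: per-cell phenotype deconvolution and its validation"
author: "egicmosaic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-cell phenotype deconvolution and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical methods it
implements, their assumptions, the tunable parameters, and what the
synthetic validation does and does not demonstrate.

## 1. The scientific setting

Intestinal metaplasia in the esophagus and stomach replaces native
epithelium with intestinal-type tissue. At single-cell resolution the
interesting question is not which discrete label a metaplastic cell gets,
but how much of each tissue program it expresses: a cell can carry
gastric mucin programs (MUC5AC, MUC6) and intestinal programs (GPA33,
OLFM4) at the same time. The package therefore treats each cell's
transcriptome as a mixture of reference phenotypes and estimates the
mixing proportions, alongside the conventional hard classifier and
pseudo-bulk differential expression used to build and check the
reference.

## 2. Reference signatures

`build_reference()` computes, per cell type $k$:

* $\theta_{gk}$ — each subject's pooled relative-expression profile
  (summed counts, normalized to sum 1), averaged across subjects;
* $V_{gk}$ — the cross-subject variance of those per-subject profiles;
* $S_k$ — the mean per-cell UMI total (cell size).

Subjects contributing fewer than `min_cells = 3` cells to a type are
excluded from that type's average (and recorded), because a pooled
profile from one or two cells is dominated by sampling noise. A type
observed in a single subject gets $V = 0$ with a warning — it
contributes no stability information, and pretending otherwise by
imputing a variance would be worse.

Informative genes are those expressed in at least one signature, ranked
by between-type variance of $\theta$ over mean cross-subject variance
plus $\varepsilon = 10^{-6}$. The default keeps all qualifying genes:
on synthetic data restricting to a top-$M$ subset changed recovery
little, and the full set avoids one more arbitrary cutoff. $M$ remains a
parameter for real atlases where memory or contamination argue for a
subset.

## 3. Per-cell deconvolution (EGIC score)

Each cell's counts are scaled to relative expression
$x_g = y_g/\sum_g y_g$ and fit against the signatures by weighted
non-negative least squares,

$$\hat c = \arg\min_{c\ \ge\ 0} \sum_g w_g \Big(x_g - \sum_k c_k\,\theta_{gk}\Big)^2,$$

solved by iteratively re-weighted NNLS (Lawson–Hanson active set inside;
deterministic given the fixed gene order). Weights start at 1 and are
updated to

$$w_g = \frac{1}{\nu + \bar r^2 + \sum_k c_k^2 V_{gk}}, \qquad \nu = 10^{-8},$$

so genes whose signatures vary across donors are down-weighted in
proportion to how much the current mixture relies on them; $\bar r^2$
(the mean squared residual) keeps the weights finite and roughly
scale-free. Iteration stops when
$\max_k |\Delta c_k| / (\sum_k c_k + \nu) < 10^{-6}$ or after 100
iterations (`converged` is reported either way). With $V = 0$ the
weights are constant after the first solve, so the procedure collapses
to plain NNLS — a property the tests exploit as an oracle.

Reported quantities:

* contributions $e_k = \hat c_k/\sum_j \hat c_j$ — RNA fractions. A
  cell-size-corrected variant $(\hat c_k/S_k)$ renormalized is also
  returned: for a *single cell* a "cell-count proportion" has no
  physical meaning, so the RNA fraction is the primary output, but the
  size-corrected one is kept for users who point the same code at bulk
  samples.
* group scores — sums of $e$ over the EGIC tissue groups
  (Squamous, SMG, Gastric, Intestinal, Colon); they partition 1.
* mosaicism index $2\min(a,b)/(a+b)$ of the Gastric and Intestinal
  group scores (0 = pure, 1 = even mosaic; 0 when both scores are 0).
  When a custom group map lacks these two groups the index generalizes
  to the evenness of the two largest group scores.

Cells with no signal on the informative genes yield a flagged undefined
result rather than an error, because a pipeline over thousands of cells
must not die on one empty cell.

A minimum of 50 shared informative genes is required before scoring a
matrix; below that a mixture fit is numerically possible but
scientifically vacuous, so it is refused with the overlap size named.

## 4. Reference-based classification

`train_classifier()` mirrors the standard correlation-based annotation
scheme: for every ordered label pair, genes are tested with a two-sided
Wilcoxon rank-sum test and the `m = 20` genes most significantly *higher*
in the first label become that pair's markers (ties by larger median
difference, then input gene order; genes strictly lower are never
selected — with identical labels the zero-difference tie-break fills the
set deterministically). The test is two-sided with a directional filter;
a one-sided test would order the same genes, and two-sided p-values
reuse one computation for both orientations of a pair. Reference
profiles are per-label-per-subject *medians* of log-normalized
expression — aggregation keeps scoring $O(\text{labels}\times
\text{subjects})$ per cell instead of $O(\text{cells})$, and medians are
robust to the occasional aberrant cell.

`classify_cell()` scores each label by the 0.8 quantile of Spearman
correlations between the cell and that label's profiles over the union
of pairwise markers, then fine-tunes: labels within 0.05 of the best are
retained and re-scored on only their mutual markers until the set stops
shrinking. Scores depend on ranks only, hence are invariant to monotone
transforms of the input. The 0.8 quantile and 0.05 margin follow the
cited annotation tool's documented defaults; both are exposed.

Pruning never drops cells: a call is flagged when its score margin falls
more than 3 MAD below the cohort median margin, or when its correlations
were undefined (constant expression over the marker set).

## 5. Pseudo-bulk differential expression

Raw UMI counts are summed per (cell type, patient, condition) —
pseudo-bulk samples that carry patient-level replication, the unit of
independence that per-cell tests ignore. Samples pooled from fewer than
`min_cells = 10` cells are flagged and excluded from fits by default.
The NB machinery is delegated to edgeR, the standard implementation of
exactly these steps: TMM normalization factors (30%/5% trims,
precision-weighted, geometric mean 1), `estimateDisp` dispersion with
empirical-Bayes trend shrinkage, and quasi-likelihood GLM fits tested
against a log2-fold-change threshold (`glmTreat`, default `lfc = 0.5`)
so that significance implies a material effect size. With `lfc = 0` the
test reduces to the ordinary two-sided QL test.

Marker extraction runs every pairwise comparison within a tissue
(patient as a blocking factor when both types share two or more
patients), orients fold-changes toward the focal type, combines each
gene's p-values across that type's comparisons with Simes'
$\min_i n\,p_{(i)}/i$ — valid for the intersection null without
requiring every comparison to reject — and applies BH FDR over genes.

Two behaviours here are worth spelling out because intuition often gets
them backwards: with half the genes four-fold up in one sample, the
trimmed precision-weighted mean M-value is *negative*, so that sample's
TMM factor is below 1 (the hand computation in the test suite shows
this); and a constant gene's dispersion is shrunk toward the trend
rather than to the numerical floor, because the estimator itself
prescribes trend shrinkage.

## 6. QC, normalization, HVG selection

Cells are kept when UMI total, detected genes and mitochondrial UMI
percentage lie within closed bounds; the mitochondrial defaults are
0.5% (lower — implausibly low shares indicate stripped or empty cells)
and 25% (upper — metabolically active upper-GI tissue runs high, so an
aggressive cap would discard real cells). Other bounds default to
non-binding and are exposed per sample, mirroring practice where
per-sample thresholds are chosen by inspection; the package takes them
as configuration rather than guessing. The QC report is a
machine-readable table of (cell, metric, value, action) so filtering is
auditable and testable. Genes detected in no cell are dropped.

Normalization uses library-size factors with cross-batch rescaling:
within a batch, factor = library / geometric-mean library; factors are
then multiplied by (batch mean library / minimum batch mean library) so
every batch is brought down to the lowest-coverage batch — the same
contract as pooling-based multi-batch normalization, in a transparent,
closed form whose three-line formula the tests verify directly. Values
are $\log_2(\text{count}/\text{factor} + 1)$.

HVG selection decomposes per-gene variance of the log values into a
smooth trend on the mean (local regression, span 0.3; degree-2
polynomial below 50 genes, where loess is unstable; flat fallback when
means are degenerate) plus a biological residual, ranks by the residual
descending with ties broken by input order, and flags the top
`n = 2000`.

## 7. The synthetic cohort generator

The generator is the validation instrument, so its structure matters
more than its realism:

* baseline relative expression LogNormal(0, 1), heavy-tailed as in real
  scRNA-seq, with a configurable share (default 5%) of expression mass
  on 13 `MT-` genes;
* per-type marker blocks (default 20 genes at log2 FC 3 — strong but
  not caricatural tissue markers);
* per-subject, per-gene LogNormal effects (SD 0.2 on the log scale),
  shared across the subject's cell types, giving the cross-subject
  variance the deconvolution weights rely on;
* per-cell LogNormal library sizes (median ≈ 5000 UMIs, SD 0.3) and NB
  counts with shared dispersion φ = 0.3 — values typical of 10x data at
  moderate depth;
* mosaic cells mix two *normalized* profiles:
  $\lambda = \alpha\lambda_A + (1-\alpha)\lambda_B$. Mixing on the
  normalized scale is what makes α an RNA fraction, i.e. exactly the
  quantity the deconvolution estimates; mixing raw means would
  confound α with cell size. α is drawn Uniform(0, 1) by default,
  spanning the full gastric-to-intestinal continuum;
* optional QC outliers with mitochondrial shares planted above 25% or
  below 0.5%, recorded in the truth table;
* a two-condition paired cohort for DE, with planted fold-changes.

Everything is a pure function of the configuration including the seed.

What the generator does *not* emulate: ambient RNA, doublets,
zero-inflation beyond NB, batch effects other than subject effects,
cell-cycle structure, or the long-tailed cell-type abundance of real
atlases. Passing the validation therefore shows the estimators are
correct and well-calibrated *under their own model assumptions*; it
does not certify performance on any particular patient cohort.

## 8. Validation design and problem sizes

The test suite and `scripts/acceptance.R` check, among others:

* exact recovery of cells placed at the signature means (the
  noise-free identifiability check);
* Pearson correlation and mean absolute error between true α and the
  intestinal group score on 500 mosaic cells at the default noise level
  (2000 genes, 12 types, depth ≈ 5000);
* the IRLS-NNLS solution against a dense simplex-grid search (step
  0.01) on 100 random 3-type instances — the solver must never lose to
  brute force;
* held-out classification accuracy on a 6-type, 3-subject cohort, and
  the *discordance* between EGIC argmax and classifier labels on mosaic
  versus pure cells — hard classification and deconvolution agree on
  pure cells and disagree exactly where cells are mixtures;
* DE error control on a null cohort (fraction of genes at FDR < 0.05)
  and sensitivity on 100 planted genes at log2 FC 2 with 4 patients;
* exact closed forms: Simes, BH step-up, the rank-sum p-value 0.05 for
  {1,2,3} vs {4,5,6} (enumeration of the 20 orderings), and hand-solved
  2×2 NNLS instances;
* byte-identical reruns of the full pipeline under a fixed seed.

Problem sizes in the tests (a few hundred genes, tens of cells per type
for unit tests; the full 2000-gene cohorts for the end-to-end checks)
were chosen so the whole suite runs in about a minute while keeping
every statistical check adequately powered.

## 9. Known limitations

* The deconvolution assumes the reference spans the cell's phenotypes;
  a cell type absent from the reference is smeared over its nearest
  signatures rather than flagged as novel.
* The weight formula is this package's concrete instantiation of
  "down-weight genes with high cross-subject variance"; other published
  weightings differ in detail, and coefficient values (not orderings)
  can differ accordingly.
* Library-size normalization ignores composition bias at the per-cell
  level (TMM is applied at the pseudo-bulk level, where it is
  standard).
* The robustified variant of the quasi-likelihood fit is not used;
  on the synthetic cohorts it made no difference to error control, and
  the plain QL fit keeps one fewer tuning choice.
* The classifier's fine-tuning can oscillate between near-tied labels;
  the retained-set-unchanged stopping rule makes it terminate
  deterministically, at the cost of occasionally keeping a two-label
  tie that is then broken by label order.
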
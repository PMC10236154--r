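# egicmosaic

Per-cell phenotype deconvolution and mosaicism scoring for
gastrointestinal single-cell RNA-seq.

## The problem

Intestinal metaplasia (IM) — the replacement of esophageal or gastric
epithelium by intestinal-type tissue — is the precursor lesion of
esophageal and gastric adenocarcinoma. Single-cell atlases of the upper
GI tract suggest that metaplastic epithelial cells are not simply
"gastric" or "intestinal": an individual cell can carry a *mosaic* of
both transcriptional programs, expressing gastric markers (MUC5AC, MUC6)
and intestinal markers (GPA33, OLFM4) simultaneously. Hard
classification hides this; what is needed is a per-cell estimate of how
much of each phenotype a cell contains.

`egicmosaic` provides that estimate, plus everything around it needed to
compute and validate it from raw UMI counts:

- **EGIC deconvolution** — each cell's relative expression
  `x_g = y_g / Σ y` is modelled as a non-negative mixture of
  multi-subject reference signatures `θ_gk` (one column per healthy cell
  type, each summing to 1):

  `ĉ = argmin_{c ≥ 0} Σ_g w_g ( x_g − Σ_k c_k θ_gk )²`,

  solved by iteratively re-weighted non-negative least squares with
  `w_g = 1 / (ν + r̄² + Σ_k c_k² V_gk)`, where `V_gk` is the
  cross-subject variance of the signatures — genes that are unstable
  across donors are down-weighted, the idea behind bulk deconvolution
  methods applied here to single cells treated as tiny bulk samples.
  Normalized contributions `e = ĉ / Σ ĉ` are summed into EGIC tissue
  groups (Esophageal-squamous, SMG, Gastric, Intestinal, Colonic), and
  the mosaicism index `2·min(a, b) / (a + b)` of the gastric and
  intestinal group scores quantifies how evenly split a cell is.
- **Reference-based classification** — a rank-sum-marker /
  Spearman-correlation classifier with fine-tuning (20 markers per label
  pair by default), the hard-label counterpart the deconvolution is
  compared against.
- **Pseudo-bulk differential expression** — UMI counts summed per cell
  type × patient × condition, TMM normalization factors, NB dispersion
  estimation and quasi-likelihood GLM threshold tests (|log2 FC| > 0.5),
  with Simes combination across pairwise comparisons and BH FDR.
- **QC, normalization, HVG selection** — mitochondrial-percentage
  bounds (0.5–25%), cross-batch scaling normalization to the
  lowest-coverage batch, mean–variance-trend highly-variable-gene
  ranking.
- **A synthetic cohort generator** — multi-tissue, multi-subject
  negative-binomial counts with planted markers, planted QC outliers and
  planted mosaic cells of known mixture weight α, so every stage can be
  validated against ground truth.

## Worked example

```r
library(egicmosaic)

cfg <- sim_config(seed = 42)                # 2000 genes, 12 GI cell types,
sim <- simulate_reference(cfg)              # 3 subjects/tissue, NB noise
ref <- build_reference(sim$counts, group_map = sim$truth$group_map)

# plant 500 gastric/intestinal mosaic cells with known alpha
mos <- simulate_mosaic(cfg, sim$truth, c("enterocyte", "foveolar"), 500)
sc  <- egic_scores(mos$counts, ref)

cor(mos$truth$mix_alpha, sc$group_Intestinal)
#> [1] 0.9518865
mean(abs(sc$group_Intestinal - mos$truth$mix_alpha))
#> [1] 0.07539313
head(sc[, c("cell_id", "group_Gastric", "group_Intestinal", "mosaicism")], 3)
#>       cell_id group_Gastric group_Intestinal mosaicism
#> 1 mosaic00001     0.3529219       0.58744372 0.7506057
#> 2 mosaic00002     0.1358334       0.82147684 0.2837814
#> 3 mosaic00003     0.8069108       0.09256126 0.2058124
```

The intestinal group score tracks the true RNA fraction α of the
intestinal component (r ≈ 0.95 at the default noise level), and the
mosaicism index is high exactly for cells near an even gastric/intestinal
split.

The full seeded pipeline (simulate → QC → normalize → HVG → reference →
EGIC → annotate → DE → report) runs via

```r
run_pipeline(pipeline_config(out_dir = "runs/demo", seed = 1))
```

or from the shell:
`Rscript inst/scripts/egic-pipeline.R --out runs/demo --seed 1`.

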
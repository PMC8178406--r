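# cardioregion

Regional transcriptomics of the four-chambered heart, as a tested,
reusable R pipeline. The package is for analysts working with bulk RNA-seq
of heart tissue sampled per chamber — left/right atria and ventricles (LA,
LV, RA, RV) — across disease groups (non-failing vs HFrEF), who want to go
from a count matrix to chamber-enriched gene catalogs, heart-specificity
calls, gene-set over-representation, and cell-type composition estimates,
with every step reproducible and testable against planted synthetic truth.

## What it computes

**Normalization.** FPKM
(`FPKM_gs = counts_gs · 10⁹ / (length_g · total_s)`) followed by
percentile anchoring: each sample is rescaled so the 70th percentile of its
nonzero values equals 10 (a refinement of upper-quartile normalization).
Genes with FPKM ≥ 1 in fewer than 5 samples of a comparison are removed
from that comparison.

**Differential expression.** Per-gene negative-binomial GLM
(Var = μ + αμ², log link, size-factor offsets by median-of-ratios) with a
Wald test on the group coefficient and optional sex/age covariates.
Gene-wise dispersions are estimated by Cox–Reid-adjusted profile likelihood
and moderated toward a fitted mean–dispersion trend (α ~ a₀ + a₁/μ) by
empirical-Bayes shrinkage; p-values are BH-adjusted per contrast.

**Subregion enrichment.** From the six pairwise chamber contrasts, a gene
is chamber-enriched (LV-, RV-, LA-, RA-Enriched) when it is up ≥ 2-fold at
BH q < 0.01 in all three comparisons against the other chambers, and
axis-enriched (Ventricles-, Atria-, Left-, Right-Enriched) when up ≥ 2-fold
at q < 0.01 in all four cross-axis comparisons (Ventricles: LV>LA, RV>LA,
LV>RA, RV>RA). Heart-Enriched genes rank in the top 3 of a multi-tissue
panel with heart FPKM ≥ 1.

**Over-representation.** Fisher's exact test of gene sets (GMT input)
within an explicit universe, scored by the odds ratio (a·d)/(b·c).

**Deconvolution.** Weighted non-negative least squares of bulk profiles
against type-mean signatures from labeled single-cell/nucleus references
(7 cardiac cell types in the emulated design), with reference QC,
multi-reference ensemble weighting by reconstruction error, and exact
Mann–Whitney group comparisons of the estimated proportions.

**Synthetic data.** Seeded generators for NB bulk counts with planted
chamber/disease effects, a GTEx-like tissue panel, labeled single-cell
references and bulk mixtures of known composition — each returning its
ground truth.

## Worked example

Simulate a two-chamber cohort with 40 genes planted 4-fold higher in LV,
then test LV vs LA:

```r
library(cardioregion)

planted <- data.frame(gene = 1:40, chambers = "LV", diseases = "*", log2fc = 2)
spec <- bulk_sim_spec(n_genes = 1000, chambers = c("LA", "LV"), diseases = "NF",
                      donors_per_group = 10, dispersion = 0.1,
                      planted_effects = planted, seed = 42)
sim <- simulate_bulk(spec)
de <- run_contrast(sim$counts, sim$gene_lengths, sim$metadata,
                   select_samples(sim$metadata, "LV"),
                   select_samples(sim$metadata, "LA"), name = "LV_vs_LA")
subset(de, padj < 0.01 & log2FC >= 1)   # 40 rows: exactly the planted genes
head(de[order(de$padj), ], 3)
#>     gene_id baseMean_A baseMean_B log2FC   pvalue     padj
#>  gene_00014        373       77.9   2.26 1.53e-29 1.53e-26
#>  gene_00017        503      102.0   2.30 1.79e-27 8.94e-25
#>  gene_00012        857      184.6   2.21 6.13e-27 2.04e-24
```

`baseMean_A`/`baseMean_B` are size-factor-normalized mean counts per group;
`log2FC` is oriented A over B, so ~2.3 ≈ the planted 4-fold effect.

Deconvolve a noisy bulk mixture of seven cardiac cell types mixed at known
proportions (cardiomyocytes 0.61, endothelium 0.20, fibroblasts 0.08, ...):

```r
ref <- simulate_reference(n_cell_types = 7, cells_per_type = 50,
                          n_genes = 500, seed = 1)
sig <- build_signature(ref$counts, ref$labels)
truthp <- setNames(c(0.61, 0.20, 0.08, 0.01, 0.08, 0.005, 0.015),
                   colnames(sig))
mix <- simulate_mixtures(ref, truthp, noise_sd = 0.1, seed = 2)
round(wnnls_deconvolve(mix$bulk, sig)$proportions, 3)
#>         Cardiomyocytes Endothelium Fibroblasts Macrophages Perivascular
#> mix_001          0.554       0.212       0.101       0.014        0.092
#>         Lymphocytes Neurons
#> mix_001       0.006   0.022
```

The full pipeline — simulate, normalize, 8 DE contrasts, classification,
enrichment, deconvolution, summary — runs from one config:

```r
res <- run_pipeline(demo_pipeline_config(outdir = "demo_out", seed = 1))
res$summary   # per-stage recovery metrics vs the planted truth
```

A thin CLI wrapping the same functions ships at
`inst/scripts/cardioregion` (`cardioregion demo --seed 1 --out demo_out`,
plus `diffexp`, `classify`, `enrich`, `deconvolve` subcommands).

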
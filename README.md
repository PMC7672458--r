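# fracseqtools

Analysis of **nucleocytoplasmic fractionation RNA-seq** (Frac-Seq)
experiments, for researchers asking whether a perturbation — typically
depletion of a nuclear export or retention factor — changes *where* a
gene's RNA sits in the cell, and how that change relates to the gene's
architecture.

The core statistic is a per-gene log2 ratio-of-ratios between knockdown
and control,

```
Δ_g = log2(N_g/C_g)_KD − log2(N_g/C_g)_control
```

(with nuclear/total and cytoplasmic/total variants), computed on
median-of-ratios-normalized replicate means with a prior count, with a
delta-method standard error and empirical-Bayes shrinkage toward zero
(`Δ̂·τ²/(τ²+se²)`). Deltas are then related to annotation-derived
features — pre-mRNA length, exonic length, exon count, intronic fraction,
exon density, 3'UTR length — via Spearman correlations, pre-mRNA length
bins (`<10 … >50 kb`), single/multi-exon classes, gene-set contrasts and
length-controlled exon-count windows, using first-principles Mann–Whitney
tests with Benjamini–Hochberg adjustment. A companion imaging module
implements the matching microscopy quantifications (area-constrained
nuclear speckle segmentation at 10% ± 0.5% of nuclear area,
brightest-speckle Pearson colocalization, speckle enrichment, smFISH spot
detection and nuclear/cytoplasmic classification, decay-ratio time
courses), and a fully seeded synthetic-data generator (GTF annotation,
negative-binomial count matrices, two-channel cell images) provides ground
truth for every stage.

## Worked example

```r
library(fracseqtools)

ann <- make_toy_annotation(default_templates(2000), seed = 11)
gm  <- gene_metrics(ann)
se  <- simulate_fracseq_counts(ann, effect_model(), replicates = 3, seed = 501)

counts <- SummarizedExperiment::assay(se, "counts")
keep <- filter_genes(compute_fpkm(counts, setNames(gm$exonic_length, gm$gene_id)), gm)
loc  <- delta_localization(se, kd = "KD_A", genes = keep)

head(loc[, c("gene_id", "delta_raw", "se", "delta_shrunk")], 3)
#>   gene_id delta_raw    se delta_shrunk
#> 1  G00001      1.88 0.280         1.73
#> 2  G00002      1.44 0.336         1.29
#> 3  G00003      2.86 0.409         2.43

feature_correlations(loc, gm)
#>              metric    n    rho        p
#> 1       gene_length 1992 -0.914 0.00e+00
#> 2   pre_mrna_length 1992 -0.918 0.00e+00
#> 3     exonic_length 1992 -0.741 0.00e+00
#> 4           n_exons 1992 -0.449 1.81e-99
#> 5 fraction_intronic 1992 -0.272 3.39e-35
#> 6      exon_density 1992  0.392 5.31e-74
#> 7       utr3_length 1669 -0.796 0.00e+00
```

The strong negative rank correlation between pre-mRNA length and the
localization delta is the generator's planted effect: short genes lose
export efficiency under the simulated knockdown and become relatively
more nuclear. Class contrasts and length bins read the same way:

```r
classes <- setNames(gm$gene_class, gm$gene_id)
group_compare(loc, classes[classes %in% c("histone_like", "ribosomal_like")])$tests
#>            group n_group n_background      U        p        q direction
#> 1   histone_like     100         1892 186109 6.62e-60 1.32e-59    higher
#> 2 ribosomal_like     100         1892 144327 7.26e-19 7.26e-19    higher

length_bin_analysis(loc, gm)$summary
#>      group   n  median     q1     q3
#> 1   <10 kb 839  0.8300  0.497  1.280
#> 2 10-20 kb 415 -0.0987 -0.391  0.167
#> 3 20-30 kb 271 -0.6208 -0.865 -0.348
#> 4 30-40 kb 140 -0.8730 -1.063 -0.556
#> 5 40-50 kb 105 -0.9868 -1.259 -0.734
#> 6   >50 kb 222 -1.0813 -1.313 -0.792
```

(Deltas are relative to the sample-wide normalization, so the typical
gene sits near zero and bins are ordered; the rank-based tests are
unaffected by this centering.)

Imaging, on a synthetic two-channel cell:

```r
img <- simulate_cell_image(seed = 7)
seg <- segment_speckles(img$sc35, img$nucleus_mask)
seg$area_fraction
#> [1] 0.1000414
brightest_speckle_pearson(img$rna, img$sc35, seg$speckle_mask)$mean_r
#> [1] 0.947
```

`run_pipeline(pipeline_config(seed = 1), "runs/demo")` executes the whole
chain (generate → features → localization → strata → imaging) with a
manifest and byte-reproducible TSV outputs; see the vignette in
`vignettes/fractionation-localization.Rmd` for the model, parameter
rationale and limitations.

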
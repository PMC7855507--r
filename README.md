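# sciquorum

Consensus differential expression, category overrepresentation and
cell-type association for two-group RNA-seq count data, built around the
analysis design used in spinal-cord-injury transcriptomics: score every
gene with **three** differential-expression algorithms that differ in how
they normalise sequencing depth, keep only genes called significant by **at
least two of the three**, and carry that conservative consensus set into
downstream functional and cellular attribution.

It is aimed at analysts who start from a gene × sample count matrix (plus a
gene-length table for FPKM) and want a reproducible, testable version of
this multi-algorithm voting workflow — including a synthetic-data generator
with recorded ground truth, so the whole pipeline can be validated without
any sequencing data.

## The method

**Three scorers, one exact test.** Each scorer places samples on a common
scale with a different size-factor estimator —

* `UQ`: upper-quartile (75th percentile of each sample's counts over
  nonzero genes, rescaled to unit geometric mean),
* `MOR`: median-of-ratios against the per-gene geometric-mean reference,
* `FPKM`: counts converted to FPKM
  (`count · 10⁹ / (length · total)`) and rescaled to a common depth —

and then applies the same exact negative-binomial conditional test: under a
shared dispersion φ, the first group's normalized count sum conditioned on
the two-group total follows a beta-binomial with shape parameters n₁/φ and
n₂/φ (exact binomial in the Poisson limit φ → 0). Two-sided p-values double
the smaller tail; each scorer is Benjamini–Hochberg adjusted independently.
Dispersions are method-of-moments estimates shrunk 50/50 toward the mean of
the gene's expression decile.

**Consensus.** A gene is accepted when it passes `Padj ≤ 0.05` and
`|log2FC| ≥ 1` (both boundaries inclusive, configurable) in ≥ 2 scorers
with concordant direction; its consensus fold change is the mean over the
supporting scorers only. Venn set algebra (`venn_counts()`,
`shared_fraction()`, `unique_genes()`) compares consensus sets across
time-points and injury ages.

**Downstream.** Category overrepresentation uses the binomial test — for a
category holding K of N genome genes and k of n study genes,
`p_over = P(X ≥ k)`, `p_under = P(X ≤ k)` for `X ~ Bin(n, K/N)` — with
Bonferroni correction. Cell-type association maps genes onto a
seven-cell-type CNS reference (astrocytes, neurons, endothelial cells,
microglia, OPCs, newly formed and myelinating oligodendrocytes), removes
genes never rising above 0.1 FPKM, expresses each gene as a percentage of
its summed expression across cell types, and clusters profiles
hierarchically (1 − Pearson correlation, average linkage).

## Worked example

```r
library(sciquorum)

cfg <- simulation_config(n_genes = 2000, fraction_de = 0.05, seed = 1)
sim <- simulate_counts(cfg)                       # counts, metadata, lengths, truth
de  <- run_de_suite(sim$counts, sim$metadata, sim$lengths)
glance(de)
#>   method_id n_significant  n_up n_down n_genes
#> 1 FPKM                 98    50     48    2000
#> 2 MOR                  97    52     45    2000
#> 3 UQ                   96    51     45    2000

consensus <- vote(threshold_filter(de), label = "P7SCI+1d")
consensus
#> # A tibble: 96 × 5
#>   gene_id support avg_log2fc direction label
#> 1 g00018        3       2.08         1 P7SCI+1d
#> 2 g00039        3      -1.86        -1 P7SCI+1d
#> ...
```

The three scorers each flag ~97 of 2,000 genes; voting keeps the 96 genes
with at least two concordant calls. Against the simulator's ground truth
(100 genes planted at |log2FC| = 2) this consensus recovers 90% of the
planted genes with a false-discovery proportion of 0.062.

```r
ann  <- simulate_annotation(cfg, sim$truth)
amap <- annotation_map(ann$annotation, ann$universe)
binomial_overrep(consensus, amap) |>
  bonferroni_adjust() |>
  significant_categories()
#>   category_id observed expected fold_enrichment direction   p_bonf
#> 1 cat001            66     13.9            4.74 over      1.54e-31
#> 2 cat002            49     10.3            4.75 over      5.98e-21
```

Exactly the two planted enriched categories are reported, at close to their
planted 5-fold enrichment. Cell-type attribution works the same way:

```r
ref    <- simulate_celltype_reference(cfg)
mapped <- map_ids(consensus, ref$reference, ref$id_map)
prof   <- percentage_profile(background_filter(mapped))
prof[3, ]   # a planted microglia marker: 95% of its expression in microglia
#>   gene_id astrocytes neurons endothelial microglia  OPCs ...
#> 1 g00054       0.833   0.833       0.833        95 0.833 ...
cluster_profiles(prof)      # ordering + dendrogram per time-point block
autoplot(prof)              # percentage heatmap
```

`run_pipeline(pipeline_config(sim = cfg, out_dir = "out"))` chains all
stages, writes every table as TSV and emits a `manifest.json` with
checksums; reruns under the same seed are byte-identical. A thin command
line lives in `inst/scripts/sciquorum-pipeline.R`
(`simulate` / `run-all` subcommands).

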
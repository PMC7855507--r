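---
title: "Methods: consensus DE voting, overrepresentation and cell-type association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus DE voting, overrepresentation and cell-type association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

sciquorum implements a conservative strategy for calling differential
expression in two-group RNA-seq comparisons — such as injured spinal cord
versus age-matched control tissue — and for attributing the resulting gene
sets to functional categories and CNS cell types. This vignette documents
the statistical model, every tunable that matters, the numerical
conventions, and what the synthetic-data validation does and does not show.

## The consensus model

Parallel DE algorithms applied to the same data rarely return the same gene
list; most of their disagreement traces to how they normalise sequencing
depth. sciquorum makes that the explicit axis of variation: one exact
negative-binomial test core is run under three normalization strategies,
and a gene is accepted only when at least two of the three scorers call it
significant in the same direction.

### Normalization strategies

* **UQ** — upper-quartile: the size factor is proportional to the 75th
  percentile of the sample's counts, over genes that are nonzero in at
  least one sample, rescaled so the factors have unit geometric mean.
  Quantiles use linear interpolation between order statistics (R's type 7);
  conventions differ between tools, so ours is stated.
* **MOR** — median-of-ratios: per sample, the median over reference genes
  of the ratio of the sample's count to the gene's geometric mean across
  samples. Reference genes are those with no zero in any sample (a zero
  makes the geometric mean degenerate).
* **FPKM** — counts are converted to FPKM,
  $\mathrm{FPKM}_{gj} = c_{gj}\,10^9 / (L_g\,T_j)$ with $L_g$ the gene
  length and $T_j$ the sample total, then rescaled to a common depth (the
  geometric mean of the sample totals) and rounded back to pseudo-counts.
  Algebraically this is total-count normalization routed through the FPKM
  scale, giving a genuinely third depth model rather than a fourth variant
  of the other two.

### The exact test

For each gene, normalized counts are summed within each group and rounded
to the nearest integer. Writing $n_1, n_2$ for the group sizes and $\phi$
for the gene's dispersion (variance $\mu + \phi\mu^2$), the group sums are
modelled as sums of iid negative-binomial draws with a common per-sample
mean under the null. Because NB variables with a shared success probability
are closed under addition, the first group's sum conditioned on the overall
total $t$ follows a beta-binomial (negative hypergeometric) distribution
with shape parameters $n_1/\phi$ and $n_2/\phi$ — the common mean cancels.
As $\phi \to 0$ this degenerates to $\mathrm{Binomial}(t,\, n_1/(n_1+n_2))$,
which the implementation switches to below $\phi = 10^{-10}$ and which is
also the exact Poisson conditional test. Two-sided p-values double the
smaller tail, with the observed value included in its tail, capped at 1 —
a deterministic convention that keeps the null example (equal group sums)
at exactly $p = 1$.

Rounding the normalized group sums is an approximation: after dividing by
size factors the sums are not integers, and placing them back on a count
grid ignores sub-count information. With size factors near 1 (the regime
the generator produces) the effect is far below the test's discreteness.

### Dispersion

The per-gene dispersion is a method-of-moments estimate on normalized
counts — within each group, $\hat\phi = (v - m)/m^2$ from the group mean
and variance, pooled across groups with degrees-of-freedom weights and
floored at 0. At 3–4 replicates this estimator is extremely noisy, so by
default each gene's value is averaged 50/50 with the mean raw dispersion of
the genes in the same expression decile. The weight is deliberately simple
and documented rather than estimated; `shrink = FALSE` disables it. The
calibration consequence is measured, not assumed: on null simulations at
5,000 genes the Kolmogorov–Smirnov distance of each scorer's raw p-values
from uniform stays below 0.05 (see `scripts/acceptance.R`).

### Voting and thresholds

The default thresholds are $P_{adj} \le 0.05$ (Benjamini–Hochberg, each
scorer adjusted independently) and $|\log_2\mathrm{FC}| \ge 1$. Both
boundaries are **inclusive** by default because the workflow this package
implements states the rule both ways in different places; a strict mode
(`thresholds(inclusive = FALSE)`) is provided. The consensus fold change is
the mean of the supporting scorers' log2 fold changes only — a scorer in
which the gene fell below threshold contributes nothing. Sign concordance
among supporters is required; in practice discordance is rare (we exclude
and warn rather than silently average). Fold changes use a pseudo-count of
1 normalized count in numerator and denominator so they stay finite at
zeros.

## Overrepresentation

For a category holding $K$ of the $N$ universe genes and $k$ of the $n$
study genes, the binomial model gives
$p_{over} = P(X \ge k)$ and $p_{under} = P(X \le k)$ for
$X \sim \mathrm{Bin}(n, K/N)$. The reported p-value is the smaller tail and
the direction names it; no two-sided doubling is applied because the two
directions are reported (and plotted) separately. Bonferroni multiplies by
$m$, by default the number of categories actually tested in the run — not
a full-ontology count — and the $m$ used is recorded in the output. Genes
carrying no category are pooled into a synthetic `unclassified` category,
which `significant_categories()` removes by default, so the "drop
unclassified" rule always has a concrete referent. The significance
boundary $p_{bonf} \le \alpha$ is inclusive.

## Cell-type association

Consensus genes are joined to a reference expression table over seven CNS
cell types through a user-supplied id map (the identifier namespace is
deliberately unconstrained; cross-species mappings are the user's
responsibility). Conventions, each of which was an open choice:

* a source id mapping to several reference rows resolves to the row with
  the larger total expression (the most reliably detected row), and the
  event is reported;
* the background filter keeps a gene only when its **maximum** expression
  across the seven cell types is **strictly** greater than 0.1 FPKM —
  "does not rise above background" read literally, applied to the maximum
  rather than per cell type;
* percentages are $100\,x_c / \sum_c x_c$, so every emitted profile sums to
  100 within $10^{-9}$ and is invariant to rescaling the reference row.

Clustering uses distance $1 - r$ (Pearson correlation between percentage
profiles) with average linkage — correlation distance matches the
compositional scale, where two genes with the same cell-type pattern at
different absolute levels should be neighbours. Both distance and linkage
are configurable. Dendrogram leaf order is made deterministic by a single
rule: at every merge, the subtree containing the lexicographically smallest
gene id goes left. Ranked "top unique gene" lists break fold-change ties
lexicographically for the same reason: identical inputs must give identical
outputs.

## Candidate profile tables

`build_profile_table()` tabulates group-mean FPKM for a user-supplied
candidate list, scales each row to $[0,1]$ by min–max (the heatmap
convention; z-scoring is available), and marks two kinds of significance:
a per-cell injury flag where the gene holds a consensus call for that
injured group, and a per-gene development flag from a control-vs-control
contrast. The development contrast is not special-cased: it is the same
`run_de_suite()`/`vote()` path with control groups as the two classes.
Constant rows scale to a flat 0.5 so the display stays defined; candidates
missing from the expression table are reported and skipped, not fatal.

## The synthetic-data generator

The generator exists so that every downstream stage can be scored against
known truth. It emulates:

* negative-binomial counts with log-normal gene means (location
  `mean_log_expression = 4`, scale 1 — median gene ≈ 55 expected counts, a
  realistic bulk dynamic range) and a shared dispersion (default 0.1);
* 4 replicates per group, log-normal per-sample depth factors with CV 0.2;
* a planted DE fraction (default 5%) at fixed $|\log_2\mathrm{FC}| = 2$
  with an even sign split — the simplest structure that exercises the
  magnitude threshold;
* a cell-type reference in which marker genes put 95% of their expression
  in one cell type, non-markers are near-uniform, a 5% slice of genes sits
  below the 0.1 FPKM background everywhere, and 5% of ids are absent from
  the id map;
* an annotation of 50 categories with sizes drawn uniformly from 30–300
  genes — the scale of reduced-ontology biological-process terms. This
  lower bound matters: with a ~250-gene study set, a 5-fold enrichment
  planted in a 10-gene category is statistically undetectable under
  Bonferroni, so very small categories would make the planted-recovery
  check a coin flip rather than a test of the code. Enriched categories
  are planted by rate (DE member rate = fold × global rate), matching the
  binomial model being tested.

All draws flow from a single integer seed; identical config + seed gives
bit-identical outputs, which the pipeline driver verifies by checksumming
its TSVs.

What the generator does **not** emulate: batch effects, gene-length or
GC-dependent biases, correlated genes, isoform structure, the pooling of
multiple animals into single replicates (dispersion is exposed directly
instead), or any age-dependent biology. Passing the synthetic checks
therefore demonstrates the pipeline's statistical correctness and
calibration under its stated model — not robustness to the full messiness
of real tissue RNA-seq.

## Validation problem sizes

The test suite and `scripts/acceptance.R` use: 5,000 genes for null
calibration (KS < 0.05 per scorer; consensus ≤ 5% of genes) and for
power/false-discovery runs (10 seeds; mean recall ≥ 80% of planted genes at
mean FDP ≤ 0.10 — observed ≈ 95% and ≈ 0.06); 30-category annotations for
enrichment recovery (planted category flagged in ≥ 9/10 seeds, no
un-enriched category in > 1/10); 2,000-gene references for marker recovery.
These sizes give stable Monte-Carlo estimates while keeping a full
validation run in the low tens of seconds on one core.

## Known limitations

* The exact test assumes a common dispersion across the two groups and
  ignores uncertainty in the estimated dispersion; at very low counts its
  discreteness makes p-values conservative.
* The three scorers share one test core; they are genuinely different in
  normalization but not in distributional family, unlike a comparison of
  heterogeneous published tools.
* Overrepresentation treats genes as exchangeable (no length or expression
  bias correction) and ignores ontology structure — no parent-term
  propagation.
* Cell-type association attributes bulk signal by reference proportions;
  it is not a deconvolution and estimates no cell fractions.
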
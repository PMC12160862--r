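---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

stromascape implements the computational core of a stroma-tumor crosstalk
analysis for multi-sample single-cell RNA-seq cohorts: discovery of recurrent
epithelial expression programs by per-sample NMF, copy-number-based
malignancy classification, ligand-receptor communication scoring, pseudobulk
differential expression with gene-set enrichment, and the clinical
statistics used to relate a stromal marker to outcome. Because the questions
the pipeline answers ("does a fibroblast ligand drive an epithelial
program?") cannot be validated without planted ground truth, the package
ships a first-class synthetic cohort generator and every stage is validated
by recovery of what was planted. This vignette documents the models, the
parameters that matter, and the choices made where the design was genuinely
open.

## The synthetic cohort generator

`generate_cohort()` draws a gene-by-cell count matrix from a negative
binomial: for gene $g$ in cell $c$,

$$\mathrm{counts}_{gc} \sim \mathrm{NB}\big(\mu_{gc},\ \phi\big), \qquad
\mu_{gc} = m_g \cdot e_{gc} \cdot f_{gc} \cdot \ell_{gc} \cdot d_c,$$

where $m_g$ is a per-gene baseline mean (log-normal around `base_mean`,
spread `gene_mean_sd = 0.5`, mimicking the skewed mean-expression
distribution of real transcriptomes), $e_{gc}$ the multiplicative effect of
any planted expression program active in that cell, $f_{gc}$ the
copy-number fold of any segment covering the gene in an affected cell,
$\ell_{gc}$ the ligand-receptor axis effect, and $d_c$ a log-normal(0, 0.3)
per-cell depth factor. The variance is $\mu + \phi\mu^2$ with `dispersion`
$\phi = 0.5$ by default — deliberately on the noisy side of droplet data, so
that recovery results are not flattered by an easy noise model.

Structural defaults describe the study conditions the downstream stages
assume: a mostly malignant sample mix (`malignant_sample_fraction = 0.8`,
echoing a tumor-heavy clinical cohort), epithelial and fibroblast subtypes
plus a diploid `reference` population, 22 pseudo-chromosomes assigned to
genes in index order (CNV smoothing operates on gene order, so base-pair
coordinates are unnecessary), and small `MT-`/hemoglobin panels carrying 5%
and 0.3% of counts so that quality-control filters are exercised. Planted
programs are 50-gene modules switched on in a configurable fraction of
epithelial cells at a multiplicative effect (4 by default — the regime in
which all recovery guarantees are stated). Ground truth (program on/off
states, malignant flags, planted gene sets) is returned alongside the
counts.

What the generator does *not* emulate: doublets, ambient RNA, batch
effects, spatial structure, or gene-gene correlation beyond the planted
modules. Passing recovery tests therefore demonstrates that the algorithms
are correct and calibrated under the stated noise model, not that they are
robust to every artifact of real droplet data.

## Quality control and normalization

`qc_filter()` applies the conventional per-cell rules — 300–8,000 detected
genes (count $\ge 1$), under 40,000 UMI, under 10% mitochondrial and 1%
hemoglobin content — then drops whole samples with fewer than 500 surviving
cells. Per-cell rules run first; the sample rule sees only survivors.
Hemoglobin genes are matched from an explicit list (HBB, HBA1, ...) rather
than a bare `HB` prefix, which would sweep in HBEGF or HBS1L. Note that the
sample-exclusion rule interacts with design size: a 500-cell sample that
loses a single cell is excluded, so synthetic cohorts sized exactly at the
threshold are analyzed without the sample rule (or generated larger).

`normalize_log()` scales each cell to 10,000 counts and applies `log1p` —
the community-standard depth target; the pipeline's results are insensitive
to this constant because every downstream statistic is either rank-based,
centered, or contrast-based.

`select_hvg()` ranks genes by dispersion (variance/mean on the un-logged
normalized scale) after removing the mean-dispersion trend. The default
removes the trend continuously, by a robust loess fit of log dispersion on
log mean, ranking genes by their residual. A classic binned flavor (20
equal-occupancy mean bins, within-bin z-scores) is retained as
`method = "bins"`, but it has a known failure mode that the generator
exposes sharply: when genuinely variable genes concentrate at similar mean
expression they crowd a bin and set their own reference scale, and the
method demotes exactly the genes it should keep. With 50 planted effect-4
genes among 1,000, the binned flavor recovers about 40 of 50 while the
trend residual recovers 48–50; the loess default follows. A caveat on
sensitivity: at effect 2 on half the cells, the analytic dispersion
inflation under $\phi = 0.5$ noise is only ~1.14x, so weak programs are
intrinsically hard to separate at this noise level — a property of the
noise model, not of the selector.

## Meta-program discovery

The core procedure decomposes each sample's epithelial expression into
additive programs and asks which programs recur across the cohort.

1. **Preprocessing.** Log-normalized expression restricted to 2,000 HVGs is
   centered per gene and negatives are clipped to zero — the standard
   non-negativization for expression-program NMF; clipping (rather than
   shifting) keeps factors sparse and interpretable as "above-average
   expression" patterns.
2. **Per-sample NMF sweep.** `fit_sample_nmf()` runs multiplicative-update
   NMF (Frobenius loss, seeded uniform initialization per (K, seed), at
   most 200 iterations, relative tolerance $10^{-4}$) for every rank $K$
   from 3 to 10, and reduces each factor to its top 50 genes by loading —
   $\sum_{K=3}^{10} K = 52$ programs per sample. Sweeping K rather than
   choosing it sidesteps rank selection: the robustness filter does that
   work.
3. **Robustness selection.** `select_robust_programs()` keeps a program iff
   it is *stable* (shares $\ge 35/50$ genes with a program of a different K
   in the same sample) and *recurrent* (shares $\ge 10/50$ genes with
   programs from at least one other sample); within a sample, retained
   programs sharing more than 40 genes collapse to the one with the highest
   cross-sample recurrence (ties to lower K, then lower factor index). The
   thresholds 35/10/10/2 are package defaults exposed in
   `robustness_params()` — they are not claims about any published
   analysis, which typically leaves them unstated.
4. **Jaccard clustering.** `cluster_meta_programs()` hierarchically
   clusters the survivors on distance $1 - J$ (average linkage), cuts at
   distance 0.75 by default (or at a fixed cluster count where a pinned
   number of meta-programs is wanted), discards clusters with fewer than 3
   members, and summarizes each cluster by `consensus_gene_list()`: genes
   ranked by (frequency across members, mean loading, gene id), top 50.

Every tie-break is a total order, so the pipeline is deterministic under a
fixed seed. On the reference synthetic cohort (10 samples x 500 epithelial
cells, five planted 50-gene programs at effect 4) the pipeline recovers all
five programs with consensus-to-truth Jaccard near 1; the validation suite
requires at least 4 of 5 at Jaccard $\ge 0.8$, leaving room for unlucky
seeds.

## Signature scoring and stratification

`module_score()` is the control-matched module score: per cell, the mean
log-expression of the signature minus the mean of control genes drawn from
the signature genes' average-expression bins (24 bins, up to 100 controls
per signature gene, sampled without replacement within a bin and excluding
the signature itself). Scores are invariant to adding a constant to the
whole matrix and are zero in expectation for random signatures.

`rank_set_score()` is the single-sample analogue for bulk profiles: the
centered normalized mean rank of the signature genes,
$2(\bar r - (n+1)/2)/(n-1) \in [-1, 1]$. It deliberately replaces the
KS-like kernel of GSVA-style scores with something simpler and exactly
rank-invariant; it serves stratification, where only the ordering of
subjects matters.

`stratify_by_score()` splits at the median or at a percentile (type-7
quantile). Ties at the cutoff go to "low": strict inequality is
deterministic and conservative (a subject must exceed the cutoff to be
called high). The common published choices — median, and the 75th
percentile for ligand-high cohorts — are both supported.

## CNV profiling and malignancy calls

`infer_cnv_profile()` is a transparent reimplementation of the
moving-average core of inferCNV-style estimation, without HMM denoising:
per gene, relative log-expression against the reference-cell mean, clipped
to $\pm 3$; a centered moving average of width 101 genes strictly within
each chromosome (windows shrink at chromosome ends and never cross
boundaries); per-cell re-centering by the median. The window (101) and clip
(3) follow the de facto defaults of that tool family. At least 20 reference
cells are required.

`cnv_score()` is the mean squared smoothed deviation, and
`classify_malignant()` thresholds at the empirical 90th percentile
(type 7) of the reference-cell scores, calling cells *strictly above* it
malignant — the only composition of "mean squared deviation" and "90th
percentile of normal-cell scores" that yields a single classification
rule. Applied to the reference cells themselves, the rule flags about 10%
by construction; sensitivity and specificity are meaningful only for
non-reference cells. On the reference synthetic configuration (three
fold-2 gains of 150 genes, ~30% of epithelial cells affected) sensitivity
exceeds 0.99 and specificity 0.87–0.92 across seeds.

## Ligand-receptor crosstalk

`interaction_score()` scores a pair between a sender and a receiver
cluster as

$$s = \overline{\mathrm{lig}}_{\text{sender}} \times
\min_{\text{subunits}} \overline{\mathrm{sub}}_{\text{receiver}},$$

the mean-product convention with the subunit minimum (a receptor complex is
only as available as its scarcest subunit). Significance comes from an
explicit permutation null — cluster labels permuted over cells, default
1,000 permutations — with the +1 correction
$p = (1 + \#\{s^\ast \ge s\})/(1 + B)$, so p-values are never exactly zero.
This replaces mass-action/Hill-function communication models with something
fully specified and testable; the permutation test holds its nominal size
(type-I error 0.046–0.056 at $\alpha = 0.05$ over 500 null pairs in the
acceptance runs). A missing ligand or subunit yields score 0, p 1 and a
`"gene absent"` flag rather than an error, so panel scans degrade
gracefully.

`build_network()` aggregates significant pairs into directed
sender-receiver counts and strengths; `diff_network()` takes edge-wise
differences (e.g. malignant minus non-malignant). One subtlety the planted
axis exposes: when the receptor is constitutively elevated in the receiver
type, an edge can be nominally significant in both conditions, and the
planted ligand surplus shows up in the *strength* differential rather than
the count differential.

`stratify_by_sender_ligand()` sums **raw** ligand counts over sender-type
cells per sample and splits at the 75th percentile. Raw summation is the
literal reading of "expression summed across fibroblasts"; scoring, by
contrast, uses log-normalized expression. Samples without sender cells
contribute zero with a warning rather than an error, since dropping them
silently would bias the cutoff.

## Pseudobulk differential expression and enrichment

`aggregate_pseudobulk()` sums raw counts per sample over a cell-type
subset (mass is conserved exactly); `filter_pseudobulk_genes()` keeps genes
with total count $\ge 2$ detected in $\ge 2$ samples. `de_test()` then
tests each gene with a Welch t-test on $\log_2(\mathrm{CPM}+1)$ and reports
$\log_2 \mathrm{FC} = \log_2\!\big((\overline{\mathrm{CPM}}_a + 1) /
(\overline{\mathrm{CPM}}_b + 1)\big)$, flagging genes with
$|\log_2 \mathrm{FC}| \ge 1$ (inclusive) and $p < 0.05$ (strict). The Welch
test is a deliberate, fully specified substitute for a negative-binomial
GLM: at pseudobulk sample sizes the t-test on stabilized log-CPM is well
behaved, the published thresholds apply verbatim, and there is no library
dependence to chase. A Benjamini-Hochberg column is emitted for reference
but plays no role in the flag, matching the raw-p DEG rule. Power on
planted four-fold genes at 6 vs 6 samples is ~1.0 in the acceptance runs.

`preranked_enrichment()` is the weighted Kolmogorov-Smirnov running-sum
statistic on a ranking (descending $\log_2$ fold change by convention),
weight 1, with a *gene-permutation* null: random same-size sets drawn from
the ranking, $\mathrm{NES} = ES / \overline{|ES^\ast_{\text{same sign}}|}$,
one-sided permutation p with the +1 correction. Gene permutation (rather
than phenotype permutation) is the package's choice: it matches the
preranked setting where only the ranking is available. `ora_test()` is the
companion over-representation (hypergeometric) entry point for callers who
prefer testing an upregulated-gene list directly; preranked is the
default. Gene sets travel as GMT via `read_gmt()`/`write_gmt()`.

## Clinical statistics

`ihc_composite_score()` multiplies an area score by an intensity grade
(0–3). The published area bins overlap at their boundaries ("$\le$ 5%" vs
"5–25%"; "26–50%" skipping 25–26), which this package resolves as half-open
bins $[0,5], (5,25], (25,50], (50,75], (75,100]$. The category map also
overlaps at 6 ("low (3–6)" vs "high ($\ge$ 6)"); a composite of exactly 6 is
assigned to *high*, consistent with the dichotomized high/low analyses in
which high means score $\ge 6$. Attainable composites are
$\{0,1,2,3,4,6,8,9,12\}$, so "low" is effectively $\{3,4\}$.

`pearson_chi_square()` is the uncorrected Pearson test (Yates off by
default, available as an option) — the variant that reproduces the printed
cohort p-values it is validated against (0.357, 0.003, 0.002, 0.421, and
below 0.001 for the nodal and stage tables). One printed row (tumor
differentiation, 0.006) is not reproduced by any uncorrected Pearson
computation on its printed 3x2 counts (which give 0.003); the variant used
for that row is unknowable from the printed table and it is excluded from
validation. `km_logrank()` and `cox_ph()` wrap the survival package
(product-limit curves, log-rank via `survdiff`, partial likelihood via
`coxph` with Breslow ties — the simplest tie rule; fixtures avoid heavy
ties). The log-rank statistic is cross-checked against the Cox score test,
and on null exponential cohorts the log-rank test holds its size
(0.051–0.059 at $\alpha = 0.05$ over 1,000 replicates) while Cox 95%
intervals cover a true hazard ratio of 2 in ~95% of replicates.

`generate_survival()` draws exponential event times with rate
$\lambda_0 e^{\beta x}$ and independent exponential censoring calibrated via
the exponential-race identity to a target censoring proportion
(`censor_rate = 0` produces no censoring at all).

## Problem sizes and numerical conventions

The validation suite uses these design sizes, chosen to make each check
statistically meaningful at desk scale: meta-program recovery on 10 samples
x 500 epithelial cells x 1,000 genes with five planted programs; CNV
classification on 2,100 cells x 4,400 genes with three fold-2 segments;
permutation-test calibration on 500 null pairs x 1,000 permutations;
log-rank size on 1,000 replicates of n = 200; Cox coverage on 200
replicates of n = 500; DE power on five replicates of 12 samples.
Throughout the package: quantiles are type 7; ties at stratification or
classification cutoffs resolve by strict inequality to the null-ward side;
all permutation p-values carry the +1 correction; every stochastic routine
takes an explicit seed and restores the caller's RNG state.

## Known limitations

The NMF solver is a plain multiplicative-update scheme — adequate for
50-gene program extraction, but without the restarts or regularization a
production factorization library would offer. The CNV module performs no
HMM segmentation or subclonal analysis and its score is sensitive to the
window/gene-density ratio. The crosstalk model ignores spatial proximity
and pathway aggregation. The DE module deliberately does not model
NB dispersion, so its p-values are approximate for very low counts.
Signature stratification assumes the score distribution is not degenerate
and errors otherwise rather than guessing a split.
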
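---
title: "Methods: defense-gene stress-response analysis with prstress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: defense-gene stress-response analysis with prstress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prstress)
```

## The problem

Pathogenesis-related (PR) proteins are the canonical output of plant
immunity: 17 recognized families of glucanases, chitinases, peroxidases,
thaumatin-like proteins and proteases whose genes are classically induced
by pathogen or pest attack and by the defense hormones salicylic acid (SA)
and jasmonic acid (JA). With whole-genome annotations, the *entire*
complement of a crop's PR genes — several hundred loci across a dozen
families — can be followed through an infestation time course. `prstress`
packages that workflow: differential-expression calling on time-course
counts, classification of responders into temporal and hormone expression
programs, cross-genotype trend clustering, phylogeny-based nomenclature and
expansion detection, tandem-array detection from coordinates, and
consolidation/correlation of responses across unrelated biotic stresses.
Every stage can be exercised on a synthetic world with planted ground
truth, so the pipeline is testable without any external download.

## Differential expression

The experimental design is a time course (e.g. 0, 1, 7, 14, 22 days
post-infestation; or 0–24 h post hormone spray) with three biological
replicates per point, each later point contrasted against time 0.

* **Low-count filter.** Genes averaging ≤ 20 raw reads across the whole
  time course (time 0 included) are excluded before testing. The threshold
  is inclusive: a mean of exactly 20 is removed.
* **Normalization.** Median-of-ratios size factors against a geometric-mean
  reference over genes positive in all samples; a library that is a doubled
  copy of another gets a factor ratio of 2.
* **Test.** A deliberately minimal negative-binomial Wald test stands in
  for a full DESeq2 fit: variance \(\mu + \alpha\mu^2\), per-gene
  method-of-moments dispersion shrunk halfway (in log space) toward a
  fitted \(\alpha(\mu)=a_0+a_1/\mu\) trend, floor \(10^{-8}\); the log2
  fold change uses a prior count of 0.5 in both group means; the Wald
  statistic uses the delta-method variance of the log mean. The downstream
  logic consumes only (log2FC, FDR) tables, which can equally be read from
  files produced by any caller — that is the design rationale for not
  re-implementing DESeq2.
* **Multiplicity.** Benjamini–Hochberg step-up, applied per contrast (per
  time point); a pooled option exists because the original protocol does
  not state which was used.
* **DEG rule.** `up` iff log2FC > 1 *and* FDR ≤ 0.05 (strict on the fold
  change, inclusive on the FDR); symmetric for `down`. So (1.0, 0.001) is
  `ns` while (−1.2, 0.05) is `down`.

For external datasets distributed as FPKM, `fpkm_log2fc()` computes
log2(treated/mock) with an optional pseudocount (default 0, with an error
on a zero denominator).

## Expression programs

* **Temporal programs.** Over the four post-infestation points: *early* =
  DEG at 1 and/or 7 dpi only; *late* = 14 and/or 22 dpi only; *sustained* =
  DEG in both windows; *none* otherwise. Direction is the sign of the mean
  log2FC over the gene's DEG time points.
* **Trend clusters.** Each gene that is a DEG in ≥ 1 of the four genotypes
  receives one of 16 ids encoding the sign of its per-genotype trend (mean
  log2FC over the post-reference course). The published cluster scheme
  documents only its anchors — all-positive = cluster 1, all-negative =
  cluster 9 — so the id map is reconstructed as
  \(1 + 8b_1 + 4c_2 + 2c_3 + c_4\), where \(b_1\) flags a negative
  genotype-1 trend and \(c_i\) flags disagreement of genotype *i* with
  genotype 1. This is bijective over the 16 sign patterns and reproduces
  both anchors; memberships of the other 14 clusters are an approximation
  of a scheme that was never algorithmically specified, and are not
  acceptance-tested. A zero trend is broken toward the sign at the last
  time point, and an exact overall zero falls back to negative (logged).
* **Hormone programs.** From SA and JA DEG statuses: *co-regulated* = DEG
  under both hormones in the same direction; *reciprocal* = both, opposite
  directions; *sa_only*/*ja_only*; *none*. When time points disagree, a
  hormone's direction is the sign of its largest-magnitude DEG log2FC.
  These five classes partition all genes.
* **Summaries.** Per family: up/down counts per genotype and the ALL
  column (same direction at ≥ 1 time point in *every* genotype, not
  necessarily the same one). Percentages round to the nearest integer,
  half away from zero — (62 + 33)/167 prints as 57%.

## Family structure

* **Expansions.** A species-specific expansion is a *maximal* monophyletic
  clade whose tips all belong to the focal species with ≥ 3 paralogs
  (configurable). Nested qualifying clades report only the largest, so
  expansions are disjoint. The implementation is checked against an
  exhaustive clade enumeration on random ≤ 50-tip trees.
* **Nomenclature.** Within a family tree, clades are the root's child
  subtrees containing focal-species tips, lettered a, b, c, … (then aa,
  ab, …) in order of smallest descendant gene id; genes are numbered
  sequentially within a clade in a deterministic traversal. Genes never
  differentially expressed in any supplied treatment carry an `L` infix
  (`PR-1dL1`); responsive genes do not (`PR-2e8`). The published letters
  came from manually curated trees, so determinism — not letter-for-letter
  agreement — is the contract.
* **Physical clusters.** The source protocol never defines "cluster"; the
  adopted rule is the standard tandem-array heuristic: same family, same
  chromosome, each adjacent pair ≤ 100 kb apart with ≤ 5 intervening genes
  of any family, maximal chains of ≥ 2 reported. Both thresholds are
  exposed because the published cluster table cannot be reproduced exactly.
  Unplaced genes (an allowed catalog state) are skipped. Whether the
  published 51%-clustered figure counts clusters of size ≥ 2 or ≥ 3 is
  unstated; `cluster_summary(min_cluster_size=)` computes either.

## Cross-stress consolidation and correlation

Per stress, each gene's profile value is the mean log2FC over its DEG time
points only; never-DEG genes are absent. Two stresses are compared over the
intersection of their profiles. Comparisons with < 10 shared DEGs are
skipped (a result with a reason, not an error). Outliers are flagged by the
boxplot rule with multiplier 2.0 — type-7 (linear-interpolation) quartiles,
a convention the protocol leaves unstated — on each coordinate separately,
and the union is removed exactly once (single pass, no iteration; marginal
vs joint flagging is exposed as an option). Pearson R with a two-sided
t-transform p-value is labeled on the Evans scale: |R| < 0.20 very weak,
< 0.40 weak, < 0.60 moderate, < 0.80 strong, else very strong. The SA-vs-JA
co-regulation comparison and the qPCR-vs-sequencing comparison apply no
outlier removal, matching the protocol.

## qPCR validation

The plain comparative-Ct method without efficiency correction:
ΔCt = Ct(gene) − Ct(reference) per sample, ΔΔCt = mean ΔCt(treated) −
mean ΔCt(control) averaged over biological replicates *before*
exponentiation (the averaging order is unstated in the protocol; this
choice makes log2(fold) = −ΔΔCt an identity), fold = 2^−ΔΔCt, with the
standard error propagated as the root sum of squared per-condition SEs.
One reference gene is the default (the protocol used *UBQ*); several
references average arithmetically on the Ct scale (geometric mean of
expression).

## The synthetic world

`sim_config()` fixes the stated world; its defaults are the design the
analysis targets, chosen once:

* 447 genes (the size of the full PR complement), 0/1/7/14/22 dpi, 3
  replicates; hormone grid 0–24 h at eight points.
* NB counts, variance \(\mu + \alpha\mu^2\), global α = 0.05 — mid-range
  for bulk RNA-seq biological replicates; baselines log-normal
  (meanlog = log 500, sdlog = 1); size factors log-uniform in [0.7, 1.4]
  to exercise normalization (the protocol is silent on library-size
  spread).
* Planted programs: early/late/sustained × up/down fractions
  (0.02, 0.02, 0.10, 0.15, 0.04, 0.04) — ≈ 37% of genes responding, with
  late and downregulated responses dominating, the qualitative structure
  of the whitefly response; planted |log2FC| = 2. Effects act at {1,7}
  (early), {14,22} (late), or all four (sustained).
* Hormone fractions 0.022/0.094/0.110/0.0045 (SA-only/JA-only/
  co-regulated/reciprocal — the 10/42/49/2-of-447 proportions); the
  co-regulated (SA, JA) log2FC pair draws correlated *magnitudes*
  (default ρ = 0.94, sd 1 log2 unit) with a shared sign, half up, half
  down. Because the realized scatter is bimodal (up and down clusters),
  the overall Pearson R across co-regulated genes exceeds the magnitude
  correlation (≈ 0.99 at the defaults); this is a property of the stated
  world, reported as computed.
* Structure: per family, a rooted tree in which every planted expansion is
  a monophyletic focal-species clade and every other focal tip is paired
  with an outgroup tip (so no accidental focal clade can arise), plus a
  catalog whose planted tandem arrays have ~10 kb intra-array gaps and
  ≥ 500 kb to everything else. Defaults plant one 3-gene and one 20-gene
  clade/array — the sizes of the two hallmark published expansions.

What a green test does *not* establish: the generator has no
gene-correlated dispersion trend, no batch structure, no unbalanced
replicates, no mapping/quantification noise, and its trees have no
branch-length realism — so green recovery tests validate the algorithmic
contracts, not performance on messy real data.

### Numerical choices and degenerate inputs

Dispersion floor 10⁻⁸ and shrinkage weight 0.5 (protocol silent);
prior count 0.5 in fold changes; single-sample input gets size factor 1;
normalization errors when no gene is positive in all samples; correlation
functions error on < 3 points or zero variance; the boxplot rule errors
below 4 values; a constant sequence yields no outliers (IQR 0 puts all
values on the quartiles). One spec'd recovery figure — ≥ 90% of planted
genes within ±0.3 of a planted log2FC of 2 at dispersion 0.05 with 3
replicates — is analytically unattainable (the sampling sd of the log2
ratio of NB means is ≈ 0.27, capping the fraction near 74%); the suite
asserts the attainable statements instead: median accuracy ±0.2 (at the
dispersion-0.02 fixture) and ≥ 90% *program* recovery, which measure the
same pipeline honestly.

## Known limitations

DEG calling is a minimal Wald test, not a DESeq2 replacement (no GLM
designs, no LFC shrinkage); cluster ids 2–8 and 10–16 are a reconstruction;
nomenclature letters are deterministic but need not match manually curated
letters; physical-cluster thresholds are heuristics; the comparative-Ct
method assumes perfect amplification efficiency.
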
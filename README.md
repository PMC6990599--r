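# prstress

Genome-wide stress-response analysis of plant defense (pathogenesis-related,
*PR*) gene families from time-course RNA-seq.

Plant genomes carry hundreds of *PR* genes across up to 17 families
(glucanases, chitinases, thaumatin-like proteins, proteases, peroxidases,
…). During pest or pathogen attack, and after treatment with the defense
hormones salicylic acid (SA) and jasmonic acid (JA), subsets of these genes
are induced or repressed with characteristic timing. `prstress` implements
the full analysis chain for such a survey, for researchers who have
per-sample count tables, family trees and gene coordinates and want
reproducible program-level summaries:

* **DEG calling** on negative-binomial time-course counts: inclusive
  low-count filter (mean ≤ 20 reads), median-of-ratios normalization, a
  minimal NB Wald test per time point vs time 0 with trend-shrunk
  method-of-moments dispersion, Benjamini–Hochberg FDR, and the field's
  threshold rule — a DEG has |log2FC| > 1 and FDR ≤ 0.05.
* **Program classification**: temporal programs (*early* = DEG at 1 and/or
  7 dpi, *late* = 14 and/or 22 dpi, *sustained* = both), the 16
  cross-genotype trend clusters (cluster 1 = positive trend in all four
  genotypes, cluster 9 = negative in all four), and hormone programs
  (SA-only / JA-only / co-regulated / reciprocal).
* **Family structure**: species-specific expansions (maximal monophyletic
  clades of ≥ 3 focal-species paralogs), clade-letter nomenclature with the
  `L` infix for never-responsive ("PR-Like") genes, and tandem physical
  clusters from BED/GFF3 coordinates.
* **Cross-stress comparison**: per-stress profiles (mean log2FC over each
  gene's DEG time points), family attribution tables, and Pearson
  correlations gated at ≥ 10 shared DEGs with single-pass boxplot-rule
  (k = 2.0) outlier removal and Evans strength labels.
* **qPCR validation**: comparative-Ct fold changes (2^−ΔΔCt) and
  platform-concordance correlation.
* **A synthetic-data module** that generates all of the above inputs with
  planted ground truth (NB counts with planted DEG programs, paired SA/JA
  responses with tunable co-regulation, trees with planted expansions,
  chromosomes with planted tandem arrays), so the whole pipeline is
  testable end to end without external data.

## Worked example

```r
library(prstress)

cfg <- default_config(seed = 1, n_genotypes = 4, n_genes = 200L)
res <- run_pipeline(cfg, out_dir = "demo_out")

res$summary$n_degs
#> [1] 74
res$summary$cluster1_n; res$summary$cluster9_n; res$summary$conserved_pct
#> [1] 17
#> [1] 27
#> [1] 59
r <- res$coreg_correlation
sprintf("coreg R = %.2f (p = %.2g, n = %d, %s)", r$R, r$p, r$n, r$strength)
#> [1] "coreg R = 0.98 (p = 1.3e-13, n = 19, very strong)"
res$expansions$size
#> [1]  3 20
res$cluster_summary$overall_pct
#> [1] 56
sprintf("qPCR concordance R = %.2f (%s)", res$concordance$R, res$concordance$strength)
#> [1] "qPCR concordance R = 0.99 (very strong)"
```

Reading: of 200 simulated genes, 74 (37%) responded to the simulated
infestation in at least one of four genotypes; 44 of them (59%) trended the
same way in all four (17 up in cluster 1, 27 down in cluster 9) — the
generator plants a 57%-conserved responder set, and the pipeline recovers
it. The SA/JA co-regulated genes show a very strong positive correlation
between hormone responses. The structure stage recovers exactly the planted
3-gene and 20-gene family expansions and the planted 20-gene tandem array
(56% of catalog genes clustered). Every output table lands in `demo_out/`
with a manifest hash header; `demo_out/manifest.json` records config, seed,
row counts and checksums, and re-running with the same seed reproduces all
outputs byte for byte.

Real data enter through `read_counts()` + `call_degs()`, or directly as
(log2FC, FDR) tables via `read_deg_table()` (statuses are always recomputed
from the thresholds, never trusted from the file), plus `read_tree()`,
`read_gene_coords()` and `read_catalog()`.

## Command line

```sh
Rscript inst/cli/prstress run --seed 1 --out run_out
Rscript inst/cli/prstress simulate --seed 3 --out sim_out
Rscript inst/cli/prstress call-degs --counts counts.tsv --meta counts.tsv.meta.tsv \
    --condition WF --out degs.tsv
Rscript inst/cli/prstress qpcr --ct ct.tsv --ref-gene UBQ --out qpcr.tsv
```

## Documentation

`vignettes/prstress-methods.Rmd` describes the statistical model, every
tunable threshold and its default, what the synthetic world does and does
not emulate, and the package's design decisions.
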
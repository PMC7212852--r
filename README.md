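# invadome

Regional differential proteomics of the glioblastoma tumor core versus its
invasive rim.

Glioblastoma has two faces: a vascularized, "angiogenic" core and an
invasive rim that infiltrates normal brain and escapes both resection and
anti-angiogenic therapy. In patient-derived xenografts the tumor cells are
human and the stroma is mouse, so label-free quantitative (LFQ) proteomics
of laser-microdissected core (condition `A`) and rim (condition `I`) tissue
yields two species-resolved proteomes per experiment, each measured over 3
biological samples x 3 technical replicates (9 columns per condition).

`invadome` is the downstream analysis pipeline for such tables, for
proteomics analysts and computational biologists who have protein-level
quantifications in hand (raw spectra processing is out of scope):

1. **Reproducibility filter** — per-triplicate coefficient of variation
   `CV = σ/μ`; a protein is kept only if every defined CV is below 0.8 in
   both conditions (`cv_filter()`).
2. **Presence aggregation** — keep proteins present in ≥ 6 of 9 columns per
   condition; flag the "common" subset present everywhere
   (`aggregate_presence()`).
3. **Normalization / imputation** — median-ratio column scaling; missing
   cells imputed at the column 1st percentile for clustering only
   (`median_ratio_normalize()`, `impute_missing()`).
4. **Differential expression** — per-protein Welch t-test (I vs A),
   Benjamini–Hochberg adjustment, `log2FC = log2(μ(I)/μ(A))`, with nested
   tiers padj < 0.01, |log2FC| > 1 (enrichment) and |log2FC| > 2 human /
   > 5 mouse (clustermap) (`diff_expr()`).
5. **Clustering** — Ward-D2 / Euclidean dendrograms with bootstrap branch
   probabilities, z-scored clustermap of the strong hits
   (`bootstrap_support()`, `clustermap_export()`).
6. **Over-representation analysis** — hypergeometric test of the hit list
   against GMT gene sets over the detected-proteome universe (`ora_test()`).
7. **Interaction network** — STRING-style edges, confidence > 0.4, MCL
   clustering written from scratch (`mcl_cluster()`).
8. **AngioScore** — per gene, the percentage of its publication abstracts
   containing an angiogenesis keyword; core vs invasive top-30 comparison
   (`angioscore()`, `compare_groups()`).

A synthetic dual-species generator with planted ground truth
(`simulate_quant()`, `simulate_corpus()`) makes the whole pipeline testable
offline. See `vignettes/invadome-methods.Rmd` for the model, parameter
choices and limitations.

## Worked example

```r
library(invadome)

sim <- simulate_quant(sim_config(seed = 1))   # 750 human + 520 mouse proteins
sim$table
#> quant_table: 1270 proteins (750 human, 520 mouse) x 18 columns
#>   conditions: A, I | missing cells: 2060 (9.0%)

cvf <- cv_filter(sim$table)                   # CV < 0.8 in both conditions
agg <- aggregate_presence(cvf$table)          # >= 6 of 9 per condition
de  <- diff_expr(median_ratio_normalize(agg$table))
de_summary(de)
#>   species   direction significant enrichment_hit clustermap_hit
#> 1   human     core-up          28             28             18
#> 3   human invasive-up          56             56             39
#> 2   mouse     core-up          20             20              0
#> 4   mouse invasive-up          45             43              8
```

The funnel here is 1270 → 1033 (CV filter) → 918 (aggregation), with 569
proteins common to all 18 columns. Against the generator's planted truth
this run detects 89% of the planted effects with a log2FC RMSE of 0.19.
The counts are hit tiers per species and direction: e.g. 18 human proteins
are core-up at padj < 0.01 with |log2FC| > 2 and would appear in the
clustermap.

```r
genes <- sprintf("G%02d", 1:60)
corp <- simulate_corpus(genes, core_genes = genes[1:30],
                        invasive_genes = genes[31:60], seed = 1)
compare_groups(angioscore(corp), genes[1:30], genes[31:60])
#> AngioScore comparison (n = 30 core, 30 invasive genes)
#>   mean core 29.05%  mean invasive 20.43%  ratio 1.42
#>   Welch t = 13.594, df = 51.8, p = 1.02e-18
```

With keyword rates 0.3 (core genes) vs 0.2 (background) the core hit list
scores ~1.5x higher, the signature of an angiogenesis-biased core.

`run_pipeline()` chains all stages and writes deterministic TSV/Newick
outputs per species; `inst/cli/invadome` exposes the same stages as a
command line (`invadome simulate|filter|diffexp|cluster|enrich|network|
angioscore|run-all`).

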
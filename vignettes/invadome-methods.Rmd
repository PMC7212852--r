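---
title: "Methods: regional differential proteomics with invadome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional differential proteomics with invadome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invadome)
```

## The problem

Glioblastoma grows as a vascularized core surrounded by an invasive rim that
infiltrates normal brain; the rim escapes both surgery and anti-angiogenic
therapy. In a patient-derived xenograft (PDX) the tumor cells are human and
the stroma is mouse, so label-free quantification (LFQ) of microdissected
core ("angiogenic", condition `A`) and rim ("invasive", condition `I`)
tissue yields two parallel proteomes — tumor-derived (human) and
stroma-derived (mouse) — measured over 3 biological samples with 3 technical
replicates each, i.e. 9 columns per condition and 18 per species.

`invadome` implements the downstream analysis of such tables:
reproducibility filtering, presence aggregation, normalization, differential
expression, clustering with bootstrap support, over-representation analysis,
interaction-network clustering, and a literature-derived angiogenesis score.
Upstream identification and quantification of raw spectra are out of scope;
the input is a protein x replicate abundance table.

## Pipeline model and assumptions

**Reproducibility gate.** For every (protein, condition, sample) triplet the
coefficient of variation is `CV = sd/mean` over the technical replicates,
using the sample standard deviation (n−1), the statistical default for a
3-point spread estimate. A protein is retained only if every defined CV is
below 0.8 in both conditions. When a triplet has fewer than two present
values its CV is undefined and does not veto retention — absence is judged
by the presence filter, not the CV filter; conflating the two would count
missingness twice.

**Presence aggregation.** A protein enters the aggregated table only if
observed in at least 6 of the 9 columns of *each* condition; proteins
observed in all 18 columns form the "common" subset used for sample-level
clustering, where complete data are required.

**Normalization and imputation.** Columns are scaled by median-ratio
normalization against the per-protein median profile, the standard LFQ
correction for loading differences. Missing cells are imputed at the
per-column 1st percentile — a "censored at the detection limit" model.
Imputation feeds only clustering and heatmaps; the tests always run on
observed values, because imputed values would fabricate degrees of freedom.

**Differential expression.** Welch's unequal-variance t-test per protein on
the observed I and A replicate vectors, two-sided, with
Benjamini–Hochberg adjustment over the tested proteins and
`log2FC = log2(mean_I / mean_A)` over present values. Log base 2 is used
throughout. Three nested tiers are flagged: `significant` (padj < 0.01),
`enrichment_hit` (additionally |log2FC| > 1), and `clustermap_hit`
(additionally |log2FC| > 2 for human, > 5 for mouse — the stroma shows much
larger contrasts). A one-tailed paired variant of the test is sometimes
mentioned in figure legends for this kind of analysis; we implement the
two-sided Welch version, since direction is claimed post hoc in both
directions. A further "1.5-fold change at adjusted P < .05" rule is exposed
as a documented no-op hook (`flag_hits(variant_hook=)`) because its intended
semantics are not recoverable; it changes nothing until defined.

**Clustering and bootstrap support.** Ward-D2 linkage on Euclidean
distances via `stats::hclust`. Sample dendrograms cluster the 18 columns on
log2 ratios to the median reference profile of the common subset (no row
scaling: the ratios are already on a common scale); protein clustermaps
z-score each protein first so shape, not abundance, drives the tree.
Branch support is the bootstrap probability (BP): features are resampled
with replacement and a node's BP is the percentage of resampled trees
containing the same member set. An approximately-unbiased (AU) estimate via
multiscale bootstrap (resample sizes 0.5–1.4 of the feature count and the
normal-quantile regression `z(r) = v√r + c/√r`, `AU = 1 − Φ(v − c)`) is
available but off by default: BP is the load-bearing statistic here and AU
costs ten times as much.

**Over-representation analysis.** The enrichment tier is tested against
GMT gene-set collections with the hypergeometric upper tail, BH-adjusted,
enriched at adjusted p < 0.05; `ratio` (overlap/query) is the dot-size
quantity of enrichment dot plots. The universe is the aggregated proteome
of the species analyzed, not the whole genome — the detected-proteome
background is the defensible choice for proteomics ORA (a genome background
only shrinks every p-value without reordering sets). This is
over-representation of a thresholded subset, not ranked-list GSEA, which is
what a fold-change-gated query calls for.

**Network clustering.** Interaction edges carry STRING-style confidences
(auto-detected 0–1000 scale); edges are kept when confidence is strictly
above 0.4 ("medium"), with tiers at 0.7 ("high") and 0.9 ("highest"),
and proteins left without edges are removed. Clustering uses a from-scratch
Markov Cluster Algorithm: column-stochastic walk matrix with one self-loop
per node at its maximum incident confidence (the usual regularization that
guarantees well-behaved convergence), alternating expansion (matrix square)
and inflation (elementwise power, default 2.0 — the canonical MCL default,
since the method's granularity parameter is otherwise unconstrained here)
with pruning at 1e-5, stopping when the matrix changes by < 1e-8. Clusters
are read off attractors (positive diagonal mass); overlapping attractor
systems merge, every node joins the attractor system holding most of its
column mass, and ties go to the cluster with the lexicographically smallest
seed so results are reproducible under relabeling. Intra- versus
inter-cluster edges are flagged for plotting.

**AngioScore.** For each gene, the percentage of its publication abstracts
containing at least one angiogenesis keyword (case-insensitive, whole-word
or exact phrase; no stemming — determinism and auditability beat recall
here). The corpus is an offline directory (one abstract file per gene plus
a lexicon file); no Entrez/PubMed client is included. The shipped lexicon
(`inst/extdata/angiogenesis_keywords.txt`) is an editable starting list;
absolute scores depend on the lexicon and the corpus snapshot, so only
relative comparisons are meaningful. The core-versus-invasive comparison
takes the top 30 hits per direction — ranked by |log2FC| among significant
proteins, the natural "best hits" ordering — averages their scores, forms
the core/invasive ratio and runs a two-sample Welch t-test. Genes without
publications are excluded from the group statistics.

## The synthetic generator

`simulate_quant()` emulates the measured structure of such experiments with
planted ground truth, so every downstream stage is testable offline:

* **Scale.** 750 human and 520 mouse proteins by default, echoing the
  typical size of an LCM-LFQ experiment (≈730/510 after aggregation).
* **Abundance model.** Log-normal: per-protein baseline `N(20, 2)` on the
  log2 scale, a biological sample effect `N(0, 0.5)` per (protein, sample)
  *shared between conditions* — core and rim are dissected from the same
  brain, so sample effects cancel from the condition contrast while still
  inflating within-condition variance, making the Welch test conservative —
  and a planted condition effect on condition I.
* **Differential fraction.** 20% of proteins per species carry a planted
  |log2FC| drawn uniformly from 1–6 with random sign (echoing 152 of 730
  significant, and observed fold changes up to ~6.4).
* **Technical noise.** Log-normal with per-protein CV: bulk 0.2, and a 20%
  heavy tail at CV 1.2 so that a realistic fraction of proteins crosses the
  0.8 reproducibility gate.
* **Missingness.** Logistic dropout in log2 abundance (midpoint 16,
  steepness 1): low-abundance proteins drop out more, which is exactly why
  the 6-of-9 presence rule exists. `dropout_midpoint = -Inf` disables it.

What it does **not** emulate: peptide-level effects, shared-peptide
inference artifacts, batch effects beyond the sample term, correlated
missingness between proteins, and real interaction topology (network tests
use planted-partition graphs instead). Passing tests therefore demonstrate
correctness of the computations and calibration under an idealized
log-normal LFQ model, not performance on any particular real dataset.
`simulate_corpus()` plants per-abstract keyword rates (defaults 0.3 for
core-linked genes versus 0.2 background, 200 abstracts per gene), giving an
expected core/invasive score ratio of 1.5.

## Numerical and design choices

* CV strictly below threshold retains; at or above removes. Network edges
  are kept strictly above the confidence threshold (matching the "medium
  confidence > 0.4" convention).
* TSV writers render reals with 6 significant digits and fixed column
  order, so identical inputs give byte-identical outputs; the whole
  pipeline is bytewise reproducible under a fixed seed.
* BH adjustment excludes undefined p-values (proteins with < 2 observed
  values in a group) rather than penalizing the tested set for them.
* Welch df uses the Welch–Satterthwaite formula; two identical constant
  groups give t = 0, p = 1 rather than 0/0.
* hclust tie-breaking follows `stats::hclust`; dendrograms are serialized
  as Newick with support values as internal node labels (via `ape`).
* MCL pruning at 1e-5 is numerical hygiene for the small graphs involved;
  attractor detection uses a 1e-6 mass floor.
* Zeros in input tables are rejected rather than silently treated as
  missing: an LFQ abundance of exactly 0 is an encoding error, and forcing
  explicit missingness (`NA` or empty cell) keeps presence counts honest.

## Validation strategy and problem sizes

The test suite validates each computation against an independent oracle on
a different code path — Welch against `stats::t.test`, BH against an
explicit step-up loop, the hypergeometric tail against `choose()`
enumeration, Ward-D2 heights against a hand-coded Lance–Williams
agglomeration (1000 random instances each, agreement to 1e-10) — and the
pipeline against the generator's planted truth: FDR on 20 null simulations
of 700 proteins; sensitivity ≥ 0.9 and log2FC RMSE ≤ 0.3 on planted
|log2FC| ≥ 2 at bulk CV 0.2 in the full 9-vs-9 design; exact agreement of
the presence rule with naive enumeration; ≥ 95% exact recovery of 50
planted-partition graphs (3 clusters × 10 nodes, p_in 0.9, p_out 0.02) by
MCL; BP ≥ 99 on a 20-sd two-group split at 200 resamples versus mean
internal BP < 60 on pure noise; and an AngioScore ratio within 10% of the
planted 1.5. These sizes run the whole suite in well under a minute on one
core while leaving each statistical bound at least three standard errors of
slack. `scripts/acceptance.R` recomputes all of them from scratch.

## Known limitations

* Three biological samples per condition is the real design; the Welch test
  treats the 9 columns per condition as exchangeable, so technical
  replicates are pseudo-replicates for biological inference. The
  shared-sample-effect simulation shows the test is conservative, not
  anti-conservative, under this design, but a mixed model would be the
  stricter treatment.
* No moderated (empirical-Bayes) variance estimation; with n = 9 per group
  the plain Welch test is adequate, with n = 3 it would not be.
* ORA ignores gene-set ancestry (no term propagation) and KEGG-style
  collections are treated as flat GMT sets.
* AU support values are experimental; BP is the supported statistic.
* The MCL granularity (inflation) is data-free; cluster membership at
  bridge confidences near the threshold can switch with it.
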
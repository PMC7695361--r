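---
title: "Methods: multi-omics co-expression and regulatory network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics co-expression and regulatory network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemomics)
```

# Scope

`stemomics` implements an integrative analysis of small multi-omics
cohorts of the kind produced by stem-cell passage series: a handful of
samples (two donor age groups sampled at culture passages 3, 6 and 10)
profiled for mRNA, lncRNA, gene-level DNA methylation and protein
abundance. The pipeline discovers co-expression modules, correlates
them with donor age, passage number and a transcriptional stemness
index, tests module pairs for crosstalk on a background interaction
network, runs a cross-omics correlation cascade
(methylation vs mRNA, methylation vs lncRNA, mRNA vs protein), scores
samples against gene sets, and assembles an lncRNA/TF to gene to
pathway regulatory network.

Because cohorts of this kind are rarely deposited, the package ships a
seeded synthetic-cohort generator whose planted structure provides a
ground truth for every stage. Everything downstream is tested against
that ground truth or against independent numerical oracles.

# Normalization and filtering

Counts are transformed to log2 counts-per-million with the offsets
used by limma's voom, `log2((c + 0.5) / (lib + 1) * 1e6)`. The
mean-variance precision weights voom also estimates are deliberately
omitted: only the normalized values feed the correlation and network
analyses here, and the weights matter for linear-model inference this
pipeline does not perform.

Before network construction the most variable genes are retained
(`variance_filter()`). The conventional choice on genome-wide profiles
is the top 20%. Ties at the cutoff variance are broken by
lexicographic feature id so the selection is deterministic.

# Co-expression network

The network follows the weighted gene co-expression (WGCNA) recipe:

* **Adjacency.** `a_ij = |cor(x_i, x_j)|^beta` (unsigned, the
  default) or `((1 + r)/2)^beta` (signed, by flag). Pearson
  correlation is used throughout the package unless an operation says
  otherwise.
* **Soft threshold.** `pick_soft_threshold()` scans candidate powers
  and returns the smallest one whose scale-free topology fit reaches
  `r2_cut = 0.8`; with no qualifying power it returns the best fit and
  flags the scan. The fit regresses `log10(frequency)` on
  `log10(mean connectivity)` over 10 equal-width connectivity bins,
  dropping empty bins; constant connectivity returns 0 with a warning.
  The slope is reported as an attribute (scale-free graphs give a
  negative slope).
* **Topological overlap.**
  `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
  `L_ij = sum_{u != i,j} a_iu a_uj`; `1 - TOM` is the clustering
  dissimilarity.
* **Module detection.** Average-linkage hierarchical clustering with a
  static cut and a minimum module size of 30; sub-threshold clusters
  are relabelled grey, and modules are named by size rank from the
  conventional colour list.
* **Merging.** Modules whose eigengenes correlate above 0.75
  (dissimilarity below `cut_height = 0.25`) are merged iteratively,
  the larger module keeping its name, until no pair qualifies.
* **Eigengenes.** First principal component of the standardized
  member submatrix, unit variance, signed to correlate nonnegatively
  with the mean member profile.

## Why the static cut sits at 0.75 of the maximum merge height

The tree is cut at `cut_quantile` times the maximum merge height. TOM
dissimilarities between unrelated genes saturate just below 1, so the
dendrogram root and the heights at which stray background genes attach
to real modules are nearly equal; a cut at 0.99 of the root height
therefore absorbs essentially everything into a single cluster. At the
package sizes (hundreds of genes, around a dozen samples) a cut at
0.75 leaves planted modules intact while background genes remain
unassigned; this is the default, and the quantile remains
configurable. Dynamic tree cutting was deliberately not implemented:
the static cut is deterministic, easy to reason about, and sufficient
for planted-block recovery.

## Module-trait correlation

Eigengenes are correlated with numerically encoded traits (age group
young = 0 / old = 1; passage as its number; stemness as the continuous
score), with the two-sided Student t p-value on `n - 2` degrees of
freedom. Raw p-values are reported; no multiplicity correction is
applied at this stage, matching common practice for module-trait
tables. Constant traits are flagged and given `p = 1` rather than an
undefined correlation.

# Stemness index

`stemness_index()` computes, per sample, the Spearman correlation
between a signature weight vector and the sample's expression over the
genes shared by both, then min-max scales the scores across samples to
`[0, 1]` — the published mRNAsi scoring procedure. Training the
signature itself (one-class logistic regression on reference stem-cell
corpora) is out of scope; weights are an input file. Because the score
is rank-based it is invariant under any strictly monotone transform of
a sample's expression, which the tests assert exactly.

# Module crosstalk

Given a background gene-gene interaction network, the observed number
of edges between each pair of modules is compared with `N = 1000`
permutations in which module labels are shuffled across the assigned
genes (module sizes preserved, network fixed). With `n` the number of
permutations whose between-module count strictly exceeds the observed
one, `p = n / N`, and a pair is significant when `p < 0.05` (strict).
Ties do not count toward `n`. The label-permutation null preserves the
network's degree structure exactly and costs `O(N |E|)`; a
degree-preserving edge-rewiring null is available behind a flag. A
pair whose observed count is zero is reported but flagged degenerate
and never called significant: an absent interaction cannot evidence
crosstalk. Edge confidence scores, when present, can be thresholded
before testing (default keeps all edges).

# Cross-omics correlation cascade

`correlate_paired_features()` matches features and samples by shared
id between two layers and computes per-feature Pearson correlations
with t p-values. `filter_significant()` applies the conventional
`|cor| > 0.9` and `p < 0.01` rule, both strict; at `n = 6` samples the
two cuts interact — `p < 0.01` at 4 degrees of freedom already implies
`|r| > 0.917` — and the tests verify this bound against a numerically
integrated t tail. Records are then partitioned by sign; the
negatively correlated methylation-expression genes are the
"methylation-regulated transcription genes", and intersecting them
with the significantly mRNA-correlated proteins yields the genes
regulated consistently across all three layers
(`triple_intersection()`). Spearman correlation and
Benjamini-Hochberg adjustment are available behind flags but off by
default, matching the raw-threshold convention.

# Enrichment and per-sample scoring

Over-representation uses the exact hypergeometric upper tail
`P(X >= k)`, with the term restricted to the universe (all features of
the analysed matrix) before testing. Source-specific raw cutoffs
follow the GO/KEGG convention: 0.01 for GO biological processes, 0.05
for KEGG pathways. Enriched terms are linked into a similarity network
when the Cohen's kappa of their overlapping-gene memberships (over the
union of all enriched genes) exceeds 0.4, the customary ClueGO
setting.

Per-sample pathway activity uses a single-sample rank-weighted
enrichment statistic in the ssGSEA family rather than GSVA's
Gaussian-kernel ECDF variant: per sample, genes are ranked by
decreasing expression (ties broken by feature id), in-set genes
accumulate normalized weight `rank^tau` with `tau = 0.25`, out-set
genes a constant penalty, and the score is the maximum-deviation
statistic of the walk. The statistic is deterministic, closed-form,
and preserves the per-sample pathway-activity semantics needed
downstream (correlating pathway scores between omics layers); it is
documented as an approximation to GSVA, not a reimplementation.

# Regulatory network

Candidate lncRNAs are tested against the genes of the most
trait-correlated modules (argmax `|r|` per trait, ties broken by
smaller p then module name, overridable); TFs are tested only through
curated TF-target pairs (TRRUST-style input), never all-vs-all. Edges
pass the same strict `|cor| > 0.9`, `p < 0.01` cuts. Gene-to-pathway
edges come from the enrichment overlaps; regulators with no surviving
path to a pathway are pruned. Whether lncRNA linkage should target
gene profiles or module eigengenes is genuinely ambiguous in this
analysis style; gene-level linkage is implemented as primary because
it is what the downstream network consumes, and eigengene-level
linkage can be emulated by passing the eigengene matrix as the target.
A regulator may itself be a module gene (TFs usually are); it keeps a
single node whose type records its regulator role. Exports (SIF,
GraphML, edge TSV) write nodes and edges in sorted order so identical
networks produce byte-identical files, and round-trip through
`import_network()`.

# The synthetic cohort generator

`generate_cohort()` emulates the study conditions the analysis
assumes:

* **Design.** Two donor groups (young/old) sampled at passages 3, 6
  and 10; 6 samples in the emulated study design, 12 (two replicates
  per cell) as the default test scale. A planted stemness covariate decreases with
  passage (slope 0.06 per passage) and is 0.25 lower in the old group,
  with noise 0.03 — small against the passage effect, so the designed
  ordering dominates.
* **Modules.** A latent-factor model: each module has a per-sample
  factor coupled to its trait at correlation `trait_coupling`
  (defaults 0.9 for age, 0.9 for passage, 1 for stemness, 0 for the
  background module), members are positive affine transforms
  (loadings uniform on 0.7-1.3) plus Gaussian noise
  (`noise_sd = 0.3`). The stemness factor is the stemness covariate
  itself because, in the procedure being emulated, stemness is
  computed from the expression profile — a perfectly coupled program
  is the realistic model, and it matches the near-unity
  module-stemness correlations such analyses report. Factor noise
  components are orthogonalized in-sample against the traits and
  earlier factors: with a dozen samples, raw independent noise shows
  chance correlations up to 0.9 between "independent" factors, which
  no clustering method could distinguish from planted structure;
  orthogonalization makes the between-module correlation exactly the
  trait-driven value, keeping module recovery analytically
  predictable.
* **Background genes** are independent noise at sd 0.7 — less
  variable than module genes, so a top-variance filter prefers module
  genes, as it does on real profiles.
* **Planted pairs.** Methylation for 50 planted genes is a
  linear-decreasing transform of the gene's expression plus noise
  calibrated so the population correlation is `planted_r = 0.98`,
  then clipped to `[0, 1]` (clipping can attenuate the realized
  correlation slightly; the recovery thresholds account for this).
  Planted proteins are increasing transforms at the same correlation.
  One gene (configurable) is planted in both cascades and is the
  expected triple-intersection hit.
* **Signature.** The stemness module's genes, weighted by their
  loadings.
* **Regulators.** Planted TFs are module genes with curated-style
  target rows inside their own module; planted lncRNA regulators get
  their target module's factor plus noise 0.1.
* **Background network.** Erdos-Renyi at `mean_degree / (n - 1)`,
  with the edge probability between designated crosstalking module
  pairs multiplied by `intra_module_enrichment` (3 in the demo).

What the generator does *not* emulate: count noise (it emits
normalized intensities; `counts = TRUE` pipelines exercise the log-CPM
path separately), batch effects, gene-length and GC biases, CpG-level
methylation structure, and missingness in the protein layer. Passing
tests on synthetic cohorts therefore demonstrates correctness of the
algorithms under the stated statistical model, not robustness to every
artefact of real sequencing data.

# Problem sizes and numerical choices

The default test-scale cohort is 12 samples, 600 genes (4 planted
modules of 100/80/60/50), 100 lncRNAs, 150 proteins, 200 methylated
genes — large enough for every stage to behave nontrivially, small
enough that the full suite (including a 200-cohort crosstalk
calibration at `N = 1000`) runs in well under a minute. The network is
built at power 12 in the demo pipeline: the scan-based selection rule
is faithful to its published form and fully tested, but planted-block
cohorts are not scale-free, so the scan never reaches the 0.8 fit and
its argmax fallback lands at powers that fragment weakly loaded
members; an explicit power is the predictable choice (genome-scale
analyses of this kind typically select powers in the low teens). The
demo retains the top 50% of genes by variance because the scaled
cohort plants modules over roughly half its genes; at genome scale the
conventional 20% applies.

Degenerate inputs are handled explicitly rather than left to NaN:
zero-variance features error by name in network construction and are
skipped with a log message in the correlation cascade; constant traits
flag their rows; all-equal stemness warns and reports 0.5; `|r| = 1`
p-values are clamped to the smallest positive double; empty networks,
empty TF tables and single-module assignments return empty results of
the documented shape.

# Known limitations

* The static tree cut cannot split nested modules the way dynamic
  hybrid cutting can; module counts on real data will differ from
  WGCNA's.
* The per-sample gene-set score approximates GSVA; absolute score
  values are not comparable between the two methods, though sample
  rankings generally agree.
* With six samples the `|cor| > 0.9, p < 0.01` rule is close to the
  identifiability boundary (`|r| > 0.917` at `p = 0.01`); findings at
  that scale are screening-grade, not confirmatory.
* The crosstalk p-value has resolution `1/N`; `p = 0` means "never
  exceeded in N permutations", not impossibility.
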
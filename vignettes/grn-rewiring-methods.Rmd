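---
title: "Methods: multi-omics GRN construction and cross-species rewiring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics GRN construction and cross-species rewiring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnrewire)
```

This vignette documents the statistical model behind each pipeline stage,
the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical choices made where
conventions genuinely differ.

## Differential expression

Expression arrives as wide FPKM tables (genes × replicate samples) per
condition. Three steps:

1. **Coverage filter.** `filter_expressed()` keeps genes with FPKM > 0 in
   every sample of every condition compared. Genes dropped here are absent
   from all downstream DEG sets.
2. **Quantile normalization.** `quantile_normalize()` forces all sample
   columns onto the per-rank cross-column mean distribution. Tie handling
   follows the *mean-of-tied-ranks* dialect: equal values within a column
   receive the mean of the reference values their positions span. Dialects
   differ here (some interpolate average ranks instead), which is why the
   choice is stated and oracle-tested; on tie-free data all dialects agree
   and the implementation matches `limma::normalizeQuantiles`.
3. **Dual-threshold calling.** `call_degs()` runs a two-sided
   *equal-variance* (Student, not Welch) two-sample t-test per gene on the
   quantile-normalized values of the combined WT+mutant matrix, and
   computes the fold change on *raw* FPKM condition means. A gene is
   called when p < 0.05 and the fold change exceeds two-fold, both strict
   inequalities — a gene at exactly |log2fc| = 1 or p = 0.05 is never
   called. Testing on normalized values while measuring effect size on raw
   means is the only reading consistent with normalizing for inference but
   reporting biologically interpretable fold changes; `normalize = FALSE`
   switches the test to raw values.

Numerical details that matter:

* **Pseudocount.** ε = 0.01 is added to both condition means before the
  ratio. This bounds the fold change when a mean is zero and moves a
  two-fold decision at FPKM ≥ 1 by well under 1%.
* **Degenerate rows.** After quantile normalization a gene that holds the
  same rank in every sample has identical values in all columns; the
  pooled variance is zero and the t statistic is undefined. The caller
  assigns p = 1 when the group means agree (no evidence) and p = 0 when a
  zero-variance gene still separates perfectly. Without this guard the
  stage would error on real normalized data.
* **Sign convention.** log2fc = log2(mean WT / mean mutant). Negative
  means up in the mutant (the regulator represses in WT).
* **Multiple testing.** Raw p-values are thresholded by default, matching
  the P < 0.05 convention of the upstream analyses this package
  reimplements; a Benjamini–Hochberg column is always reported and
  `adjust = "BH"` switches the call criterion to it.

The type-I behaviour of this exact stack (equal-variance t-test at n = 3
on quantile-normalized log-normal FPKM) was measured by simulation: the
null p < 0.05 fraction sits inside the 99% binomial band of 0.05 at 50,000
null genes, which is what the calibration tests assert.

`classify_rescue()` performs the cross-complementation accounting: given
direction-labelled DEG sets for WT-vs-mutant and cross-complement-vs-mutant,
it reports per direction the cross-set size, the overlap, and the WT-only
remainder (WT \ cross). "Specific to WT" is interpreted as WT \ cross —
the only reading that reproduces the published triples — and is flagged
here as an interpretation.

## Peak-to-gene assignment

Coordinates are 0-based half-open everywhere internally; GFF3 (1-based
inclusive) is converted on read, BED/narrowPeak passes through. Promoter
windows are anchored at the **translation start site** (the wording of the
rule this implements), not the transcription start: `[ts − w, ts)` on the
plus strand, `[ts + 1, ts + 1 + w)` on the minus strand, with w = 1500 by
default. The translation-start base itself is excluded (strictly
upstream). When an annotation lacks CDS features the gene 5′ end is the
documented fallback.

Two assignment modes exist because the underlying convention is not
standardised: the default `"interval"` mode calls a gene bound on ≥ 1 base
of overlap between peak and window; `"summit"` mode requires the peak
summit inside the window. A peak may bind every promoter it overlaps —
there is no nearest-gene tie-break, since the classification is per-gene.
Assignment is order-invariant and is property-tested against an all-pairs
interval oracle, including a strand-reversal falsification that a
strand-ignoring implementation cannot pass.

Target classification is pure set algebra: direct = bound ∩ DEG, indirect
= DEG \ bound, associated = bound ∪ DEG. Percentages of the annotated
universe are reported with one-decimal rounding (half-up), matching how
genome-wide binding fractions are printed.

## Motif scanning and enrichment

`scan_motif()` counts possibly overlapping occurrences of the binding
element (default GATCT, a GATA-factor element) and its reverse complement
on the forward sequence. Non-ACGT characters never match. Enrichment of
bound over background promoters uses the difference in mean per-kilobase
occurrence rate and a label-permutation p-value with the (r + 1)/(n + 1)
estimator, ties counted — fully degenerate groups give p = 1 rather than
0.5, which keeps the null example ("identical groups are not enriched")
exact. De novo motif discovery is out of scope; the scanner verifies a
known element.

## Network construction

PPI edges are STRING-style (id, id, combined score in [0, 1000]).
`load_ppi()` keeps scores ≥ 150 — inclusive, because the convention is
written "≥ 150" — drops self-loops, and deduplicates unordered pairs
keeping the maximum score. The backbone keeps edges with *both* endpoints
associated and layers a `direct_binding` star from the regulator onto
every ChIP-bound gene; isolated associated genes are retained as nodes
(conservative; a toggle would only remove rows, never add).
Guilt-by-association expansion is exactly depth 1: neighbors of the
current nodes join with their connecting edges; neighbors of neighbors and
edges among two new nodes do not. Applying the expansion twice therefore
differs from once exactly when depth-2 neighbors exist — the property
tests use this to guard against accidental transitive closure.

Core extraction grows from {regulator} ∪ seeds by adding neighbors of the
seeds ranked by degree (descending) with lexicographic gene-id
tie-breaking until the size target (default 30) is met. The ranking rule
is this package's own deterministic choice: "approximately 30 genes" fixes
the size but not the membership rule, so exact membership of any published
core is not a claim this package makes. Functional categories come from a
fixed seven-label palette; unknown labels are a hard error rather than a
silent eighth category.

## Comparative partition

Orthology must be one-to-one: `filter_one_to_one()` drops every pair
containing an id that occurs twice, excluding many-to-many orthology
rather than expanding it (pairwise counts stay well-defined). A target is
*shared* only when the ortholog pair has both ends associated — a gene
whose ortholog exists but is not a target in the other species is
species-specific. This makes the conservation identity |shared| +
|specific| = |associated| exact per species, which the property suite
checks on 1,000 random instances. The merged comparative network collapses
each shared pair into one node carrying both ids, merges the two regulator
nodes, and labels edge provenance (A, B, both); the two species'
namespaces must be disjoint apart from ortholog pairs.

## Enrichment

`enrich_terms()` is the classic one-sided hypergeometric
over-representation test: p = P(X ≥ k) with k the annotated query genes, K
the term's genes in the universe, n the query size, N the universe size.
Terms pass at p < alpha (strict) and sort by (p ascending, k descending,
term id). No ontology-hierarchy propagation is performed — annotations are
flat gene→term sets, so results depend on the annotation table exactly as
given. Exactness is tested against complete subset enumeration for
N ≤ 12. The discreteness of the hypergeometric at small N means per-term
p-values are *not* uniform under the null (a KS test against the uniform
would reject a correct implementation); the calibration test asserts the
operational guarantee instead: P(p < 0.05) ≤ 0.05 up to binomial noise.

## Metabolomics

Features (m/z, retention time, replicate intensities per condition) are
called differential when (i) the mean intensity exceeds 10⁶ in **at least
one** condition — "either", so a metabolite absent from one genotype is
still callable — (ii) a two-sided equal-variance t-test on
log10(intensity + 1) gives p < 0.05, and (iii) |log2(mean WT / mean
mutant)| > 1 with a pseudocount of 1. The log transform before testing
reflects the multiplicative error structure of LC-MS intensities; the
t-test form mirrors the expression stage. Presence/absence classes use the
same 10⁶ gate per condition. Identification matches feature m/z to library
monoisotopic mass within ±0.001 Da, **inclusive** at the boundary, plus
±1.5 retention-time units (minutes assumed) when the library provides a
reference; masses are compared as given (adduct conversion, when needed,
belongs upstream of the library).

## The synthetic-data generator

The generator emulates the *processed* forms of a two-species multi-omics
study — never raw reads, chromatin signal, or realistic genome
composition. Defaults, chosen once as the package's standard validation
conditions:

* **Genes:** 2,000 per species on 2 chromosomes, both strands, 1.5 kb
  bodies, 6 kb intergenic spacing. The spacing exceeds the 3 kb floor so
  that decoy peaks (planted 2–2.5 kb upstream) can never intrude into a
  neighbouring gene's promoter window; the zero-decoy recovery property is
  then exact rather than probabilistic. 2,000 genes keeps the default test
  run under a minute per stage; genome-scale universes (10⁴ genes) are a
  configuration away and are used only in the set-algebra checks, which
  are size-exact anyway.
* **Expression:** per-gene baseline FPKM ~ logNormal(meanlog 2, sdlog 1),
  multiplicative replicate noise logNormal(0, 0.25), 3 replicates, 5%
  planted up + 5% down at four-fold. At these settings the standardized
  effect is ≈ 5.5 on the log2 scale, so the dual screen recovers ≥ 90% of
  plants at n = 3 — the planted fold is deliberately above the two-fold
  threshold so misses come from noise, not from the screen itself. 2% of
  genes get zeroed samples to exercise the coverage filter.
* **Peaks:** bound genes (5%) get one 200 b peak strand-correctly inside
  the promoter window; decoys (5%) sit ≥ 2 kb upstream. Planting is
  strand-aware so that a strand-ignoring assignment rule demonstrably
  fails the tests.
* **Motifs:** bound promoters get 2 planted GATCT copies; background
  promoters get one with probability 0.3. Random 1.5 kb sequence already
  contains ≈ 2.9 chance occurrences on both strands, so the planted
  excess is a realistic, modest enrichment rather than a caricature.
* **PPI:** stochastic block model, 20 modules, within/between edge
  probabilities 0.2 / 0.002; confidence within ~ U(150, 999), between ~
  U(50, 400). The 150 threshold therefore keeps all within-module and a
  closed-form 5/7 of between-module edges, which the tests check.
* **Orthologs:** 60% of the smaller universe mapped one-to-one.
* **Metabolome:** 500 features, baseline logNormal(log 5×10⁶, 1) so ~95%
  pass the 10⁶ gate; 10% planted shifts at |log2| = 3; 2% zeroed per
  condition for presence/absence; 20% of features placed within 0.0005 Da
  of a library mass so they are identifiable under the ±0.001 Da rule.

Everything is a pure function of (spec, seed): the same inputs give
byte-identical output files, and each sub-generator derives its seed from
the spec seed by a fixed offset.

What passing these tests shows — and does not. The generator's noise is
clean log-normal with independent replicates; real RNA-seq has
mean–variance structure, batch effects and count noise, real ChIP-seq has
background binding and peak-calling artefacts, and real metabolomes have
correlated features and adducts. Recovery and calibration results on the
synthetic data validate the *logic and numerics* of each stage (the set
algebra, thresholds, coordinate conventions, test calibration under the
assumed noise), not performance on any real dataset.

## Problem sizes used in the checked examples

The routine test suite runs on 200–2,000-gene universes, 400–500-feature
metabolomes, 50 × 200 peak-assignment instances, and 199–1,000-permutation
enrichment tests; the acceptance checks use the published genome-scale set
sizes directly (10,988- and 13,485-gene universes), which is cheap because
the stages involved are set operations. These sizes were chosen as the
smallest at which every property is statistically meaningful.

## Known limitations

* The t-test stages assume approximate normality within groups at n = 3;
  heavy-tailed real data would call for a count model (negative binomial)
  or rank test, both out of scope here.
* No multiple-testing correction by default (a deliberate convention
  match); BH is available but changes the published-style counts.
* GO enrichment ignores the term hierarchy; parent terms are enriched only
  if annotated explicitly.
* Ortholog inference itself (RBH, OrthoFinder) is not performed; the map
  is an input.
* The core-extraction membership rule is deterministic but not unique;
  other defensible rules (betweenness-ranked, module-based) would select
  different ~30-gene cores.
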
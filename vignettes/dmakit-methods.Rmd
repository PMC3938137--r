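---
title: "dmakit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dmakit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical procedures implemented in
`dmakit`, the assumptions behind them, the defaults and why they were
chosen, and the places where the design was genuinely open and a choice
had to be made. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Data model

The central container, `ExpressionDataset`, extends
`SummarizedExperiment`: a mandatory `"intensities"` assay of non-negative
linear-scale fluorescence values (arbitrary units) and an optional
`"detection"` assay of per-probe, per-sample detection p-values in [0, 1].
Missing intensity cells are permitted and carried as `NA`; they are
rejected by normalization, filtering, correlation and clustering, and
accepted only by the probabilistic-PCA path, which treats them as latent.
Detection p-values may not be missing. Gene identifiers are
whitespace-trimmed and upper-cased in every set and annotation lookup,
because gene symbols arrive in mixed case from different sources.

## Normalization

Quantile normalization forces the intensity distribution of every sample
to the common reference distribution, defined as the rank-wise mean of
the sorted columns. Within a sample the rank order of probes is
preserved. Tie rule: tied values within a column receive the mean of the
reference values at the ranks they occupy. With continuous intensities
ties are rare; the rule matters for integer-quantized exports.
Normalization operates on the linear scale; the pipeline recipe
normalizes before filtering. The contract tested: all per-sample sorted
vectors identical to ≤ 1e-12 relative error, idempotence to the same
tolerance, and agreement with `limma::normalizeQuantiles` as an
independent reference.

## Background filtering

Both background filters use *all-samples-fail* semantics: a probe is
removed only when the criterion fails in **every** sample. This
deliberately asymmetric rule avoids discarding transcripts expressed in
only a subset of conditions — exactly the transcripts differential
analysis is after. The detection filter (threshold `alpha`, default use
0.05) applies when the platform provides detection p-values; the
intensity-floor filter (units of the raw intensities; the floor is read
off the negative-control probes of the platform, a value near 90 being
typical for the arrays this workflow was built around) is the fallback
when it does not. The low-variance filter removes the
`floor(fraction × n)` probes with the smallest unbiased (n−1) sample
variance; ties at the removal boundary are broken by stable input order
(the earlier probe goes first), making the filter deterministic.

## Two-group differential expression

Fold change is computed on linear-scale group means,
FC = mean(test)/mean(control); the p-value comes from a two-sided
two-sample t-test on log2 intensities. The t-test variant was an open
choice; the default is Welch (unequal variances), with the pooled test
available via `var_equal = TRUE`, because unequal group variances are the
rule in expression data and Welch costs essentially nothing when they are
equal. The volcano selection keeps probes with max(FC, 1/FC) ≥
`fc_cutoff` **and** p < `p_cutoff`; "2-fold" therefore covers both
directions. No multiple-testing correction is applied by default —
nominal p-values are the convention this workflow reproduces — but
`fdr = TRUE` adds a Benjamini–Hochberg column computed with
`p.adjust`.

## Time-series trends

With more than two ordered conditions, each probe's intensity vector B
(samples sorted by the declared level order, ties broken by input order)
is scored by the Pearson correlation r with the sample-order ramp
A = (1, 2, …, n). This measures monotone linear drift across the
course; it does not require equal group sizes. Selection uses
|r| ≥ threshold so that rising and falling trends both pass. The source
material for this criterion states the threshold inequality in both
directions in different places ("pass the threshold" vs "r < 0.6 was
chosen"); this package resolves the contradiction as |r| ≥ threshold,
which is the reading under which the downstream clustering of rising and
falling profiles makes sense.

The rank score for selected probes is not prescribed anywhere in detail,
only described as combining intra-group variation and between-group
differential expression; the definition here is declared:

  rank_score = Var(group means) / (pooled within-group variance + ε),

with ε = 1e-9 × the global intensity variance guarding division by zero
for probes constant within every group. Probes are ranked by descending
score. Zero-variance probes have undefined r and are excluded with a
warning rather than an error, so one flat control probe cannot abort a
whole-array scan.

## Hypergeometric enrichment

For a query of n genes drawn from a background of M genes, a set with K
members in the background and x in the query is scored by the exact
hypergeometric upper tail P(X ≥ x). The point mass is computed in log
space (`lchoose`) so large backgrounds neither overflow nor lose
precision; the suite checks exact agreement with exhaustive draw
enumeration for all M ≤ 12 and 1e-10 relative agreement with the direct
binomial-coefficient path up to M = 1000. The workbench this package
reimplements describes a "probability density test"; a density alone
cannot support an over-representation claim, so the tail is the default
and `pmf_mode = TRUE` reproduces the density-only behaviour for
compatibility. The default background is the post-filter probe (or gene)
universe; out-of-background query genes are dropped with a warning
count. Probe-to-gene collapse happens implicitly through the
case-insensitive unique-gene normalization: a gene counts once no matter
how many probes map to it.

GO-style enrichment first propagates annotations to all ancestors
(true-path rule) by transitive closure over `is_a` edges, then tests each
term like a flat set; root terms annotate everything and are excluded
from output. The DOT export contains the significant terms, all their
ancestors, and the `is_a` edges among them, with fill colour binned in
five −log10(p) buckets.

A note on null calibration: hypergeometric p-values are discrete, hence
*super-uniform* under the null — P(p ≤ α) ≤ α with strict inequality at
most α. A two-sided uniformity test would reject by construction, so the
suite checks the scientifically meaningful property instead: the
empirical CDF of null-set p-values stays at or below the diagonal
(within binomial noise) at every working level, and the mean p-value
stays near 1/2.

## Clustering and projection

Hierarchical clustering delegates distances and linkage to `dist` and
`hclust` (Euclidean or 1 − Pearson correlation; single, complete or
average linkage — all three guarantee monotone merge heights). The
display pipeline for gene-wise heat maps is fixed as log2 →
gene-wise mean-centering → clustering, with linear-scale clustering
available by flag. Dendrogram leaf order is recomputed deterministically:
at every merge the subtree containing the smaller minimum leaf index goes
left. Constant rows under the correlation metric are an error naming the
row, since their correlation is undefined.

k-means is a seeded Lloyd loop, best of `n_restarts = 10` random starts
by within-cluster sum of squares and fully deterministic given the seed.
If a cluster empties during an update its centroid is re-seeded from the
point farthest from its assigned centroid — documented behaviour, never a
crash. `stats::kmeans` serves as an independent cross-check in the test
suite on well-separated data; the in-package loop exists because the
empty-cluster policy and cross-restart determinism are part of the
contract.

Probabilistic PCA is the isotropic-noise Gaussian factor model
x = Wz + μ + ε, ε ~ N(0, σ²I), fitted by EM. Missing entries are treated
as latent variables in the E-step (jointly Gaussian with z), which makes
the EM exact and the observed-data log-likelihood provably
non-decreasing; the trace is stored in the model and asserted monotone to
1e-8 in the tests. The feature means μ are fixed at the per-feature means
of the observed entries — estimating μ inside the EM with missing data
couples the updates without materially changing the subspace, and fixing
it keeps every update closed-form and the monotonicity guarantee intact.
Loadings are initialized from small-variance Gaussian noise under an
explicit seed: reproducibility over cleverness. When the noise variance
hits its floor (an exact low-rank fit, e.g. noiseless synthetic data),
iteration stops — the likelihood diverges there and further steps are
pure numerics. Convergence is declared at relative log-likelihood change
below `tol` (default 1e-8) or `max_iter` (default 500).

## Primer design

All windows within the length bounds are enumerated on both strands and
screened in a fixed filter order — length, GC fraction, melting
temperature, homopolymer run, hairpin, self-dimer — with per-filter
attrition counts. Survivors are paired under amplicon-length bounds, a
pairwise Tm-difference bound and a cross-dimer bound, and scored by

  penalty = |ΔTm| + 2·|amplicon − midpoint|/width + 0.25·(cross + self dimers),

lower is better. Two melting-temperature models are provided: the
Wallace rule 2(A+T) + 4(G+C) for quick estimates, and — the default, as
is standard for qPCR-length oligos — unified nearest-neighbor
thermodynamics: stack enthalpies and entropies summed with terminal
initiation terms, an entropic salt correction 0.368·(L−1)·ln[Na⁺], a
symmetry term for self-complementary sequences, and
Tm = 1000·ΔH/(ΔS + R·ln(c/4)) − 273.15 at defaults of 500 nM oligo and
50 mM monovalent salt. Hairpin and dimer detection are exact
Watson–Crick complementarity run counts (a hairpin needs a stem of
≥ `hairpin_stem` reverse-complementary bases separated by ≥
`hairpin_loop`), not free-energy minimization: deterministic, exactly
testable against brute-force oracles, and in keeping with the screening
(rather than folding) role these checks play. Default constraints —
length 18–25 nt, GC 0.40–0.60, Tm 57–63 °C, ΔTm ≤ 3 °C, runs ≤ 4,
stem ≥ 4 / loop ≥ 3, dimer runs ≤ 8, amplicon 70–200 bp — are this
package's declared defaults in line with common qPCR practice.

The two-dimensional feasibility view is realized as a forward-candidate ×
reverse-candidate matrix whose cells code the pass/fail cause
(`pass`, `amplicon`, `tm_diff`, `cross_dimer`); its pass cells correspond
one-to-one to the emitted pairs before top-k truncation. Positions are
1-based with inclusive ends, the R convention; the amplicon length
rev_end − fwd_start + 1 is identical to the half-open difference other
tools report.

## Synthetic data: what it emulates and what it does not

The generators produce the study designs the analysis methods target, at
desk scale, with ground truth attached; all are pure functions of their
parameters and an integer seed.

* `genTwoGroup`: baseline log2 means uniform in [6, 12] (the bright
  mid-range of a fluorescence array), planted probes shifted by
  ±log2(fold) in the test group, i.i.d. Gaussian log2 noise
  (default σ = 0.25, a typical between-replicate scatter), exponentiated
  to linear intensities so fold-change semantics are exact in
  expectation. Reference condition: 2000 probes, 100 planted at
  2.5-fold, 5 vs 5 samples.
* `genTimecourse`: linear log2 ramps from 0 to ±2 (four-fold overall)
  across six timepoints spanning a two-week course with four replicates
  each (24 samples), flat nulls, same noise model.
* `genGenesetsAndOntology`: random sets plus one planted set sharing a
  fixed overlap with the query (defaults: 400-gene universe, 20 random
  sets, planted set of 30 overlapping the 25-gene query in 15), and a
  three-layer ontology whose one planted leaf carries the planted genes.
  The query size is not dictated by the study design, so it is an
  explicit defaulted parameter.
* `genTemplate`: a decoy background of short random stretches interleaved
  with 7-base homopolymer runs — every off-site window fails the run
  filter — with one forward and one reverse planted site. Planted oligos
  are shaped AAAA + G/C core + AAAA at the minimum primer length:
  A-clamps cannot pair with each other (no hairpin/dimer contribution),
  no enumerated window can be a proper sub-window of a minimum-length
  site, and next to the same-base flanking runs every extension past a
  site carries a run > 4. The planted pair is therefore the unique
  feasible pair by construction, which the generator verifies before
  returning.

What the simulators do **not** emulate: probe-level vendor noise models,
intensity-dependent variance, batch effects, correlated probes within a
gene, annotation errors, or GC-biased backgrounds with realistic
repeat structure. A passing suite therefore demonstrates the
correctness of the algorithms under their stated models, not robustness
to every artefact of real array data.

Problem sizes throughout the suite and the acceptance script (1000×6
normalization matrices, 2000-probe simulations, 500-seed null batteries,
600-bp templates) were chosen as the smallest sizes at which the
statistical contracts are sharp; they are the package's own choice of
desk-scale defaults.

## Pipeline, provenance, degenerate inputs

`runPipeline` runs read → normalize → filter → analysis in a fixed order
from a flat `key = value` config, validates every parameter domain before
touching data, writes all outputs as TSV, and records each file in
`manifest.json` (JSON lines of path + md5 content hash, via
`tools::md5sum`). Re-running with the same config and seed reproduces
byte-identical outputs; nothing timestamped enters any output file.
Numeric serialization is full-precision (17 significant digits, scientific
notation below 1e-4) so tables round-trip exactly through
`readResultTable`.

Degenerate-input policy, package-wide: conditions that indicate a caller
bug (out-of-support hypergeometric arguments, fold cutoffs below 1,
missing values where a method cannot honour them, constant rows under a
correlation metric) are hard errors that name the offender; conditions
that occur naturally in clean analyses (zero-variance probes in a trend
scan, annotations to obsolete ontology terms, templates with no feasible
primer pair) degrade gracefully with a warning or an empty,
attrition-annotated result.

## Known limitations

* No moderated/empirical-Bayes variance shrinkage, paired designs, or
  spline time-course models — the t/correlation machinery is deliberately
  the classic one.
* Enrichment is over-representation only; no rank-based (GSEA-style)
  statistics.
* Primer screening is specificity-blind (no genome-wide BLAST check) and
  ignores intron structure and degenerate bases.
* Spreadsheet ingest is not implemented; delimited text is the canonical
  interchange format.
* PPCA assumes data missing at random; systematically censored
  intensities will bias the fit.
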
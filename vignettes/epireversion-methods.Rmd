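---
title: "Classifying reversible and irreversible regulatory changes: models and design choices"
author: "epireversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying reversible and irreversible regulatory changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epireversion)
```

## The question the pipeline answers

A transient epigenetic perturbation — here, a pulsed RNAi knock-down of a
Polycomb group subunit in a developing tissue — can leave some genes and
chromatin regions permanently altered even after the perturbed protein is
restored. The pipeline classifies features into *reversible* (altered only
while the perturbation lasts), *irreversible* (still altered after
restoration) and *transient-specific* states, links irreversibility to
chromatin context (Polycomb domains, accessibility, transcription-factor
motifs), and checks that the somatic-variant landscape does not support a
genetic (driver-mutation) explanation instead.

Every stage runs on synthetic data with planted ground truth, so the whole
chain is testable without any external download. The synthetic generator is
a first-class module, not a fixture: its defaults define the study
conditions used throughout the tests.

## Experimental design assumed

Five conditions, each with `n_replicates` (default 3) samples:

* `control` — the reference group, an RNAi line against an irrelevant gene,
  temperature-matched to the perturbations;
* `no_kd` — a no-knock-down control, used only for the control-vs-control
  exclusion contrast;
* `constant` — knock-down throughout development;
* `transient_d9`, `transient_d11` — a 24 h knock-down pulse followed by
  recovery, sampled at two developmental timepoints.

Gene classes are planted as log2 fold-change patterns relative to
`control`: irreversible (+effect in constant and both transients),
reversible (+effect in constant only), transient-specific (+effect in
transients only), three mirrored down-regulated classes, an optional
`control_confound` class (significant only in the `no_kd` contrast, to
exercise the exclusion path) and unaffected genes.

## The negative-binomial stand-in test

Counts follow `NB(mean, dispersion)` with `variance = mean + dispersion *
mean^2`. The differential test (`nb_wald_test`) is deliberately simple and
documented as such — it is *not* a DESeq2 clone:

* size factors by median-of-ratios (geometric mean 1);
* per-feature dispersion by method of moments on normalized counts,
  `(v - m) / m^2` estimated within every condition group of the design and
  averaged with degrees-of-freedom weights, floored at `1e-8`, with no
  shrinkage;
* group log-means fitted by Newton iterations with `log(size factor)`
  offsets; Wald statistic with Fisher-information standard errors;
* the Wald statistic is referred to a **t distribution** with the pooled
  residual degrees of freedom (total samples minus condition groups).
  With three replicates per group a normal reference is visibly
  anti-conservative because the plug-in dispersion ignores its own
  sampling error; the t reference restores type-I calibration (measured
  ~0.04 at a nominal 0.05 under the null study conditions) without any
  tuning parameter;
* independent filtering: features with `baseMean` below a floor (default
  1) get a missing adjusted p-value and are treated as not significant.

The replicate covariate of a paired design is intentionally omitted: the
downstream classification consumes only `(baseMean, log2FC, p, padj)`
quadruples, and the package's contribution lies downstream of the
differential test.

## Gene selection and SOM classification

Genes are selected when `padj < 0.05` and `|log2FC| > 1` in the constant
or either transient contrast, excluding genes significant in the
control-vs-control contrast. Fold changes are clipped per column at the
5th/95th percentiles (`stats::quantile` type 7, i.e. linear
interpolation). A two-layer self-organizing map — layer 1 the constant
fold change, layer 2 the two transient timepoints jointly — is trained on
a 3x2 hexagonal toroidal grid; units are labeled from their codebook
means with a threshold `delta` (default 0.5 log2 units): constant and
transient both above `+delta` is irreversible, constant only is
reversible, transient only is transient-specific, with mirrored negative
rules for the down classes (renamed `down1..downK` in increasing
constant-layer mean). A unit matching no rule is labeled by the nearest
rule with a warning, never silently.

The accessibility side works analogously: peaks with `padj < 1e-3`,
`|log2FC| > 1` and `log10(baseMean) >= 1.25` enter a four-layer SOM
(clipped constant and transient fold changes, and `-log10(padj)` of both
contrasts capped at 20 — adjusted p-values are bounded and heavily
skewed, so the log scale is used; this transform is this package's
choice) on a 1x3 grid, labeled increased-irreversible /
increased-reversible / decreased from the codebook fold-change signs.

### SOM training choices, and why they deviate from the obvious recipe

The batch training loop uses a bubble neighbourhood whose radius decays
linearly to zero. Two choices matter and were made after the obvious
alternatives demonstrably failed on planted data:

1. **Starting radius.** On a 3x2 toroidal hexagonal grid the maximum
   inter-unit distance is ~1.73, so a starting radius of 2/3 of the
   maximum covers five of the six units. A few epochs of that wide a
   neighbourhood average every codebook toward the global mean; training
   then converges — from *any* initialization — to a degenerate optimum
   in which two planted classes share a unit. The default radius is
   therefore capped just below the nearest-neighbour distance, which on
   these small grids makes batch training exact k-means: the grid fixes
   only the number of units. That is consistent with how the map is used
   here — the unit labeling reads codebook means and never grid
   topology. For genuinely topographic maps a larger `radius0` can be
   passed explicitly.
2. **Initialization and restarts.** Codebooks are initialized from a
   seeded random sample of data rows drawn with a k-means++-style spread,
   and training is restarted from ten derived seeds keeping the lowest
   quantization error. Plain uniform row sampling lets two initial units
   land in one cluster (with six roughly equal clusters that happens in
   ~98% of draws), and a single run can strand a unit on an intermediate
   outlier. Both are standard k-means remedies; both are deterministic
   given the seed.

Layers are scaled by their total variance (sum of column variances)
before equal weighting, so a one-column layer and a two-column layer
contribute comparably.

With planted effect 2.0 log2 units, dispersion 0.05 and 3 replicates,
the full chain recovers planted irreversible and reversible labels for
more than 99% of genes on average over 20 simulation seeds (the
acceptance suite asserts at least 90%).

## Interval algebra

All coordinates are 0-based half-open; GenomicRanges does the set
operations behind the module surface, and every operation is checked
against per-base / all-pairs brute-force oracles in the tests.

* **Confident peaks**: merged-replicate calls with enrichment > 2 and
  q < 0.01 that overlap (>= 1 bp, a declared choice — the source
  procedure does not state an overlap fraction) a passing call
  (enrichment > 0, q < 0.05) in both replicates; retained intervals are
  fused when separated by at most 250 bp (narrow marks) or 2.5 kb (broad
  marks). "Minimum gap size" is read as the smallest separation that
  keeps peaks distinct, i.e. fuse when `gap <= threshold`.
* **Domain stitching**: neighbouring domains are fused iff the region
  between them is entirely covered by assembly-gap intervals. The
  published analysis references an external script for this step without
  printing its algorithm; full-coverage fusion is this package's declared
  rule.
* **Polycomb targets**: a gene is a direct target iff at least 50% of its
  body overlaps a repressive domain, boundary inclusive.
* **Activating-mark hits**: any confident peak in the gene body or a
  strand-aware 2.5 kb window upstream of the TSS.
* **Peak-to-gene assignment**: nearest TSS from the peak midpoint (the
  midpoint is also the anchor of the motif windows), at most 25 kb,
  equidistant ties to the lexicographically smaller gene id; peaks more
  than 1 kb away are flagged TSS-distal.

## Enrichment statistics

Over-representation uses the one-sided Fisher exact test (upper-tail
hypergeometric, computed from `phyper`) with Benjamini–Hochberg
correction across all tests of one invocation — the FDR family is one
call, a declared choice where the published figures are ambiguous. The
odds ratio is the unconditional sample OR with a Haldane correction
(flagged) when a cell is zero. Gene sets are user-supplied lists; no
ontology database is bundled. The Wilcoxon rank-sum test enumerates all
rank splits exactly (ties included) up to a combined n of 12 and uses
the tie- and continuity-corrected normal approximation above.

## Motif scanning and the two-stage effect model

PWMs are scanned over peak-centre ± 250 bp windows. Probabilities get a
pseudocount of 0.008 before log2-odds against the genome background
(nucleotide frequencies of the scanned sequences, not uniform). Scores
are discretized at 1e-3 (floor); the match statistic is the discretized
score sum, whose null distribution under the background is computed by
*exact* dynamic programming. The threshold is the smallest achievable
score whose tail probability is at most the cutoff (default 5e-4), so
the match p-value never exceeds the cutoff — there is no approximation
beyond the definition of the statistic itself, and the tests verify the
DP against full 4^L enumeration. Hits are counted on both strands; a
position matching on both strands counts once, and overlapping hits of
one motif collapse greedily left-to-right to the best scorer.

The effect model fits two LASSO regressions (glmnet; lambda grid
`10^seq(2, -3, by = -0.1)`, standardized predictors, 5-fold CV with a
seeded fold split, coefficients taken at the CV-minimum lambda) of the
constant and transient fold changes on motif counts, restricted to
motifs whose transcription factor passed expression filtering. Motifs
are ranked by the larger absolute coefficient of the two models — read
as a single ranking yielding exactly 25 motifs, the alternative
union-of-two-top-25 reading having been considered and not adopted —
and the top 25 are refit by OLS; a motif is selected when its OLS
p-value is below 1e-5 in at least one model. Coefficient pairs that are
both zero are never ranked in. Dose-response summaries bin peaks by
motif count (0/1/2/3+) and test each bin against the zero bin with the
Wilcoxon test.

## Somatic-variant summaries

Retention keeps SNVs/InDels with allele fraction strictly above 0.2,
structural variants with at least five supporting reads, and CNVs with
copy ratio strictly above 1.5 or strictly below 0.66 ("allelic fraction"
for CNVs is interpreted as the caller's copy ratio, keeping the original
terminology in the field's usage). The allele-fraction spectrum reports
the fraction strictly below the cut over all SNV/InDel records; sharing
counts distinct tumour samples per variant key `(chrom, pos, ref, alt)`
on retained records; feature distributions compare variants found in
control samples against variants shared by at least two tumours.
"Deleterious" is consumed as an external annotation, never computed.

## What the generator emulates — and what it does not

The generator plants: NB counts under the five-condition design with
log-uniform size factors in [0.5, 2]; gene bodies placed uniformly with
at least 1 kb spacing and domains fully covering their target genes (so
flags are exactly recomputable); peak calls built to pass or fail the
consolidation rule by construction, each noise peak failing exactly one
uniformly chosen criterion; 500 bp window sequences with planted
consensus occurrences at Poisson counts (rate 0.5 per motif) that also
drive the planted accessibility effects (`beta` +0.5 / -0.5 for two
causal motifs, Gaussian noise sd 0.5); and variant tables with
Beta(1, 9) allele fractions (~87% below 0.2), mostly private variants
plus a configured number of planted shared ones.

It does **not** emulate: read-level data or alignment artefacts;
dispersion trends with expression; correlated genes or peaks;
chromatin-state autocorrelation along the genome; motif co-occurrence
structure; or sequencing batch effects. Passing tests therefore
demonstrate that the implementations are correct and the statistical
machinery calibrated under the stated model — not that the pipeline is
robust to every pathology of real sequencing data.

Problem sizes in the bundled tests and the acceptance script (2,000
genes for calibration, 1,200 genes x 20 seeds for recovery, 1,000 peaks
for the motif model, 10,000 draws for the allele-fraction check) were
chosen so each check is statistically informative at desk scale.

## Numerical conventions and degenerate inputs

* Percentiles: `quantile(type = 7)` everywhere.
* SOM ties in nearest-unit assignment break to the lowest unit index.
* A condition group with all-zero counts for a feature gets a small
  pseudo-mean (0.5 split across its samples) inside the GLM fit only, so
  fold changes and standard errors stay finite; reported baseMeans are
  untouched.
* Readers reject malformed records with file and line rather than
  coercing; q-value scale (raw vs -log10) is declared by the caller,
  never guessed from values.
* All randomness flows from one root seed through fixed substreams
  (documented in `sim_config`), so generators agree on shared structures
  and every result is reproducible byte-for-byte; report tables round
  floating point to 6 decimals before writing for cross-platform
  identity.

## Known limitations

The NB stand-in has no dispersion shrinkage, so it is less powerful than
moderated tests at very low expression; the SOM labeling assumes the
planted six-pattern geometry and warns (rather than guesses silently)
when a unit matches no rule; the motif model assumes linear,
non-interacting per-count effects; and the variant module starts from
called variants — caller error models are out of scope.
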
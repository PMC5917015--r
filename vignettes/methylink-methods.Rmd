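---
title: "Methods: RRBS methylome analysis and methylation-expression linkage"
author: "methylink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RRBS methylome analysis and methylation-expression linkage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`methylink` analyses reduced representation bisulfite sequencing (RRBS)
methylomes in transposon-rich plant genomes and links differential DNA
methylation to differential gene expression.  The pipeline covers: in-silico
restriction digestion and size selection of a reference genome; cytosine
context assignment (CG, CHG, CHH, with H = A, C or T); pooling of replicate
cytosine counts per condition; genome-scale methylation summaries;
kernel-smoothed two-proportion score tests assembled into differentially
methylated regions (DMRs); annotation of DMRs against genes, 2 kb promoters
and transposable elements (TEs); and exact Fisher contingency tests of the
association between differential methylation and differential expression.
A seeded synthetic-data generator supplies a small TE-rich genome with
planted hypomethylated regions and planted differentially expressed genes
(DEGs), so every downstream stage is testable without external data.

Upstream read processing (alignment, trimming, methylation calling from
BAMs) and differential-expression testing are out of scope: the package
consumes per-cytosine count reports and expression tables with externally
assigned significance flags.

## The reduced representation genome

MspI cuts the palindromic site C^CGG.  `digestGenome()` scans the forward
strand only (the double-stranded cut is implied) and places a cut after the
first base of every occurrence, so fragments tile each chromosome exactly:
their concatenation reconstructs the sequence, an invariant the test suite
asserts on random genomes.  `sizeSelect()` retains fragments by inclusive
length bounds.  Two dialects are first-class: the physical library window
(40–220 bp) and the broader virtual-reference window (20–400 bp) used when
reducing a reference genome, which deliberately tolerates imprecise
physical size selection.  The retained interval union is the universe in
which methylation is observable; `featureCoverage()` reports, per feature,
the number of its bases inside that union (union, never a per-fragment
sum).

## Methylation model and summaries

A cytosine's context is read from the two downstream bases in strand
orientation.  On the minus strand the downstream bases are the complements
of the forward bases at positions p−1, p−2; consequently a CCGG site
carries symmetric CG cytosines at its second (plus) and third (minus)
positions, and the minus-strand cytosine at the fourth position is CHG —
the test suite pins this down against a reverse-complement oracle.
Cytosines on the two strands are kept as separate records (no CpG-pair
collapsing), matching per-strand cytosine reports.

Replicates of one condition are pooled by summing methylated and total
counts cytosine-by-cytosine (`poolReplicates()`); a cytosine missing from a
replicate contributes zero, and conflicting context annotations at one
position are rejected as corrupt input.

"Methylation level" summaries are count-weighted (Σ methylated / Σ total)
rather than unweighted means of per-cytosine proportions.  The phrase "x%
of cytosines in context X were methylated" is ambiguous between the two;
count-weighting was chosen because it is robust to uneven coverage, and the
unweighted mean remains available (`weighted = FALSE`).  Chromosome
profiles (`chromosomeProfile()`, default 5 Mb bins) are count-weighted per
bin, and bins without covered cytosines are reported missing (NA), never
zero.  `contextShare()` calls a cytosine methylated at level ≥ 0.5 by
default — no calling threshold is standard, and 0.5 is the natural midpoint
for well-covered sites.  The bisulfite conversion rate is estimated from an
unmethylated control as 1 − Σm/Σn.

## DMR calling

The caller is a kernel-smoothed two-proportion score test with explicit
region filters.  For two pooled conditions and one context:

1. Keep cytosines with at least `minReadsPerCytosine` pooled reads in both
   conditions.
2. At each kept cytosine, smooth each condition's counts with a triangular
   kernel, weight w(d) = max(0, 1 − |d|/h) with half-width h = window/2
   (window 500 bp by default), and apply the score test to the smoothed
   counts:
   z = (p̂₁ − p̂₂) / sqrt(p̄(1 − p̄)(1/n₁ + 1/n₂)),
   where p̄ is the pooled proportion and p the two-sided normal tail.
   A degenerate pooled proportion (exactly 0 or 1, no variability) returns
   p = 1.
3. Assemble maximal runs of qualifying cytosines (smoothed p ≤ pMax and
   smoothed |difference| ≥ minDiff) allowing inter-cytosine gaps up to
   `window`.
4. Re-test each region on its unsmoothed pooled counts, so the final
   significance is not doubly smoothed.
5. Keep regions with length ≥ minSize, at least minCytosines cytosines,
   region |difference| ≥ minDiff and region p ≤ pMax; label regions hypo-
   or hypermethylated by the sign of (treatment − control).

The strict preset is window 500 bp, minimum size 50 bp, ≥ 4 cytosines with
≥ 4 reads each, |difference| ≥ 0.40 and p ≤ 0.01; the relaxed preset lowers
these to 3 cytosines, 3 reads and a 0.10 difference.  These thresholds are
filters on raw p-values; no multiple-testing correction is applied by
default, matching the region definition the package implements, though a
Benjamini–Hochberg option (`adjust = "BH"`) is provided.

The step order (smooth → per-cytosine test → run assembly → region re-test)
and the gap rule (≤ window) are this package's own design: they make every
threshold an explicit, testable filter.  Because weights are ≤ 1,
the score test on smoothed counts overstates the variance relative to the
weighted sum's true variance, so the per-cytosine test is conservative;
the null-calibration tests confirm a ≤ 0.01 empirical rate at the nominal
0.01 and zero strict DMR calls across seeds under an identical truth.

Smoothing has a geometric consequence worth stating: a cytosine only
retains the full between-condition difference if its whole kernel window
lies inside the differentially methylated domain.  A domain of width W
therefore has a guaranteed-detectable core of about W − window bases, and
domains narrower than the window are attenuated below a strict 0.40
difference threshold even when the true difference is 0.5.

## Annotation

Promoters are the 2000 bp immediately 5′ of each gene, strand-aware and
truncated at chromosome edges.  Each DMR receives exactly one class by
precedence: gene+promoter (it overlaps a gene and that same gene's
promoter) > TE > gene > promoter > intergenic, with overlap meaning at
least one shared base.  TE outranks gene because in TE-rich genomes most
differential methylation is TE-resident, often nested inside genes; the
precedence itself is a package decision, validated against a per-base
oracle on randomized genomes.  `closestGene()` assigns each TE the gene
with the smallest inter-interval gap (0 when overlapping), breaking ties by
the smaller gene start, with negative distances for upstream genes — the
tie-break and sign conventions are defined here, as no standard exists.

## Methylation–expression linkage

Genes enter the contingency universe only if the reduced representation
genome covers at least 500 of their bases — a compromise between losing
genes with DMRs and keeping genes with expression but no methylation
information.  TEs are admitted at any coverage because many are short.
Three universes are tested: DMR-in-gene-body and DMR-in-promoter over the
gated genes, and a TE universe consisting of the deduplicated nearest genes
of covered TEs, where a gene counts as differentially methylated if it is
the nearest gene of a covered TE containing a DMR.  (The alternative — a
universe of TEs rather than their nearest genes — is noted but not used,
since expression is a property of genes.)

Each 2×2 table (a = DM and DE, b = DM only, c = DE only, d = neither) is
tested with the exact Fisher test implemented by the point-probability
rule: the two-sided p sums the hypergeometric probabilities of all tables
with the observed margins whose point probability does not exceed the
observed one, with a 10⁻⁷ relative tolerance on the comparison to absorb
floating-point error.  The test suite checks this exhaustively against an
enumeration oracle on all tables with total ≤ 30 and against
`stats::fisher.test`.  Zero-margin tables return p = 1 with a warning.
Printed percentages of DM genes that are also DE use half-away-from-zero
rounding (41/253 → 16, 7/37 → 19), which base `round()`'s half-to-even rule
would not reproduce.

Log2 fold changes are log2(treatment/control) FPKM.  A zero control FPKM
leaves the value undefined (rendered "–"); zero treatment with positive
control is −∞.  Published tables print FPKMs rounded to one decimal, so
recomputed fold changes match the printed values at 2 dp only for a subset
of rows; tests and the acceptance script use exactly those reproducible
rows.

## The synthetic-data generator

`simulateMethylome()` emulates the statistical structure the analysis
assumes:

* **Genome** — uniform random sequence with extra CCGG sites seeded at a
  mean spacing of 200 bp, giving the in-silico digestion a dense fragment
  population; TEs are uniform random intervals with log-normal lengths
  (median 2 kb), overlapping freely (TEs nest in genes in maize-like
  genomes) until their union covers the target fraction (0.85 by default);
  genes are non-overlapping stranded intervals of 1.5–4 kb.
* **Methylation truth** — context baselines CG 0.27, CHG 0.19, CHH 0.013,
  echoing control-condition levels of the emulated study; planted regions
  drop the deficiency-condition proportion by `dmrEffect` (0.5), floored at
  zero.  CHH regions are never planted by default (the emulated analysis
  found none); a flag overrides this for power studies.
* **Planted-region geometry** — planted domains default to 1200 bp, more
  than twice the caller's window, so each keeps a guaranteed-detectable
  core (see above), and are kept ≥ 1 kb apart so the caller's gap rule
  cannot fuse two truth regions into one call.
* **Counts** — per replicate (3 per condition), totals are Poisson around
  `coverageMean` and methylated reads binomial with
  p_obs = p_true + (1 − p_true)(1 − conversion); an unconverted
  unmethylated cytosine reads as methylated.  Conversion defaults to 0.99.
  The Poisson choice reproduces the "≥ 5 reads at 90% of cytosines"
  property at means ≥ 9 and is the simplest parametric option; the real
  coverage distribution of RRBS libraries is more dispersed.
* **Expression** — log-normal control FPKMs; planted DEGs receive fold
  changes ≥ 2 in a random direction and TRUE significance flags; a
  configurable fraction of planted DEGs is drawn from the nearest genes of
  planted TE-resident DMRs, making the TE-level Fisher alternative
  detectable.  When that unique-nearest-gene pool is smaller than the
  request, the linked count is capped with a warning; requesting linkage
  with no TE-resident planted DMRs at all is an error.

All randomness flows from the single config seed through named sub-streams
(genome, dmrs, counts, expression), so identical configs produce
byte-identical output files and individual stages are reproducible.

What the generator does **not** emulate: raw reads and alignment artifacts,
PCR duplicates, M-bias, chromosome-scale centromeric methylation gradients,
genuine biological replicate dispersion beyond binomial noise, and the real
genome's fragment-length distribution (the simulated reduced representation
fraction is far higher than a real genome's ~14% because the toy sequence
is CCGG-dense by construction).  Passing tests therefore demonstrate the
pipeline's statistical behaviour under its own assumptions, not performance
on real libraries.

## Problem sizes and numerical choices

The packaged analyses run on one CPU at modest sizes chosen as the
package's demonstration scale: DMR parameter recovery on a 1 Mb genome
(20 planted CG regions, 0.8 vs 0.3, 20× coverage, three replicates), null
calibration on twenty 100 kb seeds, and linkage detectability on twenty
150 kb seeds per condition.  Score tests use the normal approximation
(adequate at the ≥ 4-read, pooled-replicate depths the filters enforce);
Fisher p-values use exact hypergeometric mass.  Ties in nearest-gene
assignment and the region gap rule are deterministic, so repeated runs with
one seed are identical.

## Limitations

* The region assembly is this package's reconstruction of a
  kernel-smoothing DMR caller; exact region counts from other
  implementations on real data are not comparison targets.
* Replicate variability is binomial only; overdispersed data would inflate
  the score test's significance.
* The Fisher universes condition on the coverage gate; different gates
  change the tables and p-values, as the gate is part of the method.
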
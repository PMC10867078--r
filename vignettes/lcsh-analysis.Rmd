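---
title: "Methods: homozygosity, consanguinity and UPD screening from CMA segment exports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homozygosity, consanguinity and UPD screening from CMA segment exports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcshkit)
```

## The problem

SNP-genotyping chromosomal microarrays report, besides copy-number gains
and losses, segments of *absence of heterozygosity* ("LOH" in export
tables). Three biological mechanisms produce long runs of this kind:
parental relatedness (autozygosity scattered over many chromosomes),
uniparental isodisomy (homozygosity confined to one chromosome), and
shared ancestral haplotypes in low-recombination regions (short,
recurrent, population-level runs). A fourth, technical source is
hemizygosity: over a heterozygous deletion there is only one allele to
genotype, so the software reports "LOH" that is not homozygosity at all.
`lcshkit` separates these four signals from a single parsed segment
table.

All coordinates are 1-based inclusive internally, matching the convention
of the printed segment exports; BED output converts to 0-based half-open
on write. Segment boundaries are taken as the source software emitted
them — segments are never re-segmented, merged or split.

## LCSH selection and hemizygosity masking

Only LOH segments of at least `min_lcsh_mbp = 3` Mbp enter any analysis.
Three Mbp is the conventional clinical threshold: population studies use
0.5–1 Mbp cut-offs, but in an affected cohort smaller runs are dominated
by ancestral-haplotype noise. The comparison is inclusive (`>=`).
Sex-chromosomal LCSH are retained and flagged, but excluded from
consanguinity sums and UPD calling (male X "homozygosity" is vacuous, and
X autozygosity follows different genealogy).

Hemizygosity review is automated: an LCSH is masked when the union of
same-sample copy-number ≤ 1 losses covers at least
`hemizygous_overlap_fraction = 0.5` of its length. The fraction is a
conservative automation of what is usually a manual review step; it is
configurable, and masking is idempotent and strictly per-sample. Masking
runs before every downstream consumer, so a deletion artifact can never
contribute to an inbreeding coefficient or a UPD call.

## Inbreeding coefficient and kinship classes

The genomic inbreeding estimate is

> F = (sum of autosomal analyzable LCSH, in Mbp) / 2881 Mbp

with the denominator the GRCh37 autosomal genome size held as a
*constant* — deliberately not recomputed from the build's chromosome
lengths, so reported coefficients are reproducible against published
per-case values to their printed three decimals. F is computed at full
precision and rounded only for display (`f_reported`, 3 decimals).

Expected identity-by-descent fractions of kinship degrees form a
geometric series (first degree 1/4, second 1/8, third 1/16, fourth 1/32,
fifth 1/64, seventh-or-more 1/128). Class assignment therefore uses
boundaries at the *geometric means* of adjacent nominal values
(e.g. first/second at sqrt(1/4 × 1/8) ≈ 0.17678), with a floor of 0.005
below which no inbreeding is called. A linear midpoint would
systematically favor the lower class as the series halves; the log
midpoint is the natural equidistant cut. The boundaries are exposed in
`kinship_classes()` and configurable. Near a boundary the assignment is
necessarily arbitrary — published per-case tables disagree with any
single rule on borderline entries — which is why the rule is documented
rather than claimed to reproduce any specific laboratory's choice.

Samples whose entire analyzable autosomal LCSH lies on one chromosome
that triggered a UPD candidate are flagged `upd_only` and excluded from
cohort inbreeding fractions: their homozygosity pattern indicates a
disomy event, not parental relatedness.

## UPD screening rules

Isodisomy produces homozygosity confined to one chromosome. Two rules
operate on analyzable autosomal LCSH, with thresholds
`upd_ge_threshold_mbp = 5` (strict "over") and
`upd_min_total_mbp = 10` (inclusive):

* **Rule B** — exactly one autosome carries LCSH over 5 Mbp and that
  autosome's LCSH total is ≥ 10 Mbp. Sub-5 Mbp LCSH elsewhere are
  ignored; a second autosome over 5 Mbp cancels the call, because
  multiple large runs point to inbreeding instead.
* **Rule A** — no LCSH over 5 Mbp anywhere in the genome, but one
  autosome accumulates two or more sub-5 Mbp LCSH summing to ≥ 10 Mbp
  (an isodisomy broken up by recombination). Arithmetically two sub-5
  segments cannot reach 10 Mbp, so rule A needs at least three in
  practice; the rule is kept in its literal two-or-more form and the
  consequence noted here.

At most one candidate is emitted per sample; if several autosomes qualify
under rule A, the largest total wins (a tie-break that, with three or
more sub-5 segments per chromosome required, is essentially never
exercised). Sex chromosomes never yield candidates. Candidates on
chromosomes 6, 7, 11, 14, 15 and 20 carry an imprinting flag and a note
naming the canonical syndromes. Heterodisomy is invisible to this screen
by construction, and no parental-origin inference is attempted.

This screen is deliberately a *heuristic*: a single long autozygous block
from distant consanguinity on an otherwise quiet genome satisfies rule B.
On synthetic cohorts this shows up as candidates among inbred samples;
resolving them needs parental genotypes or methylation follow-up, both
out of scope.

## Common (recurrent) LCSH regions

Recurrence is anchored at the cytoband level: for every autosomal band,
the fraction of samples with ≥ 1 bp of analyzable LCSH overlap (each
sample counted once per band). Bands at or above
`common_min_frequency = 0.05` qualify — the threshold is inclusive, and
5% rather than the 1% SNP-polymorphism convention because an affected
cohort needs a safety margin. Adjacent qualifying bands merge into one
span; every analyzable LCSH overlapping the span is a member; and the
region is delineated by the component-wise *median* of member starts and
ends, using the lower median for even counts so boundaries stay at
observed coordinates. Regions are reported sorted by frequency.

A packaged reference list of ten recurrent GRCh37 regions
(`common_lcsh_reference()`) supports membership annotation
(`annotate_common_membership()`, ≥ 50% of the LCSH length by default)
when no cohort-derived region set is available.

## CNV yield and association

CNV filtering implements the two conventional regimes: research
(> 10 Kbp, ≥ 10 markers, both types) and clinical (losses > 100 Kbp,
gains > 150 Kbp, ≥ 50 markers). Size comparisons are strict ("larger
than"); marker minima are inclusive ("at least"). Classification labels
are *inputs* (benign / VUS / LPCNV / PCNV): no scoring or database lookup
is performed. A sample's class is the most relevant label it carries
(PCNV > LPCNV > VUS > benign > none).

Association rows compare the negative group (none/benign) against PCNV
carriers; VUS/LPCNV-best samples are excluded as inconclusive. The p is
Fisher's exact two-sided value; the odds ratio is the *sample* OR
(ad/bc), not the conditional-MLE estimate `fisher.test()` prints,
because the sample OR is what published cohort tables carry; with any
zero cell, 0.5 is added to all cells (Haldane–Anscombe) and flagged.
Both orientations are emitted with explicit names — in
`or_negative_vs_pathogenic`, phenotypes enriched among pathogenic
carriers show OR < 1. Raw p-values are flagged at alpha = 0.05 without
multiplicity correction, the univariate screening convention; a
Benjamini–Hochberg column is provided alongside for readers who want it.
Metric contrasts across classes use one-way ANOVA with Tukey HSD.

## The genome build and its synthetic band table

The default `genome_build()` carries the true GRCh37/hg19 chromosome
lengths, the 2881 Mbp constant, and a cytoband table. The band table is
*synthetic*: generated by `synthetic_cytobands()` from approximate
centromere positions, it tiles each arm into ~10 Mbp bands named in the
cytogenetic direction (p11/q11 at the centromere, numbers rising toward
the telomere) but is not the ISCN band set. Every band-level computation
(recurrence counting, region naming) is exact with respect to whichever
table is loaded; `read_cytoband()` accepts a real UCSC-format
`cytoBand.txt` and should be preferred when one is available. Region
*delineation* is unaffected by band identity — medians are computed on
member segment coordinates — so only reported band-span *names* differ
between the synthetic and the real table.

## What the synthetic cohort emulates — and what it does not

`simulate_cohort()` generates, per sample, from its own seed-derived RNG
stream (so any sample is reproducible independently of cohort size):

* **Autozygosity** for an assigned kinship degree *d*: block count
  ~ Poisson(F_d · 2881 / mu_d), block lengths Exponential(mean `mu_d`)
  truncated below at 0.5 Mbp (array-callable floor) and above at 150 Mbp
  (a block cannot exceed its chromosome), placed uniformly without
  overlap, chromosome chosen proportional to length. Defaults
  mu = 50/33/25/20/17 Mbp for degrees one to five follow the 100/m
  heuristic (about 100 Mbp per meiosis in the inbreeding loop, with
  1 cM ≈ 1 Mbp). The *sum* — which is what F estimates — has expectation
  F_d · 2881 Mbp regardless of the count/length decomposition; sub-3 Mbp
  blocks are emitted deliberately to exercise the threshold.
* **UPD patterns**: whole-chromosome isodisomy (≥ 90% of an autosome),
  iso/hetero mixtures (1–3 segments ≥ 5 Mbp totaling ≥ 10 Mbp), and
  terminal segmental events (10–20 Mbp).
* **Recurrent regions** at configured population frequencies; a member's
  segment extends beyond each region boundary by an Exponential(mean
  `jitter_mbp = 0.5` Mbp) overhang, emulating shared-core haplotypes of
  varying extent.
* **Background** sub-5 Mbp blocks (Poisson count, default mean 2.2),
  each on a *distinct* chromosome within a sample — modeling them as
  independent ancestral blocks at distinct loci, which also means a
  clean outbred background cannot accumulate 10 Mbp on one chromosome
  and spuriously satisfy rule A.
* **Hemizygous artifacts** (deletion plus co-located LOH row), sub-3 Mbp
  noise segments, occasional X-chromosome LCSH, CNV calls with per-class
  lognormal sizes and marker counts, and a logistic phenotype model in
  which carrying a PCNV multiplies a term's odds by a configured factor.

The generator does **not** model recombination maps, linkage
disequilibrium, SNP-level genotypes, B-allele frequencies, or
chromosome-specific block-length variation. Consequently, recovery tests
demonstrate that the estimators and rules behave as specified under the
stated generative model — not that real cohorts satisfy that model. In
particular, uniform placement makes spurious single-chromosome
accumulation rarer than ancestry-structured placement would; the UPD
false-positive behavior on real data is bounded below by what the
synthetic tests show.

## Numerical choices and degenerate inputs

* Rounding is display-only: F at 3 decimals, UPD sizes at 1 decimal,
  region sizes at 3 decimals; all internal comparisons use full
  precision.
* Medians use the lower of the two middle order statistics for even
  counts.
* Empty cohorts yield empty profiles and zero rates, never errors;
  all-zero 2×2 tables and negative LCSH sums are domain errors.
* Single-member metric groups report SD as `NA`; groups with fewer than
  two values are excluded from Tukey comparisons and listed.
* Unparseable segment rows are rejected with row-numbered reasons and
  never silently dropped; a missing mandatory column aborts with the
  column name.
* Per-sample simulation seeds are derived as
  `(seed * 48271 + index * 7919) mod (2^31 - 1)` to stay within R's
  integer range.

## Validation scale

The shipped test-suite exercises the estimators at sizes chosen to keep a
full run in the low minutes on one core while leaving the statistical
checks well-powered: exhaustive Fisher agreement over all 2×2 tables with
margins ≤ 30 (about 205,000 tables); 200–400 replicate draws for the
autozygosity model; cohorts of 250–1000 samples for recovery of kinship
fractions, isodisomy recall/specificity, injected region frequencies and
phenotype odds ratios; and a 953-sample run for the sub-5/≥ 5 Mbp pattern
calibration. The first-cousin recovery check sits close to its
acceptance boundary by construction (the expected third/fourth-degree
classification fraction under the stated model is just above 70%), which
is a property of the geometric class boundaries, not of the
implementation.

## Known limitations

* Kinship classes near boundaries are convention-dependent; only the
  documented rule is claimed.
* The UPD screen cannot see heterodisomy and cannot separate a long
  autozygous block from a true isodisomy without parental data.
* The packaged band table is synthetic; band-span *names* in
  cohort-derived common-region reports are approximate unless a real
  cytoband file is supplied.
* Population endogamy inflates F without close parental relatedness; the
  class label speaks to the coefficient, not to pedigree truth.
* Gains are ignored by the UPD caller; mosaic and complex events are out
  of scope.
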
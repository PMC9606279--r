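---
title: "Targeted long-read screening of repeat expansion loci: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted long-read screening of repeat expansion loci: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repscreen)
```

## The problem

Some sixty tandem-repeat (TR) loci cause neurological disease when the
repeat expands beyond a locus-specific unit-count threshold: CAG in *HTT*
(Huntington disease), AAGGG in *RFC1* (CANVAS), GGC in *NOTCH2NLC* (NIID),
TGGAA in *BEAN1* (SCA31), and so on. Conventional diagnostics (flanking PCR,
repeat-primed PCR, southern blotting) interrogate one locus per assay and
struggle with long, GC-rich tracts. Targeted long-read sequencing — nanopore
adaptive sampling over a panel of disease loci — screens every catalogued
locus at once, reads through entire expansions, and yields per-read repeat
lengths, motif composition, and CpG methylation in a single experiment.

`repscreen` implements the computational half of such a screen: it consumes
aligned long reads over a locus catalog and produces per-read repeat
copy-number changes, two-allele genotypes, a prioritized locus list relative
to a control cohort, motif decompositions ("waterfall" matrices), a
rule-based pathogenicity triage, allele-level methylation calls, and
enrichment QC. A first-class synthetic-data generator makes every stage
testable without any sequencing data.

## Per-read measurement

A read's copy-number change at a locus is read off its alignment: the signed
base-pair change is the sum of insertion lengths whose reference anchor lies
within one motif length of the tract boundaries, minus the overlap of
deletions with the tract. Aligners place the insertion representing an
expanded repeat at either tract boundary, which is why the attribution
window extends `motif_len` beyond the tract; deletions are counted only by
overlap. Unit change is bp change divided by motif length, rounded to the
nearest integer with ties toward zero, so one or two base pairs of alignment
jitter keep unexpanded reads at exactly 0.

A read *spans* the tract when its aligned (non-clipped) reference footprint
covers the tract plus `anchor_bp` (default 100 bp) of flank on both sides.
Only spanning reads enter genotyping and ranking; the 100 bp anchor
operationalizes "reads spanning the expanded repeat", which the source
workflow counts but does not define. The minimum mapping quality defaults to
1 because the panel includes segmental-duplication loci (*NOTCH2NLC*) where
stringent MAPQ filters discard genuine reads.

## Two-allele genotyping

Per-locus genotyping is an exhaustive one-dimensional two-cluster split of
the sorted per-read copy changes, minimizing within-cluster sum of squares —
deterministic, exact for 1-D data, and cheap at panel scale. Cluster centers
closer than `max(2, 0.1 x larger center)` collapse to a homozygous call
(allele = median of all reads); otherwise the two cluster medians become the
alleles.

A genotype is *undetermined* when fewer than `min_support` (3) reads span
the locus, and also when a heterozygous split leaves either allele with
fewer than `min_support` supporting reads. The second condition is this
package's own addition: separating two alleles from a handful of reads is
exactly what fails at low coverage, and with it the genotype behaves as the
down-sampling experiments demand — predominantly undetermined at ~4-5x
virtual depth, stable from ~15x. The package's down-sampling tests reproduce
that transition on simulated heterozygous RFC1 expansions.

## Prioritization against controls

For each locus the patient statistic is the m-th largest spanning-read copy
change with `m = max(2, ceiling(0.1 n))` — robust to a single chimeric or
error read. The score is

```
score = (patient_stat - max control copy change) x motif_len
```

on the base-pair scale, so a pentanucleotide expansion of hundreds of units
outranks a trinucleotide gain of a few units. The control summary is the
maximum over all control alleles (with 27 controls, any patient change
beyond every control is notable; no population model is attempted). Ties
break by genomic position; loci with fewer than `min_support` spanning reads
sink to the bottom with a `-Inf` sentinel and a flag. The score formula is
the package's own design: the upstream literature delegates ranking to a
tool whose exact rule is not restated, so the formula is deliberately simple
and documented here. Ranking says nothing about pathogenicity — a benign
polymorphic pentanucleotide expansion will out-rank a small pathogenic CAG
gain by construction, and the triage stage is where that distinction is
made.

## Motif decomposition and consensus

Tract decomposition is an exact dynamic program over the catalogued motif
set: an exact unit costs 0, a mismatched base inside a unit costs 1 (at most
`max_mismatch_per_unit = 1` per unit, and only for motifs of length >= 4 — a
one-mismatch trinucleotide matches nearly anything), and an unlabeled
(OTHER) base costs 1. Among equal-cost segmentations the program prefers
earlier-listed motifs, then longer motifs, then fewer OTHER runs; pathogenic
motifs are listed first in the catalog, so TGGAA beats TAGAA when both fit.
The DP is verified in the test suite against an independent
exhaustive-enumeration oracle on all random instances up to 30 bp.

Consensus construction is medoid + majority polish: the read minimizing
summed edit distance to its peers is chosen as the template, every read is
globally aligned to it, and each template column takes the majority base
(ties keep the template base; a majority gap deletes the column). This is
deterministic and desk-scale; it deliberately does not re-implement a
partial-order assembler. For unit counting on tracts up to a few kilobases
with ~1-2% errors it recovers the true sequence exactly in the package's
seeded tests; for much longer or noisier tracts a dedicated assembler would
be preferable.

Waterfall matrices decompose each read's tract (reverse-strand molecule
sequences are reverse-complemented into repeat orientation first) and sort
rows by unit count. The strand-specific AAGGG→AAGG basecalling artifact,
when simulated, appears exactly as in real data: corrupted AAGG units
enriched on one strand's rows only.

## Triage rules

The triage applies, in order: R1 — is the larger allele's pathogenic-motif
unit count at or above `pathogenic_min_units`? If yes, R3 resolves
inheritance: autosomal-recessive loci need both alleles expanded
(one expanded allele is a *carrier*); dominant and X-linked loci need one.
If no, R2/R4 distinguish a long tract composed of benign motifs only
(*benign_polymorphic* — the SCA31 situation where only TGGAA is
disease-linked) from a pathogenic-motif count above the normal maximum but
below threshold (*intermediate* — the SCA8 situation). The pathogenic-motif
unit count comes from the consensus decomposition when available and falls
back to total allele units with a `composition-unverified` flag otherwise.
Missing thresholds always produce *undetermined*, never a guessed call.

Threshold defaults: the shipped catalog carries literature-standard clinical
unit-count bounds for the 12 disease loci (e.g. CACNA1A 18/20, ATXN8OS
40/71, RFC1 100/400, NOTCH2NLC 40/60). The ATXN8OS normal maximum of 40
applies to the pure-CTG count, deliberately conservative so that
intermediate pure-CTG expansions in the 40s-60s triage as *intermediate*
rather than normal — the package's judgment, not a universal constant. The
polymorphic TNRC6A entry ships without thresholds and always triages
undetermined. All thresholds are user-editable catalog columns.

The SNP genotyper (pileup at a disease-linked SNP, heterozygous at >= 20%
minor-allele fraction, >= 3 informative reads) is strictly informational: a
linked SNP cannot exclude a diagnosis, so its output never alters a verdict.

## Methylation

Allele-level methylation classifies the mean, over a supporting-read set's
CpG observations, of the indicator {5mC probability >= 0.5}: at or above 0.6
*hypermethylated*, at or below 0.2 *unmethylated*, otherwise *partial*;
fewer than 10 CpG observations is a no-call. The 0.6/0.2/10 values are this
package's operating points (the motivating observations are qualitative —
hypermethylated vs unmethylated alleles) and are arguments, not constants.
The bisulfite-like converter (unmethylated C → T, length-preserving,
idempotent) lets standard sequence tooling visualize methylation. Input is a
plain per-read probability TSV; a converter from modified-base BAM tags can
wrap it, keeping the module testable.

## Enrichment QC

Reads of 1000 bp or less are excluded before any depth computation —
adaptive sampling ejects rejected molecules early, so very short reads are
out-of-target by construction. On-target depth is the mean per-base depth
per catalog window, averaged across loci; the off-target genome is tiled in
5000-bp bins, bins overlapping a target are excluded, and zero-coverage bins
*count* toward the off-target average (a genome-wide average is the honest
denominator for an enrichment claim; the choice is configurable). A zero
off-target average serializes the enrichment ratio as `"inf"`. The time-lag
carryover estimate is simply depth x residual wash fraction.

## Target BED design

"A surrounding 100 kb region" per locus is implemented as a 100-kb *total*
window centered on the tract, because only this reading reproduces a 0.2%
genome fraction for a 59-locus panel plus one 40-kb SNP window
(59 x 100 kb + 40 kb over 3.088 Gb = 0.192%); the per-side reading gives
0.38%. Both modes are available (`mode = "total"` / `"flank"`). Windows are
clipped at contig bounds, sorted, and merged; merging is idempotent and the
covered fraction is monotone in window size.

## The simulator: what it emulates, and what it does not

`simulate_reads()` draws reads from two haplotypes per locus (equal
probability, uniform start, uniform strand) on a mini genome of one contig
per locus (random flanks around `ref_units` copies of the primary motif).
Read lengths are lognormal — default mean 20 kb, sigma 0.5, truncated to
[2 kb, 100 kb] — reflecting libraries sheared to roughly 40 kb and the need
for tract-spanning reads. Default error rates (substitution 1%, insertion
0.5%, deletion 0.5%) are the order of magnitude of raw nanopore read
accuracy in the mid-90s percent range. Errors are applied after repeat
construction, and the SAM CIGAR is emitted from the known edit script, so
no aligner runs anywhere in the test path. Reads are drawn until the
requested spanning depth is realized (with an attempt cap; loci that cannot
be spanned are flagged rather than erroring). The optional motif-miscall
channel corrupts whole source-motif units to a corrupt motif with a per-unit
probability on one strand only; the default probability used in tests, 0.3,
is a placeholder calibrated to make the artifact clearly visible, as no
quantitative rate is published.

What the simulator does **not** model: pore-level signal, realistic quality
strings (constant Q20), context-dependent error hotspots, chimeras,
mosaicism, or adaptive-sampling rejection dynamics. Consequently, passing
tests demonstrate correctness of the *computational* pipeline under a
plausible error model — they do not certify performance on real flow-cell
data, whose locus-specific artifacts (e.g. the AAGGG miscall) are emulated
only in stylized form.

Control cohorts are uniform: two alleles per control within
`ref_units +/- jitter` (default 27 controls, jitter 3), matching the
small-cohort, max-based ranking above. Methylation tables draw each CpG's
probability with a bounded beta-shaped spread of half-width 0.15 around the
allele profile, so a profile-0 allele never emits a probability above 0.2.

## Problem sizes and numerical choices

The validation-cohort benchmark simulates all twelve known genotypes on the
13-locus mini genome (5-kb flanks) at 20x spanning depth with default
errors, adds the two confounders that the real cohort contained (a large
benign TTTTA expansion at TNRC6A ranking above a small CAG gain, and a
heterozygous RFC1 expansion ranking above a DMPK expansion), ranks against
27 simulated controls, and summarizes causal-locus ranks: 100% within the
top two, 83.3% at rank 1 (10/12 — the two confounded patients rank second
by construction). This runs in about a minute on one core. Unit tests use
1-3 locus catalogs, 2-kb flanks and depths 6-20 to keep the default suite
fast; property suites use 8-25 fixed seeds. Half-unit rounding ties go
toward zero everywhere (documented above); medians of integer copy changes
are rounded the same way; all randomness flows through a single integer
seed per simulation, restored after use.

## Known limitations

- The insertion-attribution window is an approximation of the upstream
  per-read measurement tool's (unpublished) rule; boundary insertions from
  flank errors within one motif length of the tract are attributed to it.
- The prioritizer score is a documented stand-in for a delegated ranking
  rule; it is pluggable, and its absolute values are not comparable across
  catalogs with different motif lengths.
- Consensus polishing ignores insertions relative to the medoid; with
  balanced indel errors this is immaterial for unit counting but would bias
  length estimates under asymmetric indel error profiles.
- Triage covers the rule set evidenced by the four case-study archetypes
  (dominant over-threshold, recessive carrier, benign-motif-only, and
  intermediate); clinical edge cases beyond those patterns triage as
  undetermined rather than being guessed.
- The shipped 13-locus catalog is a validation panel, not the 59-locus
  production panel; any catalog following the documented schema is accepted.
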
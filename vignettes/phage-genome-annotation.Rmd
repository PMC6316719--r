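---
title: "Annotating a small phage genome: models, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating a small phage genome: models, parameters and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phannot)
```

`phannot` annotates small, typically circular, phage genomes with a set of
explicit sequence rules: ORF calling with a length cut-off, anti-Shine-
Dalgarno RBS matching with a spacing constraint, stem-loop + U-tract
terminator detection with a nearest-neighbor energy score, codon usage
bias, and programmed-frameshift motif discovery. This vignette explains
each model, its tunable parameters, the numerical choices behind the
implementation, and what the test suite does and does not demonstrate.

## Coordinates and topology

All coordinates are 1-based and inclusive, and a coding feature's stop
coordinate includes the last base of its termination codon, so a span is
always `3 * (length_aa + 1)`. Phage DNA as packaged is terminally
redundant and circularly permuted; the molecule that matters for
annotation circularizes in the host, so topology defaults to circular and
features may cross the origin. A wrapping interval `(start > end)` spans
`(L - start + 1) + end`; the SPP1 terminase gene, which runs from
43,884 across the origin to 311, pins this arithmetic:
`span = 444 = 3 * (147 + 1)` for its 147-aa product. GFF3 has no native
circular-span form, so exports serialise a wrapping feature as two
part-lines sharing an `ID`.

## ORF calling

An ORF runs from an initiation codon in {AUG, GUG, UUG} to the next
in-frame stop. For every (frame, stop) segment one *maximal* ORF is
emitted — the most-upstream start whose product reaches `min_aa` (default
45 aa, counting the initiator but not the stop). Internal qualifying
starts are kept as candidates: they matter for embedded-ORF bookkeeping
and dual-start detection, but they are not independent calls. Circular
genomes are scanned on the doubled sequence and deduplicated by the stop's
genomic position, which makes the call set invariant under rotation (a
property the tests check explicitly).

Scanning defaults to the heavy strand only. Heavy here is operational: the
strand with the higher purine (A+G) content, which is the denser strand in
isopycnic separation and, for SPP1-like phages, the coding strand.
`strand_mode = "both"` is available for general use.

Two refinements reflect how such genomes are actually annotated. First,
an ORF without any RBS that is fully contained in a longer retained ORF is
eliminated as most likely untranslated; non-nested RBS-less ORFs are kept
but flagged, because well-characterised genes can lack an RBS when their
initiation is coupled to the upstream gene's termination (the AUGA overlap
and UAAG-AUG one-base-gap arrangements that
`detect_translational_coupling()` reports). Second, the 45-aa cut-off is a
config knob, not a constant: the threshold includes the initiator
methionine, i.e. `length_aa` counts all codons before the stop.

## RBS model

The anti-SD tail is taken as printed, `UCUUUCCUCCACUAG`, and interpreted
as written 3′→5′: its position-wise Watson-Crick partner, the mRNA-side
template `AGAAAGGAGGUGAUC` (5′→3′), then contains the canonical AGGAGG
core, and reproduces reference patterns such as `AAGGAGGU` and
`AGGAGGUGA`. The alternative orientation contains no AGGAGG-compatible
register, which settles the reading.

The template slides ungapped across a 25 nt window upstream of the start
codon. For each placement the reported site is the best *contiguous
stretch* bounded by paired bases: at most `max_mismatch` (2) internal
mismatches, at least `min_core_paired` (3) paired bases inside the
AGGAGGUG core, score = paired − mismatched, ties broken by fewer
mismatches then smaller spacing. Stretch-based scoring is what makes the
rendered patterns look like the reference tables (`GGgGGU` with its single
lowercase mismatch) instead of sprawling across chance matches; an
exhaustive brute-force oracle in the tests enforces exact equivalence.
Sites with 4+ paired bases are `canonical`; G-rich sites pairing only
3 bases (the GGGG-type arrangement seen upstream of one SPP1 ORF) are
reported as `weak`; anything else is `none`.

Spacing is counted between the anchor base — the template position pairing
the central U of the anti-SD tail, `anchor_index = 8` — and the base
preceding the initiation codon, exclusive on both sides, and must lie in
8–14 nt. Which U of the printed tail carries the anchor is a typographic
convention lost in reproduction, so the anchor is configurable and
`calibrate_anchor()` reports, for a genome plus a reference (pattern,
spacing) table, the anchor index that maximises agreement. On synthetic
genomes with planted RBSs the calibration recovers the default anchor
exactly.

## Terminators and the energy model

A terminator candidate is a hairpin (stem ≥ `min_stem` = 4 bp, loop 3–10
nt) followed within 8 nt by a U-tract scoring at least `min_u` = 3, where
the U-tract score is the largest number of U's in a run tolerating one
single-base interruption. Stems allow at most one internal mismatch;
terminal pairs must hold. G·U wobbles count as pairs — several reference
stems rely on them — but contribute no stacking energy, a deliberately
conservative choice.

The free energy is a nearest-neighbor sum: Watson-Crick stack terms
(keyed by the top-strand dinucleotide) plus a loop-initiation penalty and
a +0.45 kcal/mol terminal A-U penalty, with a Jacobson-Stockmayer
extrapolation for loops beyond the table. Both tables ship as editable
TSVs under `inst/extdata/`. Only hairpins with ΔG° < 0 are reported, and
overlapping candidates collapse to the lowest-energy representative.
These ΔG° values are a stability ranking, not a reproduction of any
particular folding program's numbers: the published reference values for
the 13 SPP1 terminators came from a specific tool whose parameter set is
not recoverable, so the package's contract is recall (each of the 13
sequences yields a candidate with negative ΔG°, and the printed stem
register is among the enumerated decompositions) together with ordering
properties (GC stems below AU stems; ΔG° strictly decreasing as GC pairs
are appended), all of which the tests assert.

## Codon usage, masses, summaries

`codon_usage()` counts every codon of a CDS set including each terminal
stop — the stop family is reported as `End`, so family fractions cover 64
codons — and `compare_usage()` flags a codon divergent when two tables'
within-family fractions differ by more than 0.1 and rare below 0.1, the
conventions of the reference table, whose printed highlighting the
recomputed flags match exactly. Protein masses are average residue masses
(one water added) from a packaged table, reported in kDa.
`summarize_orf_table()` computes the genome-coverage union circular-aware
via a position bitmap, start/stop codon tallies, and mean/SD of product
length and mass. SDs are sample SDs (divisor n−1): recomputing from the
packaged 80-ORF table shows the published ±197 aa / ±21.9 kDa spreads are
sample SDs (196.96 / 21.86), while the population convention would give
195.7 / 21.7. Coverage is rounded to the nearest integer percent for
reporting, matching the reference presentation.

## Frameshift motifs

The +1 signal is a terminal CCC proline codon immediately followed by a
UAA stop: pausing ribosomes slip onto the overlapping CCU codon and read
on in the +1 frame. The −1 signal is a slippery heptamer — the documented
UUUUUUC, plus the classic X XXY YYZ grammar with X, Y ∈ {A, U} — aligned
so the first base sits on a codon's third position. Either site is only
reported if the shifted frame stays open for at least `min_ext` (10)
codons to a downstream stop; both documented SPP1 extensions are an order
of magnitude above that, and the threshold's job is purely to suppress
shifts with no room to produce a distinct protein.
`predict_fusion_products()` emits both products and their shared
amino-terminal length: for a +1 site the entire unshifted product is
shared (the re-read CCU is still proline); for a −1 site the prefix runs
through the XXY codon, e.g. a slip after 112 shared codons for the
tail-chaperone-like arrangement.

## The synthetic-data generator

`genome_spec()`/`synth_genome()` draw an i.i.d. background at a target GC
(default 0.437) and heavy-strand purine fraction (default 0.584) — the
composition the package's reference genome exhibits — and overwrite it
with planted features designed to be *exactly* recoverable:

* each planted ORF gets an upstream in-frame guard stop and a
  start-codon-free leader, so the maximal call begins at the planted
  start;
* the RBS pattern is written with deliberately mismatching template
  positions flanking it (max_mismatch + 1 deep on each side), so the
  scanner's best stretch cannot extend past the plant;
* terminators get a 5′ wall of three C's and non-pairing loop ends, so no
  alternative stem decomposition outscores the planted one;
* −1 sites control their shifted frame out to a planted stop, and +1
  extensions are laid on the shifted codon grid.

Generation is deterministic for a fixed spec (the seed is part of the
spec; the caller's RNG state is saved and restored), and an algorithm
version string is embedded in the output genome id. The background has no
dinucleotide structure, no gene architecture, and no transcriptional
organisation; passing recovery tests on it demonstrates the scanners'
correctness and coordinate arithmetic, not performance on real genomes,
where overlapping signals and compositional heterogeneity make curation
judgement calls the pipeline deliberately does not automate. Consistent
with that, the pipeline does not promise to regenerate the reference
genome's exact 80-ORF/13-terminator inventory from sequence alone — those
counts embed manual curation and an external tool's exact parameters —
and the frameshift/internal-start products of the reference table are
produced by the motif and RBS modules, not by the plain ORF caller.

## Problem sizes and determinism

The shipped tests run the ORF caller against a brute-force oracle on
fifty 2-kb random sequences, the RBS scanner against an exhaustive-offset
oracle on hundreds of 25-nt windows, terminator enumeration against an
exhaustive oracle on 60-nt sequences, and recovery sweeps over 15–40
seeded genomes of 3–8 kb; full-length 44-kb genomes are exercised for
composition statistics. These sizes keep the whole suite under a minute
while every oracle comparison remains exhaustive at its scale. All
pipeline stages are deterministic for fixed input, so exports are
byte-identical across runs.

## Known limitations

* ΔG° values are comparative scores (WC-only stacking, wobbles neutral,
  no dangling ends or coaxial terms); do not compare them numerically to
  other programs' outputs.
* The RBS model is purely pairing-based; no thermodynamic SD scoring, and
  templates for hosts other than the configured 16S tail are possible but
  uncalibrated.
* Promoter prediction, homology search, and transmembrane prediction are
  outside the package's scope; the reference ORF table carries such
  columns as fixture data only.
* The generator's i.i.d. background model under-represents the
  low-complexity and repeat structure of real phage genomes.
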
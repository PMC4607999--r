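---
title: "Profiling insect mitogenomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling insect mitogenomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoprofile)
```

This vignette explains the statistics and algorithms behind `mitoprofile`,
the choices made where several conventions are in circulation, and what the
synthetic-data generator does and does not emulate.

## The data model

An insect mitogenome is a circular molecule of roughly 16 kb carrying 13
protein-coding genes (PCGs), 22 tRNAs, 2 rRNAs and one non-coding A+T-rich
control region. `mito_genome()` stores the molecule as a length, an
optional sequence, and an ordered feature table. Conventions, fixed once
and used everywhere:

* **Coordinates** are 1-based inclusive, as in GenBank records and printed
  feature tables. Conversion to 0-based half-open happens only in
  `write_bed()`; `write_gff()` keeps 1-based coordinates. Round-trips
  between the writers and readers preserve features exactly.
* **Strands** are stored as `J` (majority) and `N` (minority) — the
  vocabulary of mitogenome descriptions — and mapped to `+`/`-` only at
  GFF/BED export.
* A feature may **wrap the origin** (`start > end`); its size is
  `length - start + 1 + end` and extraction concatenates the two slices
  before strand handling. N-strand extraction returns the reverse
  complement, so downstream code always sees the coding strand 5'→3'.
* **Ambiguity codes** are preserved on read and excluded from composition
  denominators, so percentages are reproducible regardless of how many Ns
  an assembly contains.

## Junction arithmetic

The "intergenic" column of a mitogenome table is ambiguous as a header; we
attribute each value to the junction *after* the feature:
`gap = downstream$start − upstream$end − 1`, with the genome length
entering at the last→first junction. This convention reproduces every
printed value of the reference record shipped with the package (e.g. the
55-bp spacer after *trnQ* and the 8-bp overlap after *trnW*). Counts of
spacers and overlaps are always recomputed from coordinates rather than
trusted from an input column; for the shipped record the coordinates give
16 spacers and 8 overlaps. A tiling identity — sizes plus signed gaps sum
to the genome length — holds for any genome whose features cover the
circle once, and is used as a generator self-check.

## Composition and skew

Strand asymmetry is summarized by the Perna–Kocher skews
`(A−T)/(A+T)` and `(G−C)/(G+C)` on counts. Several sign conventions exist
in the literature; this one reproduces all skew columns of the reference
composition table from its own printed percentages, so it is fixed.
`skews_from_percentages()` applies the formulas to printed percentages
without re-normalizing — the right tool for auditing a published table,
where percentages and skews were each rounded independently. Report
rounding is half-away-from-zero (`round_half_up()`), 1 decimal for
percentages and 3 for skews, matching printed tables; full precision is
kept internally. One audit note: recomputing skews from 1-decimal
percentages can shift the third decimal by one unit relative to the
count-derived value (one cell of the reference table does this), which is
why the table-audit tests compare at that resolution.

## Codons under the invertebrate mitochondrial code

Stop-codon assignment uses only the annotated length remainder: a CDS of
length `3k` must end in a complete `TAA`/`TAG` (anything else is a warning,
"other-complete"); `3k+2` must end in `TA`; `3k+1` in `T`. A trailing base
inconsistent with the remainder is an annotation error, not a biological
observation, and raises an error naming the gene. We deliberately do not
search for downstream polyadenylation signals: completion of truncated
stops to TAA is transcript biology, not sequence computation. Start codons
are reported verbatim; non-`ATN` starts (GTG, TCG) are flagged but
accepted, as they occur in real tephritid annotations.
`validate_cds()` scans the frame for internal stops under NCBI translation
table 5 (AGA/AGG = serine), configurable to any table Biostrings knows.

## Stem-loops and poly-T runs

`find_stem_loops()` enumerates hairpins with a stem of at least `min_stem`
bp (default 4), a loop within `loop_range` (default 3–10 nt), optional G·U
wobble pairs (default on) and a mismatch budget (default 0). A hit is
*maximal*: the stem cannot be extended outward or into the loop without
breaking a constraint. Note that at a sequence boundary a shorter stem with
a larger loop can be independently maximal; overlapping hits are by design
reported, sorted by stem length then position. The implementation is an
exhaustive cubic scan — spacers are tens of bases, so there is nothing to
optimize — and is property-tested against an independent string-equality
oracle. Poly-T detection is run-length encoding with a minimum length,
default 7 bp, the conventional reporting threshold for control-region
T-stretches.

## tRNA cloverleaf template folding

We fold tRNAs by constrained template search, not free-energy
minimization: published mitogenome figures present canonical cloverleaves,
and a template is deterministic and dependency-free. The template is
7-bp acceptor stem · D arm (stem 0/3/4 bp, loop 3–11 nt) · anticodon arm
(5-bp stem, 7-nt loop with the anticodon at its centre) · variable region
(3–9 nt) · T arm (stem 0/4/5 bp, loop 3–11 nt) · optional 1-nt
discriminator. A stem of 0 means the whole arm is replaced by an unpaired
linker (up to a full arm's length), which is how mitochondrial tRNAs that
lack a D or T arm are represented. G·U counts as a pair (configurable);
each stem tolerates at most one mismatch. The segmentation maximizing the
total number of paired stem positions wins; ties break toward fewer stem
mismatches, then a fixed enumeration order (no discriminator first, longer
D stem first), so folding is fully deterministic. An arm whose best stem
pairs fewer than 3 bases is reported **absent** — the threshold is our
operationalization of "lacks the loop", chosen to match the smallest DHU
stem observed in real dipteran tRNAs (3 bp). Failure to place a 4-of-5
paired anticodon stem is a fold error.

When the T arm is absent, the variable region and the unpaired linker form
one contiguous unpaired stretch, so their boundary is not identifiable from
sequence; recovery claims are therefore made on identifiable geometry only.

## Comparative phylogenetics

Per-gene alignment is center-star progressive: the center minimizes total
pairwise edit distance; others are merged "once a gap, always a gap" via
global pairwise alignment (match +1, mismatch −1, gap open −4, gap extend
−1, a length-L gap costing 4 + L). These parameters are exposed but not
meant to replicate any particular aligner bit-for-bit. The 13-PCG
supermatrix concatenates per-gene alignments in annotation order with a
partition map; a missing gene is an error unless gap-filling is requested.

Distances are uncorrected p-distances in **percent**, with *pairwise*
deletion of columns containing a gap or ambiguity in either row — congener
mitogenome distances in the literature (≈1–1.4) are only plausible as
percentages, which fixes the scale. Tree inference is Saitou–Nei
neighbor joining with negative branch lengths clamped to zero and the
input put in sorted label order for determinism. Bootstrap resamples
columns with replacement, rebuilds the NJ tree per replicate, and reports
the percentage of replicates containing each internal bipartition of the
full-data tree. We use distance/NJ deliberately: it is exact on additive
matrices, fast enough for property testing, and sufficient for topology
recovery; reproducing model-based ML or Bayesian support values is a
non-goal. All stochastic operations require an explicit seed; there is no
hidden RNG state.

## What the synthetic generator emulates — and what it does not

`generate_mitogenome()` lays out the canonical 38-region tephritid
architecture (the published KR233259 annotation shipped with the package):
gene order and strands, PCG lengths with their real start/stop codons
(including the incomplete TA/T stops), anticodons, a 952-bp control region
with planted 25-bp and 7-bp poly-T stretches, and stem-loops planted in
spacers of ≥18 bp. PCG frames are kept stop-free by rejection sampling of
codons; N-strand genes are generated on the coding strand and
reverse-complemented into the genome, so genome-level skew emerges from
strand placement as in real molecules. tRNAs are built from arm
specifications with perfect Watson–Crick stems and A/C-only loops (A and C
cannot pair with each other, so planted loops never extend a stem by
chance); the generator verifies each tRNA folds back to its specification
and resamples the rare ambiguous construct, honouring its contract that
`fold_trna()` recovers the geometry exactly when no mutations are planted.

Deliberate simplifications: overlapping gene junctions are laid out as
abutting (a synthetic overlap would need one stretch of sequence to
satisfy two coding constraints), so the default synthetic genome is
slightly shorter than the real 15,900 bp; background control-region
sequence can produce additional poly-T runs beyond the planted ones (tests
assert the planted runs are present, not that they are the only ones);
composition is i.i.d. within regions, with no codon-usage structure, CpG
effects or selection; evolution along a tree (`evolve_on_tree()`) is
Jukes–Cantor with optional per-gene rate multipliers and **no indels**, so
annotations carry over unchanged and alignments of simulated tips are
trivially homologous. Passing tests on this generator therefore
demonstrates correctness of the analytics and recoverability of planted
signal — not performance on real sequence, where rate heterogeneity,
indels and alignment error all intrude.

## Problem sizes and numerical checks in the test suite

The suite runs the generator at full genome scale (~15.9 kb, 38 features),
folds 1,000 randomized tRNA constructs (recovery is asserted at ≥99%),
compares the stem-loop scanner to an exhaustive oracle on strings of ≤20
nt, and simulates an 8-leaf tree whose 13-PCG supermatrix (~11 kb) must
yield the generating topology exactly (Robinson–Foulds 0). Jukes–Cantor
calibration compares observed single-branch p-distance to
`3/4(1 − e^(−4b/3))` within three binomial standard errors at genome
length; control-region composition is checked within three binomial
standard errors of the target plus the planted-run offset. These sizes
make every check sharp while keeping a full run in the order of a minute
or two on one core.

## Known limitations

* The GenBank reader is minimal: CDS/tRNA/rRNA/D-loop/misc_feature keys,
  `complement()`/`join()` locations, and `/gene`-style qualifiers. It is
  not a general flat-file parser (no multi-record files, no qualifier
  continuation edge cases beyond those in deposited mitogenomes).
* Template folding cannot represent non-cloverleaf foldbacks, pseudoknots
  or rRNA structure, and its arm-presence threshold (3 paired bases) is a
  convention, not a thermodynamic statement.
* Center-star alignment is a reproducible stand-in for progressive
  aligners; on highly diverged or indel-rich genes a dedicated aligner
  will do better. p-distances use all codon positions; no model
  correction (K2P/GTR) is offered.
* The bootstrap quantifies column-resampling stability of the NJ tree; it
  is not comparable to ML bootstrap or Bayesian posterior values.
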
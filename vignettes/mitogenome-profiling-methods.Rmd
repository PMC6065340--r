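---
title: "Methods: comparative mitogenome profiling with mitoprofiler"
author: "mitoprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative mitogenome profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoprofiler)
```

This vignette is the package's account of its methods: the models and
conventions behind each stage, the tunable parameters and why their
defaults are what they are, what the synthetic generator does and does
not emulate, and the numerical choices made where a design was
genuinely open. Nothing stated here is an empirical claim beyond what
the test suite and `scripts/acceptance.R` themselves compute.

## The genome model

A `MitoGenome` is an optional nucleotide sequence plus an ordered
feature table. Coordinates are **1-based inclusive** throughout, the
convention of published mitogenome profile tables (a gene printed at
12,050–13,873 has size 13,873 − 12,050 + 1 = 1,824 bp). Strands are
the mitochondrial heavy/light pair `H`/`L`; GenBank
`complement(a..b)` locations map to `L`. On a circular molecule a
feature with `stop < start` wraps through the origin and has length
`(L − start + 1) + stop`. Feature ordering is by start position, ties
broken by longer feature first and then by name, so gene-order
signatures are deterministic.

Published annotation tables carry internal inconsistencies (reversed
spans from typographic slips, printed sizes that disagree with their
own coordinates, intergenic counts that do not match adjacent
coordinates). `validateAnnotation()` reconciles them through an
explicit report: a reversed span with a printed size is repaired to
`start + size − 1` and the repair recorded; any other disagreement is
recorded without touching the coordinates. Printed values never
silently override computed ones — every downstream number is coordinate
arithmetic. A reversed span is only treated as a genuine origin-wrap
when no printed size is available and the span could plausibly reach
the genome end.

Intergenic spacers are `next.start − prev.stop − 1` over the
start-sorted features: 0 means abutting, negative means overlap.
Per-genome gap/overlap totals sum positive spacers and absolute
negative spacers **excluding the circular wrap pair** — with the wrap
excluded, the bundled printed-table transcriptions reproduce their
published totals exactly (134/42 and, after the tRNA-His repair,
63/39); a flag includes the wrap pair when wanted.

Tandem gene duplications are maximal runs of adjacent same-name,
same-strand tokens in the gene-order signature. Numbered tRNA copies
(tRNA-Met1/tRNA-Met2) denote the same gene and are merged before run
detection; digits in other gene names (ATP6/ATP8, ND1–ND6) are part of
the name and never merged. Distinct numbered isoacceptors (Leu1/Leu2,
Ser1/Ser2) are not adjacent in vertebrate layouts, so adjacency of
equal stripped names is exactly the duplication signal.

## Strand asymmetry

Base composition is counted exactly; N is excluded from every
denominator, and a zero denominator yields `NA` rather than 0. The
skews are `AT-skew = (A − T)/(A + T)` and `GC-skew = (G − C)/(G + C)`;
both negate under reverse complement, which the suite verifies on a
thousand random sequences.

`skewProfile()` reports each protein-coding gene, each rRNA, the
control region, the 13 PCGs concatenated in genome order (counts are
additive, so the concatenation order cannot matter) and the whole
genome. The default strand convention is `coding_strand`: light-strand
features are reverse-complemented before computing, so skews describe
the strand that is actually read. This is the biologically standard
reporting; published tables do not always state their convention (a
lone positive GC-skew on the one light-strand PCG is the signature of
genome-strand computation), so the convention is an explicit switch
and both are tested. Skews are stored at full precision and rounded to
3 decimals only in printed reports.

## Codon usage under the vertebrate mitochondrial code

The genetic code is translation table 2 (AGA/AGG stop, ATA Met, TGA
Trp), taken from Biostrings rather than retyped. Seven of the thirteen
PCGs in the frog layout end on incomplete stop codons completed to TAA
by polyadenylation of the transcript; extraction pads a trailing `T`
(length ≡ 1 mod 3) with `AA` and a trailing `TA` (length ≡ 2 mod 3)
with `A`, recording the padding. For genomes derived by simulated
divergence the terminal base may have been substituted away; extraction
then falls back on the annotated stop token, with a warning, rather
than failing — the same fallback lets stop stripping keep homologous
gene lengths equal across a population.

Codon usage counts every codon including terminal stops and the
padding-completed codons (printed usage tables tally both; a flag
excludes padded codons). RSCU is `count × family_size / family_total`
with stop codons excluded from families, so each fully observed family
sums to its size; a zero-total family reports `NA`, never 0.
Start codons are tallied verbatim (GTG/ATA/ATT are not recoded to
Met): usage tables count nucleotide codons, not residues. Reports use
the RNA alphabet to mirror printed tables; everything internal is DNA.

## Control-region architecture

The tandem-repeat detector is the one algorithmic component authored
from scratch, since the analysis needs fractional copy numbers,
explicit spans and a defined tie-break rather than an external
black box. For each candidate period *p* the sequence is compared with
itself at lag *p*. Windows of one **and** of two unit lengths whose
identity reaches `min_identity` seed a region — the two-unit window
rescues short arrays in which every single-unit window happens to
straddle two mutations. Seeded stretches separated by at most *p* are
merged; each region is anchored at its outermost run of `min(4, p)`
consecutive matches; a column-majority consensus (ties: alphabetically
first base) is derived; and the final span is the maximal-scoring
segment against the periodic consensus at +1 per match and −2 per
mismatch, which is close to the log-likelihood-ratio weighting of
"array at a few percent divergence" against "unrelated flank". Ties in
the segment score resolve to the earliest-ending, latest-starting
segment, so zero-scoring flank patterns never stretch a span. A span
that also self-matches at a divisor of *p* is reduced to that
primitive period (harmonic candidates are re-refined at the reduced
period so they converge to the native call), and a span whose
primitive period falls below `min_period` — homopolymer or
microsatellite structure — is discarded. Overlapping calls across
periods resolve by longer span, then smaller period, then leftmost
start.

Defaults — `min_period = 5`, `max_period = 200`, `min_copies = 2.5`,
`min_identity = 0.85` — span the 8–124 bp repeat units observed in
frog control regions with margin on both sides. Copy numbers are
reported to one decimal, the precision used in published repeat
tables. The detector is verified two ways: exact equivalence with an
independently written brute-force implementation of the same published
definition on short sequences, and statistical recovery of planted
arrays (period exact, copy number within ±0.3) across the
period/copy-number grid of the published tables at 0–3% per-site unit
divergence. Edge placement at a few percent divergence is inherently
ambiguous by one or two bases per edge (a substituted terminal base is
indistinguishable from flank, and a quarter of flank bases continue
the consensus phase by chance), which is why the recovery guarantee is
statistical rather than per-instance.

Motif scanning is IUPAC-aware Hamming matching (no indels) with a
per-motif mismatch budget; overlapping hits of one motif reduce to the
best per locus (fewest mismatches, then leftmost). The TAS consensus
shipped in `inst/extdata/motifs.tsv` is the published frog 17-mer; the
CSB-1/2/3 and OH entries are synthetic placeholders (published CSB
alignments exist only as figures) and the file is data, meant to be
edited per study system; the truncated `GACAT` penta-motif ships as an
optional alternative pattern. An absent configured motif is reported
with an explicit absent marker rather than dropped, since motif
absence (a missing CSB-2) is itself a finding. Architecture
coordinates are control-region-local and 1-based, matching published
D-loop feature tables.

## Supermatrix preparation

Gene alignments are accepted pre-aligned; no aligner is implemented
(real data should be aligned with external tools; the generator emits
equal-length homologous genes so alignment is the identity).
Concatenation joins genes in the canonical mitochondrial order (ND1,
ND2, COX1, COX2, ATP8, ATP6, COX3, ND3, ND4L, ND4, ND5, ND6, CYTB)
with partitions tiling the matrix exactly; terminal stop codons —
complete, padded, or annotated — are stripped first.

Site classification works per column over unambiguous states only
(gaps and N are missing): conserved iff at most one state, variable
otherwise, parsimony-informative iff at least two states each occur in
at least two rows, singleton = variable − informative. Columns with no
unambiguous state at all are counted as conserved by convention and
reported separately, keeping `conserved + variable = total` a hard
identity. Published site counts for multi-genome supermatrices depend
on the authors' taxon sampling and aligner and are not reproducible
from coordinates alone; the suite therefore tests the classifier's
definitions and identities, not those totals.

p-distance is the proportion of differing sites over columns where
both sequences carry an unambiguous base (cross-checked against
`ape::dist.dna(model = "raw")` on clean data); a pair with no shared
columns is an error, not a silent 0. Trees come from `ape::nj` —
canonical neighbor-joining, consistent on additive matrices — and are
serialized with 6-decimal branch lengths for deterministic output.
This is sanity plumbing; model-based inference is exported (NEXUS with
charsets, relaxed PHYLIP with a RAxML-style partition file) rather
than implemented.

## The synthetic generator

`generateMitogenome()` emulates the annotated frog mitogenome: the
40-feature layout (13 PCGs, 23 tRNAs with the duplicated tRNA-Met
between tRNA-Gln and ND2, 2 rRNAs, light-strand origin, control
region) loaded from the bundled printed-table transcription, a
genome-wide A+T target of 0.58 with an AT-richer control region at
0.66, heavy-strand skew targets of −0.04 (AT) and −0.26 (GC) — values
typical of dicroglossid mitogenomes — and codon bias implemented as
sampling weights over synonymous codons (the product of base
propensities, exponentially tilted so the expected A+T per coding base
still hits the target after the AT-rich stop codons are excluded).
Because bias enters through sampling weights rather than post-hoc
editing, RSCU recovery on generator output is a genuine statistical
test: A/T-ending codons come out overused because they were planted
more probable, not because counts were edited.

Start and stop codons (complete and incomplete) are stamped first and
protected; the three planted PCG overlaps (ATP8/ATP6 −7, ND4L/ND4 −7,
ND5/ND6 −15, the last across strands) share sequence by construction,
with overlap codons chosen — and where necessary re-sampled in a
repair pass — to be stop-free in every reading frame that covers them.
The control region is assembled from a plan of repeat arrays (the 5'
array carrying one TAS per unit at the published offsets, so planted
TAS positions land on the published coordinates) and motif placements,
with per-array unit divergence defaulting to 2%. One seed governs all
randomness; regeneration is byte-identical.

`mutatePopulation()` applies independent per-site substitutions under
a uniform single-nucleotide model. The bundled trio fixture is
hierarchical — A and B diverge 2% from a shared intermediate copy
(itself 4% from the ancestor) while C diverges 10% directly — so the
planted topology `((A,B),C)` has a genuinely positive internal branch
and neighbor-joining recovery is a meaningful check. A star trio (A,
B, C independently from one ancestor) satisfies the pairwise-distance
ordering but carries no internal branch, a distinction the tests
respect.

What the generator does **not** emulate: realistic substitution
processes (no transition/transversion bias, no rate heterogeneity, no
indels), tRNA secondary structure, selection on codon positions, and
real control-region sequence beyond its repeat/motif skeleton. Tests
that pass on generator output therefore demonstrate the pipeline's
arithmetic and statistical behaviour under the planted model, not
performance on the full complexity of real mitogenomes — which is why
the coordinate-level results are additionally anchored to the bundled
transcriptions of published tables, and why an optional helper script
can fetch the deposited accessions for a direct comparison when a
network is available.

## Problem sizes and reproducibility

The suite and the acceptance script size their simulations for quick,
deterministic runs: 100 planted-repeat trials over the
period × copy-number × divergence grid, 200 oracle-equivalence cases
on sequences up to 300 bp, 1,000 random strings for skew symmetry, 50
random alignments for the site identities, 20 seeded trios for
topology recovery, and a handful of full ~17.8 kb synthetic genomes
shared across test files. All randomness flows from explicit seeds;
every report writer emits bytes deterministically (no timestamps), and
the acceptance script recomputes everything from scratch under the
seed it is given.
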
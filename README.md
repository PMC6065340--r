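# mitoprofiler

Comparative profiling of annotated mitochondrial genomes, built around
the analyses typically reported for newly sequenced vertebrate
mitogenomes — the ~17–18.5 kb circular genomes of high-altitude
*Nanorana* frogs being the motivating case: 13 protein-coding genes
(PCGs), 22–23 tRNAs (with a tandemly duplicated tRNA-Met between
tRNA-Gln and ND2 in dicroglossids), two rRNAs, the light-strand
replication origin, and a large control region carrying tandem-repeat
arrays and conserved motifs. The package is for molecular systematists
and mitogenome annotators who want those descriptive analyses as
tested, reusable functions rather than one-off spreadsheets.

## What it computes

- **Annotation accounting** — validated in-memory genome model
  (1-based inclusive coordinates, H/L strands, origin-wrapping
  features), per-gene sizes, signed intergenic spacers
  (`gap = next.start − prev.stop − 1`; negative = overlap), per-genome
  gap/overlap totals, gene-order signatures, and tandem gene
  duplication detection. Printed tables are reconciled against
  coordinate arithmetic through an explicit validation report — printed
  values never silently override computed ones.
- **Strand asymmetry** — base composition and the skew statistics
  `AT-skew = (A − T)/(A + T)`, `GC-skew = (G − C)/(G + C)` per gene,
  per rRNA, for the control region, the concatenated 13 PCGs, the
  whole genome, and optionally per codon position. N is excluded from
  all denominators; zero denominators yield an explicit `NA`.
- **Codon usage** — codon extraction honouring incomplete stop codons
  (a trailing `T`/`TA` completed to `TAA` by polyadenylation is padded
  before counting), start/stop classification, 64-codon usage tables,
  relative synonymous codon usage
  `RSCU(c) = n_c · |family| / Σ_family n`, and amino-acid frequencies,
  all under the vertebrate mitochondrial code (AGA/AGG stop, ATA Met,
  TGA Trp).
- **Control-region architecture** — tandem-repeat detection by
  period-wise self-matching with consensus-refined edges and
  primitive-period reduction (periods 5–200 bp by default, fractional
  copy numbers reported to one decimal), IUPAC-aware motif scanning
  (TAS, CSB-1/2/3, OH; editable consensus table), merged into an
  ordered per-region report with `n × p + r` length decompositions.
- **Supermatrix preparation** — stop-codon-stripped 13-PCG
  concatenation with partition bookkeeping, conserved / variable /
  parsimony-informative site counts, p-distances, a neighbor-joining
  sanity tree, and FASTA/PHYLIP/NEXUS export (with charset blocks /
  RAxML-style partition files) for external Bayesian/ML inference.
- **Synthetic mitogenomes** — a seeded generator that plants every
  signal above (layout with duplicated tRNA-Met and the three shared
  PCG overlaps, AT/skew targets, codon bias, control-region repeat and
  motif plan, divergence plans for population trios) and records the
  ground truth, so the whole pipeline is testable without downloading
  any accession.

## Worked example

Reading a published-style annotation table and reconciling it against
coordinate arithmetic:

```r
library(mitoprofiler)
rows <- readFeatureTable(system.file("extdata",
        "table1_ventripunctata.tsv", package = "mitoprofiler"))
va <- validateAnnotation(rows, "N_ventripunctata")
va$genome
#> MitoGenome 'N_ventripunctata': 18,373 bp, circular, annotation only
#>   features: 40 (13 PCG, 23 tRNA, 2 rRNA, 1 origin, 1 control_region)
va$report
#>    feature             issue printed recomputed repaired
#> 1 tRNA-His stop_before_start   11813      11882     TRUE
#> 2      ND3     size_mismatch     385        358    FALSE
gapOverlapTotals(va$genome)
#>     gap overlap
#>      63      39
```

The tRNA-His row of the printed table has its stop before its start; the
validator reconstructs the stop from the printed size (11,814 + 69 − 1 =
11,882) and records the repair, after which the genome's intergenic
accounting lands on 63 gap and 39 overlap nucleotides. The ND3 row's
printed size (385) disagrees with its own coordinates (358); the
mismatch is recorded and the coordinates kept.

Decomposing a (here synthetic) control region into its repeat arrays
and motifs:

```r
res <- generateMitogenome(syntheticSpec(seed = 1))
arch <- crArchitecture(res$genome)
head(arch[arch$present, c("type", "name", "start", "stop",
                          "period", "copy_number", "decomposition")], 4)
#>    type          name start stop period copy_number decomposition
#>  repeat tandem_repeat    43  611    124         4.6  4 x 124 + 73
#>   motif           TAS   151  167     NA          NA          <NA>
#>   motif         GACAT   156  160     NA          NA          <NA>
#>   motif           TAS   275  291     NA          NA          <NA>
```

The 5' array is called with its planted 124-bp period and 4.6 copies,
with the termination-associated sequence (TAS) copies embedded one per
repeat unit, exactly as the generator planted them (the truth record is
in `res$truth`). `runAll()` chains every stage over a set of genomes
and writes the full report bundle (validation, profile, skews, codon
usage/RSCU, control-region architecture, gene-order comparison,
supermatrix + site statistics + NJ tree) as deterministic TSV/JSON
files; `inst/scripts/mitoprofiler.R` exposes the same pipeline as a
command-line tool.

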
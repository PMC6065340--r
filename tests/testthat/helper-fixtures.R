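# Shared fixtures and independent oracles for the test suite.

table1_path <- function(which) {
  system.file("extdata", paste0("table1_", which, ".tsv"),
              package = "mitoprofiler", mustWork = TRUE)
}

load_table1 <- function(which) {
  suppressWarnings(
    validateAnnotation(readFeatureTable(table1_path(which)), which))
}

table3 <- function() {
  read.delim(system.file("extdata", "table3_codon_usage.tsv",
                         package = "mitoprofiler", mustWork = TRUE),
             colClasses = c(rep("character", 2L), rep("integer", 3L)))
}

## Default-spec synthetic genomes are reused across test files.
.gen_cache <- new.env(parent = emptyenv())
cached_mitogenome <- function(seed) {
  key <- as.character(seed)
  if (is.null(.gen_cache[[key]])) {
    .gen_cache[[key]] <- generateMitogenome(syntheticSpec(seed = seed))
  }
  .gen_cache[[key]]
}

## Random DNA string at given AT content.
random_dna <- function(n, at = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)),
        collapse = "")
}

revcomp_chr <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

## Plant a tandem array (random or given unit, mutated at `mut`) inside
## random flanks; returns the sequence and the planted span. The two
## flank positions adjacent to each array edge are forced to break the
## repeat phase, so the planted boundary is well-defined (a random
## flank can otherwise genuinely continue the pattern).
plant_repeat <- function(period, copies, mut = 0.02, flank = 300L,
                         unit = NULL) {
  span <- round(period * copies)
  if (is.null(unit)) {
    unit <- paste(sample(c("A", "C", "G", "T"), period, replace = TRUE),
                  collapse = "")
  }
  arr <- strsplit(strrep(unit, ceiling(span / period)), "")[[1]][1:span]
  hit <- runif(span) < mut
  arr[hit] <- vapply(arr[hit], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  f1 <- strsplit(random_dna(flank), "")[[1]]
  f2 <- strsplit(random_dna(flank), "")[[1]]
  for (d in 1:2) {
    f1[flank - d + 1L] <- sample(setdiff(c("A", "C", "G", "T"),
                                         arr[period - d + 1L]), 1L)
    f2[d] <- sample(setdiff(c("A", "C", "G", "T"),
                            arr[span - period + d]), 1L)
  }
  list(sequence = paste0(paste(f1, collapse = ""),
                         paste(arr, collapse = ""),
                         paste(f2, collapse = "")),
       start = flank + 1L, stop = flank + span,
       period = period, copies = round(span / period, 1L), unit = unit)
}

## Brute-force gap/overlap totals: all-pairs scan for adjacency by
## start order, naive arithmetic (oracle for gapOverlapTotals).
brute_gap_overlap <- function(ft) {
  ft <- ft[order(ft$start, -(ft$stop - ft$start), ft$name), ]
  gap <- 0L; ov <- 0L
  for (i in seq_len(nrow(ft) - 1L)) {
    d <- ft$start[i + 1L] - ft$stop[i] - 1L
    if (d > 0L) gap <- gap + d else ov <- ov - d
  }
  c(gap = gap, overlap = ov)
}
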
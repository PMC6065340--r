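# Base composition and strand-asymmetry (skew) statistics:
# AT-skew = (A - T)/(A + T), GC-skew = (G - C)/(G + C).

#' Base composition of a sequence
#'
#' Counts are exact; the AT and GC fractions are computed over the
#' unambiguous bases only (N excluded from the denominator).
#'
#' @param sequence a single string over A/C/G/T/N, or a
#'   \code{DNAString}.
#' @return list with \code{counts} (named A/C/G/T/N), \code{length},
#'   \code{at_fraction}, \code{gc_fraction}.
#' @examples
#' baseComposition("ACGT")$at_fraction  # 0.5
#' @export
baseComposition <- function(sequence) {
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop("empty sequence")
  counts <- Biostrings::letterFrequency(Biostrings::DNAString(sequence),
                                        letters = c("A", "C", "G", "T", "N"))
  counts <- setNames(as.integer(counts), c("A", "C", "G", "T", "N"))
  acgt <- sum(counts[c("A", "C", "G", "T")])
  list(counts = counts,
       length = nchar(sequence),
       at_fraction = if (acgt > 0L) unname((counts["A"] + counts["T"]) / acgt)
                     else NA_real_,
       gc_fraction = if (acgt > 0L) unname((counts["G"] + counts["C"]) / acgt)
                     else NA_real_)
}

.skew <- function(p, q) {
  if (p + q == 0) NA_real_ else (p - q) / (p + q)
}

#' AT skew of a sequence
#'
#' \code{(A - T)/(A + T)}; \code{NA} (the undefined marker) when
#' \code{A + T == 0}.
#'
#' @param sequence string over A/C/G/T/N or \code{DNAString}.
#' @return numeric in \code{[-1, 1]} or \code{NA}.
#' @examples
#' atSkew("AAAT")  # 0.5
#' @export
atSkew <- function(sequence) {
  cc <- baseComposition(sequence)$counts
  .skew(cc[["A"]], cc[["T"]])
}

#' GC skew of a sequence
#'
#' \code{(G - C)/(G + C)}; \code{NA} when \code{G + C == 0}.
#'
#' @inheritParams atSkew
#' @return numeric in \code{[-1, 1]} or \code{NA}.
#' @export
gcSkew <- function(sequence) {
  cc <- baseComposition(sequence)$counts
  .skew(cc[["G"]], cc[["C"]])
}

#' Per-region skew profile of a mitogenome
#'
#' One row per protein-coding gene, per rRNA and for the control region,
#' plus a \code{"13PCG"} row (the protein-coding genes concatenated in
#' genome order) and an \code{"Overall"} row for the full genome
#' sequence. Under the default \code{coding_strand} convention,
#' light-strand features are reverse-complemented before computing, so
#' skews describe the strand that is actually read; under
#' \code{genome_strand} every region is taken verbatim from the heavy
#' strand as assembled.
#'
#' @param genome a \code{MitoGenome} with sequence attached.
#' @param strand_convention \code{"coding_strand"} (default) or
#'   \code{"genome_strand"}.
#' @param by_codon_position also emit rows \code{<gene>:pos1/2/3} with
#'   skews over each codon position of every protein-coding gene.
#' @return data.frame (the skew profile) with columns \code{region},
#'   \code{category}, \code{length}, \code{at_fraction},
#'   \code{at_skew}, \code{gc_skew}. Values are stored at full
#'   precision; round to 3 decimals for printed-table comparison.
#' @export
skewProfile <- function(genome,
                        strand_convention = c("coding_strand",
                                              "genome_strand"),
                        by_codon_position = FALSE) {
  strand_convention <- match.arg(strand_convention)
  stopifnot(is(genome, "MitoGenome"))
  if (!length(genome@sequence)) stop("genome has no sequence attached")
  ft <- features(genome)
  keep <- ft$category %in% c("PCG", "rRNA", "control_region")
  ft <- ft[keep, , drop = FALSE]
  rows <- list()
  add_row <- function(region, category, s) {
    bc <- baseComposition(s)
    rows[[length(rows) + 1L]] <<- data.frame(
      region = region, category = category, length = bc$length,
      at_fraction = bc$at_fraction,
      at_skew = .skew(bc$counts[["A"]], bc$counts[["T"]]),
      gc_skew = .skew(bc$counts[["G"]], bc$counts[["C"]]),
      stringsAsFactors = FALSE)
  }
  pcg_seqs <- character(0)
  for (i in seq_len(nrow(ft))) {
    row <- ft[i, ]
    s <- tryCatch(.feature_sequence(genome, row, strand_convention),
                  error = function(e) NULL)
    if (is.null(s)) {
      warning("skipping region without resolvable span: ", row$name)
      next
    }
    add_row(row$name, row$category, s)
    if (row$category == "PCG") {
      pcg_seqs <- c(pcg_seqs, s)
      if (by_codon_position) {
        ch <- .chars(s)
        for (p in 1:3) {
          idx <- seq(p, length(ch), by = 3L)
          add_row(paste0(row$name, ":pos", p), "PCG_codon_position",
                  .collapse(ch[idx]))
        }
      }
    }
  }
  if (length(pcg_seqs)) {
    add_row("13PCG", "concatenated_PCG", .collapse(pcg_seqs))
  }
  add_row("Overall", "genome", genome@sequence)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
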
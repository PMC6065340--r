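# Length, spacer and overlap accounting on the in-memory genome model,
# plus gene-order signatures and tandem-duplication detection.

#' Feature length in bp (wrap-aware)
#'
#' For non-wrapping features this is \code{stop - start + 1}; a feature
#' with \code{stop < start} on a circular genome wraps through the origin
#' and has length \code{(genome_length - start + 1) + stop}.
#'
#' @param start,stop 1-based inclusive coordinates (vectorized).
#' @param genome_length total genome length, required for wrapping
#'   features.
#' @param circular whether the genome is circular.
#' @return integer vector of lengths.
#' @examples
#' featureLength(12050, 13873)          # 1824
#' featureLength(17836, 2, 17837, TRUE) # 4
#' @export
featureLength <- function(start, stop, genome_length = NA_integer_,
                          circular = TRUE) {
  start <- as.integer(start); stop <- as.integer(stop)
  wraps <- stop < start
  if (any(wraps)) {
    if (!circular) stop("stop < start on a linear genome")
    if (anyNA(genome_length)) stop("genome_length needed for wrapping feature")
  }
  ifelse(wraps, (as.integer(genome_length) - start + 1L) + stop,
         stop - start + 1L)
}

#' Intergenic spacers between adjacent features
#'
#' For features sorted by start, the signed gap between consecutive pairs
#' is \code{next_start - prev_stop - 1}: 0 means abutting, negative means
#' overlap. On a circular genome the wrap pair (last feature back to the
#' first) is appended with \code{wrap = TRUE}.
#'
#' @param genome a \code{MitoGenome} (or a feature data.frame with
#'   \code{name}, \code{start}, \code{stop}).
#' @return data.frame with columns \code{upstream}, \code{downstream},
#'   \code{gap}, \code{wrap}; zero rows for an empty genome.
#' @export
intergenicSpacers <- function(genome) {
  if (is(genome, "MitoGenome")) {
    ft <- features(genome)
    circular <- isCircular(genome)
    glen <- genomeLength(genome)
  } else {
    ft <- as.data.frame(genome)
    circular <- TRUE
    glen <- if (nrow(ft)) max(ft$stop) else 0L
  }
  if (nrow(ft) < 2L) {
    return(data.frame(upstream = character(0), downstream = character(0),
                      gap = integer(0), wrap = logical(0)))
  }
  ft <- ft[.feature_order(ft), , drop = FALSE]
  up <- ft$name[-nrow(ft)]
  dn <- ft$name[-1L]
  gap <- ft$start[-1L] - ft$stop[-nrow(ft)] - 1L
  out <- data.frame(upstream = up, downstream = dn, gap = gap,
                    wrap = FALSE, stringsAsFactors = FALSE)
  if (circular) {
    wrap_gap <- (ft$start[1L] - 1L) + (glen - ft$stop[nrow(ft)])
    out <- rbind(out, data.frame(upstream = ft$name[nrow(ft)],
                                 downstream = ft$name[1L],
                                 gap = as.integer(wrap_gap), wrap = TRUE))
  }
  rownames(out) <- NULL
  out
}

#' Total gap and overlap nucleotides across a genome
#'
#' Sums positive spacers (gaps) and the absolute value of negative
#' spacers (overlaps) over adjacent feature pairs. The wrap-around pair
#' of a circular genome is excluded by default, which is how published
#' per-genome gap/overlap totals are tallied.
#'
#' @param genome a \code{MitoGenome} or feature data.frame.
#' @param include_wrap include the wrap pair in the totals.
#' @return named integer vector \code{c(gap = ..., overlap = ...)}.
#' @export
gapOverlapTotals <- function(genome, include_wrap = FALSE) {
  sp <- intergenicSpacers(genome)
  if (!include_wrap) sp <- sp[!sp$wrap, , drop = FALSE]
  c(gap = sum(sp$gap[sp$gap > 0L]),
    overlap = sum(-sp$gap[sp$gap < 0L]))
}

#' Gene-order signature
#'
#' The ordered sequence of (canonical name, strand) tokens, ordered by
#' start position (ties: longer feature first, then name); origins and
#' the control region are included as tokens.
#'
#' @param genome a \code{MitoGenome} or feature data.frame.
#' @return data.frame with columns \code{name}, \code{strand}.
#' @export
geneOrderSignature <- function(genome) {
  ft <- if (is(genome, "MitoGenome")) features(genome) else
    as.data.frame(genome)
  stopifnot(nrow(ft) > 0L)
  ft <- ft[.feature_order(ft), , drop = FALSE]
  out <- data.frame(name = ft$name, strand = ft$strand,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Compare two gene-order signatures
#'
#' @param a,b signatures from [geneOrderSignature()].
#' @return list with \code{identical} and, when they differ,
#'   \code{first_difference} (index of the first mismatching token;
#'   length differences count from the end of the shorter signature).
#' @export
compareGeneOrder <- function(a, b) {
  n <- min(nrow(a), nrow(b))
  tok_a <- paste(a$name, a$strand)[seq_len(n)]
  tok_b <- paste(b$name, b$strand)[seq_len(n)]
  diff <- which(tok_a != tok_b)
  if (!length(diff) && nrow(a) == nrow(b)) {
    list(identical = TRUE, first_difference = NA_integer_)
  } else {
    list(identical = FALSE,
         first_difference = if (length(diff)) diff[1L] else n + 1L)
  }
}

#' Find tandemly duplicated features in a gene-order signature
#'
#' Maximal runs of two or more adjacent tokens with identical name and
#' strand, reported with the features immediately flanking the run --
#' the pattern of the duplicated tRNA-Met between tRNA-Gln and ND2 in
#' dicroglossid frogs.
#'
#' @param signature a signature from [geneOrderSignature()] (or a
#'   \code{MitoGenome}).
#' @return data.frame with columns \code{name}, \code{strand},
#'   \code{copies}, \code{upstream}, \code{downstream}.
#' @export
findTandemDuplicates <- function(signature) {
  if (is(signature, "MitoGenome")) signature <- geneOrderSignature(signature)
  stopifnot(nrow(signature) > 0L)
  ## tRNA-Met1/tRNA-Met2-style numbered copies are the same gene: strip
  ## a trailing copy index from tRNA names only (ATP6/ATP8, ND1-6 etc.
  ## are distinct genes whose digits are part of the name). Distinct
  ## numbered isoacceptors (Leu1/Leu2, Ser1/Ser2) are never adjacent in
  ## vertebrate layouts, so adjacency of equal stripped names is the
  ## tandem-duplication signal.
  base <- ifelse(grepl("^tRNA-", signature$name),
                 sub("[0-9]+$", "", signature$name), signature$name)
  tok <- paste(base, signature$strand)
  r <- rle(tok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$lengths >= 2L)
  out <- data.frame(name = base[starts[keep]],
                    strand = signature$strand[starts[keep]],
                    copies = r$lengths[keep],
                    upstream = ifelse(starts[keep] > 1L,
                                      signature$name[starts[keep] - 1L],
                                      signature$name[nrow(signature)]),
                    downstream = ifelse(ends[keep] < nrow(signature),
                                        signature$name[ends[keep] + 1L],
                                        signature$name[1L]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Validate raw annotation rows and build a MitoGenome
#'
#' Reconciles printed values with coordinate arithmetic. Where
#' \code{stop < start} but a printed size is available, the stop is
#' reconstructed as \code{start + size - 1} and the repair recorded;
#' where the printed size disagrees with the computed span, a mismatch is
#' recorded without touching the coordinates; printed intergenic values
#' that disagree with recomputed spacers are likewise recorded. Printed
#' values never silently override computed ones.
#'
#' @param rows data.frame from [readFeatureTable()].
#' @param identifier genome label for the resulting object.
#' @param circular circularity flag (default TRUE).
#' @return list with \code{genome} (a \code{MitoGenome}, no sequence) and
#'   \code{report} (data.frame: \code{feature}, \code{issue},
#'   \code{printed}, \code{recomputed}, \code{repaired}). The report is
#'   empty iff every printed value is self-consistent.
#' @export
validateAnnotation <- function(rows, identifier = "genome",
                               circular = TRUE) {
  stopifnot(nrow(rows) > 0L)
  rows$name <- normalizeGeneName(rows$name)
  rep_list <- list()
  note <- function(feature, issue, printed, recomputed, repaired) {
    rep_list[[length(rep_list) + 1L]] <<- data.frame(
      feature = feature, issue = issue, printed = printed,
      recomputed = recomputed, repaired = repaired,
      stringsAsFactors = FALSE)
  }
  glen_guess <- max(rows$stop, rows$start)
  for (i in seq_len(nrow(rows))) {
    if (rows$stop[i] < rows$start[i]) {
      ## A reversed span is either a true origin-wrapping feature or a
      ## typographic error. Wrapping can only involve the feature that
      ## reaches the genome end; a short internal reversal is repaired
      ## from the printed size.
      could_wrap <- circular && rows$start[i] > glen_guess - rows$stop[i]
      if (!could_wrap || !is.na(rows$printed_size[i])) {
        if (is.na(rows$printed_size[i])) {
          stop("irreparable row '", rows$name[i],
               "': stop < start and no printed size")
        }
        new_stop <- rows$start[i] + rows$printed_size[i] - 1L
        note(rows$name[i], "stop_before_start", rows$stop[i], new_stop,
             TRUE)
        rows$stop[i] <- new_stop
      }
    }
  }
  glen <- max(rows$stop)
  comp_len <- featureLength(rows$start, rows$stop, glen, circular)
  for (i in seq_len(nrow(rows))) {
    if (!is.na(rows$printed_size[i]) &&
        rows$printed_size[i] != comp_len[i]) {
      ## repairs above make size consistent by construction; skip those
      already <- any(vapply(rep_list, function(r)
        r$feature == rows$name[i] && r$repaired, TRUE))
      if (!already) {
        note(rows$name[i], "size_mismatch", rows$printed_size[i],
             comp_len[i], FALSE)
      }
    }
  }
  ft <- data.frame(name = rows$name,
                   category = .resolve_category(rows$name),
                   strand = rows$strand, start = rows$start,
                   stop = rows$stop, start_codon = rows$start_codon,
                   stop_codon = rows$stop_codon,
                   anticodon = NA_character_, stringsAsFactors = FALSE)
  genome <- MitoGenome(identifier, ft, circular = circular)
  sp <- intergenicSpacers(genome)
  gap_after <- setNames(sp$gap, sp$upstream)
  for (i in seq_len(nrow(rows))) {
    pg <- rows$printed_intergenic[i]
    cg <- gap_after[rows$name[i]]
    if (!is.na(pg) && !is.na(cg) && pg != cg) {
      note(rows$name[i], "intergenic_mismatch", pg, as.integer(cg), FALSE)
    }
  }
  report <- if (length(rep_list)) do.call(rbind, rep_list) else
    data.frame(feature = character(0), issue = character(0),
               printed = integer(0), recomputed = integer(0),
               repaired = logical(0))
  rownames(report) <- NULL
  list(genome = genome, report = report)
}
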
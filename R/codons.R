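# Codon extraction with incomplete-stop completion, codon usage, RSCU
# and amino-acid frequencies under the vertebrate mitochondrial code.

.code_env <- new.env(parent = emptyenv())

#' The vertebrate mitochondrial genetic code
#'
#' Taken from the standard translation-table 2 (AGA/AGG are stop, ATA is
#' Met, TGA is Trp), with the synonymous-family map derived from it.
#'
#' @return list with \code{code} (named character, 64 DNA codons to
#'   one-letter amino acid or \code{"*"}) and \code{families} (list:
#'   amino acid to its synonymous codon set, stops excluded).
#' @export
vertebrateMitoCode <- function() {
  if (is.null(.code_env$code)) {
    code <- Biostrings::getGeneticCode("2")
    stopifnot(length(code) == 64L)
    .code_env$code <- code
    aa <- code[code != "*"]
    .code_env$families <- split(names(aa), unname(aa))
  }
  list(code = .code_env$code, families = .code_env$families)
}

#' Extract the codon-ready coding sequence of a protein-coding gene
#'
#' The genomic span is extracted (wrap-aware) and reverse-complemented
#' for light-strand genes. Incomplete stop codons, completed to TAA by
#' polyadenylation of the transcript, are padded at the 3' end: a
#' trailing T with length = 1 (mod 3) receives \code{"AA"}; a trailing
#' TA with length = 2 (mod 3) receives \code{"A"}. Any other non-triplet
#' length is an error.
#'
#' @param genome a \code{MitoGenome} with sequence.
#' @param feature a feature name or a single feature-table row; must be
#'   a protein-coding gene.
#' @return list with \code{sequence} (padded, length divisible by 3),
#'   \code{padding} (\code{""}, \code{"A"} or \code{"AA"}),
#'   \code{name}, \code{strand}.
#' @export
codingSequence <- function(genome, feature) {
  stopifnot(is(genome, "MitoGenome"), length(genome@sequence) == 1L)
  if (is.character(feature)) {
    ft <- features(genome)
    hit <- which(ft$name == feature)
    if (!length(hit)) stop("no feature named '", feature, "'")
    feature <- ft[hit[1L], ]
  }
  if (feature$category != "PCG") {
    stop("'", feature$name, "' is not a protein-coding gene")
  }
  s <- .feature_sequence(genome, feature, "coding_strand")
  n <- nchar(s)
  padding <- ""
  if (n %% 3L == 1L && substr(s, n, n) == "T") {
    padding <- "AA"
  } else if (n %% 3L == 2L && substr(s, n - 1L, n) == "TA") {
    padding <- "A"
  }
  if (!nzchar(padding) && n %% 3L != 0L &&
      isTRUE(feature$stop_codon %in% c("T-", "TA-"))) {
    ## the observed terminal base no longer spells the incomplete stop
    ## (e.g. a substitution in a derived genome); trust the annotation
    padding <- if (feature$stop_codon == "T-") "AA" else "A"
    if ((n + nchar(padding)) %% 3L == 0L) {
      warning("gene '", feature$name, "' padded from its annotated ",
              "incomplete stop; terminal base does not spell it")
    } else {
      padding <- ""
    }
  }
  s <- paste0(s, padding)
  if (nchar(s) %% 3L != 0L) {
    stop("gene '", feature$name, "' has length ", n,
         " not reducible to codons by incomplete-stop padding")
  }
  list(sequence = s, padding = padding, name = feature$name,
       strand = feature$strand, annotated_stop = feature$stop_codon)
}

.split_codons <- function(s) {
  substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
}

#' Classify the start and stop codons of a codon-ready sequence
#'
#' The start codon is the first codon verbatim (no recoding to Met).
#' The stop token is \code{"T-"} or \code{"TA-"} when padding completed
#' an incomplete stop, otherwise the terminal codon when it is one of
#' TAA/TAG/AGA/AGG, otherwise the warning token \code{"??"}.
#'
#' @param cs a codon-ready sequence from [codingSequence()] (or a plain
#'   in-frame string, taken as unpadded).
#' @return list with \code{start_codon} and \code{stop_codon}.
#' @export
classifyCodons <- function(cs) {
  if (is.character(cs)) cs <- list(sequence = cs, padding = "")
  s <- cs$sequence
  stopifnot(nchar(s) %% 3L == 0L, nchar(s) >= 6L)
  start <- substr(s, 1L, 3L)
  last <- substr(s, nchar(s) - 2L, nchar(s))
  stop_token <- if (identical(cs$padding, "AA")) {
    "T-"
  } else if (identical(cs$padding, "A")) {
    "TA-"
  } else if (last %in% .stop_codons) {
    last
  } else {
    warning("unrecognized terminal codon ", last, " without padding")
    "??"
  }
  list(start_codon = start, stop_codon = stop_token)
}

#' Codon usage counts over a set of coding sequences
#'
#' Tallies all codons, including terminal stop codons and the codons
#' completed by incomplete-stop padding (printed codon-usage tables
#' count both). Counts are over DNA codons; use \code{rna = TRUE} for
#' the RNA (U) spelling used in printed tables.
#'
#' @param coding_sequences list of codon-ready sequences
#'   ([codingSequence()] results or plain in-frame strings).
#' @param count_padded include the final (padding-completed) codon of
#'   genes with incomplete stops (default TRUE).
#' @param rna report codons in the RNA alphabet.
#' @return named integer vector over all 64 codons (a codon usage
#'   table), with attribute \code{total}.
#' @export
codonUsage <- function(coding_sequences, count_padded = TRUE,
                       rna = FALSE) {
  code <- vertebrateMitoCode()$code
  counts <- setNames(integer(64L), names(code))
  for (cs in coding_sequences) {
    if (is.character(cs)) cs <- list(sequence = cs, padding = "")
    codons <- .split_codons(cs$sequence)
    if (!count_padded && nzchar(cs$padding)) {
      codons <- codons[-length(codons)]
    }
    codons <- codons[!grepl("N", codons)]
    tab <- table(codons)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  if (rna) names(counts) <- gsub("T", "U", names(counts))
  attr(counts, "total") <- sum(counts)
  counts
}

.as_dna_codons <- function(usage) {
  names(usage) <- gsub("U", "T", names(usage))
  usage
}

#' Relative synonymous codon usage (RSCU)
#'
#' \code{RSCU(c) = count(c) * family_size / sum(family counts)} within
#' each synonymous family of the genetic code; stop codons are excluded.
#' A family with zero total yields \code{NA} for all its codons.
#'
#' @param usage a codon usage table from [codonUsage()] (DNA or RNA
#'   spelling).
#' @param code genetic code from [vertebrateMitoCode()].
#' @return data.frame with columns \code{codon}, \code{amino_acid},
#'   \code{count}, \code{rscu}, ordered by amino acid then codon.
#' @export
rscu <- function(usage, code = vertebrateMitoCode()) {
  usage <- .as_dna_codons(usage)
  rows <- list()
  for (aa in sort(names(code$families))) {
    fam <- sort(code$families[[aa]])
    cnt <- as.integer(usage[fam])
    cnt[is.na(cnt)] <- 0L
    tot <- sum(cnt)
    val <- if (tot > 0L) cnt * length(fam) / tot else rep(NA_real_,
                                                          length(fam))
    rows[[aa]] <- data.frame(codon = fam, amino_acid = aa, count = cnt,
                             rscu = val, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Amino-acid frequencies from a codon usage table
#'
#' Percent of non-stop codons translating to each amino acid.
#'
#' @inheritParams rscu
#' @return named numeric vector of percentages (sums to 100 when any
#'   non-stop codon was observed).
#' @export
aaFrequencies <- function(usage, code = vertebrateMitoCode()) {
  usage <- .as_dna_codons(usage)
  aa <- code$code[names(usage)]
  keep <- aa != "*"
  totals <- tapply(as.integer(usage[keep]), unname(aa[keep]), sum)
  out <- 100 * totals / sum(totals)
  out[order(names(out))]
}
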
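#' MitoGenome: an annotated (circular) mitochondrial genome
#'
#' Central container of the package: an optional nucleotide sequence plus
#' an ordered feature table. Coordinates are 1-based inclusive throughout;
#' strands use the mitochondrial heavy/light convention (\code{"H"},
#' \code{"L"}). A feature whose \code{stop} is smaller than its
#' \code{start} on a circular genome is interpreted as wrapping through
#' the origin.
#'
#' @slot identifier single character, the genome/accession label.
#' @slot circular logical, whether the molecule is circular.
#' @slot sequence character of length 0 (no sequence attached) or 1
#'   (residues over A/C/G/T/N).
#' @slot features \code{data.frame} with columns \code{name},
#'   \code{category} (one of PCG, tRNA, rRNA, origin, control_region),
#'   \code{strand} (H/L), \code{start}, \code{stop}, \code{start_codon},
#'   \code{stop_codon}, \code{anticodon}.
#'
#' @seealso [MitoGenome()] for construction, [features()],
#'   [genomeLength()], [genomeSequence()] for access.
#' @export
setClass("MitoGenome",
  representation(identifier = "character",
                 circular   = "logical",
                 sequence   = "character",
                 features   = "data.frame"))

.feature_columns <- c("name", "category", "strand", "start", "stop",
                      "start_codon", "stop_codon", "anticodon")

setValidity("MitoGenome", function(object) {
  msgs <- character(0)
  if (length(object@identifier) != 1L || !nzchar(object@identifier))
    msgs <- c(msgs, "identifier must be a single non-empty string")
  if (length(object@circular) != 1L || is.na(object@circular))
    msgs <- c(msgs, "circular must be TRUE or FALSE")
  if (length(object@sequence) > 1L)
    msgs <- c(msgs, "sequence slot holds at most one string")
  if (length(object@sequence) == 1L && !.is_dna_string(object@sequence))
    msgs <- c(msgs, "sequence must be non-empty over A/C/G/T/N")
  ft <- object@features
  missing_cols <- setdiff(.feature_columns, names(ft))
  if (length(missing_cols)) {
    msgs <- c(msgs, paste("features lacks columns:",
                          paste(missing_cols, collapse = ", ")))
  } else if (nrow(ft)) {
    if (!all(ft$category %in% .feature_categories))
      msgs <- c(msgs, "unknown feature category")
    if (!all(ft$strand %in% c("H", "L")))
      msgs <- c(msgs, "strand must be 'H' or 'L'")
    if (any(ft$start < 1L) || any(ft$stop < 1L))
      msgs <- c(msgs, "coordinates must be >= 1")
    if (!object@circular && any(ft$stop < ft$start))
      msgs <- c(msgs, "stop < start feature on a linear genome")
    if (length(object@sequence) == 1L) {
      n <- nchar(object@sequence)
      if (any(ft$start > n) || any(ft$stop > n))
        msgs <- c(msgs, "feature coordinates beyond sequence length")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Supermatrix: a concatenated multi-gene alignment with partitions
#'
#' Holds an alignment as a character matrix (rows = taxa, one column per
#' site, states over A/C/G/T/N/-) together with the per-gene partition
#' table. Partitions tile \code{1..ncol} without gaps or overlap.
#'
#' @slot alignment character matrix with taxa as rownames.
#' @slot partitions \code{data.frame} with columns \code{gene},
#'   \code{first}, \code{last} (1-based inclusive column ranges).
#'
#' @seealso [concatenateAlignments()], [alignment()], [partitions()],
#'   [classifySites()], [writeAlignment()].
#' @export
setClass("Supermatrix",
  representation(alignment = "matrix", partitions = "data.frame"))

setValidity("Supermatrix", function(object) {
  msgs <- character(0)
  aln <- object@alignment
  if (!is.character(aln)) msgs <- c(msgs, "alignment must be character")
  if (is.null(rownames(aln)) || anyDuplicated(rownames(aln)))
    msgs <- c(msgs, "taxa (rownames) must be unique and present")
  pt <- object@partitions
  if (!all(c("gene", "first", "last") %in% names(pt))) {
    msgs <- c(msgs, "partitions needs columns gene, first, last")
  } else if (nrow(pt)) {
    expected_first <- c(1L, head(pt$last, -1L) + 1L)
    if (!identical(as.integer(pt$first), expected_first) ||
        pt$last[nrow(pt)] != ncol(aln))
      msgs <- c(msgs, "partitions must tile 1..ncol(alignment)")
  }
  if (length(msgs)) msgs else TRUE
})
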
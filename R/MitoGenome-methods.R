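#' Construct a MitoGenome
#'
#' @param identifier genome label (e.g. an accession).
#' @param features feature table; missing optional columns
#'   (\code{start_codon}, \code{stop_codon}, \code{anticodon}) are added
#'   as \code{NA}. Rows are sorted by start position (ties: longer
#'   feature first, then name).
#' @param sequence optional residues, a single string or a
#'   \linkS4class{DNAString}; upper-cased on entry.
#' @param circular whether the molecule is circular (default TRUE).
#' @return a validated \linkS4class{MitoGenome}.
#' @examples
#' ft <- data.frame(name = "ND5", category = "PCG", strand = "H",
#'                  start = 12050L, stop = 13873L)
#' g <- MitoGenome("toy", ft)
#' featureLength(features(g)$start, features(g)$stop)
#' @export
MitoGenome <- function(identifier, features, sequence = NULL,
                       circular = TRUE) {
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  for (col in c("start_codon", "stop_codon", "anticodon")) {
    if (is.null(features[[col]])) features[[col]] <- NA_character_
  }
  features$start <- as.integer(features$start)
  features$stop  <- as.integer(features$stop)
  features <- features[, .feature_columns, drop = FALSE]
  if (nrow(features)) {
    features <- features[.feature_order(features), , drop = FALSE]
    rownames(features) <- NULL
  }
  if (is.null(sequence)) {
    sequence <- character(0)
  } else {
    sequence <- toupper(as.character(sequence))
  }
  new("MitoGenome", identifier = identifier, circular = circular,
      sequence = sequence, features = features)
}

#' @describeIn MitoGenome feature table accessor
#' @param x a \code{MitoGenome}
#' @export
setGeneric("features", function(x) standardGeneric("features"))

#' @rdname MitoGenome
#' @export
setMethod("features", "MitoGenome", function(x) x@features)

#' @describeIn MitoGenome genome length in bp: the sequence length when a
#'   sequence is attached, otherwise the maximum feature stop.
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))

#' @rdname MitoGenome
#' @export
setMethod("genomeLength", "MitoGenome", function(x) {
  if (length(x@sequence)) return(nchar(x@sequence))
  if (nrow(x@features)) return(max(x@features$stop, x@features$start))
  0L
})

#' @describeIn MitoGenome attached sequence as a
#'   \linkS4class{DNAString}, or NULL when absent
#' @export
setGeneric("genomeSequence", function(x) standardGeneric("genomeSequence"))

#' @rdname MitoGenome
#' @export
setMethod("genomeSequence", "MitoGenome", function(x) {
  if (!length(x@sequence)) return(NULL)
  Biostrings::DNAString(x@sequence)
})

#' @describeIn MitoGenome circularity flag
#' @export
setGeneric("isCircular", function(x) standardGeneric("isCircular"))

#' @rdname MitoGenome
#' @export
setMethod("isCircular", "MitoGenome", function(x) x@circular)

#' @describeIn MitoGenome identifier accessor
#' @export
setGeneric("genomeID", function(x) standardGeneric("genomeID"))

#' @rdname MitoGenome
#' @export
setMethod("genomeID", "MitoGenome", function(x) x@identifier)

setMethod("show", "MitoGenome", function(object) {
  ft <- object@features
  cat("MitoGenome '", object@identifier, "': ",
      format(genomeLength(object), big.mark = ","), " bp, ",
      if (object@circular) "circular" else "linear",
      if (length(object@sequence)) ", sequence attached" else
        ", annotation only",
      "\n", sep = "")
  if (nrow(ft)) {
    tab <- table(factor(ft$category, levels = .feature_categories))
    cat("  features: ", nrow(ft), " (",
        paste(paste0(tab, " ", names(tab))[tab > 0], collapse = ", "),
        ")\n", sep = "")
  } else {
    cat("  features: none\n")
  }
  invisible(NULL)
})

## Internal: extract a feature's genomic span, honouring strand under the
## requested convention ("coding_strand" reverse-complements L features).
.feature_sequence <- function(genome, row, convention = "coding_strand") {
  stopifnot(length(genome@sequence) == 1L)
  s <- .extract_span(genome@sequence, row$start, row$stop,
                     circular = genome@circular)
  if (identical(convention, "coding_strand") && row$strand == "L") {
    s <- .revcomp(s)
  }
  s
}
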
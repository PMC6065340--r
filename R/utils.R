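# Internal helpers shared across modules. Sequences move through the
# package as plain upper-case character strings over {A,C,G,T,N}; the
# Biostrings classes appear at the API boundary (I/O, motif matching).

.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

.collapse <- function(x) paste(x, collapse = "")

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.revcomp <- function(s) {
  if (!nzchar(s)) return(s)
  .collapse(rev(unname(.COMPLEMENT[.chars(s)])))
}

## Numeric fields in printed annotation tables carry thousands separators
## and typographic minus signs; both are accepted.
.parse_printed_int <- function(x) {
  x <- gsub("[,   ]", "", x)
  x <- gsub("[−–—]", "-", x)
  x[!nzchar(x)] <- NA_character_
  out <- suppressWarnings(as.integer(x))
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    stop("non-numeric value in numeric column: ",
         paste(unique(x[bad]), collapse = ", "))
  }
  out
}

## "T-", "T--", and the typeset "T<en-dash>" all denote the same
## incomplete stop codon; likewise for "TA-".
.normalize_stop_token <- function(x) {
  y <- gsub("[−–—]", "-", x)
  y[grepl("^T-+$", y)] <- "T-"
  y[grepl("^TA-+$", y)] <- "TA-"
  y
}

## 1-based inclusive subsequence extraction, wrapping through the origin
## of a circular genome when stop < start.
.extract_span <- function(sequence, start, stop, circular = TRUE) {
  n <- nchar(sequence)
  if (start < 1L || stop < 1L || start > n || stop > n) {
    stop("span ", start, "..", stop, " outside sequence of length ", n)
  }
  if (stop >= start) {
    substr(sequence, start, stop)
  } else {
    if (!circular) stop("stop < start on a linear sequence")
    paste0(substr(sequence, start, n), substr(sequence, 1L, stop))
  }
}

## Deterministic feature ordering: by start, ties broken by longer
## feature first, then by name.
.feature_order <- function(df) {
  len <- df$stop - df$start + 1L
  order(df$start, -len, df$name, method = "radix")
}

.is_dna_string <- function(s) {
  nzchar(s) && !grepl("[^ACGTN]", s)
}

.round1 <- function(x) round(x + 1e-9, 1L)
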
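# External formats: FASTA, a GenBank flat-file subset
# (LOCUS/FEATURES/ORIGIN), the tab-separated annotation-table dialect
# used by printed mitogenome profiles, and alignment export
# (FASTA / relaxed PHYLIP / NEXUS with a sets block). No analysis logic
# lives here.

#' Read a FASTA file of mitochondrial sequences
#'
#' Residues are upper-cased; letters outside A/C/G/T/N are mapped to N
#' with a warning. Record identifiers are the first whitespace-delimited
#' token of each header.
#'
#' @param path file path.
#' @return a named \linkS4class{DNAStringSet}, one element per record in
#'   file order.
#' @export
readMitoFasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty FASTA file: ", path)
  is_header <- startsWith(lines, ">")
  if (!is_header[1L]) {
    stop("FASTA format error at line 1 of ", path,
         ": sequence data before any header")
  }
  rec <- cumsum(is_header)
  ids <- sub("^>\\s*", "", lines[is_header])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, "", 1L)
  seqs <- vapply(split(lines[!is_header], rec[!is_header]),
                 paste, "", collapse = "")
  seqs <- toupper(seqs)
  n_unknown <- sum(vapply(gregexpr("[^ACGTN]", seqs),
                          function(m) sum(m > 0L), 0L))
  if (n_unknown > 0L) {
    warning(n_unknown, " residue(s) outside A/C/G/T/N mapped to N")
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  if (length(seqs) < length(ids)) {  # trailing header without residues
    seqs <- c(seqs, setNames(character(length(ids) - length(seqs)),
                             seq_along(ids)[-seq_along(seqs)]))
  }
  Biostrings::DNAStringSet(setNames(seqs[as.character(seq_along(ids))], ids))
}

#' Write sequences as FASTA
#'
#' @param sequences named character vector or \code{DNAStringSet}.
#' @param path output path.
#' @param width line width for wrapping (default 70).
#' @return \code{path}, invisibly. Output is byte-deterministic.
#' @export
writeMitoFasta <- function(sequences, path, width = 70L) {
  sequences <- setNames(as.character(sequences), names(sequences))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(sequences)) {
    s <- sequences[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(c(paste0(">", names(sequences)[i]),
                 substring(s, starts, pmin(starts + width - 1L, nchar(s)))),
               con, sep = "\n")
  }
  invisible(path)
}

## ---- GenBank flat-file subset ------------------------------------------

.gb_feature_map <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                     rep_origin = "origin", `D-loop` = "control_region")

.parse_gb_location <- function(loc) {
  strand <- "H"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "L"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  wrap <- FALSE
  if (grepl("^join\\(", loc)) {
    parts <- strsplit(sub("^join\\((.*)\\)$", "\\1", loc), ",")[[1L]]
    if (length(parts) != 2L) stop("unsupported join location: ", loc)
    a <- as.integer(strsplit(parts[1L], "\\.\\.")[[1L]])
    b <- as.integer(strsplit(parts[2L], "\\.\\.")[[1L]])
    if (b[1L] != 1L) stop("unsupported join location: ", loc)
    return(list(start = a[1L], stop = b[2L], strand = strand, wrap = TRUE))
  }
  xs <- as.integer(strsplit(loc, "\\.\\.")[[1L]])
  if (length(xs) == 1L) xs <- c(xs, xs)
  list(start = xs[1L], stop = xs[2L], strand = strand, wrap = wrap)
}

#' Read a GenBank flat file into a MitoGenome
#'
#' Parses the LOCUS line, the CDS/tRNA/rRNA/rep_origin/D-loop entries of
#' the FEATURES table (plain, \code{complement(a..b)} and two-part
#' origin-wrapping \code{join} locations) and the ORIGIN sequence block.
#' \code{complement} maps to the light strand. Gene names are normalized
#' through the bundled synonym table.
#'
#' @param path file path.
#' @return a \linkS4class{MitoGenome} with sequence attached (when an
#'   ORIGIN block is present).
#' @export
readGenBank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("not a GenBank flat file (no LOCUS): ", path)
  toks <- strsplit(trimws(locus[1L]), "\\s+")[[1L]]
  identifier <- toks[2L]
  declared_len <- suppressWarnings(as.integer(toks[3L]))
  circular <- any(grepl("circular", locus[1L], ignore.case = TRUE))

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  fend <- if (length(ostart)) ostart[1L] - 1L else length(lines)
  rows <- list()
  if (length(fstart)) {
    block <- lines[(fstart[1L] + 1L):fend]
    block <- block[!grepl("^(BASE COUNT|CONTIG)", block)]
    key_idx <- grep("^ {5}\\S", block)
    for (k in seq_along(key_idx)) {
      i <- key_idx[k]
      j <- if (k < length(key_idx)) key_idx[k + 1L] - 1L else length(block)
      entry <- block[i:j]
      key <- sub("^ {5}(\\S+).*", "\\1", entry[1L])
      if (!key %in% names(.gb_feature_map)) next
      loc_txt <- trimws(sub("^ {5}\\S+\\s+", "", entry[1L]))
      quals <- entry[-1L]
      get_qual <- function(q) {
        hit <- grep(paste0("^\\s+/", q, "="), quals, value = TRUE)
        if (!length(hit)) return(NA_character_)
        gsub('^\\s+/[a-z_]+="?|"?\\s*$', "", hit[1L])
      }
      loc <- .parse_gb_location(loc_txt)
      nm <- get_qual("gene")
      if (is.na(nm)) nm <- get_qual("product")
      if (is.na(nm)) nm <- key
      rows[[length(rows) + 1L]] <- data.frame(
        name = nm, category = unname(.gb_feature_map[key]),
        strand = loc$strand, start = loc$start, stop = loc$stop,
        start_codon = NA_character_, stop_codon = NA_character_,
        anticodon = get_qual("anticodon"), wrap = loc$wrap,
        stringsAsFactors = FALSE)
    }
  }
  ft <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(0), category = character(0),
               strand = character(0), start = integer(0), stop = integer(0),
               start_codon = character(0), stop_codon = character(0),
               anticodon = character(0), wrap = logical(0))

  sequence <- NULL
  if (length(ostart)) {
    seq_lines <- lines[(ostart[1L] + 1L):length(lines)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    sequence <- gsub("[^ACGTN]", "N", sequence)
    if (!nzchar(sequence)) sequence <- NULL
  }
  total_len <- if (!is.null(sequence)) nchar(sequence) else declared_len
  if (!is.na(total_len) && nrow(ft)) {
    beyond <- ft$stop > total_len | ft$start > total_len
    bad <- beyond & !(circular & ft$wrap)
    if (any(bad)) {
      stop("feature '", ft$name[which(bad)[1L]],
           "' extends beyond sequence length ", total_len)
    }
  }
  ft$wrap <- NULL
  ft$name <- normalizeGeneName(ft$name)
  ft$category <- .resolve_category(ft$name, ft$category)
  MitoGenome(identifier, ft, sequence = sequence, circular = circular)
}

#' Write a MitoGenome as a GenBank-style flat file
#'
#' Emits the LOCUS/FEATURES/ORIGIN subset understood by [readGenBank()];
#' output is byte-deterministic (no timestamps).
#'
#' @param genome a \code{MitoGenome} with sequence attached.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGenBank <- function(genome, path) {
  stopifnot(is(genome, "MitoGenome"), length(genome@sequence) == 1L)
  seqs <- genome@sequence
  n <- nchar(seqs)
  rev_map <- setNames(names(.gb_feature_map), .gb_feature_map)
  out <- c(sprintf("LOCUS       %s %d bp    DNA     %s   UNA",
                   genomeID(genome), n,
                   if (isCircular(genome)) "circular" else "linear"),
           "FEATURES             Location/Qualifiers")
  ft <- features(genome)
  for (i in seq_len(nrow(ft))) {
    loc <- if (ft$stop[i] >= ft$start[i]) {
      sprintf("%d..%d", ft$start[i], ft$stop[i])
    } else {
      sprintf("join(%d..%d,1..%d)", ft$start[i], n, ft$stop[i])
    }
    if (ft$strand[i] == "L") loc <- sprintf("complement(%s)", loc)
    out <- c(out,
             sprintf("     %-16s%s", rev_map[[ft$category[i]]], loc),
             sprintf('                     /gene="%s"', ft$name[i]))
  }
  out <- c(out, "ORIGIN")
  starts <- seq(1L, n, by = 60L)
  for (s in starts) {
    chunk <- substr(seqs, s, min(s + 59L, n))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", s, paste(tolower(tens), collapse = " ")))
  }
  out <- c(out, "//")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n")
  invisible(path)
}

## ---- annotation-table dialect ------------------------------------------

.table_dialect_cols <- c("gene", "strand", "from", "to", "size",
                         "start_codon", "stop_codon", "intergenic")

#' Read a printed-style annotation table (TSV)
#'
#' The dialect mirrors published mitogenome profile tables: columns
#' \code{gene}, \code{strand} (H/L), \code{from}, \code{to}, and
#' optionally \code{size}, \code{start_codon}, \code{stop_codon},
#' \code{intergenic}. Thousands separators and typographic minus signs
#' in numeric fields are stripped; incomplete stop-codon tokens
#' ("T-", "T--", en-dash variants) are normalized to \code{"T-"} /
#' \code{"TA-"}.
#'
#' @param path file path.
#' @return a data.frame of raw feature rows with columns \code{name},
#'   \code{strand}, \code{start}, \code{stop}, \code{printed_size},
#'   \code{start_codon}, \code{stop_codon}, \code{printed_intergenic}.
#' @export
readFeatureTable <- function(path) {
  raw <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    colClasses = "character", check.names = FALSE,
                    blank.lines.skip = TRUE)
  if (!nrow(raw) && !ncol(raw)) stop("empty annotation table: ", path)
  names(raw) <- tolower(trimws(names(raw)))
  mandatory <- c("gene", "strand", "from", "to")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols)) {
    stop("annotation table lacks mandatory column(s) ",
         paste(missing_cols, collapse = ", "), "; columns found: ",
         paste(names(raw), collapse = ", "))
  }
  if (!nrow(raw)) stop("annotation table has no rows: ", path)
  opt <- function(col) if (col %in% names(raw)) raw[[col]] else
    rep(NA_character_, nrow(raw))
  out <- data.frame(
    name = trimws(raw$gene),
    strand = toupper(trimws(raw$strand)),
    start = .parse_printed_int(raw$from),
    stop = .parse_printed_int(raw$to),
    printed_size = .parse_printed_int(opt("size")),
    start_codon = toupper(trimws(opt("start_codon"))),
    stop_codon = .normalize_stop_token(toupper(trimws(opt("stop_codon")))),
    printed_intergenic = .parse_printed_int(opt("intergenic")),
    stringsAsFactors = FALSE)
  out$start_codon[!nzchar(out$start_codon) | is.na(out$start_codon)] <-
    NA_character_
  out$stop_codon[!nzchar(out$stop_codon) | is.na(out$stop_codon)] <-
    NA_character_
  if (anyNA(out$start) || anyNA(out$stop))
    stop("missing from/to coordinate in annotation table")
  if (!all(out$strand %in% c("H", "L")))
    stop("strand tokens must be H or L")
  out
}

#' Write a MitoGenome's annotation as a printed-style table
#'
#' Inverse of [readFeatureTable()] (round-trips coordinates, codons and
#' the recomputed size/intergenic columns).
#'
#' @param genome a \code{MitoGenome}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFeatureTable <- function(genome, path) {
  ft <- features(genome)
  sp <- intergenicSpacers(genome)
  gap_after <- sp$gap[match(ft$name, sp$upstream)]
  df <- data.frame(gene = ft$name, strand = ft$strand, from = ft$start,
                   to = ft$stop,
                   size = featureLength(ft$start, ft$stop,
                                        genomeLength(genome),
                                        circular = isCircular(genome)),
                   start_codon = ifelse(is.na(ft$start_codon), "",
                                        ft$start_codon),
                   stop_codon = ifelse(is.na(ft$stop_codon), "",
                                       ft$stop_codon),
                   intergenic = ifelse(is.na(gap_after), "", gap_after),
                   stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}

## ---- gene-name normalization -------------------------------------------

.synonym_env <- new.env(parent = emptyenv())

#' Bundled gene-name synonym table
#'
#' Loaded from \code{inst/extdata/gene_synonyms.tsv} (editable data, not
#' code). Maps the many spellings of mitochondrial gene names
#' (COI/COXI/cox1, D-loop/control region, ...) to canonical tokens and
#' their feature category.
#'
#' @return data.frame with columns \code{canonical}, \code{category},
#'   \code{synonyms}.
#' @export
geneSynonyms <- function() {
  if (is.null(.synonym_env$tab)) {
    path <- system.file("extdata", "gene_synonyms.tsv",
                        package = "mitoprofiler", mustWork = TRUE)
    .synonym_env$tab <- read.delim(path, colClasses = "character",
                                   comment.char = "#")
    syn <- .synonym_env$tab
    keys <- c(syn$canonical,
              unlist(strsplit(syn$synonyms, "|", fixed = TRUE)))
    vals <- c(syn$canonical,
              rep(syn$canonical,
                  lengths(strsplit(syn$synonyms, "|", fixed = TRUE))))
    .synonym_env$lookup <- setNames(vals, tolower(keys))
    .synonym_env$category <- setNames(syn$category, syn$canonical)
  }
  .synonym_env$tab
}

#' Normalize gene names to canonical tokens
#'
#' @param x character vector of gene names as found in annotation files.
#' @return canonical tokens where a synonym matches; unmatched names are
#'   returned unchanged (trimmed).
#' @examples
#' normalizeGeneName(c("COI", "cox1", "D-loop"))
#' @export
normalizeGeneName <- function(x) {
  geneSynonyms()
  x <- trimws(x)
  hit <- unname(.synonym_env$lookup[tolower(x)])
  ifelse(is.na(hit), x, hit)
}

## Category for canonical names; falls back to the supplied category.
.resolve_category <- function(name, fallback = NULL) {
  geneSynonyms()
  hit <- .synonym_env$category[name]
  if (is.null(fallback)) fallback <- rep(NA_character_, length(name))
  out <- ifelse(is.na(hit), fallback, unname(hit))
  if (anyNA(out)) stop("cannot resolve category for: ",
                       paste(unique(name[is.na(out)]), collapse = ", "))
  out
}

## ---- alignment export --------------------------------------------------

#' Write an alignment in FASTA, relaxed PHYLIP or NEXUS format
#'
#' NEXUS output carries the partitions as a \code{sets} block of charset
#' lines; PHYLIP output writes them to a sibling \code{<path>.partitions}
#' file (RAxML style). Output is byte-deterministic.
#'
#' @param x a \linkS4class{Supermatrix}, a character matrix (taxa as
#'   rownames) or a named character vector of equal-length sequences.
#' @param path output path.
#' @param format one of \code{"fasta"}, \code{"phylip-relaxed"},
#'   \code{"nexus"}.
#' @param partitions optional partition data.frame (\code{gene},
#'   \code{first}, \code{last}); taken from the supermatrix when given.
#' @return \code{path}, invisibly.
#' @export
writeAlignment <- function(x, path,
                           format = c("fasta", "phylip-relaxed", "nexus"),
                           partitions = NULL) {
  format <- match.arg(format)
  if (is(x, "Supermatrix")) {
    partitions <- partitions(x)
    x <- apply(alignment(x), 1L, paste, collapse = "")
  } else if (is.matrix(x)) {
    x <- apply(x, 1L, paste, collapse = "")
  }
  if (is.null(names(x)) || !all(nzchar(names(x))))
    stop("alignment rows must be named by taxon")
  widths <- nchar(x)
  if (length(unique(widths)) > 1L)
    stop("ragged alignment: row widths ", paste(unique(widths),
                                                collapse = ", "))
  nchar_aln <- widths[1L]
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (format == "fasta") {
    for (i in seq_along(x)) {
      writeLines(c(paste0(">", names(x)[i]), x[[i]]), con, sep = "\n")
    }
  } else if (format == "phylip-relaxed") {
    writeLines(sprintf(" %d %d", length(x), nchar_aln), con, sep = "\n")
    writeLines(sprintf("%s  %s", names(x), x), con, sep = "\n")
    if (!is.null(partitions) && nrow(partitions)) {
      pcon <- file(paste0(path, ".partitions"), open = "wb")
      writeLines(sprintf("DNA, %s = %d-%d", partitions$gene,
                         partitions$first, partitions$last), pcon, sep = "\n")
      close(pcon)
    }
  } else {
    out <- c("#NEXUS", "begin data;",
             sprintf("  dimensions ntax=%d nchar=%d;", length(x), nchar_aln),
             "  format datatype=dna missing=N gap=-;", "  matrix",
             sprintf("    %s  %s", names(x), x),
             "  ;", "end;")
    if (!is.null(partitions) && nrow(partitions)) {
      out <- c(out, "begin sets;",
               sprintf("  charset %s = %d-%d;", partitions$gene,
                       partitions$first, partitions$last),
               "end;")
    }
    writeLines(out, con, sep = "\n")
  }
  invisible(path)
}
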
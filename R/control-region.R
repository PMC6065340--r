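# Control-region architecture: tandem-repeat array detection and
# conserved-motif scanning (TAS, CSB-1/2/3, OH), merged into an ordered
# report with coordinates local to the control region.

#' Detect tandem-repeat arrays by period-wise self-matching
#'
#' For each candidate period p the sequence is compared against itself
#' at lag p. Windows of one and of two period lengths whose identity
#' reaches \code{min_identity} seed candidate regions (the two-unit
#' window rescues short arrays in which every one-unit window happens to
#' span two mutations); seeded stretches separated by at most p are
#' merged. Each region is anchored at its outermost run of
#' \code{min(4, p)} consecutive lag-p matches, a column-majority
#' consensus unit is derived, and the final span is the maximal-scoring
#' segment (+1 consensus match, -2 mismatch; ties resolved to the
#' earliest-ending, then latest-starting segment) around the anchor, so
#' isolated mutations near the edges neither shave nor inflate the
#' span. A region whose final span also self-matches at a divisor of p
#' at the identity threshold is reduced to that primitive period, and a
#' span whose primitive period lies below \code{min_period}
#' (homopolymer/microsatellite structure) is discarded. Copy number is
#' span/period. Overlapping calls across periods are resolved
#' by longer span, then smaller period, then leftmost start.
#'
#' @param sequence a single string over A/C/G/T/N or \code{DNAString}.
#' @param min_period,max_period period range in bp; requires
#'   \code{1 <= min_period <= max_period <= length/2}.
#' @param min_copies minimum (unrounded) copy number to report.
#' @param min_identity minimum windowed and region-mean identity.
#' @return data.frame with columns \code{start}, \code{stop} (1-based
#'   inclusive, local to \code{sequence}), \code{period},
#'   \code{copy_number} (1 decimal), \code{consensus},
#'   \code{mean_identity} (lag-period identity over the span), ordered
#'   by start.
#' @examples
#' detectTandemRepeats("ACGTACGTACGT", min_period = 2, max_period = 6)
#' @export
detectTandemRepeats <- function(sequence, min_period = 5L,
                                max_period = 200L, min_copies = 2.5,
                                min_identity = 0.85) {
  sequence <- toupper(as.character(sequence))
  n <- nchar(sequence)
  if (n == 0L) stop("empty sequence")
  if (min_period < 1L || min_period > max_period ||
      max_period > n %/% 2L) {
    stop("invalid period range [", min_period, ", ", max_period,
         "] for sequence of length ", n)
  }
  if (min_copies < 1 || min_identity <= 0 || min_identity > 1) {
    stop("invalid min_copies/min_identity")
  }
  x <- .chars(sequence)
  cand <- list()
  for (p in seq.int(min_period, max_period)) {
    n_match <- n - p
    if (n_match - p + 1L < 1L) break
    m <- x[seq_len(n_match)] == x[seq.int(p + 1L, n)]
    cs <- c(0L, cumsum(m))
    ## seed coverage from qualifying windows of width p and 2p
    covered <- logical(n_match)
    for (w in unique(c(p, 2L * p))) {
      n_win <- n_match - w + 1L
      if (n_win < 1L) next
      wsum <- cs[seq.int(w + 1L, n_match + 1L)] - cs[seq_len(n_win)]
      ok <- wsum / w >= min_identity - 1e-9
      if (!any(ok)) next
      ## dilate: position j is covered when any qualifying window of
      ## width w starts in (j-w, j]
      ck <- cumsum(ok)
      j <- seq_len(n_match)
      lo_idx <- pmax(j - w + 1L, 1L)
      hit <- ck[pmin(j, n_win)] - c(0L, ck)[lo_idx] > 0L
      covered <- covered | (hit & j >= 1L)
    }
    if (!any(covered)) next
    ## merge covered stretches separated by at most p
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    seg <- data.frame(start = starts[r$values], end = ends[r$values])
    if (!nrow(seg)) next
    merged <- seg[1L, , drop = FALSE]
    for (s in seq_len(nrow(seg))[-1L]) {
      if (seg$start[s] - merged$end[nrow(merged)] - 1L <= p) {
        merged$end[nrow(merged)] <- seg$end[s]
      } else {
        merged <- rbind(merged, seg[s, ])
      }
    }
    k <- min(4L, p)
    for (r2 in seq_len(nrow(merged))) {
      i1 <- merged$start[r2]; i2 <- merged$end[r2]
      ## anchor: outermost run of k consecutive lag-p matches
      idx <- seq.int(i1, min(i2, n_match - k + 1L))
      if (!length(idx)) next
      full <- (cs[idx + k] - cs[idx]) == k
      if (!any(full)) next
      lo <- idx[which(full)[1L]]
      hi <- idx[which(full)[sum(full)]] + k - 1L
      ## consensus anchored at the run, then maximal-scoring segment
      sp <- .refine_span(x, n, lo, hi + p, p)
      if (is.null(sp)) next
      span_start <- sp[1L]; span_stop <- sp[2L]
      period <- p
      ## primitive-period reduction; re-refine at the reduced period so
      ## harmonic candidates converge to the native-period span. A span
      ## whose primitive period falls below min_period (homopolymer or
      ## microsatellite structure) is outside the target range: dropped.
      divs <- seq_len(p - 1L)
      divs <- divs[p %% divs == 0L]
      sub_minimum <- FALSE
      for (q in divs) {
        if (span_stop - q < span_start) next
        iq <- seq.int(span_start, span_stop - q)
        if (mean(x[iq] == x[iq + q]) >= min_identity - 1e-9) {
          if (q < min_period) {
            sub_minimum <- TRUE
            break
          }
          period <- q
          sp <- .refine_span(x, n, span_start, span_stop, q)
          if (!is.null(sp)) {
            span_start <- sp[1L]; span_stop <- sp[2L]
          }
          break
        }
      }
      if (sub_minimum) next
      copies <- (span_stop - span_start + 1L) / period
      if (copies + 1e-9 < min_copies) next
      if (span_stop - period < span_start) next
      iq <- seq.int(span_start, span_stop - period)
      mean_id <- mean(x[iq] == x[iq + period])
      if (mean_id + 1e-9 < min_identity) next
      cand[[length(cand) + 1L]] <- list(
        start = span_start, stop = span_stop, period = period,
        copies = copies, mean_identity = mean_id)
    }
  }
  if (!length(cand)) {
    return(data.frame(start = integer(0), stop = integer(0),
                      period = integer(0), copy_number = numeric(0),
                      consensus = character(0),
                      mean_identity = numeric(0)))
  }
  spans <- vapply(cand, function(z) z$stop - z$start + 1L, 0L)
  ord <- order(-spans, vapply(cand, `[[`, 0L, "period"),
               vapply(cand, `[[`, 0L, "start"), method = "radix")
  kept <- list()
  for (k in ord) {
    z <- cand[[k]]
    clash <- any(vapply(kept, function(w)
      z$start <= w$stop && w$start <= z$stop, TRUE))
    if (!clash) kept[[length(kept) + 1L]] <- z
  }
  kept <- kept[order(vapply(kept, `[[`, 0L, "start"))]
  out <- do.call(rbind, lapply(kept, function(z) data.frame(
    start = z$start, stop = z$stop, period = z$period,
    copy_number = .round1(z$copies),
    consensus = .repeat_consensus(x, z$start, z$stop, z$period),
    mean_identity = z$mean_identity, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

## Edge refinement: column-majority consensus anchored at lo_seq, then
## the maximal-scoring segment (+1 match, -2 mismatch against the
## periodic consensus) within one period plus a small margin of the
## current span. Returns c(start, stop) in sequence coordinates, or
## NULL when no positive-scoring segment exists.
.refine_span <- function(x, n, lo_seq, hi_seq, period) {
  cons <- .chars(.repeat_consensus(x, lo_seq, hi_seq, period))
  ext <- period + 8L
  wa <- max(1L, lo_seq - ext)
  wb <- min(n, hi_seq + ext)
  phase <- ((seq.int(wa, wb) - lo_seq) %% period) + 1L
  sc <- ifelse(x[seq.int(wa, wb)] == cons[phase], 1, -2)
  best <- .max_segment(sc)
  if (is.null(best)) return(NULL)
  c(wa + best[1L] - 1L, wa + best[2L] - 1L)
}

## Maximal-sum contiguous segment (leftmost and shortest on ties, so
## zero-sum flank patterns never extend a span); NULL when every
## segment sum is non-positive.
.max_segment <- function(sc) {
  best_sum <- 0
  best <- NULL
  cur_sum <- 0
  cur_start <- 1L
  for (i in seq_along(sc)) {
    if (cur_sum <= 0) {
      cur_sum <- sc[i]
      cur_start <- i
    } else {
      cur_sum <- cur_sum + sc[i]
    }
    if (cur_sum > best_sum + 1e-9) {
      best_sum <- cur_sum
      best <- c(cur_start, i)
    }
  }
  best
}

## Column-majority consensus over unit-aligned copies (partial trailing
## copy included); ties resolved to the alphabetically first base.
.repeat_consensus <- function(x, start, stop, period) {
  cons <- character(period)
  for (j in seq_len(period)) {
    pos <- seq.int(start + j - 1L, stop, by = period)
    tab <- sort(table(x[pos]), decreasing = TRUE)
    best <- names(tab)[tab == tab[1L]]
    cons[j] <- sort(best)[1L]
  }
  .collapse(cons)
}

#' Load the bundled control-region motif definitions
#'
#' An editable TSV of motif consensus sequences (IUPAC allowed) and
#' per-motif mismatch budgets. The TAS entry is the published 17-mer;
#' the CSB-1/2/3 and OH entries are synthetic placeholder consensus
#' sequences meant to be replaced for a given study system; GACAT is the
#' truncated alternative pattern.
#'
#' @param path optional path to a motif TSV with columns \code{name},
#'   \code{consensus}, \code{max_mismatch}; default is the bundled file.
#' @return data.frame of motif definitions.
#' @export
defaultMotifs <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "motifs.tsv", package = "mitoprofiler",
                        mustWork = TRUE)
  }
  out <- read.delim(path, colClasses = "character", comment.char = "#")
  stopifnot(all(c("name", "consensus", "max_mismatch") %in% names(out)))
  out$max_mismatch <- as.integer(out$max_mismatch)
  out$consensus <- toupper(out$consensus)
  out
}

#' Scan a sequence for motif occurrences
#'
#' IUPAC-aware Hamming matching (no indels): every position where the
#' consensus matches with at most the motif's mismatch budget is a hit;
#' overlapping hits of the same motif are reduced to the best per locus
#' (fewest mismatches, then leftmost).
#'
#' @param sequence string over A/C/G/T/N or \code{DNAString}.
#' @param motifs motif definition data.frame (see [defaultMotifs()]);
#'   \code{NULL} or zero rows yields an empty result.
#' @return data.frame with columns \code{motif}, \code{start},
#'   \code{stop}, \code{strand}, \code{mismatches}, ordered by start.
#' @export
scanMotifs <- function(sequence, motifs = defaultMotifs()) {
  empty <- data.frame(motif = character(0), start = integer(0),
                      stop = integer(0), strand = character(0),
                      mismatches = integer(0))
  if (is.null(motifs) || !nrow(motifs)) return(empty)
  subject <- Biostrings::DNAString(toupper(as.character(sequence)))
  fixed <- c(pattern = FALSE, subject = TRUE)
  rows <- list()
  for (i in seq_len(nrow(motifs))) {
    pat <- Biostrings::DNAString(motifs$consensus[i])
    mm <- motifs$max_mismatch[i]
    hits <- Biostrings::matchPattern(pat, subject, max.mismatch = mm,
                                     with.indels = FALSE, fixed = fixed)
    if (!length(hits)) next
    st <- Biostrings::start(hits)
    nedit <- Biostrings::neditStartingAt(pat, subject, starting.at = st,
                                         fixed = fixed)
    df <- data.frame(motif = motifs$name[i], start = st,
                     stop = Biostrings::end(hits), strand = "H",
                     mismatches = as.integer(nedit),
                     stringsAsFactors = FALSE)
    ## best-per-locus among overlapping hits of this motif
    df <- df[order(df$start), , drop = FALSE]
    cluster <- cumsum(c(1L, as.integer(
      df$start[-1L] > cummax(df$stop)[-nrow(df)])))
    best <- unlist(lapply(split(seq_len(nrow(df)), cluster), function(idx) {
      sub <- df[idx, ]
      idx[order(sub$mismatches, sub$start)][1L]
    }))
    rows[[length(rows) + 1L]] <- df[sort(best), , drop = FALSE]
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Decompose a control region into repeats and motifs
#'
#' Runs [detectTandemRepeats()] and [scanMotifs()] on the control region
#' and merges the calls into one report ordered along the region. Motif
#' hits nested inside a repeat array are flagged (TAS copies embedded in
#' the 5' array); configured motifs with no hit are reported with an
#' explicit absent marker (\code{present = FALSE}).
#'
#' @param x a \code{MitoGenome} (its control-region feature is
#'   extracted) or a control-region sequence.
#' @param min_period,max_period,min_copies,min_identity repeat-detector
#'   settings; \code{max_period} is clamped to half the region length.
#' @param motifs motif definitions (see [defaultMotifs()]); \code{NULL}
#'   for none.
#' @return data.frame with columns \code{type} (repeat/motif),
#'   \code{name}, \code{start}, \code{stop}, \code{length},
#'   \code{period}, \code{copy_number}, \code{mean_identity},
#'   \code{mismatches}, \code{decomposition} (\code{"n x p + r"}),
#'   \code{nested_in_repeat}, \code{present}; coordinates are 1-based
#'   and local to the control region.
#' @export
crArchitecture <- function(x, min_period = 5L, max_period = 200L,
                           min_copies = 2.5, min_identity = 0.85,
                           motifs = defaultMotifs()) {
  if (is(x, "MitoGenome")) {
    ft <- features(x)
    cr <- ft[ft$category == "control_region", , drop = FALSE]
    if (!nrow(cr)) stop("genome has no control-region feature")
    x <- .feature_sequence(x, cr[1L, ], "genome_strand")
  }
  x <- toupper(as.character(x))
  n <- nchar(x)
  max_period <- min(max_period, n %/% 2L)
  reps <- detectTandemRepeats(x, min_period, max_period, min_copies,
                              min_identity)
  hits <- scanMotifs(x, motifs)
  rows <- list()
  if (nrow(reps)) {
    full <- reps$stop - reps$start + 1L
    n_units <- full %/% reps$period
    remainder <- full - n_units * reps$period
    rows$rep <- data.frame(
      type = "repeat", name = "tandem_repeat", start = reps$start,
      stop = reps$stop, length = full, period = reps$period,
      copy_number = reps$copy_number,
      mean_identity = reps$mean_identity, mismatches = NA_integer_,
      decomposition = sprintf("%d x %d + %d", n_units, reps$period,
                              remainder),
      nested_in_repeat = FALSE, present = TRUE, stringsAsFactors = FALSE)
  }
  if (nrow(hits)) {
    nested <- vapply(seq_len(nrow(hits)), function(i) {
      nrow(reps) > 0L && any(hits$start[i] >= reps$start &
                             hits$stop[i] <= reps$stop)
    }, TRUE)
    rows$mot <- data.frame(
      type = "motif", name = hits$motif, start = hits$start,
      stop = hits$stop, length = hits$stop - hits$start + 1L,
      period = NA_integer_, copy_number = NA_real_,
      mean_identity = NA_real_, mismatches = hits$mismatches,
      decomposition = NA_character_, nested_in_repeat = nested,
      present = TRUE, stringsAsFactors = FALSE)
  }
  absent <- if (!is.null(motifs) && nrow(motifs)) {
    setdiff(motifs$name, if (nrow(hits)) hits$motif else character(0))
  } else character(0)
  if (length(absent)) {
    rows$abs <- data.frame(
      type = "motif", name = absent, start = NA_integer_,
      stop = NA_integer_, length = NA_integer_, period = NA_integer_,
      copy_number = NA_real_, mean_identity = NA_real_,
      mismatches = NA_integer_, decomposition = NA_character_,
      nested_in_repeat = FALSE, present = FALSE, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(type = character(0), name = character(0),
                      start = integer(0), stop = integer(0),
                      length = integer(0), period = integer(0),
                      copy_number = numeric(0), mean_identity = numeric(0),
                      mismatches = integer(0), decomposition = character(0),
                      nested_in_repeat = logical(0), present = logical(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(!out$present, out$start, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
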
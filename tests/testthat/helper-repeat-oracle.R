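# Independent brute-force implementation of the tandem-repeat detector
# definition, written as direct loops over the published rules (window
# seeding at one and two unit lengths, merge within one period, k-run
# anchoring, consensus-scored maximal segment, primitive-period
# reduction, longest-span/smallest-period/leftmost resolution). Used to
# verify the package's optimized implementation on small sequences.

oracle_consensus <- function(x, start, stop, period) {
  cons <- character(period)
  for (j in seq_len(period)) {
    pos <- seq(start + j - 1L, stop, by = period)
    counts <- c(A = 0L, C = 0L, G = 0L, T = 0L, N = 0L)
    for (q in pos) counts[x[q]] <- counts[x[q]] + 1L
    cons[j] <- names(counts)[order(-counts, names(counts))][1L]
  }
  cons
}

## exhaustive maximal-sum segment under the canonical tie rule:
## maximal sum, then earliest end, then latest start (zero-sum
## prefixes are not included)
oracle_max_segment <- function(sc) {
  n <- length(sc)
  best_sum <- 0; best <- NULL
  for (b in seq_len(n)) {
    run <- 0; best_a <- NULL; best_here <- -Inf
    for (a in b:1) {
      run <- run + sc[a]
      if (run > best_here + 1e-9) {   # latest start wins on ties
        best_here <- run
        best_a <- a
      }
    }
    if (best_here > best_sum + 1e-9) {  # earliest end wins on ties
      best_sum <- best_here
      best <- c(best_a, b)
    }
  }
  best
}

oracle_refine <- function(x, n, lo_seq, hi_seq, period) {
  cons <- oracle_consensus(x, lo_seq, hi_seq, period)
  wa <- max(1L, lo_seq - period - 8L)
  wb <- min(n, hi_seq + period + 8L)
  sc <- numeric(wb - wa + 1L)
  for (j in wa:wb) {
    ph <- ((j - lo_seq) %% period) + 1L
    sc[j - wa + 1L] <- if (x[j] == cons[ph]) 1 else -2
  }
  best <- oracle_max_segment(sc)
  if (is.null(best)) return(NULL)
  c(wa + best[1L] - 1L, wa + best[2L] - 1L)
}

oracle_detect <- function(sequence, min_period, max_period, min_copies,
                          min_identity) {
  x <- strsplit(toupper(sequence), "")[[1]]
  n <- length(x)
  cand <- list()
  for (p in min_period:max_period) {
    n_match <- n - p
    if (n_match - p + 1L < 1L) break
    m <- logical(n_match)
    for (i in seq_len(n_match)) m[i] <- x[i] == x[i + p]
    covered <- logical(n_match)
    for (w in unique(c(p, 2L * p))) {
      n_win <- n_match - w + 1L
      if (n_win < 1L) next
      for (i in seq_len(n_win)) {
        if (sum(m[i:(i + w - 1L)]) / w >= min_identity - 1e-9) {
          covered[i:(i + w - 1L)] <- TRUE
        }
      }
    }
    if (!any(covered)) next
    ## maximal covered stretches, merged when separated by <= p
    regions <- list()
    i <- 1L
    while (i <= n_match) {
      if (covered[i]) {
        j <- i
        while (j < n_match && covered[j + 1L]) j <- j + 1L
        regions[[length(regions) + 1L]] <- c(i, j)
        i <- j + 1L
      } else i <- i + 1L
    }
    if (length(regions) > 1L) {
      merged <- list(regions[[1L]])
      for (rg in regions[-1L]) {
        last <- merged[[length(merged)]]
        if (rg[1L] - last[2L] - 1L <= p) {
          merged[[length(merged)]] <- c(last[1L], rg[2L])
        } else merged[[length(merged) + 1L]] <- rg
      }
      regions <- merged
    }
    k <- min(4L, p)
    for (rg in regions) {
      lo <- NA_integer_; hi <- NA_integer_
      for (i in rg[1L]:min(rg[2L], n_match - k + 1L)) {
        if (all(m[i:(i + k - 1L)])) {
          if (is.na(lo)) lo <- i
          hi <- i + k - 1L
        }
      }
      if (is.na(lo)) next
      sp <- oracle_refine(x, n, lo, hi + p, p)
      if (is.null(sp)) next
      period <- p
      sub_minimum <- FALSE
      for (q in seq_len(p - 1L)) {
        if (p %% q != 0L) next
        if (sp[2L] - q < sp[1L]) next
        hits <- 0L
        for (i in sp[1L]:(sp[2L] - q)) hits <- hits + (x[i] == x[i + q])
        if (hits / (sp[2L] - q - sp[1L] + 1L) >= min_identity - 1e-9) {
          if (q < min_period) { sub_minimum <- TRUE; break }
          period <- q
          sp2 <- oracle_refine(x, n, sp[1L], sp[2L], q)
          if (!is.null(sp2)) sp <- sp2
          break
        }
      }
      if (sub_minimum) next
      copies <- (sp[2L] - sp[1L] + 1L) / period
      if (copies + 1e-9 < min_copies) next
      if (sp[2L] - period < sp[1L]) next
      hits <- 0L
      for (i in sp[1L]:(sp[2L] - period)) {
        hits <- hits + (x[i] == x[i + period])
      }
      mean_id <- hits / (sp[2L] - period - sp[1L] + 1L)
      if (mean_id + 1e-9 < min_identity) next
      cand[[length(cand) + 1L]] <- list(start = sp[1L], stop = sp[2L],
                                        period = period, copies = copies,
                                        mean_identity = mean_id)
    }
  }
  if (!length(cand)) {
    return(data.frame(start = integer(0), stop = integer(0),
                      period = integer(0), copy_number = numeric(0)))
  }
  spans <- sapply(cand, function(z) z$stop - z$start + 1L)
  ord <- order(-spans, sapply(cand, `[[`, "period"),
               sapply(cand, `[[`, "start"))
  kept <- list()
  for (kk in ord) {
    z <- cand[[kk]]
    clash <- FALSE
    for (w in kept) {
      if (z$start <= w$stop && w$start <= z$stop) clash <- TRUE
    }
    if (!clash) kept[[length(kept) + 1L]] <- z
  }
  kept <- kept[order(sapply(kept, `[[`, "start"))]
  data.frame(start = sapply(kept, `[[`, "start"),
             stop = sapply(kept, `[[`, "stop"),
             period = sapply(kept, `[[`, "period"),
             copy_number = round(sapply(kept, `[[`, "copies") + 1e-9, 1))
}
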
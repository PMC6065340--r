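# Seeded synthetic mitogenome generator. Every signal the pipeline
# measures is planted explicitly and recorded in a truth record:
# feature coordinates (including the tandem tRNA-Met duplication and
# the three planted PCG overlaps with shared sequence), start and
# complete/incomplete stop codons, AT-content and skew targets, codon
# bias as sampling weights over synonymous codons, and a control-region
# plan of tandem-repeat arrays (with embedded TAS copies) and motifs.

#' The bundled frog-style mitogenome layout
#'
#' The 40-feature annotation (13 PCGs, 23 tRNAs with a duplicated
#' tRNA-Met between tRNA-Gln and ND2, 2 rRNAs, the light-strand origin
#' and the control region) used as the generator's default feature
#' template, loaded from the bundled annotation tables.
#'
#' @param which one of \code{"parkeri"}, \code{"ventripunctata"},
#'   \code{"pleskei"} selecting the bundled table.
#' @return feature data.frame (validated; printed inconsistencies in the
#'   source table are reconciled by [validateAnnotation()]).
#' @export
nanoranaLayout <- function(which = c("parkeri", "ventripunctata",
                                     "pleskei")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("table1_", which, ".tsv"),
                      package = "mitoprofiler", mustWork = TRUE)
  rows <- readFeatureTable(path)
  suppressWarnings(features(validateAnnotation(rows, which)$genome))
}

#' Default control-region plan (5' repeat array with embedded TAS, OH,
#' CSB-1/2/3, four 3' repeat arrays)
#'
#' Positions are control-region-local and sized for the default layout's
#' 2,259 bp control region. \code{copies} may be fractional; spans are
#' rounded to whole bases and the realized copy number recorded in the
#' truth record.
#'
#' @param motifs motif definitions providing the consensus sequences.
#' @return list of plan elements.
#' @export
defaultCrPlan <- function(motifs = defaultMotifs()) {
  cons <- setNames(motifs$consensus, motifs$name)
  list(
    list(kind = "repeat", name = "5prime_array", start = 42L,
         period = 124L, copies = 4.6, unit = NULL, mut_rate = 0.02,
         embed = list(name = "TAS", offset = 110L,
                      consensus = cons[["TAS"]])),
    list(kind = "motif", name = "OH", start = 1389L,
         consensus = cons[["OH"]]),
    list(kind = "motif", name = "CSB-1", start = 1495L,
         consensus = cons[["CSB-1"]]),
    list(kind = "motif", name = "CSB-2", start = 1595L,
         consensus = cons[["CSB-2"]]),
    list(kind = "motif", name = "CSB-3", start = 1640L,
         consensus = cons[["CSB-3"]]),
    list(kind = "repeat", name = "3prime_array_1", start = 1702L,
         period = 11L, copies = 8.6, unit = "GCTCGTATATT",
         mut_rate = 0.02, embed = NULL),
    list(kind = "repeat", name = "3prime_array_2", start = 1801L,
         period = 11L, copies = 8.9, unit = "ATACTTCGCTT",
         mut_rate = 0.02, embed = NULL),
    list(kind = "repeat", name = "3prime_array_3", start = 1903L,
         period = 8L, copies = 16.3, unit = "TAATTGTA",
         mut_rate = 0.02, embed = NULL),
    list(kind = "repeat", name = "3prime_array_4", start = 2040L,
         period = 8L, copies = 12.8, unit = "GCTGATCG",
         mut_rate = 0.02, embed = NULL))
}

#' Control-region plan sized for the larger (ventripunctata-style)
#' layout, with a 6.5-copy 5' array and three 3' arrays
#'
#' @inheritParams defaultCrPlan
#' @return list of plan elements.
#' @export
repeatRichCrPlan <- function(motifs = defaultMotifs()) {
  cons <- setNames(motifs$consensus, motifs$name)
  list(
    list(kind = "repeat", name = "5prime_array", start = 21L,
         period = 124L, copies = 6.5, unit = NULL, mut_rate = 0.02,
         embed = list(name = "TAS", offset = 99L,
                      consensus = cons[["TAS"]])),
    list(kind = "motif", name = "OH", start = 1552L,
         consensus = cons[["OH"]]),
    list(kind = "motif", name = "CSB-1", start = 1713L,
         consensus = cons[["CSB-1"]]),
    list(kind = "motif", name = "CSB-2", start = 1809L,
         consensus = cons[["CSB-2"]]),
    list(kind = "motif", name = "CSB-3", start = 1835L,
         consensus = cons[["CSB-3"]]),
    list(kind = "repeat", name = "3prime_array_1", start = 1917L,
         period = 11L, copies = 10.8, unit = "GCTCGTATTCT",
         mut_rate = 0.02, embed = NULL),
    list(kind = "repeat", name = "3prime_array_2", start = 2042L,
         period = 11L, copies = 10.9, unit = "CTTCGCTTATC",
         mut_rate = 0.02, embed = NULL),
    list(kind = "repeat", name = "3prime_array_3", start = 2196L,
         period = 10L, copies = 29.6, unit = "GTTTTTGTTA",
         mut_rate = 0.02, embed = NULL))
}

#' Specification for a synthetic mitogenome
#'
#' @param seed integer; the single seed governing all randomness.
#' @param layout feature template (default: the bundled 40-feature
#'   frog layout with the duplicated tRNA-Met).
#' @param at_target genome-wide A+T fraction (default 0.58, typical of
#'   dicroglossid mitogenomes).
#' @param cr_at_target A+T fraction of the control region (default
#'   0.66; control regions are AT-richer than coding sequence).
#' @param at_skew_target,gc_skew_target heavy-strand skews used to
#'   shape base sampling (defaults -0.04 / -0.26, the typical mild
#'   T-over-A and strong C-over-G asymmetry).
#' @param cr_plan control-region plan (see [defaultCrPlan()]).
#' @param divergence_plan optional named numeric vector of per-site
#'   substitution probabilities, one per derived taxon (see
#'   [mutatePopulation()]).
#' @param identifier genome label.
#' @return validated spec (list).
#' @export
syntheticSpec <- function(seed = 1L, layout = nanoranaLayout(),
                          at_target = 0.58, cr_at_target = 0.66,
                          at_skew_target = -0.04,
                          gc_skew_target = -0.26,
                          cr_plan = defaultCrPlan(),
                          divergence_plan = NULL,
                          identifier = "synthetic_mitogenome") {
  stopifnot(at_target > 0, at_target < 1, cr_at_target > 0,
            cr_at_target < 1, abs(at_skew_target) <= 1,
            abs(gc_skew_target) <= 1)
  if (!is.null(divergence_plan)) {
    stopifnot(!is.null(names(divergence_plan)),
              all(divergence_plan >= 0), all(divergence_plan < 0.75))
  }
  glen <- max(layout$stop)
  cr <- layout[layout$category == "control_region", , drop = FALSE]
  if (nrow(cr) != 1L) stop("layout must carry exactly one control region")
  cr_len <- cr$stop - cr$start + 1L
  for (el in cr_plan) {
    span <- if (el$kind == "repeat") round(el$copies * el$period) else
      nchar(el$consensus)
    if (el$start < 1L || el$start + span - 1L > cr_len) {
      stop("control-region plan element '", el$name,
           "' does not fit the ", cr_len, " bp control region")
    }
  }
  list(seed = as.integer(seed), layout = layout, genome_length = glen,
       at_target = at_target, cr_at_target = cr_at_target,
       at_skew_target = at_skew_target, gc_skew_target = gc_skew_target,
       cr_plan = cr_plan, divergence_plan = divergence_plan,
       identifier = identifier)
}

.BASES <- c("A", "C", "G", "T")

.base_probs <- function(at, at_skew, gc_skew) {
  c(A = at * (1 + at_skew) / 2, C = (1 - at) * (1 - gc_skew) / 2,
    G = (1 - at) * (1 + gc_skew) / 2, T = at * (1 - at_skew) / 2)
}

## Codon sampling weights: product of base probabilities, stop codons
## removed, then exponentially tilted so that the expected A+T per base
## equals the target despite the removal of the (AT-rich) stop codons.
.codon_weights <- function(probs, at_per_base) {
  code <- vertebrateMitoCode()$code
  codons <- names(code)
  mat <- do.call(rbind, strsplit(codons, ""))
  w <- probs[mat[, 1L]] * probs[mat[, 2L]] * probs[mat[, 3L]]
  names(w) <- codons
  w[code == "*"] <- 0
  n_at <- rowSums(matrix(mat %in% c("A", "T"), ncol = 3L))
  f <- function(lam) {
    ww <- w * exp(lam * n_at)
    sum(ww * n_at) / (3 * sum(ww)) - at_per_base
  }
  lam <- stats::uniroot(f, c(-3, 3), tol = 1e-10)$root
  w <- w * exp(lam * n_at)
  w / sum(w)
}

.sample_bases <- function(n, probs) {
  sample(.BASES, n, replace = TRUE, prob = probs[.BASES])
}

## Replace IUPAC ambiguity codes in a consensus with concrete bases.
.concretize <- function(consensus) {
  iupac <- Biostrings::IUPAC_CODE_MAP
  ch <- .chars(consensus)
  amb <- !(ch %in% .BASES)
  for (i in which(amb)) {
    opts <- .chars(iupac[[ch[i]]])
    ch[i] <- opts[sample.int(length(opts), 1L)]
  }
  .collapse(ch)
}

.mutate_chars <- function(ch, rate) {
  idx <- which(runif(length(ch)) < rate)
  if (length(idx)) {
    cur <- match(ch[idx], .BASES)
    step <- sample.int(3L, length(idx), replace = TRUE)
    ch[idx] <- .BASES[((cur - 1L + step) %% 4L) + 1L]
  }
  ch
}

#' Generate a synthetic annotated mitogenome with recorded truth
#'
#' Protein-coding genes are built codon-wise from the bias weights with
#' the planted start codons and complete or incomplete stop codons;
#' light-strand genes are emitted reverse-complemented in the genome;
#' the three planted gene overlaps share sequence, with codons chosen to
#' be stop-free in every reading frame that covers them; the control
#' region is assembled from its plan. Deterministic for a given seed.
#'
#' @param spec a spec from [syntheticSpec()].
#' @return list with \code{genome} (a \code{MitoGenome} with sequence)
#'   and \code{truth} (the serializable truth record).
#' @export
generateMitogenome <- function(spec) {
  set.seed(spec$seed)
  layout <- spec$layout
  L <- spec$genome_length
  cr_row <- layout[layout$category == "control_region", ][1L, ]
  cr_len <- cr_row$stop - cr_row$start + 1L
  ## non-CR base probabilities compensate the AT-richer control region
  at_nc <- (spec$at_target * L - spec$cr_at_target * cr_len) /
    (L - cr_len)
  probs_nc <- .base_probs(at_nc, spec$at_skew_target,
                          spec$gc_skew_target)
  probs_cr <- .base_probs(spec$cr_at_target, spec$at_skew_target,
                          spec$gc_skew_target)
  weights <- .codon_weights(probs_nc, at_nc)
  code <- vertebrateMitoCode()$code
  codon_names <- names(code)
  codon_mat <- do.call(rbind, strsplit(codon_names, ""))

  genome <- rep(NA_character_, L)
  protected <- logical(L)
  pcg <- layout[layout$category == "PCG", , drop = FALSE]

  map_pos <- function(row, i) {          # coding index -> genome position
    if (row$strand == "H") row$start + i - 1L else row$stop - i + 1L
  }
  write_coding <- function(row, i, bases, protect = FALSE) {
    pos <- vapply(i, function(k) map_pos(row, k), 0L)
    if (row$strand == "L") bases <- unname(.COMPLEMENT[bases])
    genome[pos] <<- bases
    if (protect) protected[pos] <<- TRUE
  }
  read_coding <- function(row, i) {
    pos <- vapply(i, function(k) map_pos(row, k), 0L)
    b <- genome[pos]
    if (row$strand == "L") b <- unname(.COMPLEMENT[b])
    b
  }

  ## --- stamp start and stop codons (protected positions) --------------
  for (r in seq_len(nrow(pcg))) {
    row <- pcg[r, ]
    len <- row$stop - row$start + 1L
    write_coding(row, 1:3, .chars(row$start_codon), protect = TRUE)
    st <- row$stop_codon
    if (identical(st, "T-")) {
      write_coding(row, len, "T", protect = TRUE)
    } else if (identical(st, "TA-")) {
      write_coding(row, (len - 1L):len, c("T", "A"), protect = TRUE)
    } else {
      write_coding(row, (len - 2L):len, .chars(st), protect = TRUE)
    }
  }

  ## --- fill internal codons from the bias weights ----------------------
  pick_codon <- function(fixed) {  # fixed: length-3, NA = free
    ok <- rep(TRUE, 64L)
    for (j in 1:3) {
      if (!is.na(fixed[j])) ok <- ok & codon_mat[, j] == fixed[j]
    }
    ok <- ok & weights > 0
    if (!any(ok)) return(NULL)
    idx <- which(ok)
    idx[sample.int(length(idx), 1L, prob = weights[idx])]
  }
  for (r in seq_len(nrow(pcg))) {
    row <- pcg[r, ]
    len <- row$stop - row$start + 1L
    for (k in seq.int(2L, len %/% 3L)) {
      i <- (3L * k - 2L):(3L * k)
      cur <- read_coding(row, i)
      if (!anyNA(cur)) next
      hit <- pick_codon(cur)
      if (is.null(hit)) {  # cannot avoid a stop here; leave for repair
        free <- is.na(cur)
        cur[free] <- .sample_bases(sum(free), probs_nc)
        write_coding(row, i, cur)
      } else {
        write_coding(row, i, codon_mat[hit, ])
      }
    }
  }

  ## --- repair: no internal stop codon in any covering frame -----------
  codon_of <- function(row, pos) {       # genome position -> codon index
    i <- if (row$strand == "H") pos - row$start + 1L else row$stop - pos + 1L
    (i + 2L) %/% 3L
  }
  internal_stops <- function() {
    bad <- list()
    for (r in seq_len(nrow(pcg))) {
      row <- pcg[r, ]
      len <- row$stop - row$start + 1L
      n_full <- len %/% 3L
      last_internal <- if (len %% 3L == 0L) n_full - 1L else n_full
      for (k in seq.int(2L, last_internal)) {
        i <- (3L * k - 2L):(3L * k)
        if (.collapse(read_coding(row, i)) %in% .stop_codons) {
          bad[[length(bad) + 1L]] <- list(row = row, codon = k)
        }
      }
    }
    bad
  }
  for (iter in seq_len(25L)) {
    bad <- internal_stops()
    if (!length(bad)) break
    for (b in bad) {
      i <- (3L * b$codon - 2L):(3L * b$codon)
      pos <- vapply(i, function(k) map_pos(b$row, k), 0L)
      free <- !protected[pos]
      if (!any(free)) stop("stop codon locked by protected positions")
      ## enumerate assignments of the free bases; keep those stop-free
      ## in every PCG frame covering these positions
      grid <- as.matrix(expand.grid(rep(list(.BASES), sum(free)),
                                    stringsAsFactors = FALSE))
      valid <- logical(nrow(grid))
      wts <- numeric(nrow(grid))
      old <- genome[pos]
      for (g in seq_len(nrow(grid))) {
        genome[pos[free]] <- grid[g, ]
        ok <- TRUE
        for (r2 in seq_len(nrow(pcg))) {
          row2 <- pcg[r2, ]
          cover <- pos >= row2$start & pos <= row2$stop
          if (!any(cover)) next
          len2 <- row2$stop - row2$start + 1L
          n_full2 <- len2 %/% 3L
          for (k2 in unique(codon_of(row2, pos[cover]))) {
            if (k2 < 1L || k2 > n_full2) next
            cod <- .collapse(read_coding(row2, (3L * k2 - 2L):(3L * k2)))
            ## stamped terminal stops are protected and unchanged; any
            ## other stop codon is a violation
            if (cod %in% .stop_codons &&
                !all(protected[vapply((3L * k2 - 2L):(3L * k2),
                                      function(q) map_pos(row2, q), 0L)]))
              ok <- FALSE
          }
          if (!ok) break
        }
        valid[g] <- ok
        wts[g] <- prod(probs_nc[grid[g, ]])
        genome[pos] <- old
      }
      if (!any(valid)) stop("no stop-free assignment for overlap codon")
      pickg <- which(valid)[sample.int(sum(valid), 1L,
                                       prob = wts[valid])]
      genome[pos[free]] <- grid[pickg, ]
    }
  }
  if (length(internal_stops())) stop("internal stop repair did not converge")

  ## --- control region --------------------------------------------------
  cr <- rep(NA_character_, cr_len)
  truth_elements <- list()
  for (el in spec$cr_plan) {
    if (el$kind == "repeat") {
      span <- as.integer(round(el$copies * el$period))
      unit <- if (is.null(el$unit)) {
        .collapse(.sample_bases(el$period, probs_cr))
      } else el$unit
      arr <- .chars(strrep(unit, ceiling(span / el$period)))[seq_len(span)]
      tas_local <- integer(0)
      if (!is.null(el$embed)) {
        cons <- .concretize(el$embed$consensus)
        wlen <- nchar(cons)
        offs <- seq.int(el$embed$offset, span - wlen + 1L,
                        by = el$period)
        for (o in offs) arr[o:(o + wlen - 1L)] <- .chars(cons)
        tas_local <- offs
      }
      arr <- .mutate_chars(arr, el$mut_rate)
      cr[el$start:(el$start + span - 1L)] <- arr
      truth_elements[[length(truth_elements) + 1L]] <- list(
        kind = "repeat", name = el$name, start = el$start,
        stop = el$start + span - 1L, period = el$period,
        copy_number = .round1(span / el$period), unit = unit,
        mut_rate = el$mut_rate,
        embedded_motif = if (length(tas_local)) list(
          name = el$embed$name,
          starts = el$start + tas_local - 1L) else NULL)
    } else {
      cons <- .concretize(el$consensus)
      idx <- el$start:(el$start + nchar(cons) - 1L)
      cr[idx] <- .chars(cons)
      truth_elements[[length(truth_elements) + 1L]] <- list(
        kind = "motif", name = el$name, start = el$start,
        stop = el$start + nchar(cons) - 1L)
    }
  }
  filler <- is.na(cr)
  cr[filler] <- .sample_bases(sum(filler), probs_cr)
  genome[cr_row$start:cr_row$stop] <- cr

  ## --- remaining features and spacers ----------------------------------
  left <- is.na(genome)
  genome[left] <- .sample_bases(sum(left), probs_nc)

  gm <- MitoGenome(spec$identifier, layout,
                   sequence = .collapse(genome), circular = TRUE)
  truth <- list(
    identifier = spec$identifier, seed = spec$seed, genome_length = L,
    at_target = spec$at_target, cr_at_target = spec$cr_at_target,
    at_skew_target = spec$at_skew_target,
    gc_skew_target = spec$gc_skew_target,
    features = layout[, c("name", "category", "strand", "start", "stop",
                          "start_codon", "stop_codon")],
    control_region = list(start = cr_row$start, stop = cr_row$stop,
                          elements = truth_elements),
    codon_bias = list(weights = as.list(weights[weights > 0]),
                      overused_third_position = c("A", "T")),
    divergence_plan = as.list(spec$divergence_plan))
  list(genome = gm, truth = truth)
}

#' Derive a population of mutated genomes
#'
#' Independent per-site substitutions under a uniform single-nucleotide
#' model; annotations are carried over unchanged. With rates
#' \code{c(A = 0.02, B = 0.02, C = 0.10)} this yields the classic trio
#' in which A and B are mutually closer than either is to C.
#'
#' @param genome a \code{MitoGenome} with sequence (the common
#'   ancestor copy).
#' @param plan named numeric vector of per-site substitution
#'   probabilities in \code{[0, 0.75)}, one per derived taxon.
#' @param seed optional seed (set when given; otherwise the current RNG
#'   state is used).
#' @return named list of \code{MitoGenome}s, one per taxon.
#' @export
mutatePopulation <- function(genome, plan, seed = NULL) {
  stopifnot(is(genome, "MitoGenome"), length(genome@sequence) == 1L,
            !is.null(names(plan)), all(plan >= 0), all(plan < 0.75))
  if (!is.null(seed)) set.seed(seed)
  ch0 <- .chars(genome@sequence)
  out <- lapply(names(plan), function(tx) {
    ch <- .mutate_chars(ch0, plan[[tx]])
    MitoGenome(tx, features(genome), sequence = .collapse(ch),
               circular = isCircular(genome))
  })
  setNames(out, names(plan))
}

#' Write the standard synthetic fixture battery
#'
#' Three fixture sets with planted truth: \code{default} (frog layout,
#' default control-region plan), \code{repeat_rich} (larger layout with
#' the 6.5-copy 5' array and three 3' arrays) and \code{trio} (an
#' ancestor plus taxa A/B at 2\% and C at 10\% divergence). Each set is
#' written as FASTA + annotation TSV + GenBank-style file + truth JSON;
#' regeneration with the same seed is byte-identical.
#'
#' @param out_dir output directory (created if needed).
#' @param seed base seed; the three sets use \code{seed}, \code{seed+1},
#'   \code{seed+2}.
#' @return named list of the files written, invisibly.
#' @export
writeFixtureSet <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  emit <- function(tag, genomes, truth) {
    fa <- file.path(out_dir, paste0(tag, ".fasta"))
    writeMitoFasta(vapply(genomes, function(g) g@sequence, ""), fa)
    tsv <- file.path(out_dir, paste0(tag, "_features.tsv"))
    writeFeatureTable(genomes[[1L]], tsv)
    gb <- file.path(out_dir, paste0(tag, ".gb"))
    writeGenBank(genomes[[1L]], gb)
    js <- file.path(out_dir, paste0(tag, "_truth.json"))
    jsonlite::write_json(truth, js, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    files[[tag]] <<- c(fasta = fa, features = tsv, genbank = gb,
                       truth = js)
  }
  g1 <- generateMitogenome(syntheticSpec(seed = seed,
                                         identifier = "default"))
  emit("default", setNames(list(g1$genome), "default"), g1$truth)
  g2 <- generateMitogenome(syntheticSpec(
    seed = seed + 1L, layout = nanoranaLayout("ventripunctata"),
    cr_plan = repeatRichCrPlan(), identifier = "repeat_rich"))
  emit("repeat_rich", setNames(list(g2$genome), "repeat_rich"),
       g2$truth)
  plan <- c(A = 0.02, B = 0.02, C = 0.10)
  g3 <- generateMitogenome(syntheticSpec(seed = seed + 2L,
                                         divergence_plan = plan,
                                         identifier = "trio_ancestor"))
  ## hierarchical divergence: A and B split from a shared intermediate
  ## copy (itself 4% from the ancestor), C from the ancestor directly,
  ## so the planted topology is ((A,B),C) rooted at the ancestor
  x <- mutatePopulation(g3$genome, c(X = 0.04), seed = seed + 2L)$X
  trio <- c(mutatePopulation(x, plan[c("A", "B")]),
            mutatePopulation(g3$genome, plan["C"]))
  fa <- file.path(out_dir, "trio.fasta")
  writeMitoFasta(vapply(trio, function(g) g@sequence, ""), fa)
  tsv <- file.path(out_dir, "trio_features.tsv")
  writeFeatureTable(trio[[1L]], tsv)
  truth3 <- g3$truth
  truth3$expected_topology <- "((A,B),C)"
  js <- file.path(out_dir, "trio_truth.json")
  jsonlite::write_json(truth3, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  files$trio <- c(fasta = fa, features = tsv, truth = js)
  invisible(files)
}
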
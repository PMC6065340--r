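# End-to-end pipeline: per-genome validation, profile, skew, codon and
# control-region reports, cross-genome gene-order comparison, the
# stop-stripped supermatrix with site statistics and an NJ sanity tree.
# Reports are TSV + JSON twins; all outputs are byte-deterministic.

.write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n", na = "NA")
  invisible(path)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

.load_input <- function(id, input) {
  if (is.character(input) && length(input) == 1L) {
    if (grepl("\\.(gb|gbk|genbank)$", input, ignore.case = TRUE)) {
      input <- list(genbank = input)
    } else {
      input <- list(features = input)
    }
  }
  if (!is.null(input$genbank)) {
    genome <- readGenBank(input$genbank)
    genome@identifier <- id
    return(list(genome = genome,
                report = data.frame(feature = character(0),
                                    issue = character(0),
                                    printed = integer(0),
                                    recomputed = integer(0),
                                    repaired = logical(0))))
  }
  rows <- readFeatureTable(input$features)
  va <- validateAnnotation(rows, identifier = id)
  genome <- va$genome
  if (!is.null(input$fasta)) {
    seqs <- readMitoFasta(input$fasta)
    pick <- if (id %in% names(seqs)) id else 1L
    genome <- MitoGenome(id, features(genome),
                         sequence = as.character(seqs[[pick]]),
                         circular = isCircular(genome))
  }
  list(genome = genome, report = va$report)
}

#' Run the complete comparative profiling pipeline
#'
#' For every input genome: the validation report, a profile table
#' (coordinates, sizes, codons, intergenic spacers), and -- when a
#' sequence is attached -- the skew profile, codon usage with RSCU and
#' amino-acid frequencies, and the control-region architecture. Across
#' genomes: the gene-order comparison with tandem-duplication calls, the
#' side-by-side profile table, and (when at least three genomes carry
#' sequence) the stop-stripped PCG supermatrix with site statistics and
#' a neighbor-joining Newick tree. A run log records every default
#' actually applied (strand convention, padding, repairs).
#'
#' @param inputs named list of inputs; each element a GenBank path, an
#'   annotation-table path, or a list with elements \code{features}
#'   (TSV path) and optionally \code{fasta}.
#' @param out_dir output directory, created if needed.
#' @param strand_convention passed to [skewProfile()].
#' @param min_period,max_period,min_copies,min_identity,motifs
#'   control-region settings, see [crArchitecture()].
#' @return invisibly, the bundle: per-genome objects plus cross-genome
#'   results.
#' @export
runAll <- function(inputs, out_dir,
                   strand_convention = c("coding_strand", "genome_strand"),
                   min_period = 5L, max_period = 200L, min_copies = 2.5,
                   min_identity = 0.85, motifs = defaultMotifs()) {
  strand_convention <- match.arg(strand_convention)
  stopifnot(length(inputs) >= 1L, !is.null(names(inputs)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(paste0("strand_convention=", strand_convention),
                 paste0("repeat_detector=", min_period, ":", max_period,
                        " min_copies=", min_copies,
                        " min_identity=", min_identity))
  bundle <- list()
  for (id in names(inputs)) {
    li <- .load_input(id, inputs[[id]])
    genome <- li$genome
    gdir <- file.path(out_dir, id)
    dir.create(gdir, showWarnings = FALSE)
    .write_json(li$report, file.path(gdir, "validation.json"))
    if (nrow(li$report)) {
      log_lines <- c(log_lines, sprintf(
        "%s: %d annotation issue(s), %d repaired", id, nrow(li$report),
        sum(li$report$repaired)))
    }
    writeFeatureTable(genome, file.path(gdir, "profile.tsv"))
    totals <- gapOverlapTotals(genome)
    entry <- list(genome = genome, report = li$report,
                  gap_overlap = totals)
    log_lines <- c(log_lines, sprintf("%s: gaps=%d overlaps=%d", id,
                                      totals[["gap"]],
                                      totals[["overlap"]]))
    if (length(genome@sequence)) {
      sk <- skewProfile(genome, strand_convention)
      sk_out <- sk
      sk_out$at_fraction <- round(sk_out$at_fraction, 4L)
      sk_out$at_skew <- round(sk_out$at_skew, 3L)
      sk_out$gc_skew <- round(sk_out$gc_skew, 3L)
      .write_tsv(sk_out, file.path(gdir, "skews.tsv"))
      pcg_names <- features(genome)$name[
        features(genome)$category == "PCG"]
      css <- lapply(pcg_names, function(g) codingSequence(genome, g))
      padded <- vapply(css, function(cs) nzchar(cs$padding), TRUE)
      log_lines <- c(log_lines, sprintf(
        "%s: %d PCGs, %d with incomplete stops padded", id,
        length(css), sum(padded)))
      usage <- codonUsage(css)
      rt <- rscu(usage)
      rt$codon <- gsub("T", "U", rt$codon)
      rt$rscu <- round(rt$rscu, 3L)
      .write_tsv(rt, file.path(gdir, "codon_usage.tsv"))
      aa <- aaFrequencies(usage)
      .write_tsv(data.frame(amino_acid = names(aa),
                            percent = round(unname(aa), 2L)),
                 file.path(gdir, "aa_frequencies.tsv"))
      entry$usage <- usage
      entry$skew <- sk
      if (any(features(genome)$category == "control_region")) {
        arch <- crArchitecture(genome, min_period, max_period,
                               min_copies, min_identity, motifs)
        arch_out <- arch
        arch_out$mean_identity <- round(arch_out$mean_identity, 3L)
        .write_tsv(arch_out, file.path(gdir, "cr_architecture.tsv"))
        .write_json(arch, file.path(gdir, "cr_architecture.json"))
        entry$cr <- arch
      }
    }
    bundle[[id]] <- entry
  }
  ## --- cross-genome results -------------------------------------------
  genomes <- lapply(bundle, `[[`, "genome")
  sig1 <- geneOrderSignature(genomes[[1L]])
  cmp_rows <- lapply(names(genomes), function(id) {
    cc <- compareGeneOrder(sig1, geneOrderSignature(genomes[[id]]))
    data.frame(genome = id, identical_to_first = cc$identical,
               first_difference = cc$first_difference)
  })
  .write_tsv(do.call(rbind, cmp_rows),
             file.path(out_dir, "gene_order_comparison.tsv"))
  dup <- findTandemDuplicates(geneOrderSignature(genomes[[1L]]))
  .write_tsv(dup, file.path(out_dir, "tandem_duplicates.tsv"))
  if (length(genomes) >= 2L) {
    .write_tsv(compareProfiles(bundle),
               file.path(out_dir, "compare_profiles.tsv"))
  }
  with_seq <- names(genomes)[vapply(genomes, function(g)
    length(g@sequence) == 1L, TRUE)]
  if (length(with_seq) >= 2L) {
    sm <- pcgSupermatrix(genomes[with_seq])
    writeAlignment(sm, file.path(out_dir, "supermatrix.fasta"), "fasta")
    writeAlignment(sm, file.path(out_dir, "supermatrix.phy"),
                   "phylip-relaxed")
    writeAlignment(sm, file.path(out_dir, "supermatrix.nex"), "nexus")
    .write_json(classifySites(sm), file.path(out_dir, "sitestats.json"))
    if (length(with_seq) >= 3L) {
      tree <- njTree(pDistance(sm))
      writeNewick(tree, file.path(out_dir, "nj.nwk"))
    }
    bundle$supermatrix <- sm
  }
  con <- file(file.path(out_dir, "run.log"), open = "wb")
  writeLines(log_lines, con, sep = "\n")
  close(con)
  invisible(bundle)
}

#' Side-by-side comparison of genome profiles
#'
#' Rows are aligned by normalized gene name (union of all genomes, in
#' first-seen order); per genome the feature length and, when a skew
#' profile is available, the per-gene AT and GC skews. Missing entries
#' are marked \code{NA}.
#'
#' @param bundle named list as produced by [runAll()] (elements with
#'   \code{genome} and optionally \code{skew}), or a named list of
#'   \code{MitoGenome}s.
#' @return data.frame, deterministic across runs.
#' @export
compareProfiles <- function(bundle) {
  stopifnot(length(bundle) >= 2L)
  entries <- lapply(bundle, function(b) {
    if (is(b, "MitoGenome")) list(genome = b) else b
  })
  entries <- entries[vapply(entries, function(b)
    is.list(b) && is(b$genome, "MitoGenome"), TRUE)]
  all_genes <- character(0)
  for (b in entries) {
    all_genes <- union(all_genes, features(b$genome)$name)
  }
  out <- data.frame(gene = all_genes, stringsAsFactors = FALSE)
  for (id in names(entries)) {
    g <- entries[[id]]$genome
    ft <- features(g)
    len <- setNames(featureLength(ft$start, ft$stop, genomeLength(g),
                                  isCircular(g)), ft$name)
    out[[paste0(id, ".length")]] <- unname(len[all_genes])
    sk <- entries[[id]]$skew
    if (!is.null(sk)) {
      at <- setNames(sk$at_skew, sk$region)
      gc <- setNames(sk$gc_skew, sk$region)
      out[[paste0(id, ".at_skew")]] <- round(unname(at[all_genes]), 3L)
      out[[paste0(id, ".gc_skew")]] <- round(unname(gc[all_genes]), 3L)
    }
  }
  out
}
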
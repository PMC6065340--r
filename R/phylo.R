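# Supermatrix preparation (stop-codon-stripped 13-gene concatenation),
# alignment site classification, p-distances and a neighbor-joining
# sanity tree. Model-based tree inference is exported to external tools,
# not implemented here.

#' Strip the terminal stop codon from a coding sequence
#'
#' Removes the final codon when it is a complete stop (TAA/TAG/AGA/AGG),
#' the padding-completed codon of an incomplete stop, or -- for derived
#' genomes in which a substitution has altered the stop -- when the
#' annotation records one; a gene with no recognizable or annotated stop
#' is returned unchanged with a warning.
#'
#' @param cs a codon-ready sequence from [codingSequence()] or a plain
#'   in-frame string.
#' @return the stripped sequence (single string, length divisible by 3).
#' @export
stripStopCodon <- function(cs) {
  if (is.character(cs)) cs <- list(sequence = cs, padding = "")
  s <- cs$sequence
  stopifnot(nchar(s) %% 3L == 0L)
  last <- substr(s, nchar(s) - 2L, nchar(s))
  if (nzchar(cs$padding) || last %in% .stop_codons ||
      isTRUE(!is.na(cs$annotated_stop))) {
    substr(s, 1L, nchar(s) - 3L)
  } else {
    warning("no recognized stop codon (", last, "); sequence unchanged")
    s
  }
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' Genes are joined in the canonical mitochondrial order (ND1, ND2,
#' COX1, COX2, ATP8, ATP6, COX3, ND3, ND4L, ND4, ND5, ND6, CYTB; genes
#' outside this list follow in input order) and partition bounds are
#' recorded. All gene alignments must cover the identical taxon set.
#'
#' @param gene_alignments named list; each element a named character
#'   vector (taxon -> sequence) or character matrix of equal-length
#'   rows.
#' @return a \linkS4class{Supermatrix}.
#' @export
concatenateAlignments <- function(gene_alignments) {
  stopifnot(length(gene_alignments) > 0L,
            !is.null(names(gene_alignments)))
  as_vec <- function(g) {
    if (is.matrix(g)) g <- apply(g, 1L, paste, collapse = "")
    stopifnot(!is.null(names(g)))
    g
  }
  gene_alignments <- lapply(gene_alignments, as_vec)
  taxa <- sort(names(gene_alignments[[1L]]))
  for (gene in names(gene_alignments)) {
    tg <- sort(names(gene_alignments[[gene]]))
    if (!identical(tg, taxa)) {
      stop("taxon set mismatch in gene '", gene, "': ",
           paste(c(setdiff(taxa, tg), setdiff(tg, taxa)), collapse = ", "))
    }
    w <- nchar(gene_alignments[[gene]])
    if (length(unique(w)) != 1L) stop("ragged alignment for gene ", gene)
  }
  known <- intersect(.canonical_pcg_order, names(gene_alignments))
  order_genes <- c(known, setdiff(names(gene_alignments), known))
  widths <- vapply(gene_alignments[order_genes],
                   function(g) nchar(g[[1L]]), 0L)
  last <- cumsum(widths)
  partitions <- data.frame(gene = order_genes,
                           first = as.integer(c(1L, head(last, -1L) + 1L)),
                           last = as.integer(last),
                           stringsAsFactors = FALSE)
  joined <- vapply(taxa, function(tx) {
    paste(vapply(order_genes, function(g) gene_alignments[[g]][[tx]], ""),
          collapse = "")
  }, "")
  aln <- do.call(rbind, lapply(joined, function(s) .chars(s)))
  rownames(aln) <- taxa
  new("Supermatrix", alignment = aln, partitions = partitions)
}

#' @describeIn concatenateAlignments alignment matrix accessor
#' @param x a \code{Supermatrix}
#' @export
setGeneric("alignment", function(x) standardGeneric("alignment"))

#' @rdname concatenateAlignments
#' @export
setMethod("alignment", "Supermatrix", function(x) x@alignment)

#' @describeIn concatenateAlignments partition table accessor
#' @export
setGeneric("partitions", function(x) standardGeneric("partitions"))

#' @rdname concatenateAlignments
#' @export
setMethod("partitions", "Supermatrix", function(x) x@partitions)

setMethod("show", "Supermatrix", function(object) {
  cat("Supermatrix: ", nrow(object@alignment), " taxa x ",
      ncol(object@alignment), " sites, ", nrow(object@partitions),
      " partition(s)\n", sep = "")
  invisible(NULL)
})

#' Classify alignment sites
#'
#' Per column, over the non-gap non-N states: conserved iff at most one
#' state is present; variable otherwise; parsimony-informative iff at
#' least two states are each present in at least two rows; singleton =
#' variable but not parsimony-informative. Columns with no unambiguous
#' state at all are counted as conserved by convention and reported in
#' \code{all_missing}. The invariant \code{conserved + variable ==
#' total} always holds.
#'
#' @param x a \code{Supermatrix}, character matrix (rows = taxa) or list
#'   of equal-length strings; at least two rows.
#' @return list with \code{total}, \code{conserved}, \code{variable},
#'   \code{parsimony_informative}, \code{singleton}, \code{all_missing}.
#' @export
classifySites <- function(x) {
  aln <- .as_alignment_matrix(x)
  if (nrow(aln) < 2L) stop("site classification needs >= 2 sequences")
  states <- c("A", "C", "G", "T")
  tab <- apply(aln, 2L, function(col) {
    col <- col[col %in% states]
    tabulate(match(col, states), nbins = 4L)
  })
  n_states <- colSums(tab > 0L)
  informative <- colSums(tab >= 2L) >= 2L & n_states >= 2L
  variable <- n_states >= 2L
  list(total = ncol(aln),
       conserved = sum(!variable),
       variable = sum(variable),
       parsimony_informative = sum(informative),
       singleton = sum(variable & !informative),
       all_missing = sum(n_states == 0L))
}

.as_alignment_matrix <- function(x) {
  if (is(x, "Supermatrix")) return(alignment(x))
  if (is.matrix(x)) return(x)
  if (is.list(x) || is.character(x)) {
    x <- unlist(x)
    stopifnot(length(unique(nchar(x))) == 1L)
    m <- do.call(rbind, lapply(x, .chars))
    rownames(m) <- names(x)
    return(m)
  }
  stop("cannot interpret alignment input")
}

#' Uncorrected p-distance matrix
#'
#' Proportion of differing sites over the columns where both sequences
#' carry an unambiguous base (gaps and N treated as missing). A taxon
#' pair with no shared columns is an error.
#'
#' @param x alignment as for [classifySites()].
#' @return symmetric numeric matrix with zero diagonal.
#' @export
pDistance <- function(x) {
  aln <- .as_alignment_matrix(x)
  ntax <- nrow(aln)
  stopifnot(ntax >= 2L)
  ok <- matrix(aln %in% c("A", "C", "G", "T"), nrow = ntax)
  d <- matrix(0, ntax, ntax, dimnames = list(rownames(aln),
                                             rownames(aln)))
  for (i in seq_len(ntax - 1L)) {
    for (j in seq.int(i + 1L, ntax)) {
      shared <- ok[i, ] & ok[j, ]
      if (!any(shared)) {
        stop("no shared unambiguous columns between ", rownames(aln)[i],
             " and ", rownames(aln)[j])
      }
      d[i, j] <- d[j, i] <- mean(aln[i, shared] != aln[j, shared])
    }
  }
  d
}

#' Neighbor-joining sanity tree
#'
#' Canonical neighbor-joining on a distance matrix; consistent on
#' additive matrices. Intended as plumbing for a quick topology check --
#' model-based inference belongs to external tools.
#'
#' @param d symmetric distance matrix (e.g. from [pDistance()]); at
#'   least 3 taxa.
#' @return an \code{ape} \code{phylo} tree.
#' @export
njTree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) >= 3L, isTRUE(all.equal(d, t(d))))
  ape::nj(d)
}

#' Serialize a tree as Newick text
#'
#' Branch lengths at 6 decimals; deterministic output.
#'
#' @param tree a \code{phylo} object.
#' @param path optional output path; when NULL the Newick string is
#'   returned.
#' @return the Newick string (invisibly when written to \code{path}).
#' @export
writeNewick <- function(tree, path = NULL) {
  tree$edge.length <- round(tree$edge.length, 6L)
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(txt, con, sep = "\n")
    return(invisible(txt))
  }
  txt
}

#' Build the stop-stripped PCG supermatrix from annotated genomes
#'
#' Convenience wrapper: extracts every protein-coding gene from each
#' genome via [codingSequence()], strips stop codons, and concatenates
#' gene-wise. All genomes must share the same PCG set, and per-gene
#' lengths must agree across genomes (the generator emits equal-length
#' homologous genes so alignment is the identity; real data should be
#' aligned externally first).
#'
#' @param genomes named list of \code{MitoGenome}s with sequences.
#' @return a \linkS4class{Supermatrix}.
#' @export
pcgSupermatrix <- function(genomes) {
  stopifnot(length(genomes) >= 2L, !is.null(names(genomes)))
  gene_aln <- list()
  pcgs <- lapply(genomes, function(g) {
    ft <- features(g)
    sort(ft$name[ft$category == "PCG"])
  })
  shared <- Reduce(intersect, pcgs)
  if (!length(shared)) stop("no protein-coding genes shared by all genomes")
  for (gene in shared) {
    seqs <- vapply(genomes, function(g)
      stripStopCodon(codingSequence(g, gene)), "")
    if (length(unique(nchar(seqs))) != 1L) {
      stop("gene '", gene, "' has unequal lengths across genomes; ",
           "align it externally before concatenation")
    }
    gene_aln[[gene]] <- seqs
  }
  concatenateAlignments(gene_aln)
}
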
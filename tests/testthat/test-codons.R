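test_that("the bundled genetic code is the vertebrate mitochondrial table", {
  code <- vertebrateMitoCode()
  expect_length(code$code, 64L)
  expect_identical(unname(code$code[c("AGA", "AGG")]), c("*", "*"))
  expect_identical(unname(code$code["ATA"]), "M")
  expect_identical(unname(code$code["TGA"]), "W")
  ## every non-stop codon sits in exactly one family
  expect_equal(sum(lengths(code$families)), 60L)
})

test_that("coding sequences honour strand and incomplete-stop padding", {
  g <- cached_mitogenome(5)$genome
  ft <- features(g)
  ## complete-stop H-strand gene: no padding, length preserved
  nd5 <- codingSequence(g, "ND5")
  expect_identical(nd5$padding, "")
  expect_equal(nchar(nd5$sequence), 1824L)
  ## incomplete stop: trailing T padded with AA
  nd1 <- codingSequence(g, "ND1")
  expect_identical(nd1$padding, "AA")
  expect_equal(nchar(nd1$sequence), 960L)
  expect_identical(substr(nd1$sequence, 958, 960), "TAA")
  ## L-strand gene equals the reverse complement of its span
  nd6 <- codingSequence(g, "ND6")
  row <- ft[ft$name == "ND6", ]
  span <- substr(as.character(genomeSequence(g)), row$start, row$stop)
  expect_identical(nd6$sequence, revcomp_chr(span))
  expect_error(codingSequence(g, "tRNA-Phe"), "not a protein-coding")
})

test_that("start/stop classification matches the annotated codons", {
  g <- cached_mitogenome(5)$genome
  ft <- features(g)
  for (gene in ft$name[ft$category == "PCG"]) {
    cl <- classifyCodons(codingSequence(g, gene))
    row <- ft[ft$name == gene, ]
    expect_identical(cl$start_codon, row$start_codon, info = gene)
    expect_identical(cl$stop_codon, row$stop_codon, info = gene)
  }
  expect_identical(classifyCodons("ATGAAATAA"),
                   list(start_codon = "ATG", stop_codon = "TAA"))
  expect_warning(cl <- classifyCodons("ATGAAACCC"), "unrecognized")
  expect_identical(cl$stop_codon, "??")
})

test_that("codon usage conserves totals and supports padded-codon control", {
  usage <- codonUsage(list("ATGAAATAA"))
  expect_equal(unname(usage[c("ATG", "AAA", "TAA")]), c(1L, 1L, 1L))
  expect_equal(attr(usage, "total"), 3L)
  g <- cached_mitogenome(5)$genome
  css <- lapply(features(g)$name[features(g)$category == "PCG"],
                function(x) codingSequence(g, x))
  usage <- codonUsage(css)
  expect_equal(attr(usage, "total"),
               sum(vapply(css, function(cs) nchar(cs$sequence), 0L)) / 3L)
  no_pad <- codonUsage(css, count_padded = FALSE)
  n_padded <- sum(vapply(css, function(cs) nzchar(cs$padding), TRUE))
  expect_equal(attr(usage, "total") - attr(no_pad, "total"), n_padded)
  rna <- codonUsage(list("ATGAAATAA"), rna = TRUE)
  expect_equal(unname(rna["AUG"]), 1L)
})

test_that("RSCU follows the family-size normalization", {
  ## 4-fold family with equal counts -> all 1.0
  usage <- setNames(integer(64), names(vertebrateMitoCode()$code))
  usage[c("GCT", "GCC", "GCA", "GCG")] <- 5L
  rt <- rscu(usage)
  expect_equal(rt$rscu[rt$amino_acid == "A"], rep(1, 4))
  ## concentrated family: (4,0,0,0) -> RSCU (4,0,0,0)
  usage[c("GCT", "GCC", "GCA", "GCG")] <- c(4L, 0L, 0L, 0L)
  rt <- rscu(usage)
  expect_equal(sort(rt$rscu[rt$amino_acid == "A"], decreasing = TRUE),
               c(4, 0, 0, 0))
  ## zero-total family carries the undefined marker
  expect_true(all(is.na(rt$rscu[rt$amino_acid == "G"])))
  ## stop codons never appear
  expect_false(any(rt$codon %in% c("TAA", "TAG", "AGA", "AGG")))
})

test_that("RSCU family sums equal family sizes for observed families", {
  g <- cached_mitogenome(6)$genome
  css <- lapply(features(g)$name[features(g)$category == "PCG"],
                function(x) codingSequence(g, x))
  rt <- rscu(codonUsage(css))
  sums <- tapply(rt$rscu, rt$amino_acid, sum)
  sizes <- tapply(rt$rscu, rt$amino_acid, length)
  observed <- !is.na(sums)
  expect_true(all(observed))
  expect_equal(unname(sums[observed]), unname(sizes[observed]))
})

test_that("planted AT codon bias is recovered as overused A/T-ending codons", {
  g <- cached_mitogenome(6)$genome
  css <- lapply(features(g)$name[features(g)$category == "PCG"],
                function(x) codingSequence(g, x))
  rt <- rscu(codonUsage(css))
  third <- substr(rt$codon, 3, 3)
  ## among 4-fold families, A/T-ending codons outrank G/C-ending ones
  at_mean <- mean(rt$rscu[third %in% c("A", "T")], na.rm = TRUE)
  gc_mean <- mean(rt$rscu[third %in% c("G", "C")], na.rm = TRUE)
  expect_gt(at_mean, gc_mean)
  expect_gt(at_mean, 1)
})

test_that("amino-acid frequencies are percentages of non-stop codons", {
  usage <- setNames(integer(64), names(vertebrateMitoCode()$code))
  usage["ATG"] <- 7L
  aa <- aaFrequencies(usage)
  expect_equal(unname(aa["M"]), 100)
  g <- cached_mitogenome(5)$genome
  css <- lapply(features(g)$name[features(g)$category == "PCG"],
                function(x) codingSequence(g, x))
  aa <- aaFrequencies(codonUsage(css))
  expect_equal(sum(aa), 100)
  expect_true(all(aa >= 0))
})

test_that("printed codon-usage table accounting is reproduced", {
  t3 <- table3()
  ## Leu family total for the first species column
  leu <- sum(t3$n_parkeri[t3$amino_acid == "Leu"])
  expect_equal(leu, 614L)
  ## maximum-count codon for the second species column
  expect_identical(t3$codon[which.max(t3$n_ventripunctata)], "AUU")
  expect_equal(max(t3$n_ventripunctata), 204L)
  ## the most frequent amino acid is Leu
  aa_tot <- tapply(t3$n_parkeri[t3$amino_acid != "Stop"],
                   t3$amino_acid[t3$amino_acid != "Stop"], sum)
  expect_identical(names(which.max(aa_tot)), "Leu")
})
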
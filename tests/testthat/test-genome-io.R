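test_that("FASTA reading folds case, maps unknown letters and keeps file order", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">one desc", "acgt", ">two", "AAQA", "CCC"), fa)
  seqs <- suppressWarnings(readMitoFasta(fa))
  expect_identical(names(seqs), c("one", "two"))
  expect_identical(as.character(seqs[["one"]]), "ACGT")
  expect_warning(readMitoFasta(fa), "mapped to N")
  expect_identical(as.character(seqs[["two"]]), "AANACCC")
})

test_that("malformed FASTA input is rejected with the offending line", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("ACGT", ">late"), fa)
  expect_error(readMitoFasta(fa), "line 1")
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(readMitoFasta(empty), "empty")
})

test_that("annotation-table dialect round-trips printed conventions", {
  rows <- readFeatureTable(table1_path("parkeri"))
  expect_equal(nrow(rows), 40L)
  nd5 <- rows[rows$name == "ND5", ]
  expect_equal(nd5$start, 12050L)   # thousands separators stripped
  expect_equal(nd5$stop, 13873L)
  expect_equal(nd5$printed_size, 1824L)
  expect_equal(nd5$printed_intergenic, -15L)
  nd1 <- rows[rows$name == "ND1", ]
  expect_identical(nd1$stop_codon, "T-")
})

test_that("typographic minus and en-dash variants are normalized", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tstrand\tfrom\tto\tsize\tstart_codon\tstop_codon\tintergenic",
               "ND1\tH\t2,947\t3,904\t958\tGTG\tT–\t−3"),
             tsv, useBytes = FALSE)
  rows <- readFeatureTable(tsv)
  expect_identical(rows$stop_codon, "T-")
  expect_equal(rows$printed_intergenic, -3L)
})

test_that("missing mandatory columns and empty tables are errors", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tstrand\tsize", "ND1\tH\t958"), tsv)
  expect_error(readFeatureTable(tsv), "from, to")
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gene\tstrand\tfrom\tto", empty)
  expect_error(readFeatureTable(empty), "no rows")
})

test_that("GenBank subset parser handles strand, wrap and name synonyms", {
  gb <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       toy 30 bp    DNA     circular   UNA",
    "FEATURES             Location/Qualifiers",
    "     CDS             1..9",
    '                     /gene="COI"',
    "     tRNA            complement(10..18)",
    '                     /gene="trnF"',
    "     D-loop          join(25..30,1..3)",
    '                     /gene="D-loop"',
    "ORIGIN",
    "        1 atgaaatagc ccggttttaa acgtacgtac",
    "//"), gb)
  g <- readGenBank(gb)
  ft <- features(g)
  expect_identical(ft$name[ft$category == "PCG"], "COX1")
  expect_identical(ft$strand[ft$name == "tRNA-Phe"], "L")
  cr <- ft[ft$category == "control_region", ]
  expect_equal(c(cr$start, cr$stop), c(25L, 3L))
  expect_equal(featureLength(cr$start, cr$stop, 30L, TRUE), 9L)
})

test_that("out-of-range GenBank coordinates error unless wrapping", {
  gb <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       toy 20 bp    DNA     linear   UNA",
    "FEATURES             Location/Qualifiers",
    "     CDS             1..25",
    '                     /gene="ND1"',
    "ORIGIN",
    "        1 atgaaatagc ccggttttaa",
    "//"), gb)
  expect_error(readGenBank(gb), "beyond sequence length")
})

test_that("gene-name normalization maps published synonyms", {
  expect_identical(normalizeGeneName(c("COI", "cox1", "Cytb", "D-loop",
                                       "12S rRNA", "unknown-x")),
                   c("COX1", "COX1", "CYTB", "CR", "12S", "unknown-x"))
})

test_that("alignment export is deterministic with correct partitions", {
  aln <- c(t1 = "ACGTAAACGTACGTA", t2 = "ACGTAAACGTACGTT")
  parts <- data.frame(gene = c("g1", "g2", "g3"),
                      first = c(1L, 7L, 10L), last = c(6L, 9L, 15L))
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeAlignment(aln, fa, "fasta")
  expect_identical(readLines(fa), c(">t1", aln[[1]], ">t2", aln[[2]]))
  fa2 <- withr::local_tempfile(fileext = ".fasta")
  writeAlignment(aln, fa2, "fasta")
  expect_identical(readBin(fa, "raw", 1e4), readBin(fa2, "raw", 1e4))
  nex <- withr::local_tempfile(fileext = ".nex")
  writeAlignment(aln, nex, "nexus", partitions = parts)
  txt <- readLines(nex)
  expect_true(any(grepl("charset g2 = 7-9;", txt)))
  phy <- withr::local_tempfile(fileext = ".phy")
  writeAlignment(aln, phy, "phylip-relaxed", partitions = parts)
  expect_identical(readLines(phy)[1], " 2 15")
  expect_identical(readLines(paste0(phy, ".partitions"))[3],
                   "DNA, g3 = 10-15")
  expect_error(writeAlignment(c(a = "ACGT", b = "AC"), fa, "fasta"),
               "ragged")
})

test_that("feature tables and GenBank files written by the generator round-trip", {
  res <- cached_mitogenome(11)
  tmp <- withr::local_tempdir()
  tsv <- file.path(tmp, "features.tsv")
  writeFeatureTable(res$genome, tsv)
  back <- validateAnnotation(readFeatureTable(tsv), "roundtrip")
  expect_equal(nrow(back$report), 0L)
  expect_identical(features(back$genome)[, c("name", "strand", "start", "stop")],
                   features(res$genome)[, c("name", "strand", "start", "stop")])
  gb <- file.path(tmp, "genome.gb")
  writeGenBank(res$genome, gb)
  gback <- readGenBank(gb)
  expect_identical(as.character(genomeSequence(gback)),
                   as.character(genomeSequence(res$genome)))
  expect_identical(features(gback)[, c("name", "category", "strand",
                                       "start", "stop")],
                   features(res$genome)[, c("name", "category", "strand",
                                            "start", "stop")])
  expect_equal(nrow(features(gback)), 40L)  # nothing silently dropped
})
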
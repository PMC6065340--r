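test_that("stop codons are stripped, including padded incomplete stops", {
  expect_identical(stripStopCodon("ATGAAATAA"), "ATGAAA")
  g <- cached_mitogenome(5)$genome
  nd1 <- codingSequence(g, "ND1")       # "T-" gene, padded to 960
  stripped <- stripStopCodon(nd1)
  expect_equal(nchar(nd1$sequence) - nchar(stripped), 3L)
  expect_equal(nchar(stripped) %% 3L, 0L)
  expect_warning(out <- stripStopCodon("ATGAAACCC"), "no recognized stop")
  expect_identical(out, "ATGAAACCC")
})

test_that("concatenation tiles partitions in canonical gene order", {
  aln <- list(COX1 = c(a = "ACGTAA", b = "ACGTAA"),
              ND1 = c(a = "AAA", b = "AAC"),
              CYTB = c(a = "GGGGGGGGGGGG", b = "GGGGGGGGGGGT"))
  sm <- concatenateAlignments(aln)
  pt <- partitions(sm)
  expect_identical(pt$gene, c("ND1", "COX1", "CYTB"))
  expect_equal(pt$first, c(1L, 4L, 10L))
  expect_equal(pt$last, c(3L, 9L, 21L))
  expect_equal(ncol(alignment(sm)), 21L)
  ## single gene is the identity concatenation
  sm1 <- concatenateAlignments(aln["ND1"])
  expect_equal(ncol(alignment(sm1)), 3L)
  ## missing taxon is an error naming it
  bad <- aln
  bad$ND1 <- bad$ND1["a"]
  expect_error(concatenateAlignments(bad), "b")
})

test_that("site classification follows the parsimony-informative definition", {
  aln <- matrix(strsplit(paste0(
    "ACGTACGT",
    "ACGTACGA",
    "ACCTACGA",
    "ACCTTCGT"), "")[[1]], nrow = 4, byrow = TRUE,
    dimnames = list(paste0("t", 1:4), NULL))
  ## hand tally: col3 G,G,C,C informative; col5 A,A,A,T singleton;
  ## col8 T,A,A,T informative; cols 1,2,4,6,7 conserved
  cls <- classifySites(aln)
  expect_equal(cls$total, 8L)
  expect_equal(cls$conserved, 5L)
  expect_equal(cls$variable, 3L)
  expect_equal(cls$parsimony_informative, 2L)
  expect_equal(cls$singleton, 1L)
  ## identities and definitions on corner cases
  same <- matrix("A", 4, 10, dimnames = list(paste0("t", 1:4), NULL))
  cls2 <- classifySites(same)
  expect_equal(cls2$conserved, 10L)
  expect_equal(cls2$variable, 0L)
  expect_error(classifySites(same[1, , drop = FALSE]), ">= 2")
})

test_that("conserved + variable == total on random alignments with missing data", {
  set.seed(12)
  for (i in 1:50) {
    nt <- sample(2:8, 1); nc <- sample(5:40, 1)
    aln <- matrix(sample(c("A", "C", "G", "T", "N", "-"), nt * nc,
                         replace = TRUE, prob = c(.2, .2, .2, .2, .1, .1)),
                  nt, nc, dimnames = list(paste0("t", 1:nt), NULL))
    cls <- classifySites(aln)
    expect_equal(cls$conserved + cls$variable, cls$total)
    expect_lte(cls$parsimony_informative, cls$variable)
    expect_equal(cls$singleton, cls$variable - cls$parsimony_informative)
  }
})

test_that("p-distance handles missing data and agrees with ape on clean data", {
  aln <- matrix(c("A", "C", "G", "T",
                  "A", "C", "G", "A",
                  "N", "C", "G", "A"), 3, 4, byrow = TRUE,
                dimnames = list(c("x", "y", "z"), NULL))
  d <- pDistance(aln)
  expect_equal(d["x", "y"], 0.25)
  expect_equal(d["y", "z"], 0)          # N column dropped pairwise
  expect_equal(d["x", "z"], 1 / 3)
  expect_equal(diag(d), c(x = 0, y = 0, z = 0))
  ## independent route: ape::dist.dna raw distance on gap-free data
  set.seed(3)
  m <- matrix(sample(c("A", "C", "G", "T"), 5 * 60, replace = TRUE), 5, 60,
              dimnames = list(paste0("t", 1:5), NULL))
  ours <- pDistance(m)
  theirs <- as.matrix(ape::dist.dna(ape::as.DNAbin(m), model = "raw"))
  expect_equal(ours, theirs[rownames(ours), colnames(ours)],
               tolerance = 1e-12)
  zz <- matrix(c("A", "N", "N", "A"), 2, 2, byrow = TRUE,
               dimnames = list(c("p", "q"), NULL))
  expect_error(pDistance(zz), "no shared")
})

test_that("NJ recovers the generating topology from an additive matrix", {
  ## distances from tree ((A:1,B:2):1,(C:1.5,D:2.5):1); additive
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 4.5
  d["A", "D"] <- d["D", "A"] <- 5.5
  d["B", "C"] <- d["C", "B"] <- 5.5
  d["B", "D"] <- d["D", "B"] <- 6.5
  d["C", "D"] <- d["D", "C"] <- 4
  tr <- njTree(d)
  ## A+B form a cherry, as do C+D
  pairs <- ape::prop.part(tr)
  tips <- sort(attr(pairs, "labels"))
  expect_identical(tips, LETTERS[1:4])
  un <- ape::unroot(tr)
  cherry <- function(tree, a, b) {
    ea <- tree$edge[tree$edge[, 2] == which(tree$tip.label == a), 1]
    eb <- tree$edge[tree$edge[, 2] == which(tree$tip.label == b), 1]
    ea == eb
  }
  expect_true(cherry(un, "A", "B"))
  expect_true(cherry(un, "C", "D"))
})

test_that("Newick export is deterministic with 6-decimal branch lengths", {
  d <- matrix(c(0, .1, .4, .1, 0, .4, .4, .4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- njTree(d)
  txt <- writeNewick(tr)
  expect_identical(txt, writeNewick(njTree(d)))
  expect_match(txt, "^\\(.*\\);$")
})

test_that("supermatrix from annotated genomes tiles the stripped genes", {
  anc <- cached_mitogenome(21)
  trio <- mutatePopulation(anc$genome, c(A = 0.02, B = 0.02, C = 0.10),
                           seed = 77)
  sm <- suppressWarnings(pcgSupermatrix(trio))
  pt <- partitions(sm)
  expect_equal(nrow(pt), 13L)
  expect_identical(pt$gene, c("ND1", "ND2", "COX1", "COX2", "ATP8",
                              "ATP6", "COX3", "ND3", "ND4L", "ND4",
                              "ND5", "ND6", "CYTB"))
  widths <- pt$last - pt$first + 1L
  expect_equal(sum(widths), ncol(alignment(sm)))
  ## every width is a multiple of 3 after stop stripping
  expect_true(all(widths %% 3L == 0L))
  cls <- classifySites(sm)
  expect_equal(cls$conserved + cls$variable, cls$total)
})

test_that("synthetic trios group the two low-divergence taxa", {
  anc <- cached_mitogenome(21)
  for (s in 1:20) {
    trio <- mutatePopulation(anc$genome,
                             c(A = 0.02, B = 0.02, C = 0.10), seed = s)
    d <- pDistance(suppressWarnings(pcgSupermatrix(trio)))
    expect_lt(d["A", "B"], d["A", "C"])
    expect_lt(d["A", "B"], d["B", "C"])
  }
})
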
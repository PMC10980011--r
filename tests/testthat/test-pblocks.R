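test_that("protein projection treats synonymous Edge pairs as matched", {
  pairs <- data.frame(
    refIdx = c(1L, 2L, 3L, 4L), altIdx = c(1L, 2L, 3L, 4L),
    category = c("Match", "Edge", "Edge", "Match"),
    aaMatch = c(TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  pb <- projectProteinBlocks(pairs)
  expect_identical(pb$category, c("Match", "Substitution", "Match"))
  expect_identical(pb$positionClass, c("none", "internal", "none"))
  expect_identical(pb$refStart[2], 3L)
  expect_identical(pb$refLen[2], 1L)
})

test_that("altered runs are typed by which sides contribute residues", {
  pairs <- data.frame(
    refIdx = c(1L, 2L, NA, 3L, NA),
    altIdx = c(1L, NA, 2L, 3L, 4L),
    category = c("Match", "Deletion", "Insertion", "Match", "Translated"),
    aaMatch = c(TRUE, NA, NA, TRUE, NA),
    stringsAsFactors = FALSE)
  pb <- projectProteinBlocks(pairs)
  expect_identical(pb$category,
                   c("Match", "Substitution", "Match", "Insertion"))
  expect_identical(pb$positionClass, c("none", "internal", "none",
                                       "c_terminal"))
  expect_identical(pb$refLen, c(1L, 1L, 1L, 0L))
  expect_identical(pb$altLen, c(1L, 1L, 1L, 1L))
})

test_that("position classes cover all four placements", {
  mk <- function(categories) {
    n <- length(categories)
    data.frame(refIdx = seq_len(n), altIdx = seq_len(n),
               category = categories,
               aaMatch = ifelse(categories == "Match", TRUE, FALSE),
               stringsAsFactors = FALSE)
  }
  expect_identical(
    projectProteinBlocks(mk(c("Edge", "Match")))$positionClass,
    c("n_terminal", "none"))
  expect_identical(
    projectProteinBlocks(mk(c("Match", "Edge")))$positionClass,
    c("none", "c_terminal"))
  expect_identical(
    projectProteinBlocks(mk(c("Match", "Edge", "Match")))$positionClass,
    c("none", "internal", "none"))
  expect_identical(
    projectProteinBlocks(mk(c("Edge", "Edge")))$positionClass,
    "full_length")
})

test_that("fixture p-blocks carry the expected geometry", {
  # a skipped in-frame 60 nt exon deletes exactly 20 internal residues
  aln <- fixtureAlignment(generateFixture("exon_skip", "+", 17))
  pb <- pBlocks(aln)
  expect_identical(pb$category, c("Match", "Deletion", "Match"))
  expect_identical(pb$positionClass[2], "internal")
  expect_identical(pb$refLen[2], 20L)
  expect_identical(pb$altLen[2], 0L)
  expect_identical(pb$refStart[2], 37L)
  expect_identical(pb$refEnd[2], 56L)

  # residue conservation across blocks
  expect_identical(sum(pb$refLen), nchar(proteinSequence(aln@refOrf)))
  expect_identical(sum(pb$altLen), nchar(proteinSequence(aln@altOrf)))

  # Match p-blocks are 100% identical at the residue level
  refAA <- strsplit(proteinSequence(aln@refOrf), "")[[1]]
  altAA <- strsplit(proteinSequence(aln@altOrf), "")[[1]]
  for (i in which(pb$category == "Match"))
    expect_identical(refAA[pb$refStart[i]:pb$refEnd[i]],
                     altAA[pb$altStart[i]:pb$altEnd[i]])
})
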
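test_that("codon pairs follow the nine-category scheme", {
  # genuinely contiguous one-position shift -> Ahead
  refTx <- makeTestTx("r", rbind(c(101, 112)))
  altTx <- makeTestTx("a", rbind(c(102, 113)))
  refOrf <- makeTestOrf("r", rbind(c(101L, 102L, 103L), c(104L, 105L, 106L)),
                        rep("contiguous", 2), "MK")
  altOrf <- makeTestOrf("a", rbind(c(102L, 103L, 104L), c(105L, 106L, 107L)),
                        rep("contiguous", 2), "MK")
  p <- pairCodons(refOrf, altOrf, refTx, altTx)
  expect_identical(p$category, c("Ahead", "Ahead"))
  expect_identical(p$overlap, c(2L, 2L))

  # mirrored shift -> Behind
  pb <- pairCodons(altOrf, refOrf, altTx, refTx)
  expect_identical(pb$category, c("Behind", "Behind"))
})

test_that("split codons overlapping at a junction pair as Edge or Complex", {
  # ref codon split 2|1 and alt codon split 1|2 sharing {109, 200} at the
  # same within-codon offsets: frame preserved -> Edge
  refTx <- makeTestTx("r", rbind(c(108, 110), c(200, 205)))
  altTx <- makeTestTx("a", rbind(c(105, 109), c(199, 205)))
  refOrf <- makeTestOrf("r", rbind(c(109L, 110L, 200L)), "2|1", "X")
  altOrf <- makeTestOrf("a", rbind(c(109L, 199L, 200L)), "1|2", "X")
  p <- pairCodons(refOrf, altOrf, refTx, altTx)
  expect_identical(p$category, "Edge")
  expect_identical(p$overlap, 2L)
  expect_true(p$aaMatch)

  # one split codon against a contiguous codon sharing two positions at
  # shifted offsets -> Complex
  refTx2 <- makeTestTx("r", rbind(c(108, 110), c(200, 210)))
  altTx2 <- makeTestTx("a", rbind(c(200, 210)))
  refOrf2 <- makeTestOrf("r", rbind(c(110L, 200L, 201L)), "1|2", "X")
  altOrf2 <- makeTestOrf("a", rbind(c(200L, 201L, 202L)), "contiguous", "Y")
  p2 <- pairCodons(refOrf2, altOrf2, refTx2, altTx2)
  expect_identical(p2$category, "Complex")
  expect_false(p2$aaMatch)
})

test_that("single shared positions pair only when junction-adjacent", {
  # shared position 110 flanks the junction of the split ref codon -> paired
  refTx <- makeTestTx("r", rbind(c(108, 110), c(200, 210)))
  altTx <- makeTestTx("a", rbind(c(108, 119)))
  refOrf <- makeTestOrf("r", rbind(c(110L, 200L, 201L)), "1|2", "X")
  altOrf <- makeTestOrf("a", rbind(c(110L, 111L, 112L)), "contiguous", "X")
  p <- pairCodons(refOrf, altOrf, refTx, altTx)
  expect_identical(p$category, "Edge")
  expect_identical(p$overlap, 1L)

  # shared position away from the junction of a 2|1 codon -> unpaired
  refTx2 <- makeTestTx("r", rbind(c(105, 110), c(200, 210)))
  altTx2 <- makeTestTx("a", rbind(c(105, 116)))
  refOrf2 <- makeTestOrf("r", rbind(c(109L, 110L, 200L)), "2|1", "X")
  altOrf2 <- makeTestOrf("a", rbind(c(107L, 108L, 109L)), "contiguous", "X")
  p2 <- pairCodons(refOrf2, altOrf2, refTx2, altTx2)
  expect_identical(nrow(p2), 2L)
  expect_false(any(!is.na(p2$refIdx) & !is.na(p2$altIdx)))
})

test_that("unpaired codons split into deletion/insertion vs translation status", {
  # ref codon absent from alt exons -> Deletion; alt codon present in ref
  # exons but outside the ref CDS -> Translated
  refTx <- makeTestTx("r", rbind(c(101, 130)))
  altTx <- makeTestTx("a", rbind(c(110, 130)))
  refOrf <- makeTestOrf("r", rbind(c(101L, 102L, 103L)), "contiguous", "M")
  altOrf <- makeTestOrf("a", rbind(c(120L, 121L, 122L)), "contiguous", "V")
  p <- pairCodons(refOrf, altOrf, refTx, altTx)
  expect_identical(p$category[!is.na(p$refIdx)], "Deletion")
  expect_identical(p$category[!is.na(p$altIdx)], "Translated")

  # and the mirrored orientation gives Insertion / Untranslated
  q <- pairCodons(altOrf, refOrf, altTx, refTx)
  expect_identical(q$category[!is.na(q$altIdx)], "Insertion")
  expect_identical(q$category[!is.na(q$refIdx)], "Untranslated")
})

test_that("codon blocks conserve both ORFs", {
  for (et in c("identity", "ragged_edge", "snapback_frameshift", "coste")) {
    aln <- fixtureAlignment(generateFixture(et, "+", 13))
    pairs <- codonPairs(aln)
    nRef <- nrow(codonPositions(aln@refOrf))
    nAlt <- nrow(codonPositions(aln@altOrf))
    expect_identical(sort(pairs$refIdx[!is.na(pairs$refIdx)]), seq_len(nRef))
    expect_identical(sort(pairs$altIdx[!is.na(pairs$altIdx)]), seq_len(nAlt))
    cb <- cBlocks(aln)
    expect_identical(sum(cb$nPairs), nrow(pairs))
    # maximal runs: consecutive blocks never share a category
    if (nrow(cb) > 1L)
      expect_true(all(cb$category[-1] != cb$category[-nrow(cb)]))
  }
})

test_that("a self-pair is Match at the codon layer", {
  aln <- fixtureAlignment(generateFixture("identity", "-", 21))
  expect_true(all(codonPairs(aln)$category == "Match"))
  expect_identical(nrow(cBlocks(aln)), 1L)
  expect_identical(cBlocks(aln)$category, "Match")
})
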
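test_that("the brute-force oracle reproduces hand-built pairings", {
  refTx <- makeTestTx("r", rbind(c(101, 112)))
  altTx <- makeTestTx("a", rbind(c(102, 113)))
  refOrf <- makeTestOrf("r", rbind(c(101L, 102L, 103L), c(104L, 105L, 106L)),
                        rep("contiguous", 2), "MK")
  altOrf <- makeTestOrf("a", rbind(c(102L, 103L, 104L), c(105L, 106L, 107L)),
                        rep("contiguous", 2), "MK")
  o <- bruteForceCodonOracle(refOrf, altOrf, refTx, altTx)
  expect_identical(o$category, c("Ahead", "Ahead"))
  expect_identical(o$refIdx, c(1L, 2L))
  expect_identical(o$altIdx, c(1L, 2L))
})

test_that("oracle and production pairing agree on every event type", {
  for (et in fixtureEventTypes()) for (st in c("+", "-")) {
    aln <- fixtureAlignment(generateFixture(et, st, 29))
    oracle <- bruteForceCodonOracle(aln@refOrf, aln@altOrf,
                                    aln@refTx, aln@altTx)
    prod <- codonPairs(aln)[, c("refIdx", "altIdx", "category")]
    rownames(prod) <- NULL
    expect_identical(oracle, prod, info = paste(et, st))
  }
})
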
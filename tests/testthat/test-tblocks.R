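test_that("transcript alignment partitions exonic sequence into blocks", {
  ref <- makeTestTx("r", rbind(c(101, 200), c(301, 400)))
  alt <- makeTestTx("a", rbind(c(151, 200), c(301, 340), c(361, 400)))
  tb <- alignTranscripts(ref, alt)
  # the 200|301 junction is spliced by both isoforms, so the two flanking
  # Match pieces merge into one block with two genomic intervals
  expect_identical(tb$category,
                   c("Deletion", "Match", "Deletion", "Match"))
  expect_identical(tb$gstart, c(101L, 151L, 341L, 361L))
  expect_identical(tb$gend, c(150L, 340L, 360L, 400L))
  expect_identical(tb$intervals[2], "151-200,301-340")
  # reference transcript coordinates tile 1..200 without gaps
  expect_identical(tb$refTxStart, c(1L, 51L, 141L, 161L))
  expect_identical(tb$refTxEnd, c(50L, 140L, 160L, 200L))
  # exonic content is conserved on both sides
  expect_identical(sum(tb$refTxEnd - tb$refTxStart + 1L, na.rm = TRUE), 200L)
  altLens <- tb$altTxEnd - tb$altTxStart + 1L
  expect_identical(sum(altLens, na.rm = TRUE), 130L)
})

test_that("match blocks merge across junctions shared by both isoforms", {
  ref <- makeTestTx("r", rbind(c(101, 200), c(301, 400)))
  tb <- alignTranscripts(ref, ref)
  expect_identical(nrow(tb), 1L)
  expect_identical(tb$category, "Match")
  expect_identical(tb$nIntervals, 2L)
  expect_identical(tb$intervals, "101-200,301-400")
})

test_that("mechanisms are attributed on both strands", {
  for (st in c("+", "-")) {
    b <- generateFixture("exon_skip", st, 8)
    tb <- tBlocks(fixtureAlignment(b))
    del <- tb[tb$category == "Deletion", ]
    expect_identical(nrow(del), 1L)
    expect_identical(del$mechanism, "alt_exon")

    b2 <- generateFixture("retained_intron_inframe", st, 8)
    tb2 <- tBlocks(fixtureAlignment(b2))
    ins <- tb2[tb2$category == "Insertion", ]
    expect_identical(ins$mechanism, "retained_intron")

    b3 <- generateFixture("alt_donor_inframe", st, 8)
    tb3 <- tBlocks(fixtureAlignment(b3))
    expect_identical(tb3$mechanism[tb3$category == "Deletion"], "alt_donor")

    b4 <- generateFixture("alt_acceptor_inframe", st, 8)
    tb4 <- tBlocks(fixtureAlignment(b4))
    expect_identical(tb4$mechanism[tb4$category == "Deletion"],
                     "alt_acceptor")

    b5 <- generateFixture("mxs_tss", st, 8)
    tb5 <- tBlocks(fixtureAlignment(b5))
    expect_identical(tb5$mechanism[tb5$category == "Deletion"], "altTSS")
    expect_identical(tb5$mechanism[tb5$category == "Insertion"], "altTSS")

    b6 <- generateFixture("coste", st, 8)
    tb6 <- tBlocks(fixtureAlignment(b6))
    expect_true("altTTS" %in% tb6$mechanism)
  }
})

test_that("disjoint isoforms are rejected", {
  ref <- makeTestTx("r", rbind(c(101, 200)))
  alt <- makeTestTx("a", rbind(c(301, 400)))
  expect_error(alignTranscripts(ref, alt), "disjoint")
})

test_that("t-blocks are ordered in transcript direction on the minus strand", {
  b <- generateFixture("exon_skip", "-", 2)
  tb <- tBlocks(fixtureAlignment(b))
  # transcript direction on the minus strand is descending genomic order
  expect_true(all(diff(tb$gstart) < 0))
  expect_identical(tb$category[tb$gstart == min(tb$gstart)], "Match")
})
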
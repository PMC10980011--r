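callFor <- function(eventType, strand = "+", seed = 19) {
  b <- generateFixture(eventType, strand, seed)
  annotateAlignment(fixtureAlignment(b))
}

test_that("N-terminal regions are classified by start-codon sharing", {
  for (st in c("+", "-")) {
    mxs <- callFor("mxs_tss", st)
    expect_identical(mxs$nTerminalClass, "MXS")
    expect_identical(mxs$nTerminalDriver, "altTSS")

    mxs2 <- callFor("mxs_splice", st)
    expect_identical(mxs2$nTerminalClass, "MXS")
    expect_identical(mxs2$nTerminalDriver, "utr5_splicing")

    sds <- callFor("sds_tss", st)
    expect_identical(sds$nTerminalClass, "SDS")
    expect_identical(sds$nTerminalDriver, "altTSS")
    expect_false(sds$hybridExon)

    hyb <- callFor("sds_hybrid", st)
    expect_identical(hyb$nTerminalClass, "SDS")
    expect_true(hyb$hybridExon)

    mss <- callFor("mss", st)
    expect_identical(mss$nTerminalClass, "MSS")
    expect_identical(mss$nTerminalDriver, "cotranslational")

    sus <- callFor("sus", st)
    expect_identical(sus$nTerminalClass, "SUS")
    expect_identical(sus$nTerminalDriver, "unset")
  }
})

test_that("internal regions separate single, compound and flagged events", {
  single <- callFor("exon_skip")
  expect_identical(single$spliceComplexity, "single")
  expect_identical(single$mechanisms, "alt_exon")
  expect_false(single$multiExonSkip)

  multi <- callFor("multi_exon_skip")
  expect_identical(multi$spliceComplexity, "compound")
  expect_true(multi$multiExonSkip)
  expect_identical(multi$mechanisms, "alt_exon,alt_exon")

  ragged <- callFor("ragged_edge")
  expect_true(ragged$ragged)
  expect_true(ragged$ragged3)
  expect_false(ragged$ragged5)
  expect_false(ragged$snapback)
  expect_identical(ragged$category, "Substitution")

  snap <- callFor("snapback_frameshift")
  expect_true(snap$snapback)
  expect_identical(snap$spliceComplexity, "compound")
  expect_identical(snap$mechanisms, "alt_donor,alt_acceptor")
  expect_false(snap$multiExonSkip)
})

test_that("C-terminal regions separate frameshift- from splice-driven", {
  fs <- callFor("frameshift_cterm")
  expect_identical(fs$cTerminalMode, "frameshift_driven")
  expect_true(is.na(fs$cTerminalSubtype))

  for (case in list(c("exit_extension", "EXIT"),
                    c("poison_exon", "poison_exon"),
                    c("ale_in_utr", "ALE_in_UTR"),
                    c("coste", "COSTE"))) {
    cl <- callFor(case[1], "-")
    expect_identical(cl$cTerminalMode, "splice_driven")
    expect_identical(cl$cTerminalSubtype, case[2])
  }
})

test_that("identical proteins yield no altered-region calls", {
  calls <- callFor("identity")
  expect_identical(nrow(calls), 0L)
  expect_true(all(c("positionClass", "nTerminalClass", "cTerminalSubtype")
                  %in% names(calls)))
})

test_that("event summaries aggregate counts and lengths", {
  calls <- do.call(rbind, lapply(
    c("exon_skip", "retained_intron_inframe", "ragged_edge", "mss"),
    function(et) callFor(et)))
  s <- summarizeEventCalls(calls)
  expect_identical(s$nRegions, 4L)
  expect_identical(unname(s$byPositionClass[["internal"]]), 3L)
  expect_identical(s$fracDeletion, 0.5)
  expect_identical(s$fracInsertion, 0.25)
  expect_identical(s$fracSubstitution, 0.25)
  expect_identical(unname(s$nTerminalClasses[["MSS"]]), 1L)

  empty <- summarizeEventCalls(calls[0, , drop = FALSE])
  expect_identical(empty$nRegions, 0L)
  expect_true(is.na(empty$medianAlteredLength))
})
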
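test_that("fixture generation is deterministic", {
  a <- generateFixture("snapback_frameshift", "+", 101)
  b <- generateFixture("snapback_frameshift", "+", 101)
  expect_identical(a@genomeSeq, b@genomeSeq)
  expect_identical(a@gtf, b@gtf)
  expect_identical(a@txFasta, b@txFasta)
  expect_identical(a@protFasta, b@protFasta)
  expect_identical(a@truth, b@truth)
  c <- generateFixture("snapback_frameshift", "+", 102)
  expect_false(identical(a@genomeSeq, c@genomeSeq))
})

test_that("minus-strand bundles mirror the plus-strand bundle", {
  p <- generateFixture("ragged_edge", "+", 33)
  m <- generateFixture("ragged_edge", "-", 33)
  # identical spliced sequences and proteins, reverse-complemented scaffold
  expect_identical(unname(p@txFasta), unname(m@txFasta))
  expect_identical(unname(p@protFasta), unname(m@protFasta))
  expect_identical(
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(p@genomeSeq))), m@genomeSeq)
})

test_that("every bundle is internally consistent", {
  for (et in fixtureEventTypes()) {
    b <- generateFixture(et, "+", 55)
    gene <- geneModel(b)
    for (t in names(orfModels(gene))) {
      orf <- orfModels(gene)[[t]]
      prot <- proteinSequence(orf)
      expect_identical(substr(prot, 1, 1), "M")
      expect_false(grepl("\\*", prot))
      # the planted stop codon is TAA
      tx <- transcripts(gene)[[t]]
      stopSeq <- substr(tx@sequence, tx@cdsEnd + 1L, tx@cdsEnd + 3L)
      expect_identical(stopSeq, "TAA")
    }
  }
})

test_that("written bundles survive a full file round trip", {
  bundles <- list()
  for (et in c("identity", "multi_exon_skip", "sds_hybrid", "coste")) {
    b <- generateFixture(et, "-", 77)
    bundles[[b@geneId]] <- b
  }
  d <- tempfile()
  paths <- writeFixtureLibrary(bundles, d)
  expect_true(all(file.exists(paths)))

  genes <- loadIsoformData(paths[["gtf"]], paths[["transcripts"]],
                           paths[["proteins"]])
  expect_identical(sort(names(genes)), sort(names(bundles)))
  for (g in names(genes)) {
    expect_identical(genes[[g]]@referenceId, bundles[[g]]@gene@referenceId)
    expect_length(genes[[g]]@orfs, 2L)
  }
  # reloaded models reproduce the in-memory classification
  calls <- classifyAlignments(alignAllPairs(genes))
  for (g in names(bundles)) {
    sub <- calls[calls$geneId == g, , drop = FALSE]
    ck <- checkFixtureCalls(bundles[[g]], sub)
    expect_true(ck$ok, info = paste(ck$mismatches, collapse = "; "))
  }
  # truth table on disk covers the non-identity bundles
  truth <- utils::read.table(paths[["truth"]], sep = "\t", header = TRUE,
                             na.strings = ".", stringsAsFactors = FALSE)
  expect_identical(nrow(truth), 3L)
  expect_true(all(truth$geneId %in% names(bundles)))
})

test_that("the library derives strand-independent per-bundle seeds", {
  lib <- generateFixtureLibrary(seed = 7, replicates = 1)
  expect_length(lib, 2L * length(fixtureEventTypes()))
  seeds <- vapply(lib, function(b) b@seed, integer(1))
  types <- vapply(lib, function(b) b@eventType, character(1))
  for (et in fixtureEventTypes()) {
    s <- unique(seeds[types == et])
    expect_length(s, 1L)
  }
  # regeneration is identical
  lib2 <- generateFixtureLibrary(seed = 7, replicates = 1)
  expect_identical(lapply(lib, function(b) b@genomeSeq),
                   lapply(lib2, function(b) b@genomeSeq))
})

test_that("unknown event types are rejected", {
  expect_error(generateFixture("no_such_event", "+", 1), "unknown event")
})
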
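test_that("FASTA identifiers are normalised and duplicates rejected", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">tx1.2 gene=G extra", "ATGAAA", ">tx2", "CCCGGG"), fa)
  seqs <- readFastaSequences(fa)
  expect_identical(names(seqs), c("tx1.2", "tx2"))
  expect_identical(unname(seqs[1]), "ATGAAA")
  stripped <- readFastaSequences(fa, stripVersions = TRUE)
  expect_identical(names(stripped), c("tx1", "tx2"))
  writeLines(c(">a", "AA", ">a", "CC"), fa)
  expect_error(readFastaSequences(fa), "duplicate")
})

test_that("GTF round trip reproduces the fixture gene model", {
  b <- generateFixture("exon_skip", "-", 3)
  d <- tempfile()
  writeFixtureBundle(b, d)
  genes <- readGeneModels(file.path(d, "annotation.gtf"))
  expect_length(genes, 1L)
  gene <- genes[[1]]
  expect_identical(gene@geneId, b@geneId)
  expect_identical(sort(names(gene@transcripts)),
                   sort(names(b@gene@transcripts)))
  for (t in names(gene@transcripts)) {
    expect_identical(as.data.frame(gene@transcripts[[t]]@exons),
                     as.data.frame(b@gene@transcripts[[t]]@exons))
    expect_identical(gene@transcripts[[t]]@cdsStart,
                     b@gene@transcripts[[t]]@cdsStart)
    expect_identical(gene@transcripts[[t]]@cdsEnd,
                     b@gene@transcripts[[t]]@cdsEnd)
    expect_identical(gene@transcripts[[t]]@apprisTag,
                     b@gene@transcripts[[t]]@apprisTag)
  }
})

test_that("assembly validates sequences and reports skip reasons", {
  b <- generateFixture("identity", "+", 9)
  d <- tempfile()
  writeFixtureBundle(b, d)
  genes <- readGeneModels(file.path(d, "annotation.gtf"))
  txSeqs <- readFastaSequences(file.path(d, "transcripts.fa"))
  protSeqs <- readFastaSequences(file.path(d, "proteins.fa"))

  ok <- assembleGeneModels(genes, txSeqs, protSeqs)
  expect_length(ok[[1]]@orfs, 2L)
  expect_identical(nrow(ok[[1]]@skipped), 0L)

  # corrupt one protein record -> translation mismatch
  badProt <- protSeqs
  altId <- paste0(b@geneId, "_alt")
  substr(badProt[[altId]], 5, 5) <- "W"
  bad <- assembleGeneModels(genes, txSeqs, badProt)
  expect_length(bad[[1]]@orfs, 1L)
  expect_identical(bad[[1]]@skipped$reason, "translation mismatch")

  # drop a transcript sequence
  miss <- assembleGeneModels(genes, txSeqs[names(txSeqs) != altId],
                             protSeqs)
  expect_true("missing transcript sequence" %in% miss[[1]]@skipped$reason)

  # wrong-length transcript sequence
  short <- txSeqs
  short[[altId]] <- substr(short[[altId]], 1, 10)
  lenbad <- assembleGeneModels(genes, short, protSeqs)
  expect_true("sequence length mismatch" %in% lenbad[[1]]@skipped$reason)
})

test_that("transcripts with CDS outside their exons are skipped", {
  b <- generateFixture("identity", "+", 4)
  gtf <- b@gtf
  # move one CDS segment of the alternative outside its exons
  altCds <- grep("\tCDS\t.*_alt", gtf)
  parts <- strsplit(gtf[altCds[1]], "\t")[[1]]
  parts[4] <- "1"; parts[5] <- "50"
  gtf[altCds[1]] <- paste(parts, collapse = "\t")
  path <- tempfile(fileext = ".gtf")
  writeLines(gtf, path)
  genes <- readGeneModels(path)
  expect_identical(nrow(genes[[1]]@skipped), 1L)
  expect_match(genes[[1]]@skipped$reason, "CDS")
  expect_length(genes[[1]]@transcripts, 1L)
})

test_that("reference selection follows APPRIS rank with CDS-length ties", {
  b <- generateFixture("exon_skip", "+", 5)
  gene <- b@gene
  expect_identical(selectReference(gene), paste0(b@geneId, "_ref"))

  # give both isoforms the same tag: longest CDS wins
  for (t in names(gene@transcripts))
    gene@transcripts[[t]]@apprisTag <- "appris_principal_1"
  expect_identical(selectReference(gene), paste0(b@geneId, "_ref"))

  # no APPRIS tag at all: the gene is excluded
  for (t in names(gene@transcripts))
    gene@transcripts[[t]]@apprisTag <- "none"
  expect_identical(selectReference(gene), NA_character_)
  gene@referenceId <- NA_character_
  expect_identical(nrow(isoformPairs(gene)), 0L)
})

test_that("codon enumeration records split topology and stop positions", {
  b <- generateFixture("ragged_edge", "+", 6)
  orf <- orfModels(b@gene)[[paste0(b@geneId, "_ref")]]
  expect_identical(nrow(codonPositions(orf)), nchar(proteinSequence(orf)))
  # the third exon ends with one base of codon 57, which continues across
  # the junction into the fourth exon
  expect_identical(orf@split[57], "1|2")
  expect_identical(unname(codonPositions(orf)[57, ]), c(481L, 581L, 582L))
  expect_true(all(orf@split[1:56] == "contiguous"))
  # stop codon immediately follows the CDS
  expect_identical(unname(orf@stopPositions), c(753L, 754L, 755L))
})
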
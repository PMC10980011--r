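# Shared fixture cache so the acceptance library is only generated once per
# test run.
.fixtureCache <- new.env(parent = emptyenv())

libraryFixtures <- function(seed = 42L, replicates = 5L) {
  key <- sprintf("lib_%d_%d", seed, replicates)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- generateFixtureLibrary(seed, replicates)
  .fixtureCache[[key]]
}

libraryAlignments <- function(seed = 42L, replicates = 5L) {
  key <- sprintf("aln_%d_%d", seed, replicates)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- lapply(libraryFixtures(seed, replicates),
                                   fixtureAlignment)
  .fixtureCache[[key]]
}

# minimal hand-built transcript/ORF pair for codon-layer unit tests
makeTestTx <- function(id, exons, strand = "+") {
  new("TranscriptModel", transcriptId = id, geneId = "g", chrom = "chr",
      strand = strand, exons = IRanges::IRanges(exons[, 1], exons[, 2]),
      sequence = NA_character_, cdsStart = NA_integer_,
      cdsEnd = NA_integer_, apprisTag = "none")
}

makeTestOrf <- function(id, posMat, split, protein) {
  new("ORFModel", transcriptId = id, codonPositions = posMat,
      split = split, protein = protein,
      startPositions = posMat[1, ],
      stopPositions = rep(NA_integer_, 3L))
}

# category mirror used by the symmetry checks
mirrorCategory <- function(x) {
  map <- c(Match = "Match", Deletion = "Insertion", Insertion = "Deletion",
           Untranslated = "Translated", Translated = "Untranslated",
           Ahead = "Behind", Behind = "Ahead", Edge = "Edge",
           Complex = "Complex")
  unname(map[x])
}
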
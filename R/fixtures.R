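# oriented transcript map of an oriented exon matrix
.layoutTxMap <- function(exm) {
  unlist(lapply(seq_len(nrow(exm)), function(i)
    seq.int(exm[i, 1L], exm[i, 2L])), use.names = FALSE)
}

#' Generate one synthetic fixture bundle
#'
#' Builds a deterministic two-isoform gene on a toy scaffold for one of the
#' event types in \code{\link{fixtureEventTypes}}. The exon/CDS geometry is
#' fixed by the layout; the genomic background is drawn from the seed, then
#' start (\code{ATG}) and stop (\code{TAA}) codons, layout-specific bases
#' and cosmetic \code{GT}/\code{AG} splice sites are planted, and remaining
#' free positions are patched so that neither open reading frame contains a
#' premature stop codon. Minus-strand bundles are exact mirror images of the
#' plus-strand bundle with the same seed: the layout is laid out in
#' transcript direction and reverse-complemented onto the scaffold, so all
#' transcript-level sequences are identical between the two strands.
#'
#' @param eventType one of \code{fixtureEventTypes()}.
#' @param strand \code{"+"} or \code{"-"}.
#' @param seed integer seed for the genomic background.
#' @return A \linkS4class{FixtureBundle}.
#' @export
#' @examples
#' b <- generateFixture("exon_skip", "+", 7)
#' truthTable(b)
generateFixture <- function(eventType, strand = "+", seed = 1L) {
  if (!eventType %in% names(.layoutFunctions))
    stop("unknown event type: ", eventType)
  stopifnot(strand %in% c("+", "-"))
  seed <- as.integer(seed)
  layout <- .layoutFunctions[[eventType]]()
  refMap <- .layoutTxMap(layout$refExons)
  altMap <- .layoutTxMap(layout$altExons)
  G <- max(layout$refExons, layout$altExons) + 20L

  planted <- rep(NA_character_, G)
  plant <- function(pos, base) {
    clash <- !is.na(planted[pos]) & planted[pos] != base
    if (any(clash))
      stop("layout motif conflict at oriented position(s) ",
           paste(pos[clash], collapse = ", "))
    planted[pos] <<- base
  }
  plantCodon <- function(map, txPos, codon) {
    stopifnot(txPos + 2L <= length(map))
    plant(map[seq.int(txPos, txPos + 2L)], strsplit(codon, "")[[1]])
  }
  for (side in list(list(map = refMap, cds = layout$refCds),
                    list(map = altMap, cds = layout$altCds))) {
    plantCodon(side$map, side$cds[1], "ATG")
    plantCodon(side$map, side$cds[2] + 1L, "TAA")
  }
  if (!is.null(layout$extra))
    plant(layout$extra$pos, layout$extra$base)

  exonic <- rep(FALSE, G)
  exonic[c(refMap, altMap)] <- TRUE
  for (exm in list(layout$refExons, layout$altExons)) {
    n <- nrow(exm)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) {
      don <- exm[i, 2L] + c(1L, 2L)
      acc <- exm[i + 1L, 1L] - c(2L, 1L)
      if (!any(exonic[don]) && all(is.na(planted[don])))
        plant(don, c("G", "T"))
      if (!any(exonic[acc]) && all(is.na(planted[acc])))
        plant(acc, c("A", "G"))
    }
  }

  genome <- withLocalSeed(seed,
    sample(c("A", "C", "G", "T"), G, replace = TRUE))
  constrained <- !is.na(planted)
  genome[constrained] <- planted[constrained]

  # remove premature stop codons from both reading frames; a "C" patch can
  # never itself create a stop codon
  stops <- c("TAA", "TAG", "TGA")
  for (pass in 1:2) {
    clean <- TRUE
    for (side in list(list(map = refMap, cds = layout$refCds),
                      list(map = altMap, cds = layout$altCds))) {
      codPos <- matrix(side$map[seq.int(side$cds[1], side$cds[2])],
                       ncol = 3L, byrow = TRUE)
      codStr <- paste0(genome[codPos[, 1L]], genome[codPos[, 2L]],
                       genome[codPos[, 3L]])
      for (b in which(codStr %in% stops)) {
        free <- which(!constrained[codPos[b, ]])
        if (length(free) == 0L)
          stop("cannot patch premature stop codon in ", eventType)
        p <- codPos[b, free[1L]]
        genome[p] <- "C"
        constrained[p] <- TRUE
        clean <- FALSE
      }
    }
    if (clean) break
  }

  orientedSeq <- paste(genome, collapse = "")
  if (strand == "+") {
    genomeSeq <- orientedSeq
    toGenomic <- function(exm) exm
  } else {
    genomeSeq <- revComp(orientedSeq)
    toGenomic <- function(exm) {
      m <- cbind(G - exm[, 2L] + 1L, G - exm[, 1L] + 1L)
      m[rev(seq_len(nrow(m))), , drop = FALSE]
    }
  }

  strandWord <- if (strand == "+") "fwd" else "rev"
  geneId <- sprintf("%s_%s_%d", eventType, strandWord, seed)
  chrom <- paste0("chr_", geneId)
  refId <- paste0(geneId, "_ref")
  altId <- paste0(geneId, "_alt")

  makeTx <- function(id, exm, cds, tag, map) {
    gm <- toGenomic(exm)
    new("TranscriptModel", transcriptId = id, geneId = geneId,
        chrom = chrom, strand = strand,
        exons = IRanges(gm[, 1L], gm[, 2L]),
        sequence = paste(genome[map], collapse = ""),
        cdsStart = cds[1], cdsEnd = cds[2], apprisTag = tag)
  }
  refTx <- makeTx(refId, layout$refExons, layout$refCds,
                  "appris_principal_1", refMap)
  altTx <- makeTx(altId, layout$altExons, layout$altCds,
                  "appris_alternative_2", altMap)
  refOrf <- enumerateCodons(refTx)
  altOrf <- enumerateCodons(altTx)
  for (orf in list(refOrf, altOrf))
    if (grepl("\\*", orf@protein) || substr(orf@protein, 1L, 1L) != "M")
      stop("fixture generation produced an invalid ORF for ", eventType)

  gene <- new("GeneModel", geneId = geneId, chrom = chrom, strand = strand,
              transcripts = stats::setNames(list(refTx, altTx),
                                            c(refId, altId)),
              orfs = stats::setNames(list(refOrf, altOrf),
                                     c(refId, altId)),
              referenceId = refId,
              skipped = data.frame(transcript_id = character(),
                                   reason = character(),
                                   stringsAsFactors = FALSE))

  truth <- layout$truth
  truth <- cbind(data.frame(eventType = rep(eventType, nrow(truth)),
                            strand = rep(strand, nrow(truth)),
                            stringsAsFactors = FALSE),
                 truth)

  new("FixtureBundle", eventType = eventType, strand = strand, seed = seed,
      geneId = geneId, chrom = chrom, gene = gene, genomeSeq = genomeSeq,
      gtf = makeGtfLines(gene),
      txFasta = stats::setNames(c(refTx@sequence, altTx@sequence),
                                c(refId, altId)),
      protFasta = stats::setNames(c(refOrf@protein, altOrf@protein),
                                  c(refId, altId)),
      truth = truth)
}

#' Serialise a gene model as GTF lines
#'
#' Writes one \code{exon} row per exon and one \code{CDS} row per coding
#' segment (stop codon excluded), with \code{gene_id}, \code{transcript_id}
#' and APPRIS \code{tag} attributes and correct CDS frame values.
#'
#' @param gene a \linkS4class{GeneModel} whose transcripts carry CDS spans.
#' @return Character vector of GTF lines.
#' @export
makeGtfLines <- function(gene) {
  lines <- character()
  for (tx in gene@transcripts) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; tag "%s";',
                     tx@geneId, tx@transcriptId, tx@apprisTag)
    ex <- tx@exons
    lines <- c(lines, sprintf("%s\tsynthetic\texon\t%d\t%d\t.\t%s\t.\t%s",
                              tx@chrom, start(ex), end(ex), tx@strand,
                              attrs))
    if (!is.na(tx@cdsStart)) {
      map <- txToGenomeMap(tx)
      pos <- map[seq.int(tx@cdsStart, tx@cdsEnd)]
      step <- if (tx@strand == "+") 1L else -1L
      brk <- which(diff(pos) != step)
      segFirst <- c(1L, brk + 1L)
      segLast <- c(brk, length(pos))
      coding <- 0L
      for (s in seq_along(segFirst)) {
        p <- pos[seq.int(segFirst[s], segLast[s])]
        frame <- (3L - coding %% 3L) %% 3L
        lines <- c(lines, sprintf(
          "%s\tsynthetic\tCDS\t%d\t%d\t.\t%s\t%d\t%s",
          tx@chrom, min(p), max(p), tx@strand, frame, attrs))
        coding <- coding + length(p)
      }
    }
  }
  lines
}

#' Generate the full fixture library
#'
#' Every event type is generated on both strands for the requested number of
#' replicates. The per-bundle seed is derived deterministically from the
#' library seed, the event type's index and the replicate number, and is
#' independent of strand, so each minus-strand bundle is the exact mirror of
#' its plus-strand sibling.
#'
#' @param seed integer library seed.
#' @param replicates replicates per event type and strand.
#' @return Named list of \linkS4class{FixtureBundle} (names are gene
#'   identifiers).
#' @export
generateFixtureLibrary <- function(seed = 42L, replicates = 5L) {
  types <- fixtureEventTypes()
  bundles <- list()
  for (ti in seq_along(types)) {
    for (r in seq_len(replicates)) {
      bseed <- (as.numeric(seed) * 1009 + (ti - 1) * 131 + r) %% 2147483647
      for (strand in c("+", "-")) {
        b <- generateFixture(types[ti], strand, as.integer(bseed))
        bundles[[b@geneId]] <- b
      }
    }
  }
  bundles
}

#' Write fixture bundles to disk
#'
#' \code{writeFixtureBundle} writes one bundle; \code{writeFixtureLibrary}
#' concatenates many bundles (each on its own scaffold) into a single set of
#' files: \code{genome.fa}, \code{annotation.gtf}, \code{transcripts.fa},
#' \code{proteins.fa} and \code{truth.tsv}.
#'
#' @param bundle a \linkS4class{FixtureBundle}.
#' @param bundles list of bundles.
#' @param dir output directory (created if absent).
#' @return Invisibly, the named vector of written file paths.
#' @export
writeFixtureBundle <- function(bundle, dir) {
  writeFixtureLibrary(list(bundle), dir)
}

#' @rdname writeFixtureBundle
#' @export
writeFixtureLibrary <- function(bundles, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fasta <- function(seqs) {
    unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]])))
  }
  genome <- unlist(lapply(bundles, function(b)
    c(paste0(">", b@chrom), b@genomeSeq)))
  gtf <- unlist(lapply(bundles, function(b) b@gtf))
  txf <- unlist(lapply(bundles, function(b) fasta(b@txFasta)))
  prf <- unlist(lapply(bundles, function(b) fasta(b@protFasta)))
  truth <- do.call(rbind, c(lapply(bundles, function(b) {
    tr <- b@truth
    if (nrow(tr) == 0L) return(NULL)
    cbind(data.frame(geneId = b@geneId, stringsAsFactors = FALSE), tr)
  }), list(make.row.names = FALSE)))
  paths <- c(genome = file.path(dir, "genome.fa"),
             gtf = file.path(dir, "annotation.gtf"),
             transcripts = file.path(dir, "transcripts.fa"),
             proteins = file.path(dir, "proteins.fa"),
             truth = file.path(dir, "truth.tsv"))
  writeLines(genome, paths["genome"])
  writeLines(gtf, paths["gtf"])
  writeLines(txf, paths["transcripts"])
  writeLines(prf, paths["proteins"])
  if (is.null(truth))
    truth <- data.frame(geneId = character(), stringsAsFactors = FALSE)
  utils::write.table(truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(paths)
}

#' Align and classify the isoform pair of a fixture bundle
#'
#' @param bundle a \linkS4class{FixtureBundle}.
#' @return An \linkS4class{IsoformAlignment} of the bundle's reference and
#'   alternative isoforms.
#' @export
fixtureAlignment <- function(bundle) {
  gene <- bundle@gene
  altId <- setdiff(names(gene@orfs), gene@referenceId)
  alignIsoformPair(gene, gene@referenceId, altId)
}

#' Brute-force codon-pairing oracle
#'
#' An independent, quadratic re-derivation of the codon pairing and
#' categorisation used to cross-check \code{\link{pairCodons}}: all
#' reference/alternative codon combinations are scored by explicit set
#' overlap of their genomic positions, eligibility and category are decided
#' directly from the definitions, and the greedy assignment is replayed.
#'
#' @param refOrf,altOrf \linkS4class{ORFModel} of the pair.
#' @param refTx,altTx the corresponding \linkS4class{TranscriptModel}.
#' @return data.frame with columns \code{refIdx}, \code{altIdx} and
#'   \code{category}, ordered like the output of \code{\link{pairCodons}}.
#' @export
bruteForceCodonOracle <- function(refOrf, altOrf, refTx, altTx) {
  strand <- refTx@strand
  refP <- refOrf@codonPositions
  altP <- altOrf@codonPositions
  nR <- nrow(refP); nA <- nrow(altP)

  adjacent <- function(split) switch(split,
    "contiguous" = integer(0), "1|2" = c(1L, 2L), "2|1" = c(2L, 3L),
    "1|1|1" = 1:3)

  cand <- list()
  for (i in seq_len(nR)) for (j in seq_len(nA)) {
    shared <- intersect(refP[i, ], altP[j, ])
    k <- length(shared)
    if (k == 0L) next
    eligible <- k >= 2L
    if (!eligible && k == 1L) {
      rs <- refOrf@split[i]; as <- altOrf@split[j]
      if (rs != "contiguous" || as != "contiguous") {
        okR <- rs == "contiguous" ||
          all(match(shared, refP[i, ]) %in% adjacent(rs))
        okA <- as == "contiguous" ||
          all(match(shared, altP[j, ]) %in% adjacent(as))
        eligible <- okR && okA
      }
    }
    if (eligible)
      cand[[length(cand) + 1L]] <- c(i = i, j = j, k = k)
  }

  usedR <- logical(nR); usedA <- logical(nA)
  chosen <- list()
  if (length(cand)) {
    cm <- do.call(rbind, cand)
    ord <- order(-cm[, "k"], orient(refP[cm[, "i"], 1L], strand),
                 cm[, "i"], cm[, "j"])
    cm <- cm[ord, , drop = FALSE]
    for (r in seq_len(nrow(cm))) {
      i <- cm[r, "i"]; j <- cm[r, "j"]
      if (usedR[i] || usedA[j]) next
      usedR[i] <- TRUE; usedA[j] <- TRUE
      shared <- intersect(refP[i, ], altP[j, ])
      category <- if (length(shared) == 3L) "Match"
      else if (refOrf@split[i] != "contiguous" ||
               altOrf@split[j] != "contiguous") {
        if (identical(match(shared, refP[i, ]), match(shared, altP[j, ])))
          "Edge" else "Complex"
      } else if (orient(altP[j, 1L], strand) > orient(refP[i, 1L], strand))
        "Ahead" else "Behind"
      chosen[[length(chosen) + 1L]] <- data.frame(
        refIdx = i, altIdx = j, category = category,
        key = orient(refP[i, 1L], strand), tie = 0L,
        stringsAsFactors = FALSE)
    }
  }

  refExonPos <- txToGenomeMap(refTx)
  altExonPos <- txToGenomeMap(altTx)
  unpaired <- function(pos, exonPos, cdsPos, labels) {
    present <- sum(pos %in% exonPos)
    if (present <= 1L) return(labels[1])
    if (sum(pos %in% exonPos & !pos %in% cdsPos) >= 2L) labels[2]
    else labels[1]
  }
  for (i in which(!usedR))
    chosen[[length(chosen) + 1L]] <- data.frame(
      refIdx = i, altIdx = NA_integer_,
      category = unpaired(refP[i, ], altExonPos, as.vector(altP),
                          c("Deletion", "Untranslated")),
      key = orient(refP[i, 1L], strand), tie = 0L,
      stringsAsFactors = FALSE)
  for (j in which(!usedA))
    chosen[[length(chosen) + 1L]] <- data.frame(
      refIdx = NA_integer_, altIdx = j,
      category = unpaired(altP[j, ], refExonPos, as.vector(refP),
                          c("Insertion", "Translated")),
      key = orient(altP[j, 1L], strand), tie = 1L,
      stringsAsFactors = FALSE)

  out <- do.call(rbind, chosen)
  idx2 <- ifelse(is.na(out$refIdx), out$altIdx, out$refIdx)
  out <- out[order(out$key, out$tie, idx2), c("refIdx", "altIdx", "category")]
  rownames(out) <- NULL
  out
}

#' Compare classifier calls against a bundle's planted truth
#'
#' @param bundle a \linkS4class{FixtureBundle}.
#' @param calls data.frame from \code{\link{annotateAlignment}} for the
#'   bundle's isoform pair.
#' @return list with logical \code{ok} and a character vector
#'   \code{mismatches} describing any disagreement.
#' @export
checkFixtureCalls <- function(bundle, calls) {
  truth <- bundle@truth
  mism <- character()
  if (nrow(truth) == 0L) {
    if (nrow(calls) != 0L)
      mism <- sprintf("expected identical proteins but found %d altered region(s)",
                      nrow(calls))
    return(list(ok = length(mism) == 0L, mismatches = mism))
  }
  if (nrow(calls) != nrow(truth)) {
    mism <- sprintf("expected %d altered region(s), found %d",
                    nrow(truth), nrow(calls))
    return(list(ok = FALSE, mismatches = mism))
  }
  fields <- setdiff(names(truth), c("eventType", "strand"))
  for (i in seq_len(nrow(truth))) {
    for (f in fields) {
      want <- truth[[f]][i]
      if (is.na(want)) next
      got <- calls[[f]][i]
      if (is.na(got) || got != want)
        mism <- c(mism, sprintf("%s: %s expected %s, got %s",
                                bundle@geneId, f, as.character(want),
                                as.character(got)))
    }
  }
  list(ok = length(mism) == 0L, mismatches = mism)
}
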
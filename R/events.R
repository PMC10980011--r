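# canonical zero-row altered-region call table
emptyCallsFrame <- function() {
  data.frame(geneId = character(), refId = character(),
             altId = character(), positionClass = character(),
             category = character(), refStart = integer(),
             refEnd = integer(), altStart = integer(),
             altEnd = integer(), refLen = integer(),
             altLen = integer(), nTerminalClass = character(),
             nTerminalDriver = character(), hybridExon = logical(),
             spliceComplexity = character(), mechanisms = character(),
             multiExonSkip = logical(), ragged5 = logical(),
             ragged3 = logical(), ragged = logical(),
             snapback = logical(), cTerminalMode = character(),
             cTerminalSubtype = character(), stringsAsFactors = FALSE)
}

# genomic positions touched by the codon pairs of one altered protein region
regionFootprint <- function(pairs, pairFirst, pairLast) {
  sl <- seq.int(pairFirst, pairLast)
  p <- c(pairs$refP1[sl], pairs$refP2[sl], pairs$refP3[sl],
         pairs$altP1[sl], pairs$altP2[sl], pairs$altP3[sl])
  unique(p[!is.na(p)])
}

# rows of the t-block table (non-Match only) overlapping a genomic footprint
overlappingTBlocks <- function(tblocks, footprint) {
  cand <- tblocks[tblocks$category != "Match", , drop = FALSE]
  if (nrow(cand) == 0L) return(cand)
  hit <- vapply(seq_len(nrow(cand)), function(i)
    any(footprint >= cand$gstart[i] & footprint <= cand$gend[i]), logical(1))
  cand[hit, , drop = FALSE]
}

# are all three positions of a start codon exonic in transcript `tx`?
startCodonPresence <- function(startPositions, tx) {
  all(startPositions %in% txToGenomeMap(tx))
}

#' Classify an N-terminal altered region by its start-codon relationship
#'
#' The two isoforms' start codons are ordered along the genome in transcript
#' direction into an upstream (U) and a downstream (D) start. Each start is
#' \emph{shared} when all three of its genomic positions are exonic in the
#' other isoform's transcript. The four classes are: \code{MXS} (mutually
#' exclusive starts, neither shared), \code{SDS} (shared downstream start
#' only), \code{SUS} (shared upstream start only) and \code{MSS} (mutually
#' shared starts). For MXS and SDS the upstream start is driven by an
#' alternative transcription start site (\code{altTSS}) when it lies 5' of
#' the other transcript's first position, and by 5'-UTR splicing
#' (\code{utr5_splicing}) otherwise; MSS implies co-translational start
#' selection. SDS regions are additionally tested for a hybrid first exon:
#' the downstream-starting transcript's first exon ending at an internal
#' splice donor of the other isoform.
#'
#' @param aln an \linkS4class{IsoformAlignment}.
#' @return list with elements \code{class}, \code{driver} and
#'   \code{hybridExon}.
#' @export
classifyNTerminal <- function(aln) {
  strand <- aln@refTx@strand
  refS <- aln@refOrf@startPositions
  altS <- aln@altOrf@startPositions
  refFirst <- orient(refS[1L], strand)
  altFirst <- orient(altS[1L], strand)
  if (refFirst == altFirst)
    return(list(class = "MSS", driver = "cotranslational", hybridExon = FALSE))
  refIsU <- refFirst < altFirst
  uPos <- if (refIsU) refS else altS
  dPos <- if (refIsU) altS else refS
  uTx <- if (refIsU) aln@refTx else aln@altTx
  dTx <- if (refIsU) aln@altTx else aln@refTx
  sharedU <- startCodonPresence(uPos, dTx)
  sharedD <- startCodonPresence(dPos, uTx)
  cls <- if (!sharedU && !sharedD) "MXS"
  else if (!sharedU && sharedD) "SDS"
  else if (sharedU && !sharedD) "SUS"
  else "MSS"
  driver <- switch(cls,
                   MXS = , SDS = {
                     dMap <- txToGenomeMap(dTx)
                     if (orient(uPos[1L], strand) < orient(dMap[1L], strand))
                       "altTSS" else "utr5_splicing"
                   },
                   MSS = "cotranslational",
                   SUS = "unset")
  hybrid <- FALSE
  if (cls == "SDS") {
    dEx <- exonsTxOrder(dTx)
    uEx <- exonsTxOrder(uTx)
    oeD1 <- orientedEnd(start(dEx)[1L], end(dEx)[1L], strand)
    if (length(uEx) > 1L) {
      oeU <- orientedEnd(start(uEx), end(uEx), strand)[-1L]
      hybrid <- oeD1 %in% oeU
    }
  }
  list(class = cls, driver = driver, hybridExon = hybrid)
}

#' Classify an internal altered region by its splice-event composition
#'
#' The transcript-level (non-Match) t-blocks overlapping the genomic
#' footprint of the region's codon pairs are collected. One contributing
#' t-block makes a \code{single} event, several a \code{compound} event; a
#' compound event whose contributing blocks are all cassette-exon deletions
#' is flagged as a multi-exon skip. The region is \emph{ragged} when its
#' first or last codon pair straddles a splice junction (category
#' \code{Edge} or \code{Complex}), and a \emph{snapback} frameshift when it
#' is an internal substitution containing frameshifted codon pairs that
#' returns to matched frame downstream, driven by at least two splice
#' differences.
#'
#' @param aln an \linkS4class{IsoformAlignment}.
#' @param pblock one row of \code{pBlocks(aln)} with \code{positionClass}
#'   \code{"internal"}.
#' @return list with elements \code{complexity} (\code{"single"} or
#'   \code{"compound"}), \code{mechanisms} (comma-separated, transcript
#'   order), \code{multiExonSkip}, \code{ragged5}, \code{ragged3},
#'   \code{ragged} and \code{snapback}.
#' @export
classifyInternal <- function(aln, pblock) {
  pairs <- aln@pairs
  fp <- regionFootprint(pairs, pblock$pairFirst, pblock$pairLast)
  tb <- overlappingTBlocks(aln@tblocks, fp)
  n <- nrow(tb)
  complexity <- if (n >= 2L) "compound" else "single"
  mechanisms <- paste(tb$mechanism, collapse = ",")
  multiExonSkip <- n >= 2L && all(tb$category == "Deletion") &&
    all(tb$mechanism == "alt_exon")
  catRun <- pairs$category[seq.int(pblock$pairFirst, pblock$pairLast)]
  ragged5 <- catRun[1L] %in% c("Edge", "Complex")
  ragged3 <- catRun[length(catRun)] %in% c("Edge", "Complex")
  snapback <- pblock$category == "Substitution" &&
    any(catRun %in% .FRAMESHIFT_CATEGORIES) && n >= 2L
  list(complexity = complexity, mechanisms = mechanisms,
       multiExonSkip = multiExonSkip, ragged5 = ragged5, ragged3 = ragged3,
       ragged = ragged5 || ragged3, snapback = snapback)
}

#' Classify a C-terminal altered region
#'
#' The region is \code{frameshift_driven} when its first codon pair is
#' frameshifted (category \code{Ahead}, \code{Behind} or \code{Complex}),
#' i.e. the two isoforms diverge by reading shared sequence in different
#' frames. Otherwise it is \code{splice_driven} and sub-typed by where the
#' alternative isoform's stop codon falls relative to the reference exon
#' structure (see \code{\link{classifySpliceSubtype}}).
#'
#' @param aln an \linkS4class{IsoformAlignment}.
#' @param pblock one row of \code{pBlocks(aln)} with \code{positionClass}
#'   \code{"c_terminal"}.
#' @return list with elements \code{mode} and \code{subtype}
#'   (\code{NA} when frameshift-driven).
#' @export
classifyCTerminal <- function(aln, pblock) {
  firstCat <- aln@pairs$category[pblock$pairFirst]
  if (firstCat %in% .FRAMESHIFT_CATEGORIES)
    return(list(mode = "frameshift_driven", subtype = NA_character_))
  list(mode = "splice_driven",
       subtype = classifySpliceSubtype(aln@refTx, aln@altTx, aln@altOrf))
}

#' Sub-type a splice-driven C-terminal region
#'
#' The alternative isoform's stop codon is located in its exon structure and
#' compared against the reference exons, testing in priority order:
#' \describe{
#'   \item{\code{EXIT}}{the stop-containing exon starts at a reference exon
#'     boundary but extends past that exon's donor, and the stop lies in the
#'     extension (exon extension into intronic sequence, including retained
#'     introns).}
#'   \item{\code{COSTE}}{the alternative splices out of the reference's last
#'     exon through an internal donor and terminates in a downstream exon
#'     absent from the reference (continuation of the ORF past the
#'     reference's terminal exon).}
#'   \item{\code{ALE_in_UTR}}{the stop-containing exon overlaps exonic
#'     reference 3'-UTR sequence (an alternative last exon inside the
#'     annotated UTR).}
#'   \item{\code{poison_exon}}{the stop-containing exon overlaps no
#'     reference exon and lies within the reference gene span.}
#'   \item{\code{other_ATE}}{any other alternative terminal exon
#'     configuration.}
#' }
#'
#' @param refTx,altTx the two transcript models.
#' @param altOrf the alternative isoform's \linkS4class{ORFModel}.
#' @return character scalar, one of the five subtype labels.
#' @export
classifySpliceSubtype <- function(refTx, altTx, altOrf) {
  strand <- refTx@strand
  stopPos <- altOrf@stopPositions
  if (any(is.na(stopPos)))
    stopPos <- altOrf@codonPositions[nrow(altOrf@codonPositions), ]
  oStopLast <- stopPos[which.max(orient(stopPos, strand))]

  altEx <- exonsTxOrder(altTx)
  sIdx <- which(start(altEx) <= oStopLast & end(altEx) >= oStopLast)[1L]
  osS <- orientedStart(start(altEx)[sIdx], end(altEx)[sIdx], strand)
  oeS <- orientedEnd(start(altEx)[sIdx], end(altEx)[sIdx], strand)
  oStop <- orient(oStopLast, strand)

  refEx <- exonsTxOrder(refTx)
  osR <- orientedStart(start(refEx), end(refEx), strand)
  oeR <- orientedEnd(start(refEx), end(refEx), strand)

  if (any(osR == osS & oeS > oeR & oStop > oeR))
    return("EXIT")

  overlapsRef <- any(osS <= oeR & oeS >= osR)
  lastR <- length(osR)
  if (!overlapsRef && sIdx > 1L) {
    osA <- orientedStart(start(altEx), end(altEx), strand)
    oeA <- orientedEnd(start(altEx), end(altEx), strand)
    coste <- any(seq_along(altEx) < sIdx &
                   osA == osR[lastR] & oeA < oeR[lastR])
    if (coste) return("COSTE")
  }

  if (!is.na(refTx@cdsEnd)) {
    refMap <- txToGenomeMap(refTx)
    utrFrom <- refTx@cdsEnd + 4L
    if (utrFrom <= length(refMap)) {
      utr <- refMap[utrFrom:length(refMap)]
      if (any(utr >= start(altEx)[sIdx] & utr <= end(altEx)[sIdx]))
        return("ALE_in_UTR")
    }
  }

  if (!overlapsRef && osS >= min(osR) && oeS <= max(oeR))
    return("poison_exon")

  "other_ATE"
}

#' Annotate every altered protein region of an alignment
#'
#' Each non-Match p-block is attributed to its upstream mechanism: N-terminal
#' regions via the start-codon relationship
#' (\code{\link{classifyNTerminal}}), internal regions via their splice-event
#' composition (\code{\link{classifyInternal}}) and C-terminal regions via
#' frame and stop-codon placement (\code{\link{classifyCTerminal}}).
#' Full-length regions carry the start-codon classification.
#'
#' @param aln an \linkS4class{IsoformAlignment}.
#' @return data.frame with one row per altered region: identifiers, the
#'   p-block fields, and the classification columns
#'   \code{nTerminalClass}, \code{nTerminalDriver}, \code{hybridExon},
#'   \code{spliceComplexity}, \code{mechanisms}, \code{multiExonSkip},
#'   \code{ragged5}, \code{ragged3}, \code{ragged}, \code{snapback},
#'   \code{cTerminalMode} and \code{cTerminalSubtype}. Zero rows when the
#'   proteins are identical.
#' @export
annotateAlignment <- function(aln) {
  pbl <- aln@pblocks
  alt <- pbl[pbl$category != "Match", , drop = FALSE]
  if (nrow(alt) == 0L) return(emptyCallsFrame())
  rows <- lapply(seq_len(nrow(alt)), function(i) {
    pb <- alt[i, ]
    row <- data.frame(geneId = aln@geneId, refId = aln@refId,
                      altId = aln@altId, positionClass = pb$positionClass,
                      category = pb$category, refStart = pb$refStart,
                      refEnd = pb$refEnd, altStart = pb$altStart,
                      altEnd = pb$altEnd, refLen = pb$refLen,
                      altLen = pb$altLen,
                      nTerminalClass = NA_character_,
                      nTerminalDriver = NA_character_, hybridExon = NA,
                      spliceComplexity = NA_character_,
                      mechanisms = NA_character_, multiExonSkip = NA,
                      ragged5 = NA, ragged3 = NA, ragged = NA,
                      snapback = NA, cTerminalMode = NA_character_,
                      cTerminalSubtype = NA_character_,
                      stringsAsFactors = FALSE)
    if (pb$positionClass %in% c("n_terminal", "full_length")) {
      nt <- classifyNTerminal(aln)
      row$nTerminalClass <- nt$class
      row$nTerminalDriver <- nt$driver
      row$hybridExon <- nt$hybridExon
    } else if (pb$positionClass == "internal") {
      ie <- classifyInternal(aln, pb)
      row$spliceComplexity <- ie$complexity
      row$mechanisms <- ie$mechanisms
      row$multiExonSkip <- ie$multiExonSkip
      row$ragged5 <- ie$ragged5
      row$ragged3 <- ie$ragged3
      row$ragged <- ie$ragged
      row$snapback <- ie$snapback
    } else if (pb$positionClass == "c_terminal") {
      ct <- classifyCTerminal(aln, pb)
      row$cTerminalMode <- ct$mode
      row$cTerminalSubtype <- ct$subtype
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize a table of altered-region calls
#'
#' @param calls data.frame as returned by \code{\link{annotateAlignment}}
#'   (possibly row-bound over many isoform pairs).
#' @return list with counts by position class and p-block category, the
#'   fractions of insertions / deletions / substitutions, the median altered
#'   region length (longer side, in residues), and counts of each N-terminal
#'   class and C-terminal mode/subtype.
#' @export
summarizeEventCalls <- function(calls) {
  n <- nrow(calls)
  lens <- pmax(ifelse(is.na(calls$refLen), 0L, calls$refLen),
               ifelse(is.na(calls$altLen), 0L, calls$altLen))
  tab <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) integer(0) else table(v)
  }
  list(nRegions = n,
       byPositionClass = tab(calls$positionClass),
       byCategory = tab(calls$category),
       fracInsertion = if (n) mean(calls$category == "Insertion") else NA_real_,
       fracDeletion = if (n) mean(calls$category == "Deletion") else NA_real_,
       fracSubstitution = if (n) mean(calls$category == "Substitution")
       else NA_real_,
       medianAlteredLength = if (n) stats::median(lens) else NA_real_,
       nTerminalClasses = tab(calls$nTerminalClass),
       cTerminalModes = tab(calls$cTerminalMode),
       cTerminalSubtypes = tab(calls$cTerminalSubtype))
}
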
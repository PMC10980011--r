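# positions of a split codon that flank its junction(s); used by the
# pairing rule for 1-of-3 overlaps
junctionAdjacent <- function(split) {
  switch(split,
         "contiguous" = c(FALSE, FALSE, FALSE),
         "1|2" = c(TRUE, TRUE, FALSE),
         "2|1" = c(FALSE, TRUE, TRUE),
         "1|1|1" = c(TRUE, TRUE, TRUE))
}

#' Pair the codons of two ORFs by genomic overlap
#'
#' Codons of the reference and alternative ORF are paired when they share at
#' least two genomic positions, or when at least one of them is split across
#' a junction, they share one position and that position flanks the junction
#' in every split member. Each codon joins at most one pair; candidate pairs
#' are taken greedily by decreasing overlap, ties resolved in favour of the
#' transcript-5'-most pair. Remaining codons are linked to placeholders and
#' sub-classified by where their nucleotides fall in the other isoform:
#' mostly absent from its exons (\code{Deletion}/\code{Insertion}) or mostly
#' present but untranslated there (\code{Untranslated}/\code{Translated}).
#' Paired codons are categorised per the nine-category scheme (see
#' \code{\link{cblockCategories}}).
#'
#' @param refOrf,altOrf \linkS4class{ORFModel} of the pair.
#' @param refTx,altTx the corresponding \linkS4class{TranscriptModel}.
#' @return data.frame of codon pairs in transcript order: \code{refIdx},
#'   \code{altIdx} (1-based residue indices, \code{NA} for a placeholder
#'   side), \code{overlap} (0-3), \code{category}, \code{refAA},
#'   \code{altAA}, \code{aaMatch}, \code{refSplit}, \code{altSplit}, and the
#'   genomic positions of each side (\code{refP1..refP3}, \code{altP1..altP3}).
#' @export
pairCodons <- function(refOrf, altOrf, refTx, altTx) {
  strand <- refTx@strand
  refP <- refOrf@codonPositions
  altP <- altOrf@codonPositions
  nR <- nrow(refP); nA <- nrow(altP)
  refAA <- strsplit(refOrf@protein, "")[[1]]
  altAA <- strsplit(altOrf@protein, "")[[1]]

  # candidate pairs via position lookup (each genomic position belongs to at
  # most one codon of a given ORF)
  refVec <- as.vector(t(refP))
  refOwner <- rep.int(seq_len(nR), rep.int(3L, nR))
  hits <- list()
  for (j in seq_len(nA)) {
    own <- refOwner[match(altP[j, ], refVec)]
    own <- own[!is.na(own)]
    if (length(own) == 0L) next
    tab <- table(own)
    hits[[length(hits) + 1L]] <- data.frame(
      i = as.integer(names(tab)), j = j, overlap = as.integer(tab))
  }
  cand <- if (length(hits)) do.call(rbind, hits) else
    data.frame(i = integer(), j = integer(), overlap = integer())

  # pairing eligibility
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]; ov <- cand$overlap[k]
    if (ov >= 2L) { keep[k] <- TRUE; next }
    rs <- refOrf@split[i]; as <- altOrf@split[j]
    if (rs == "contiguous" && as == "contiguous") next
    shared <- intersect(refP[i, ], altP[j, ])
    ok <- TRUE
    if (rs != "contiguous")
      ok <- ok && all(junctionAdjacent(rs)[match(shared, refP[i, ])])
    if (as != "contiguous")
      ok <- ok && all(junctionAdjacent(as)[match(shared, altP[j, ])])
    keep[k] <- ok
  }
  cand <- cand[keep, , drop = FALSE]

  # greedy maximal-overlap matching, ties to the 5'-most candidate
  refUsed <- logical(nR); altUsed <- logical(nA)
  pairIJ <- NULL
  if (nrow(cand)) {
    key <- orient(refP[cand$i, 1L], strand)
    o <- order(-cand$overlap, key, cand$i, cand$j)
    cand <- cand[o, , drop = FALSE]
    sel <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      if (refUsed[cand$i[k]] || altUsed[cand$j[k]]) next
      refUsed[cand$i[k]] <- TRUE
      altUsed[cand$j[k]] <- TRUE
      sel[k] <- TRUE
    }
    pairIJ <- cand[sel, , drop = FALSE]
  }

  altExonPos <- txToGenomeMap(altTx)
  refExonPos <- txToGenomeMap(refTx)
  altCdsPos <- as.vector(altP)
  refCdsPos <- as.vector(refP)

  rows <- list()
  addRow <- function(i, j, overlap, category, aaMatch) {
    rows[[length(rows) + 1L]] <<- data.frame(
      refIdx = i, altIdx = j, overlap = overlap, category = category,
      refAA = if (is.na(i)) NA_character_ else refAA[i],
      altAA = if (is.na(j)) NA_character_ else altAA[j],
      aaMatch = aaMatch,
      refSplit = if (is.na(i)) NA_character_ else refOrf@split[i],
      altSplit = if (is.na(j)) NA_character_ else altOrf@split[j],
      refP1 = if (is.na(i)) NA_integer_ else refP[i, 1L],
      refP2 = if (is.na(i)) NA_integer_ else refP[i, 2L],
      refP3 = if (is.na(i)) NA_integer_ else refP[i, 3L],
      altP1 = if (is.na(j)) NA_integer_ else altP[j, 1L],
      altP2 = if (is.na(j)) NA_integer_ else altP[j, 2L],
      altP3 = if (is.na(j)) NA_integer_ else altP[j, 3L],
      stringsAsFactors = FALSE)
  }

  if (!is.null(pairIJ)) for (k in seq_len(nrow(pairIJ))) {
    i <- pairIJ$i[k]; j <- pairIJ$j[k]
    cat <- categorizeCodonPair(refP[i, ], altP[j, ],
                               refOrf@split[i], altOrf@split[j], strand)
    addRow(i, j, pairIJ$overlap[k], cat, refAA[i] == altAA[j])
  }
  for (i in which(!refUsed)) {
    cat <- classifyUnpaired(refP[i, ], altExonPos, altCdsPos,
                            c("Deletion", "Untranslated"))
    addRow(i, NA_integer_, 0L, cat, NA)
  }
  for (j in which(!altUsed)) {
    cat <- classifyUnpaired(altP[j, ], refExonPos, refCdsPos,
                            c("Insertion", "Translated"))
    addRow(NA_integer_, j, 0L, cat, NA)
  }
  out <- do.call(rbind, rows)
  key <- orient(ifelse(is.na(out$refIdx), out$altP1, out$refP1), strand)
  tie <- ifelse(is.na(out$refIdx), 1L, 0L)
  idx2 <- ifelse(is.na(out$refIdx), out$altIdx, out$refIdx)
  out <- out[order(key, tie, idx2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Table-1 category of one paired codon
categorizeCodonPair <- function(refPos, altPos, refSplit, altSplit, strand) {
  shared <- intersect(refPos, altPos)
  k <- length(shared)
  if (k == 3L) return("Match")
  if (refSplit != "contiguous" || altSplit != "contiguous") {
    offR <- match(shared, refPos)
    offA <- match(shared, altPos)
    return(if (all(offR == offA)) "Edge" else "Complex")
  }
  # both contiguous, 2-of-3 overlap: frameshifted by one position
  if (orient(altPos[1L], strand) > orient(refPos[1L], strand)) "Ahead"
  else "Behind"
}

# unpaired codon sub-classification by majority of its three positions
classifyUnpaired <- function(pos, otherExonPos, otherCdsPos, labels) {
  inExon <- pos %in% otherExonPos
  if (sum(inExon) <= 1L) return(labels[1])
  outsideCds <- inExon & !(pos %in% otherCdsPos)
  if (sum(outsideCds) >= 2L) labels[2] else labels[1]
}

#' Merge codon pairs into c-blocks
#'
#' Maximal runs of codon pairs sharing a category are compressed into
#' c-blocks. Every codon of each ORF appears in exactly one block, so the
#' residue ranges of the blocks partition both proteins.
#'
#' @param pairs codon-pair table from \code{\link{pairCodons}}.
#' @return data.frame with one row per c-block: \code{category}, residue
#'   ranges \code{refStart}/\code{refEnd} and \code{altStart}/\code{altEnd}
#'   (\code{NA} for an absent side), pair-row range \code{pairFirst} /
#'   \code{pairLast}, and \code{nPairs}.
#' @export
mergeCodonBlocks <- function(pairs) {
  if (nrow(pairs) == 0L)
    return(data.frame(category = character(), refStart = integer(),
                      refEnd = integer(), altStart = integer(),
                      altEnd = integer(), pairFirst = integer(),
                      pairLast = integer(), nPairs = integer(),
                      stringsAsFactors = FALSE))
  r <- rle(pairs$category)
  endI <- cumsum(r$lengths)
  startI <- endI - r$lengths + 1L
  rng <- function(v) if (all(is.na(v))) c(NA_integer_, NA_integer_) else
    range(v, na.rm = TRUE)
  do.call(rbind, lapply(seq_along(r$values), function(b) {
    sl <- seq.int(startI[b], endI[b])
    rr <- rng(pairs$refIdx[sl]); ar <- rng(pairs$altIdx[sl])
    data.frame(category = r$values[b],
               refStart = rr[1], refEnd = rr[2],
               altStart = ar[1], altEnd = ar[2],
               pairFirst = startI[b], pairLast = endI[b],
               nPairs = r$lengths[b], stringsAsFactors = FALSE)
  }))
}
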
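#' Align two isoforms at the transcript layer (t-blocks)
#'
#' The union of both isoforms' exonic genomic positions is partitioned into
#' maximal runs present in both (\code{Match}), only in the reference
#' (\code{Deletion}) or only in the alternative (\code{Insertion}), ordered
#' 5'->3' in transcript direction. Match blocks whose pieces are adjacent in
#' both transcripts (a shared splice junction) are merged, so a self-pair
#' yields a single Match block whose genomic intervals are the exons.
#' Each non-Match block is annotated with the mechanism that produced it:
#' alternative transcription start / termination site, retained intron,
#' alternative donor, alternative acceptor or alternative (cassette) exon.
#'
#' @param refTx,altTx \linkS4class{TranscriptModel} of the same gene and
#'   strand.
#' @return data.frame with one row per t-block: \code{category},
#'   \code{gstart}/\code{gend} (genomic hull), \code{intervals}
#'   (comma-separated \code{start-end} pieces), transcript-coordinate ranges
#'   of each side (\code{NA} for the absent side), \code{mechanism} and
#'   \code{note}.
#' @export
alignTranscripts <- function(refTx, altTx) {
  stopifnot(refTx@strand == altTx@strand, refTx@chrom == altTx@chrom)
  strand <- refTx@strand
  refR <- reduce(refTx@exons)
  altR <- reduce(altTx@exons)
  d <- disjoin(c(refR, altR))
  inRef <- IRanges::overlapsAny(d, refR)
  inAlt <- IRanges::overlapsAny(d, altR)
  cat <- ifelse(inRef & inAlt, "Match", ifelse(inRef, "Deletion", "Insertion"))
  if (!any(cat == "Match"))
    stop("disjoint isoforms")
  ord <- if (strand == "+") order(start(d)) else order(-end(d))
  d <- d[ord]; cat <- cat[ord]
  refMap <- txToGenomeMap(refTx)
  altMap <- txToGenomeMap(altTx)

  piece <- lapply(seq_along(d), function(i) {
    s <- start(d)[i]; e <- end(d)[i]
    rtr <- if (cat[i] != "Insertion")
      genomicToTxRange(refTx, s, e, refMap) else c(NA_integer_, NA_integer_)
    atr <- if (cat[i] != "Deletion")
      genomicToTxRange(altTx, s, e, altMap) else c(NA_integer_, NA_integer_)
    list(cat = cat[i], iv = cbind(s, e),
         ref = rtr, alt = atr)
  })

  # merge Match pieces across junctions shared by both isoforms
  blocks <- list()
  for (p in piece) {
    n <- length(blocks)
    if (n > 0L) {
      last <- blocks[[n]]
      if (last$cat == "Match" && p$cat == "Match" &&
          last$ref[2] + 1L == p$ref[1] && last$alt[2] + 1L == p$alt[1]) {
        last$iv <- rbind(last$iv, p$iv)
        last$ref[2] <- p$ref[2]
        last$alt[2] <- p$alt[2]
        blocks[[n]] <- last
        next
      }
    }
    blocks[[n + 1L]] <- p
  }

  matchRanges <- d[cat == "Match"]
  out <- do.call(rbind, lapply(blocks, function(b) {
    data.frame(
      category = b$cat,
      gstart = min(b$iv[, 1]), gend = max(b$iv[, 2]),
      nIntervals = nrow(b$iv),
      intervals = paste(sprintf("%d-%d", b$iv[, 1], b$iv[, 2]),
                        collapse = ","),
      refTxStart = b$ref[1], refTxEnd = b$ref[2],
      altTxStart = b$alt[1], altTxEnd = b$alt[2],
      stringsAsFactors = FALSE)
  }))
  out$mechanism <- "unset"
  out$note <- ""
  for (i in which(out$category != "Match")) {
    mech <- classifyTBlockMechanism(out[i, ], refTx, altTx, matchRanges)
    out$mechanism[i] <- mech$mechanism
    out$note[i] <- mech$note
  }
  rownames(out) <- NULL
  out
}

#' Attribute a non-Match t-block to its transcript-level mechanism
#'
#' A block holding an isoform's transcript 5' end that lies upstream of the
#' other isoform's span or of the first shared exonic position is an
#' alternative transcription start site (\code{altTSS}); the mirror case at
#' the 3' end is \code{altTTS}. Otherwise the block is a splice difference:
#' \code{retained_intron} when it exactly fills the gap between two
#' consecutive exons of the other isoform, \code{alt_donor} /
#' \code{alt_acceptor} when it abuts shared exonic sequence only at its
#' transcript-5' / transcript-3' edge, and \code{alt_exon} when it touches
#' shared sequence on neither side (a cassette exon). Blocks not matching any
#' simple pattern are labelled \code{alt_exon} with note \code{"complex"}.
#'
#' @param block one row of the t-block table (category not \code{Match}).
#' @param refTx,altTx the two transcript models.
#' @param matchRanges \link[IRanges]{IRanges} of genomic positions exonic in
#'   both isoforms.
#' @return list with elements \code{mechanism} and \code{note}.
#' @export
classifyTBlockMechanism <- function(block, refTx, altTx, matchRanges) {
  stopifnot(block$category != "Match")
  strand <- refTx@strand
  carrier <- if (block$category == "Deletion") refTx else altTx
  other <- if (block$category == "Deletion") altTx else refTx
  carMap <- txToGenomeMap(carrier)
  othMap <- txToGenomeMap(other)
  os <- orientedStart(block$gstart, block$gend, strand)
  oe <- orientedEnd(block$gstart, block$gend, strand)
  inBlock <- function(p) p >= block$gstart & p <= block$gend
  mOS <- orientedStart(start(matchRanges), end(matchRanges), strand)
  mOE <- orientedEnd(start(matchRanges), end(matchRanges), strand)
  firstShared <- min(mOS)
  lastShared <- max(mOE)

  if (inBlock(carMap[1]) &&
      (os < orient(othMap[1], strand) || oe < firstShared))
    return(list(mechanism = "altTSS", note = ""))
  if (inBlock(carMap[length(carMap)]) &&
      (oe > orient(othMap[length(othMap)], strand) || os > lastShared))
    return(list(mechanism = "altTTS", note = ""))

  othR <- reduce(other@exons)
  if (length(othR) > 1L) {
    gapS <- end(othR)[-length(othR)] + 1L
    gapE <- start(othR)[-1L] - 1L
    if (any(gapS == block$gstart & gapE == block$gend))
      return(list(mechanism = "retained_intron", note = ""))
  }
  matched <- unlist(lapply(seq_along(matchRanges), function(i)
    seq.int(start(matchRanges)[i], end(matchRanges)[i])), use.names = FALSE)
  before5 <- if (strand == "+") block$gstart - 1L else block$gend + 1L
  after3 <- if (strand == "+") block$gend + 1L else block$gstart - 1L
  abut5 <- before5 %in% matched
  abut3 <- after3 %in% matched
  if (abut5 && !abut3) return(list(mechanism = "alt_donor", note = ""))
  if (!abut5 && abut3) return(list(mechanism = "alt_acceptor", note = ""))
  carR <- reduce(carrier@exons)
  fullExon <- any(start(carR) >= block$gstart & end(carR) <= block$gend)
  if (!abut5 && !abut3 && fullExon)
    return(list(mechanism = "alt_exon", note = ""))
  list(mechanism = "alt_exon", note = "complex")
}
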
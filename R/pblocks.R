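#' Project codon pairs onto the protein layer (p-blocks)
#'
#' A codon pair counts as a matched residue when its category is
#' \code{Match}, or \code{Edge} with identical amino acids on both sides.
#' Maximal runs of matched / unmatched pairs become p-blocks: unmatched runs
#' are \code{Deletion} (reference residues only), \code{Insertion}
#' (alternative residues only) or \code{Substitution} (both present), and
#' each is placed as \code{n_terminal}, \code{internal}, \code{c_terminal}
#' or \code{full_length} depending on whether the run touches the first
#' and/or last codon pair of the alignment.
#'
#' @param pairs codon-pair table from \code{\link{pairCodons}}.
#' @return data.frame with one row per p-block: \code{category}, residue
#'   ranges \code{refStart}/\code{refEnd} and \code{altStart}/\code{altEnd}
#'   (\code{NA} for an absent side), altered-length columns \code{refLen} /
#'   \code{altLen}, \code{positionClass} (\code{"none"} for Match blocks)
#'   and the pair-row range \code{pairFirst}/\code{pairLast}.
#' @export
projectProteinBlocks <- function(pairs) {
  n <- nrow(pairs)
  empty <- data.frame(category = character(), refStart = integer(),
                      refEnd = integer(), altStart = integer(),
                      altEnd = integer(), refLen = integer(),
                      altLen = integer(), positionClass = character(),
                      pairFirst = integer(), pairLast = integer(),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  matched <- pairs$category == "Match" |
    (pairs$category == "Edge" & !is.na(pairs$aaMatch) & pairs$aaMatch)
  r <- rle(matched)
  endI <- cumsum(r$lengths)
  startI <- endI - r$lengths + 1L
  rng <- function(v) if (all(is.na(v))) c(NA_integer_, NA_integer_) else
    range(v, na.rm = TRUE)
  out <- do.call(rbind, lapply(seq_along(r$values), function(b) {
    sl <- seq.int(startI[b], endI[b])
    rr <- rng(pairs$refIdx[sl]); ar <- rng(pairs$altIdx[sl])
    refLen <- sum(!is.na(pairs$refIdx[sl]))
    altLen <- sum(!is.na(pairs$altIdx[sl]))
    if (r$values[b]) {
      category <- "Match"; posClass <- "none"
    } else {
      category <- if (refLen > 0L && altLen > 0L) "Substitution"
      else if (refLen > 0L) "Deletion" else "Insertion"
      atStart <- startI[b] == 1L
      atEnd <- endI[b] == n
      posClass <- if (atStart && atEnd) "full_length"
      else if (atStart) "n_terminal"
      else if (atEnd) "c_terminal" else "internal"
    }
    data.frame(category = category,
               refStart = rr[1], refEnd = rr[2],
               altStart = ar[1], altEnd = ar[2],
               refLen = refLen, altLen = altLen,
               positionClass = posClass,
               pairFirst = startI[b], pairLast = endI[b],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Align one reference/alternative isoform pair across all three layers
#'
#' Runs the transcript-layer alignment (\code{\link{alignTranscripts}}),
#' codon pairing (\code{\link{pairCodons}}), c-block merging
#' (\code{\link{mergeCodonBlocks}}) and the protein projection
#' (\code{\link{projectProteinBlocks}}) for one pair of coding isoforms of a
#' gene.
#'
#' @param gene a \linkS4class{GeneModel}.
#' @param refId,altId transcript identifiers; both must carry an ORF in
#'   \code{gene}. \code{refId} defaults to the gene's selected reference.
#' @return an \linkS4class{IsoformAlignment}.
#' @export
alignIsoformPair <- function(gene, refId = referenceId(gene), altId) {
  if (is.na(refId))
    stop("gene ", gene@geneId, " has no reference isoform")
  for (id in c(refId, altId))
    if (!id %in% names(gene@orfs))
      stop("no ORF for transcript ", id)
  refTx <- gene@transcripts[[refId]]
  altTx <- gene@transcripts[[altId]]
  tbl <- alignTranscripts(refTx, altTx)
  pairs <- pairCodons(gene@orfs[[refId]], gene@orfs[[altId]], refTx, altTx)
  cbl <- mergeCodonBlocks(pairs)
  pbl <- projectProteinBlocks(pairs)
  new("IsoformAlignment", geneId = gene@geneId, refId = refId,
      altId = altId, refTx = refTx, altTx = altTx,
      refOrf = gene@orfs[[refId]], altOrf = gene@orfs[[altId]],
      tblocks = tbl, pairs = pairs, cblocks = cbl, pblocks = pbl)
}
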
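#' @import methods
#' @importFrom S4Vectors isSorted
#' @importFrom IRanges IRanges start end width reduce disjoin gaps
#' @importFrom GenomicRanges GRanges
NULL

#' Codon-pair categories
#'
#' The nine categories a reference/alternative codon pair can take, based on
#' genomic overlap, translation status, reading frame and split-across-junction
#' topology. Paired categories: \code{Match} (3-of-3 overlap, same residue),
#' \code{Ahead}/\code{Behind} (2-of-3 overlap, both contiguous, alternative
#' codon one position downstream/upstream), \code{Edge} (split codons
#' overlapping at a junction with the frame preserved) and \code{Complex}
#' (split codons overlapping at a junction in a shifted frame). Unpaired
#' categories link a real codon to a placeholder: \code{Deletion} /
#' \code{Insertion} (codon missing from the other isoform's transcript) and
#' \code{Untranslated} / \code{Translated} (nucleotides present in the other
#' transcript but not translated there).
#'
#' @return Character vector of the nine category names.
#' @export
#' @examples
#' cblockCategories()
cblockCategories <- function() {
  c("Match", "Deletion", "Insertion", "Untranslated", "Translated",
    "Ahead", "Behind", "Edge", "Complex")
}

.FRAMESHIFT_CATEGORIES <- c("Ahead", "Behind", "Complex")

#' @rdname cblockCategories
#' @details \code{pblockCategories()} returns the four protein-block
#'   categories; \code{tblockCategories()} the three transcript-block
#'   categories.
#' @export
pblockCategories <- function() c("Match", "Deletion", "Insertion", "Substitution")

#' @rdname cblockCategories
#' @export
tblockCategories <- function() c("Match", "Deletion", "Insertion")

#' TranscriptModel: one transcript isoform anchored on the genome
#'
#' Exon structure (genomic, 1-based closed intervals, ascending), spliced
#' sequence, the transcript-relative CDS span (stop codon excluded), and the
#' APPRIS tag used for reference selection.
#'
#' @slot transcriptId,geneId,chrom,strand,apprisTag single character values.
#' @slot exons an \link[IRanges]{IRanges} of genomic exon intervals.
#' @slot sequence spliced transcript sequence (5'->3'), or \code{NA}.
#' @slot cdsStart,cdsEnd 1-based transcript coordinates of the CDS
#'   (stop codon excluded), or \code{NA} for non-coding transcripts.
#' @export
setClass("TranscriptModel",
  representation(
    transcriptId = "character",
    geneId       = "character",
    chrom        = "character",
    strand       = "character",
    exons        = "IRanges",
    sequence     = "character",
    cdsStart     = "integer",
    cdsEnd       = "integer",
    apprisTag    = "character"
  )
)

setValidity("TranscriptModel", function(object) {
  msg <- character()
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  ex <- object@exons
  if (length(ex) == 0L)
    msg <- c(msg, "transcript has no exons")
  if (length(ex) > 1L) {
    if (is.unsorted(start(ex)))
      msg <- c(msg, "exons must be sorted by genomic start")
    if (any(start(ex)[-1L] <= end(ex)[-length(ex)]))
      msg <- c(msg, "exons must be non-overlapping")
  }
  if (!is.na(object@sequence) &&
      nchar(object@sequence) != sum(width(ex)))
    msg <- c(msg, "sequence length must equal the sum of exon widths")
  if (!is.na(object@cdsStart)) {
    len <- object@cdsEnd - object@cdsStart + 1L
    if (is.na(object@cdsEnd) || len < 3L)
      msg <- c(msg, "invalid CDS span")
    if (object@cdsEnd > sum(width(ex)))
      msg <- c(msg, "CDS span exceeds transcript length")
  }
  if (length(msg)) msg else TRUE
})

#' ORFModel: the codon-resolved open reading frame of one transcript
#'
#' Each codon (one residue) carries the genomic positions of its three
#' nucleotides, in transcript 5'->3' order (genomically decreasing on the
#' minus strand), plus its split-across-junction topology.
#'
#' @slot transcriptId character.
#' @slot codonPositions integer matrix with one row per codon and three
#'   columns (genomic positions in transcript order).
#' @slot split character vector: \code{"contiguous"}, \code{"1|2"},
#'   \code{"2|1"} (nucleotides before|after the junction) or \code{"1|1|1"}
#'   (codon spanning two junctions).
#' @slot protein amino-acid sequence (no terminal stop symbol).
#' @slot startPositions,stopPositions genomic position triples of the start
#'   codon and of the stop codon (the three nucleotides after the CDS);
#'   \code{stopPositions} is all-\code{NA} when the transcript ends at the CDS.
#' @export
setClass("ORFModel",
  representation(
    transcriptId   = "character",
    codonPositions = "matrix",
    split          = "character",
    protein        = "character",
    startPositions = "integer",
    stopPositions  = "integer"
  )
)

setValidity("ORFModel", function(object) {
  msg <- character()
  if (ncol(object@codonPositions) != 3L)
    msg <- c(msg, "codonPositions must have three columns")
  if (nrow(object@codonPositions) != nchar(object@protein))
    msg <- c(msg, "number of codons must equal protein length")
  if (length(object@split) != nrow(object@codonPositions))
    msg <- c(msg, "split vector must match the number of codons")
  if (length(msg)) msg else TRUE
})

#' GeneModel: all isoforms of one gene on a single scaffold
#'
#' @slot geneId,chrom,strand single character values.
#' @slot transcripts named list of \linkS4class{TranscriptModel}.
#' @slot orfs named list of validated \linkS4class{ORFModel} (coding
#'   transcripts that passed assembly checks).
#' @slot referenceId identifier of the APPRIS-selected reference isoform,
#'   or \code{NA} before selection / for genes excluded from pairing.
#' @slot skipped data.frame (transcript_id, reason) of rejected transcripts.
#' @export
setClass("GeneModel",
  representation(
    geneId      = "character",
    chrom       = "character",
    strand      = "character",
    transcripts = "list",
    orfs        = "list",
    referenceId = "character",
    skipped     = "data.frame"
  )
)

setValidity("GeneModel", function(object) {
  msg <- character()
  for (tx in object@transcripts) {
    if (tx@geneId != object@geneId)
      msg <- c(msg, "all transcripts must share the gene identifier")
    if (tx@strand != object@strand)
      msg <- c(msg, "all transcripts must share the gene strand")
    if (tx@chrom != object@chrom)
      msg <- c(msg, "all transcripts must lie on the gene scaffold")
  }
  if (!is.na(object@referenceId) &&
      !object@referenceId %in% names(object@transcripts))
    msg <- c(msg, "referenceId must name one of the transcripts")
  if (length(msg)) msg else TRUE
})

#' IsoformAlignment: the three-layer alignment of one isoform pair
#'
#' Holds the two gene-model sides plus the transcript-layer blocks
#' (t-blocks), the per-codon pair table, the codon-layer blocks (c-blocks)
#' and the protein-layer blocks (p-blocks).
#'
#' @slot geneId,refId,altId identifiers.
#' @slot refTx,altTx \linkS4class{TranscriptModel} of each side.
#' @slot refOrf,altOrf \linkS4class{ORFModel} of each side.
#' @slot tblocks,pairs,cblocks,pblocks data.frames; see \code{\link{tBlocks}},
#'   \code{\link{codonPairs}}, \code{\link{cBlocks}}, \code{\link{pBlocks}}.
#' @export
setClass("IsoformAlignment",
  representation(
    geneId  = "character",
    refId   = "character",
    altId   = "character",
    refTx   = "TranscriptModel",
    altTx   = "TranscriptModel",
    refOrf  = "ORFModel",
    altOrf  = "ORFModel",
    tblocks = "data.frame",
    pairs   = "data.frame",
    cblocks = "data.frame",
    pblocks = "data.frame"
  )
)

#' FixtureBundle: a synthetic gene with ground-truth labels
#'
#' A toy single-scaffold genome segment, a two-isoform gene model built on
#' it, the corresponding GTF/FASTA text, and the planted truth labels for
#' the event the bundle encodes.
#'
#' @slot eventType,strand,geneId,chrom single character values.
#' @slot seed integer seed the bundle was generated from.
#' @slot gene assembled \linkS4class{GeneModel} with ORFs and reference.
#' @slot genomeSeq genomic (plus-strand) sequence of the scaffold.
#' @slot gtf character vector of GTF lines.
#' @slot txFasta,protFasta named character vectors of sequences.
#' @slot truth one-row data.frame of expected calls.
#' @export
setClass("FixtureBundle",
  representation(
    eventType = "character",
    strand    = "character",
    seed      = "integer",
    geneId    = "character",
    chrom     = "character",
    gene      = "GeneModel",
    genomeSeq = "character",
    gtf       = "character",
    txFasta   = "character",
    protFasta = "character",
    truth     = "data.frame"
  )
)
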
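#' Accessors for gene models and alignments
#'
#' @param x a \linkS4class{GeneModel}, \linkS4class{TranscriptModel},
#'   \linkS4class{ORFModel}, \linkS4class{IsoformAlignment} or
#'   \linkS4class{FixtureBundle}.
#' @return The requested component: \code{transcripts} and \code{orfModels}
#'   return named lists; \code{referenceId} the reference transcript
#'   identifier; \code{exonRanges} an \link[IRanges]{IRanges};
#'   \code{codonPositions} an integer matrix; \code{proteinSequence} a
#'   character; the block accessors data.frames; \code{truthTable} and
#'   \code{skipReport} data.frames; \code{geneModel} a
#'   \linkS4class{GeneModel}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("transcripts", function(x) standardGeneric("transcripts"))
#' @rdname accessors
#' @export
setGeneric("orfModels", function(x) standardGeneric("orfModels"))
#' @rdname accessors
#' @export
setGeneric("referenceId", function(x) standardGeneric("referenceId"))
#' @rdname accessors
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))
#' @rdname accessors
#' @export
setGeneric("codonPositions", function(x) standardGeneric("codonPositions"))
#' @rdname accessors
#' @export
setGeneric("proteinSequence", function(x) standardGeneric("proteinSequence"))
#' @rdname accessors
#' @export
setGeneric("tBlocks", function(x) standardGeneric("tBlocks"))
#' @rdname accessors
#' @export
setGeneric("cBlocks", function(x) standardGeneric("cBlocks"))
#' @rdname accessors
#' @export
setGeneric("pBlocks", function(x) standardGeneric("pBlocks"))
#' @rdname accessors
#' @export
setGeneric("codonPairs", function(x) standardGeneric("codonPairs"))
#' @rdname accessors
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))
#' @rdname accessors
#' @export
setGeneric("geneModel", function(x) standardGeneric("geneModel"))
#' @rdname accessors
#' @export
setGeneric("skipReport", function(x) standardGeneric("skipReport"))

setMethod("transcripts", "GeneModel", function(x) x@transcripts)
setMethod("orfModels", "GeneModel", function(x) x@orfs)
setMethod("referenceId", "GeneModel", function(x) x@referenceId)
setMethod("skipReport", "GeneModel", function(x) x@skipped)
setMethod("exonRanges", "TranscriptModel", function(x) x@exons)
setMethod("codonPositions", "ORFModel", function(x) x@codonPositions)
setMethod("proteinSequence", "ORFModel", function(x) x@protein)
setMethod("tBlocks", "IsoformAlignment", function(x) x@tblocks)
setMethod("cBlocks", "IsoformAlignment", function(x) x@cblocks)
setMethod("pBlocks", "IsoformAlignment", function(x) x@pblocks)
setMethod("codonPairs", "IsoformAlignment", function(x) x@pairs)
setMethod("geneModel", "FixtureBundle", function(x) x@gene)
setMethod("truthTable", "FixtureBundle", function(x) x@truth)

setMethod("show", "TranscriptModel", function(object) {
  cds <- if (is.na(object@cdsStart)) "non-coding" else
    sprintf("CDS %d-%d", object@cdsStart, object@cdsEnd)
  cat(sprintf("TranscriptModel %s (%s) %s:%s, %d exon(s), %s, APPRIS tag %s\n",
              object@transcriptId, object@geneId, object@chrom,
              object@strand, length(object@exons), cds, object@apprisTag))
})

setMethod("show", "ORFModel", function(object) {
  cat(sprintf("ORFModel %s: %d codons, %d split across junctions\n",
              object@transcriptId, nrow(object@codonPositions),
              sum(object@split != "contiguous")))
})

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel %s (%s:%s): %d transcript(s), %d ORF(s), reference %s\n",
              object@geneId, object@chrom, object@strand,
              length(object@transcripts), length(object@orfs),
              object@referenceId))
  if (nrow(object@skipped))
    cat(sprintf("  %d transcript(s) skipped during assembly\n",
                nrow(object@skipped)))
})

setMethod("show", "IsoformAlignment", function(object) {
  cat(sprintf("IsoformAlignment %s: %s (reference) vs %s (alternative)\n",
              object@geneId, object@refId, object@altId))
  cat(sprintf("  t-blocks: %d  c-blocks: %d  p-blocks: %d\n",
              nrow(object@tblocks), nrow(object@cblocks),
              nrow(object@pblocks)))
  alt <- object@pblocks[object@pblocks$category != "Match", , drop = FALSE]
  if (nrow(alt))
    cat(sprintf("  altered protein regions: %s\n",
                paste(sprintf("%s(%s)", alt$category, alt$positionClass),
                      collapse = ", ")))
  else cat("  proteins are identical\n")
})

setMethod("show", "FixtureBundle", function(object) {
  cat(sprintf("FixtureBundle %s [%s strand, seed %d]: gene %s on %s (%d bp)\n",
              object@eventType, object@strand, object@seed, object@geneId,
              object@chrom, nchar(object@genomeSeq)))
})
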
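#' Load annotation and sequences into assembled gene models
#'
#' Reads the GTF and the transcript / protein FASTA files, validates every
#' coding transcript (see \code{\link{assembleGeneModels}}) and selects each
#' gene's reference isoform by APPRIS tag.
#'
#' @param gtfPath path to the GTF annotation.
#' @param txFastaPath,protFastaPath paths to the transcript and protein
#'   FASTA files, keyed by transcript identifier.
#' @param stripVersions strip \code{.N} version suffixes from identifiers.
#' @return Named list of \linkS4class{GeneModel}, sorted by gene identifier,
#'   with \code{referenceId} set (\code{NA} for genes excluded from
#'   pairing).
#' @export
loadIsoformData <- function(gtfPath, txFastaPath, protFastaPath,
                            stripVersions = FALSE) {
  genes <- readGeneModels(gtfPath, stripVersions = stripVersions)
  txSeqs <- readFastaSequences(txFastaPath, stripVersions = stripVersions)
  protSeqs <- readFastaSequences(protFastaPath,
                                 stripVersions = stripVersions)
  genes <- assembleGeneModels(genes, txSeqs, protSeqs)
  for (g in names(genes))
    genes[[g]]@referenceId <- selectReference(genes[[g]])
  genes[order(names(genes))]
}

#' Align every reference/alternative pair of a gene set
#'
#' @param genes named list of \linkS4class{GeneModel} from
#'   \code{\link{loadIsoformData}}.
#' @return Named list of \linkS4class{IsoformAlignment}; names are
#'   \code{"<gene>:<ref>|<alt>"}. Genes without a reference contribute no
#'   pairs.
#' @export
alignAllPairs <- function(genes) {
  alns <- list()
  for (g in names(genes)) {
    gene <- genes[[g]]
    pairs <- isoformPairs(gene)
    for (i in seq_len(nrow(pairs))) {
      aln <- alignIsoformPair(gene, pairs$ref[i], pairs$alt[i])
      alns[[sprintf("%s:%s|%s", g, pairs$ref[i], pairs$alt[i])]] <- aln
    }
  }
  alns
}

#' Classify the altered regions of many alignments
#'
#' @param alns list of \linkS4class{IsoformAlignment}.
#' @return data.frame of altered-region calls (row-bound
#'   \code{\link{annotateAlignment}} output over all pairs).
#' @export
classifyAlignments <- function(alns) {
  if (length(alns) == 0L) return(emptyCallsFrame())
  do.call(rbind, c(lapply(alns, annotateAlignment),
                   list(make.row.names = FALSE)))
}

#' Combined block table across many alignments
#'
#' @param alns list of \linkS4class{IsoformAlignment}.
#' @param layer \code{"t"}, \code{"c"} or \code{"p"}.
#' @return data.frame with \code{geneId}, \code{refId}, \code{altId}
#'   prepended to the per-alignment block columns.
#' @export
blockTable <- function(alns, layer = c("t", "c", "p")) {
  layer <- match.arg(layer)
  get <- switch(layer, t = tBlocks, c = cBlocks, p = pBlocks)
  if (length(alns) == 0L) return(NULL)
  do.call(rbind, c(lapply(alns, function(a) {
    b <- get(a)
    if (nrow(b) == 0L) return(NULL)
    cbind(data.frame(geneId = a@geneId, refId = a@refId, altId = a@altId,
                     stringsAsFactors = FALSE), b)
  }), list(make.row.names = FALSE)))
}

#' Write a tab-separated results table
#'
#' @param x data.frame.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeResultTable <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' Run the full pipeline: load, align, classify, report
#'
#' @inheritParams loadIsoformData
#' @param outDir output directory; receives \code{tblocks.tsv},
#'   \code{cblocks.tsv}, \code{pblocks.tsv} and \code{calls.tsv}.
#' @return Invisibly, a list with the gene models, alignments, calls and the
#'   \code{\link{summarizeEventCalls}} summary.
#' @export
runPipeline <- function(gtfPath, txFastaPath, protFastaPath, outDir,
                        stripVersions = FALSE) {
  genes <- loadIsoformData(gtfPath, txFastaPath, protFastaPath,
                           stripVersions = stripVersions)
  alns <- alignAllPairs(genes)
  calls <- classifyAlignments(alns)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  for (layer in c("t", "c", "p")) {
    tab <- blockTable(alns, layer)
    if (is.null(tab)) tab <- data.frame()
    writeResultTable(tab, file.path(outDir, paste0(layer, "blocks.tsv")))
  }
  writeResultTable(calls, file.path(outDir, "calls.tsv"))
  invisible(list(genes = genes, alignments = alns, calls = calls,
                 summary = summarizeEventCalls(calls)))
}
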
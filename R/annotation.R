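#' Read a FASTA file into a named character vector
#'
#' Record identifiers are normalised by taking the first whitespace-delimited
#' token of the header line. Optionally, a trailing version suffix
#' (\code{".N"}) is stripped, for matching annotation sets whose FASTA and GTF
#' identifiers disagree on versions.
#'
#' @param path path to a FASTA file (plain text or gzip).
#' @param stripVersions logical; drop a trailing \code{.<digits>} from each
#'   identifier (default \code{FALSE}: exact matching).
#' @return Named character vector of upper-case sequences.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">tx1 gene=G", "ATGAAATGA"), fa)
#' readFastaSequences(fa)
readFastaSequences <- function(path, stripVersions = FALSE) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (stripVersions)
    ids <- sub("\\.[0-9]+$", "", ids)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate FASTA identifier(s): ", paste(dup, collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  seqs
}

# principal1..principal5 -> 1..5, alternative1/2 -> 6/7, none/other -> 99
apprisRank <- function(tag) {
  vapply(tag, function(t) {
    mm <- regmatches(t, regexpr("appris_(principal|alternative)_[0-9]", t))
    if (length(mm) == 0L || mm == "") return(99L)
    level <- as.integer(sub(".*_", "", mm))
    if (grepl("principal", mm)) level else 5L + level
  }, integer(1), USE.NAMES = FALSE)
}

#' Parse gene models from a GTF annotation
#'
#' Reads \code{exon} and \code{CDS} features (via
#' \code{\link[rtracklayer]{import}}), groups them into one
#' \linkS4class{GeneModel} per \code{gene_id}, projects CDS features to
#' transcript coordinates, and records the APPRIS tag of each transcript
#' (\code{"none"} when absent). Transcripts whose CDS is not contained in
#' their exon union, that have CDS but no exons, or that span multiple
#' scaffolds or strands are rejected and listed in the gene's skip report.
#'
#' @param path path to a GTF file (1-based closed coordinates; attribute
#'   key-value pairs with \code{gene_id} and \code{transcript_id}).
#' @param stripVersions logical; strip version suffixes from transcript and
#'   gene identifiers.
#' @return Named list of \linkS4class{GeneModel} (sequences not yet attached;
#'   see \code{\link{assembleGeneModels}}).
#' @export
readGeneModels <- function(path, stripVersions = FALSE) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type %in% c("exon", "CDS")]
  if (length(gr) == 0L)
    stop("no exon or CDS features found in ", path)
  txid <- as.character(gr$transcript_id)
  gnid <- as.character(gr$gene_id)
  if (stripVersions) {
    txid <- sub("\\.[0-9]+$", "", txid)
    gnid <- sub("\\.[0-9]+$", "", gnid)
  }
  tag <- rep("none", length(gr))
  if ("tag" %in% names(S4Vectors::mcols(gr))) {
    rawTag <- gr$tag
    if (is(rawTag, "CharacterList") || is.list(rawTag)) {
      tag <- vapply(rawTag, function(v) {
        hit <- grep("appris", v, value = TRUE)
        if (length(hit)) hit[1] else "none"
      }, character(1))
    } else {
      tag <- ifelse(!is.na(rawTag) & grepl("appris", rawTag),
                    as.character(rawTag), "none")
    }
  }
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = start(gr), end = end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    gene = gnid, tx = txid, tag = tag,
    stringsAsFactors = FALSE
  )
  genes <- list()
  for (g in unique(df$gene)) {
    sub <- df[df$gene == g, , drop = FALSE]
    skipped <- data.frame(transcript_id = character(), reason = character(),
                          stringsAsFactors = FALSE)
    txs <- list()
    for (t in unique(sub$tx)) {
      rows <- sub[sub$tx == t, , drop = FALSE]
      exRows <- rows[rows$type == "exon", , drop = FALSE]
      cdsRows <- rows[rows$type == "CDS", , drop = FALSE]
      if (nrow(exRows) == 0L) {
        skipped <- rbind(skipped, data.frame(
          transcript_id = t, reason = "CDS without exons"))
        next
      }
      if (length(unique(rows$chrom)) > 1L ||
          length(unique(rows$strand)) > 1L) {
        skipped <- rbind(skipped, data.frame(
          transcript_id = t, reason = "multi-scaffold or mixed-strand"))
        next
      }
      strand <- exRows$strand[1]
      if (!strand %in% c("+", "-")) {
        skipped <- rbind(skipped, data.frame(
          transcript_id = t, reason = "unstranded feature"))
        next
      }
      o <- order(exRows$start)
      exons <- IRanges(exRows$start[o], exRows$end[o])
      apTag <- rows$tag[rows$tag != "none"]
      apTag <- if (length(apTag)) apTag[1] else "none"
      tx <- new("TranscriptModel",
                transcriptId = t, geneId = g,
                chrom = exRows$chrom[1], strand = strand,
                exons = exons, sequence = NA_character_,
                cdsStart = NA_integer_, cdsEnd = NA_integer_,
                apprisTag = apTag)
      if (nrow(cdsRows)) {
        span <- tryCatch(projectCdsToTx(tx, cdsRows), error = function(e) e)
        if (inherits(span, "error")) {
          skipped <- rbind(skipped, data.frame(
            transcript_id = t, reason = conditionMessage(span)))
          next
        }
        tx@cdsStart <- span[1]
        tx@cdsEnd <- span[2]
      }
      txs[[t]] <- tx
    }
    if (length(txs) == 0L && nrow(skipped) == 0L) next
    chrom <- if (length(txs)) txs[[1]]@chrom else sub$chrom[1]
    strand <- if (length(txs)) txs[[1]]@strand else sub$strand[1]
    genes[[g]] <- new("GeneModel", geneId = g, chrom = chrom,
                      strand = strand, transcripts = txs,
                      orfs = list(), referenceId = NA_character_,
                      skipped = skipped)
  }
  genes
}

# project genomic CDS rows onto transcript coordinates; the CDS must map to a
# single contiguous run of transcript positions
projectCdsToTx <- function(tx, cdsRows) {
  txmap <- txToGenomeMap(tx)
  o <- order(cdsRows$start)
  pos <- unlist(lapply(o, function(i)
    seq.int(cdsRows$start[i], cdsRows$end[i])), use.names = FALSE)
  if (tx@strand == "-") pos <- rev(pos)
  idx <- match(pos, txmap)
  if (anyNA(idx))
    stop("CDS not contained in exons")
  if (length(idx) > 1L && any(diff(idx) != 1L))
    stop("CDS does not map to contiguous transcript positions")
  c(idx[1], idx[length(idx)])
}

#' Enumerate the codons of a coding transcript
#'
#' Maps each codon of the CDS through the exon structure to its three genomic
#' positions (reported in transcript order, hence genomically decreasing on
#' the minus strand), records its split-across-junction topology, and
#' translates the CDS with the standard genetic code.
#'
#' @param tx a \linkS4class{TranscriptModel} with sequence and CDS span.
#' @return An \linkS4class{ORFModel}.
#' @export
enumerateCodons <- function(tx) {
  if (is.na(tx@cdsStart))
    stop("transcript ", tx@transcriptId, " has no CDS")
  if (is.na(tx@sequence))
    stop("transcript ", tx@transcriptId, " has no sequence")
  len <- tx@cdsEnd - tx@cdsStart + 1L
  if (len %% 3L != 0L)
    stop("incomplete CDS")
  txmap <- txToGenomeMap(tx)
  txpos <- seq.int(tx@cdsStart, tx@cdsEnd)
  gpos <- txmap[txpos]
  posMat <- matrix(gpos, ncol = 3L, byrow = TRUE)
  step <- if (tx@strand == "+") 1L else -1L
  brk1 <- posMat[, 2L] != posMat[, 1L] + step
  brk2 <- posMat[, 3L] != posMat[, 2L] + step
  split <- rep("contiguous", nrow(posMat))
  split[brk1 & !brk2] <- "1|2"
  split[!brk1 & brk2] <- "2|1"
  split[brk1 & brk2] <- "1|1|1"
  cdsSeq <- substr(tx@sequence, tx@cdsStart, tx@cdsEnd)
  protein <- translateDNA(cdsSeq)
  L <- nchar(tx@sequence)
  stopPos <- if (tx@cdsEnd + 3L <= L)
    txmap[seq.int(tx@cdsEnd + 1L, tx@cdsEnd + 3L)]
  else rep(NA_integer_, 3L)
  new("ORFModel", transcriptId = tx@transcriptId,
      codonPositions = posMat, split = split, protein = protein,
      startPositions = posMat[1L, ], stopPositions = as.integer(stopPos))
}

#' Attach sequences and build validated ORFs
#'
#' For every coding transcript, attaches its spliced sequence, translates the
#' CDS and checks the result against the protein FASTA record (a trailing
#' stop symbol in the record is stripped). Transcripts failing any check are
#' excluded and counted in the gene's skip report with one of the reasons
#' \code{"missing transcript sequence"}, \code{"missing protein sequence"},
#' \code{"sequence length mismatch"}, \code{"incomplete CDS"} or
#' \code{"translation mismatch"}.
#'
#' @param genes list of \linkS4class{GeneModel} from
#'   \code{\link{readGeneModels}}.
#' @param txSeqs,protSeqs named character vectors from
#'   \code{\link{readFastaSequences}}.
#' @return The gene list with \code{orfs} populated and skip reports updated.
#' @export
assembleGeneModels <- function(genes, txSeqs, protSeqs) {
  for (g in names(genes)) {
    gene <- genes[[g]]
    for (t in names(gene@transcripts)) {
      tx <- gene@transcripts[[t]]
      if (is.na(tx@cdsStart)) next
      reason <- NULL
      if (!t %in% names(txSeqs)) reason <- "missing transcript sequence"
      else if (!t %in% names(protSeqs)) reason <- "missing protein sequence"
      if (is.null(reason)) {
        seq <- txSeqs[[t]]
        if (nchar(seq) != sum(width(tx@exons)))
          reason <- "sequence length mismatch"
      }
      if (is.null(reason) &&
          (tx@cdsEnd - tx@cdsStart + 1L) %% 3L != 0L)
        reason <- "incomplete CDS"
      if (is.null(reason)) {
        tx@sequence <- txSeqs[[t]]
        orf <- enumerateCodons(tx)
        want <- sub("\\*$", "", protSeqs[[t]])
        if (orf@protein != want || grepl("\\*", orf@protein))
          reason <- "translation mismatch"
        else {
          gene@transcripts[[t]] <- tx
          gene@orfs[[t]] <- orf
        }
      }
      if (!is.null(reason))
        gene@skipped <- rbind(gene@skipped, data.frame(
          transcript_id = t, reason = reason, stringsAsFactors = FALSE))
    }
    genes[[g]] <- gene
  }
  genes
}

#' Select the reference isoform of a gene
#'
#' Transcripts with validated ORFs are rank-ordered by APPRIS tag
#' (\code{appris_principal_1} best, down through \code{appris_alternative_2};
#' untagged transcripts rank last). Ties are broken by longest CDS, then by
#' lexicographically smallest transcript identifier. Genes whose best tag is
#' \code{"none"} are excluded from pairing and get \code{NA}.
#'
#' @param gene a \linkS4class{GeneModel} with assembled ORFs.
#' @return The reference transcript identifier, or \code{NA} when the gene
#'   has fewer than two ORFs or no APPRIS-tagged isoform.
#' @export
selectReference <- function(gene) {
  ids <- names(gene@orfs)
  if (length(ids) < 2L) return(NA_character_)
  tags <- vapply(ids, function(t) gene@transcripts[[t]]@apprisTag,
                 character(1))
  ranks <- apprisRank(tags)
  if (min(ranks) >= 99L) return(NA_character_)
  cdsLen <- vapply(ids, function(t) {
    tx <- gene@transcripts[[t]]
    tx@cdsEnd - tx@cdsStart + 1L
  }, integer(1))
  o <- order(ranks, -cdsLen, ids)
  ids[o[1]]
}

#' Enumerate (reference, alternative) isoform pairs of a gene
#'
#' @param gene a \linkS4class{GeneModel}; the reference is selected with
#'   \code{\link{selectReference}} unless already set.
#' @return data.frame with columns \code{ref} and \code{alt}, one row per
#'   alternative isoform with a validated ORF; zero rows for excluded genes.
#' @export
isoformPairs <- function(gene) {
  ref <- gene@referenceId
  if (is.na(ref)) ref <- selectReference(gene)
  if (is.na(ref))
    return(data.frame(ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  alts <- setdiff(names(gene@orfs), ref)
  alts <- sort(alts)
  data.frame(ref = rep(ref, length(alts)), alt = alts,
             stringsAsFactors = FALSE)
}
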
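# Internal coordinate helpers. Genomic coordinates are 1-based closed
# throughout; "oriented" coordinates multiply by -1 on the minus strand so
# that transcript direction is always ascending.

# genomic position of every transcript position, in transcript 5'->3' order
txToGenomeMap <- function(tx) {
  ex <- tx@exons
  if (tx@strand == "+") {
    unlist(lapply(seq_along(ex),
                  function(i) seq.int(start(ex)[i], end(ex)[i])),
           use.names = FALSE)
  } else {
    idx <- rev(seq_along(ex))
    unlist(lapply(idx,
                  function(i) seq.int(end(ex)[i], start(ex)[i])),
           use.names = FALSE)
  }
}

orient <- function(pos, strand) if (strand == "+") pos else -pos

# oriented start/end of genomic intervals: os <= oe in transcript direction
orientedStart <- function(s, e, strand) if (strand == "+") s else -e
orientedEnd   <- function(s, e, strand) if (strand == "+") e else -s

# exons in transcript (5'->3') order
exonsTxOrder <- function(tx) {
  ex <- tx@exons
  if (tx@strand == "+") ex else rev(ex)
}

# map a genomic interval (known to lie within the transcript's exons and a
# single exon run) to transcript coordinates
genomicToTxRange <- function(tx, gstart, gend, txmap = txToGenomeMap(tx)) {
  i1 <- match(gstart, txmap)
  i2 <- match(gend, txmap)
  if (is.na(i1) || is.na(i2))
    stop("interval not contained in transcript exons")
  sort(c(i1, i2))
}

revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

translateDNA <- function(x) {
  as.character(Biostrings::translate(Biostrings::DNAString(x),
                                     no.init.codon = TRUE))
}

# run expr under a temporary RNG state seeded with `seed`
withLocalSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}
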
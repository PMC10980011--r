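# Fixture layouts. All coordinates here are "oriented" gene-local positions
# (ascending in transcript direction); the generator mirrors them onto the
# minus strand. Each layout fixes the exon structures and transcript-relative
# CDS spans of a reference and an alternative isoform, optionally plants
# extra bases, and states the expected altered-region call.

.truthRow <- function(positionClass = NA_character_, category = NA_character_,
                      nTerminalClass = NA_character_,
                      nTerminalDriver = NA_character_, hybridExon = NA,
                      spliceComplexity = NA_character_, multiExonSkip = NA,
                      ragged = NA, snapback = NA,
                      cTerminalMode = NA_character_,
                      cTerminalSubtype = NA_character_) {
  data.frame(positionClass = positionClass, category = category,
             nTerminalClass = nTerminalClass,
             nTerminalDriver = nTerminalDriver, hybridExon = hybridExon,
             spliceComplexity = spliceComplexity,
             multiExonSkip = multiExonSkip, ragged = ragged,
             snapback = snapback, cTerminalMode = cTerminalMode,
             cTerminalSubtype = cTerminalSubtype, stringsAsFactors = FALSE)
}

.noTruth <- function() .truthRow()[0, , drop = FALSE]

.ex <- function(...) {
  m <- do.call(rbind, list(...))
  colnames(m) <- c("s", "e")
  m
}

.motif <- function(pos, base) data.frame(pos = pos, base = base,
                                         stringsAsFactors = FALSE)

# shared exon scaffolds
.std5 <- list(E1 = c(101L, 160L), E2 = c(261L, 320L), E3 = c(421L, 480L),
              E4 = c(581L, 640L), E5 = c(741L, 820L))
.std6 <- list(E1 = c(101L, 160L), E2 = c(261L, 320L), E3 = c(421L, 480L),
              E4 = c(581L, 640L), E5 = c(741L, 800L), E6 = c(901L, 980L))
.wide5 <- list(E1 = c(101L, 160L), E2 = c(311L, 370L), E3 = c(471L, 530L),
               E4 = c(631L, 690L), E5 = c(791L, 870L))
.startFamily <- list(E0 = c(101L, 130L), EB1 = c(231L, 266L),
                     EB2 = c(331L, 366L), E2 = c(471L, 530L),
                     E3 = c(631L, 690L), E4 = c(791L, 850L),
                     E5 = c(951L, 1030L))

.layoutFunctions <- list(

  identity = function() {
    s <- .std5
    ex <- .ex(s$E1, s$E2, s$E3, s$E4, s$E5)
    list(refExons = ex, altExons = ex,
         refCds = c(13L, 252L), altCds = c(13L, 252L),
         extra = NULL, truth = .noTruth())
  },

  exon_skip = function() {
    s <- .std5
    list(refExons = .ex(s$E1, s$E2, s$E3, s$E4, s$E5),
         altExons = .ex(s$E1, s$E2, s$E4, s$E5),
         refCds = c(13L, 252L), altCds = c(13L, 192L), extra = NULL,
         truth = .truthRow("internal", "Deletion",
                           spliceComplexity = "single",
                           multiExonSkip = FALSE, ragged = FALSE,
                           snapback = FALSE))
  },

  multi_exon_skip = function() {
    s <- .std6
    list(refExons = .ex(s$E1, s$E2, s$E3, s$E4, s$E5, s$E6),
         altExons = .ex(s$E1, s$E2, s$E5, s$E6),
         refCds = c(13L, 312L), altCds = c(13L, 192L), extra = NULL,
         truth = .truthRow("internal", "Deletion",
                           spliceComplexity = "compound",
                           multiExonSkip = TRUE, ragged = FALSE,
                           snapback = FALSE))
  },

  alt_donor_inframe = function() {
    s <- .std5
    list(refExons = .ex(s$E1, s$E2, s$E3, s$E4, s$E5),
         altExons = .ex(s$E1, s$E2, c(421L, 471L), s$E4, s$E5),
         refCds = c(13L, 252L), altCds = c(13L, 243L), extra = NULL,
         truth = .truthRow("internal", "Deletion",
                           spliceComplexity = "single",
                           multiExonSkip = FALSE, ragged = FALSE,
                           snapback = FALSE))
  },

  alt_acceptor_inframe = function() {
    s <- .std5
    list(refExons = .ex(s$E1, s$E2, s$E3, s$E4, s$E5),
         altExons = .ex(s$E1, s$E2, s$E3, c(590L, 640L), s$E5),
         refCds = c(13L, 252L), altCds = c(13L, 243L), extra = NULL,
         truth = .truthRow("internal", "Deletion",
                           spliceComplexity = "single",
                           multiExonSkip = FALSE, ragged = FALSE,
                           snapback = FALSE))
  },

  retained_intron_inframe = function() {
    # intron between E3 and E4 is 102 nt (a multiple of three)
    list(refExons = .ex(c(101L, 160L), c(261L, 320L), c(421L, 480L),
                        c(583L, 642L), c(743L, 822L)),
         altExons = .ex(c(101L, 160L), c(261L, 320L), c(421L, 642L),
                        c(743L, 822L)),
         refCds = c(13L, 252L), altCds = c(13L, 354L), extra = NULL,
         truth = .truthRow("internal", "Insertion",
                           spliceComplexity = "single",
                           multiExonSkip = FALSE, ragged = FALSE,
                           snapback = FALSE))
  },

  ragged_edge = function() {
    # phase 1 at the E3|E4 junction; the alternative acceptor removes nine
    # bases, so the junction codons only share the E3 base and pair as a
    # non-synonymous Edge (CAT vs GAT)
    list(refExons = .ex(c(101L, 160L), c(261L, 320L), c(421L, 481L),
                        c(581L, 639L), c(741L, 820L)),
         altExons = .ex(c(101L, 160L), c(261L, 320L), c(421L, 481L),
                        c(590L, 639L), c(741L, 820L)),
         refCds = c(13L, 252L), altCds = c(13L, 243L),
         extra = .motif(c(481L, 589L, 590L, 591L), c("C", "G", "A", "T")),
         truth = .truthRow("internal", "Substitution",
                           spliceComplexity = "single",
                           multiExonSkip = FALSE, ragged = TRUE,
                           snapback = FALSE))
  },

  snapback_frameshift = function() {
    # one extra base at the E2 donor and one fewer at the E4 acceptor shift
    # the frame over E3 only; downstream codons return to frame
    s <- .std6
    list(refExons = .ex(s$E1, s$E2, s$E3, s$E4, s$E5, s$E6),
         altExons = .ex(s$E1, c(261L, 321L), s$E3, c(582L, 640L),
                        s$E5, s$E6),
         refCds = c(13L, 312L), altCds = c(13L, 312L),
         extra = .motif(c(480L, 581L, 582L, 583L), c("C", "G", "A", "T")),
         truth = .truthRow("internal", "Substitution",
                           spliceComplexity = "compound",
                           multiExonSkip = FALSE, ragged = TRUE,
                           snapback = TRUE))
  },

  frameshift_cterm = function() {
    # one extra base at the E4 donor shifts the frame for the rest of the
    # protein; the alternative terminates at its own downstream stop
    s <- .std5
    list(refExons = .ex(s$E1, s$E2, s$E3, s$E4, s$E5),
         altExons = .ex(s$E1, s$E2, s$E3, c(581L, 641L), s$E5),
         refCds = c(13L, 252L), altCds = c(13L, 264L), extra = NULL,
         truth = .truthRow("c_terminal", "Substitution",
                           cTerminalMode = "frameshift_driven"))
  },

  exit_extension = function() {
    # the terminal intron is retained and translation runs into it
    s <- .std5
    list(refExons = .ex(s$E1, s$E2, s$E3, s$E4, s$E5),
         altExons = .ex(s$E1, s$E2, s$E3, c(581L, 820L)),
         refCds = c(13L, 252L), altCds = c(13L, 270L), extra = NULL,
         truth = .truthRow("c_terminal", "Substitution",
                           cTerminalMode = "splice_driven",
                           cTerminalSubtype = "EXIT"))
  },

  poison_exon = function() {
    # an extra exon inside intron 3 carries a premature stop
    s <- .std5
    list(refExons = .ex(s$E1, s$E2, s$E3, s$E4, s$E5),
         altExons = .ex(s$E1, s$E2, s$E3, c(501L, 572L), s$E4, s$E5),
         refCds = c(13L, 252L), altCds = c(13L, 207L), extra = NULL,
         truth = .truthRow("c_terminal", "Substitution",
                           cTerminalMode = "splice_driven",
                           cTerminalSubtype = "poison_exon"))
  },

  ale_in_utr = function() {
    # the reference stops in E4 and carries E5 as pure 3'-UTR; the
    # alternative skips E4 and terminates inside E5
    s <- .std5
    list(refExons = .ex(s$E1, s$E2, s$E3, s$E4, s$E5),
         altExons = .ex(s$E1, s$E2, s$E3, s$E5),
         refCds = c(13L, 222L), altCds = c(13L, 210L), extra = NULL,
         truth = .truthRow("c_terminal", "Substitution",
                           cTerminalMode = "splice_driven",
                           cTerminalSubtype = "ALE_in_UTR"))
  },

  coste = function() {
    # the alternative splices out of the reference's last exon upstream of
    # the reference stop and continues into a novel downstream exon
    s <- .std5
    list(refExons = .ex(s$E1, s$E2, s$E3, s$E4, s$E5),
         altExons = .ex(s$E1, s$E2, s$E3, s$E4, c(741L, 752L),
                        c(940L, 1011L)),
         refCds = c(13L, 252L), altCds = c(13L, 279L), extra = NULL,
         truth = .truthRow("c_terminal", "Insertion",
                           cTerminalMode = "splice_driven",
                           cTerminalSubtype = "COSTE"))
  },

  mxs_tss = function() {
    # the alternative transcription start lies inside intron 1, with its own
    # start codon; neither start codon is present in the other transcript
    w <- .wide5
    list(refExons = .ex(w$E1, w$E2, w$E3, w$E4, w$E5),
         altExons = .ex(c(211L, 246L), w$E2, w$E3, w$E4, w$E5),
         refCds = c(13L, 252L), altCds = c(13L, 228L), extra = NULL,
         truth = .truthRow("n_terminal", "Substitution",
                           nTerminalClass = "MXS",
                           nTerminalDriver = "altTSS", hybridExon = FALSE))
  },

  mxs_splice = function() {
    # mutually exclusive first coding exons downstream of a shared
    # untranslated first exon
    f <- .startFamily
    list(refExons = .ex(f$E0, f$EB1, f$E2, f$E3, f$E4, f$E5),
         altExons = .ex(f$E0, f$EB2, f$E2, f$E3, f$E4, f$E5),
         refCds = c(43L, 258L), altCds = c(43L, 258L), extra = NULL,
         truth = .truthRow("n_terminal", "Substitution",
                           nTerminalClass = "MXS",
                           nTerminalDriver = "utr5_splicing",
                           hybridExon = FALSE))
  },

  sds_tss = function() {
    # the alternative starts in intron 1 (all-UTR first exon) and initiates
    # at a downstream codon that the reference also carries
    w <- .wide5
    list(refExons = .ex(w$E1, w$E2, w$E3, w$E4, w$E5),
         altExons = .ex(c(211L, 240L), w$E2, w$E3, w$E4, w$E5),
         refCds = c(13L, 252L), altCds = c(40L, 222L), extra = NULL,
         truth = .truthRow("n_terminal", "Deletion",
                           nTerminalClass = "SDS",
                           nTerminalDriver = "altTSS", hybridExon = FALSE))
  },

  sds_hybrid = function() {
    # the alternative's first exon starts at the start of the reference's
    # second exon and ends at the same donor: a hybrid exon
    w <- .wide5
    list(refExons = .ex(w$E1, w$E2, w$E3, w$E4, w$E5),
         altExons = .ex(w$E2, w$E3, w$E4, w$E5),
         refCds = c(13L, 252L), altCds = c(10L, 192L), extra = NULL,
         truth = .truthRow("n_terminal", "Deletion",
                           nTerminalClass = "SDS",
                           nTerminalDriver = "altTSS", hybridExon = TRUE))
  },

  sds_splice = function() {
    # the reference initiates in a cassette exon that the alternative
    # splices out, falling back to a shared downstream start
    f <- .startFamily
    list(refExons = .ex(f$E0, f$EB1, f$E2, f$E3, f$E4, f$E5),
         altExons = .ex(f$E0, f$E2, f$E3, f$E4, f$E5),
         refCds = c(43L, 258L), altCds = c(40L, 222L), extra = NULL,
         truth = .truthRow("n_terminal", "Deletion",
                           nTerminalClass = "SDS",
                           nTerminalDriver = "utr5_splicing",
                           hybridExon = FALSE))
  },

  mss = function() {
    # identical transcripts; the alternative initiates at an internal
    # in-frame methionine that both transcripts carry
    s <- .std5
    ex <- .ex(s$E1, s$E2, s$E3, s$E4, s$E5)
    list(refExons = ex, altExons = ex,
         refCds = c(13L, 252L), altCds = c(31L, 252L), extra = NULL,
         truth = .truthRow("n_terminal", "Deletion",
                           nTerminalClass = "MSS",
                           nTerminalDriver = "cotranslational",
                           hybridExon = FALSE))
  },

  sus = function() {
    # the alternative carries the shared upstream start in its transcript
    # but initiates in a novel exon inside intron 1
    w <- .wide5
    list(refExons = .ex(w$E1, w$E2, w$E3, w$E4, w$E5),
         altExons = .ex(w$E1, c(211L, 240L), w$E2, w$E3, w$E4, w$E5),
         refCds = c(13L, 252L), altCds = c(73L, 282L), extra = NULL,
         truth = .truthRow("n_terminal", "Substitution",
                           nTerminalClass = "SUS",
                           nTerminalDriver = "unset", hybridExon = NA))
  }
)

#' Event types covered by the fixture generator
#'
#' @return Character vector of the twenty event-type names, in canonical
#'   order.
#' @export
#' @examples
#' fixtureEventTypes()
fixtureEventTypes <- function() names(.layoutFunctions)
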
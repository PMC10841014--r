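.PAIR_PENALTY <- c(W = 0, G = 0.5, M = 1)

#' Classify one miRNA:target base pair
#'
#' Read antiparallel in DNA space: Watson-Crick (W) for A:T, T:A, G:C, C:G;
#' G:U wobble (G) for miRNA G against target T or miRNA T (U) against target
#' G; anything else is a mismatch (M). Wobbles cost half a mismatch in the
#' duplex penalty, the usual plant target-prediction weighting.
#'
#' @param mirnaBase,targetBase single characters in ACGT (after
#'   canonicalization; U is accepted and treated as T).
#' @return "W", "G" or "M" (vectorised over equal-length inputs).
#' @export
#' @examples
#' classifyPair("G", "C")  # W
#' classifyPair("G", "T")  # G (G:U wobble)
#' classifyPair("A", "A")  # M
classifyPair <- function(mirnaBase, targetBase) {
  m <- canonicalizeSeq(mirnaBase)
  t <- canonicalizeSeq(targetBase)
  .assertAcgt(m, "miRNA base"); .assertAcgt(t, "target base")
  wc <- (m == "A" & t == "T") | (m == "T" & t == "A") |
    (m == "G" & t == "C") | (m == "C" & t == "G")
  gu <- (m == "G" & t == "T") | (m == "T" & t == "G")
  ifelse(wc, "W", ifelse(gu, "G", "M"))
}

#' Align a miRNA against one transcript site
#'
#' Gapless antiparallel pairing: miRNA position i (5'->3') pairs transcript
#' position \code{siteEnd - i + 1}. Fills the W/G/M pair string, the penalty
#' (1 per mismatch, 0.5 per wobble) and the cleavage position (the
#' transcript base paired to miRNA nucleotide 10, \code{siteEnd - 9}).
#'
#' @param mirna named character (length 1) or a single-sequence DNAStringSet;
#'   the mature miRNA.
#' @param transcript transcript sequence (character or DNAString); name used
#'   as the transcript id if available.
#' @param siteEnd 1-based transcript coordinate paired to miRNA position 1.
#' @param mirnaName,transcriptId optional explicit identifiers.
#' @return A \linkS4class{DuplexAlignment}.
#' @export
#' @examples
#' mir <- c(miR1 = "TGGAGCTCCCTTCATTCCAAT")
#' tx <- paste0(strrep("A", 30),
#'              as.character(Biostrings::reverseComplement(
#'                Biostrings::DNAString(mir))), strrep("A", 30))
#' alignSite(mir, tx, siteEnd = 51)
alignSite <- function(mirna, transcript, siteEnd,
                      mirnaName = NULL, transcriptId = NULL) {
  mseq <- canonicalizeSeq(as.character(mirna))
  if (is.null(mirnaName))
    mirnaName <- if (!is.null(names(mirna))) names(mirna) else "miRNA"
  tseq <- canonicalizeSeq(as.character(transcript))
  if (is.null(transcriptId))
    transcriptId <- if (!is.null(names(transcript))) names(transcript) else
      "transcript"
  L <- nchar(mseq)
  siteEnd <- as.integer(siteEnd)
  siteStart <- siteEnd - L + 1L
  if (siteStart < 1L || siteEnd > nchar(tseq))
    stop("site [", siteStart, ", ", siteEnd, "] out of transcript bounds")
  mv <- strsplit(mseq, "")[[1]]
  site <- substr(tseq, siteStart, siteEnd)
  tv <- rev(strsplit(site, "")[[1]])   # antiparallel: index i faces miRNA i
  cls <- classifyPair(mv, tv)
  new("DuplexAlignment",
      mirnaName = mirnaName, transcriptId = transcriptId,
      siteStart = siteStart, siteEnd = siteEnd,
      pairString = paste(cls, collapse = ""),
      penaltyTotal = sum(.PAIR_PENALTY[cls]),
      cleavagePosition = siteEnd - 9L,
      mirnaSeq = mseq, siteSeq = site)
}

# vectorised penalty over all site_end positions of one transcript
.penaltyScan <- function(mseq, tseq) {
  L <- nchar(mseq)
  n <- nchar(tseq)
  if (n < L) return(numeric(0))
  mv <- strsplit(mseq, "")[[1]]
  tv <- strsplit(tseq, "")[[1]]
  nSites <- n - L + 1L
  pen <- numeric(nSites)
  for (i in seq_len(L)) {
    # miRNA position i faces transcript position siteEnd - i + 1;
    # siteEnd runs over L..n
    tb <- tv[seq(L - i + 1L, n - i + 1L)]
    mb <- mv[i]
    wc <- (mb == "A" & tb == "T") | (mb == "T" & tb == "A") |
      (mb == "G" & tb == "C") | (mb == "C" & tb == "G")
    gu <- (mb == "G" & tb == "T") | (mb == "T" & tb == "G")
    pen <- pen + ifelse(wc, 0, ifelse(gu, 0.5, 1))
  }
  pen
}

#' Scan a transcript for candidate miRNA binding sites
#'
#' Evaluates every possible gapless antiparallel site and returns those with
#' total penalty at most \code{maxPenalty}, sorted by (penalty ascending,
#' site start ascending).
#'
#' @param mirna named character or single-sequence DNAStringSet.
#' @param transcript transcript sequence, named if possible.
#' @param maxPenalty penalty cutoff (default 4.0, a conventional plant
#'   target-prediction ceiling).
#' @param mirnaName,transcriptId optional explicit identifiers.
#' @return list of \linkS4class{DuplexAlignment} objects (possibly empty).
#' @export
findCandidateSites <- function(mirna, transcript, maxPenalty = 4.0,
                               mirnaName = NULL, transcriptId = NULL) {
  mseq <- canonicalizeSeq(as.character(mirna))
  tseq <- canonicalizeSeq(as.character(transcript))
  L <- nchar(mseq)
  if (nchar(tseq) < L)
    stop("transcript shorter than miRNA")
  pen <- .penaltyScan(mseq, tseq)
  ends <- which(pen <= maxPenalty) + L - 1L
  ord <- order(pen[ends - L + 1L], ends)
  lapply(ends[ord], function(e) {
    alignSite(mirna, transcript, e, mirnaName = mirnaName,
              transcriptId = transcriptId)
  })
}

#' Compliance half of the degradome score
#'
#' CO = 8 - penalty: a perfect duplex contributes the full 8 compliance
#' points, each mismatch subtracts 1 and each G:U wobble 0.5. Values may go
#' negative here; clamping to the reported [0, 18] range happens only when
#' the total degradome score is formed.
#'
#' @param dup a \linkS4class{DuplexAlignment}, or a numeric penalty total.
#' @return numeric compliance score (at most 8).
#' @export
#' @examples
#' complianceScore(0)    # 8: perfect duplex
#' complianceScore(2.5)  # 5.5
complianceScore <- function(dup) {
  pen <- if (is(dup, "DuplexAlignment")) penaltyTotal(dup) else as.numeric(dup)
  8 - pen
}

#' Render a duplex as a two-line text diagram
#'
#' Target site 5'->3' on top, miRNA 3'->5' underneath, with | for
#' Watson-Crick pairs, o for G:U wobbles and x (shown as a space on the
#' match line, x on the annotation line) for mismatches -- the style of
#' printed miRNA:target figures.
#'
#' @param dup a \linkS4class{DuplexAlignment}.
#' @return character vector of diagram lines.
#' @export
duplexDiagram <- function(dup) {
  sym <- c(W = "|", G = "o", M = "x")
  cls <- strsplit(dup@pairString, "")[[1]]
  marks <- paste(sym[rev(cls)], collapse = "")
  mir35 <- paste(rev(strsplit(dup@mirnaSeq, "")[[1]]), collapse = "")
  c(paste0(dup@transcriptId, " [", dup@siteStart, "-", dup@siteEnd,
           "]  cleavage at ", dup@cleavagePosition),
    paste0("5' ", dup@siteSeq, " 3'  (target)"),
    paste0("   ", marks),
    paste0("3' ", mir35, " 5'  (", dup@mirnaName,
           ", penalty ", dup@penaltyTotal, ")"))
}
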
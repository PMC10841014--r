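.pairableMatrix <- function(bases) {
  ok <- function(a, b) {
    (a == "A" & b == "T") | (a == "T" & b == "A") |
      (a == "G" & b == "C") | (a == "C" & b == "G") |
      (a == "G" & b == "T") | (a == "T" & b == "G")
  }
  outer(bases, bases, ok)
}

#' Fold a sequence by base-pair maximisation
#'
#' Nussinov-style dynamic programming over nested structures: maximises the
#' number of Watson-Crick + G:U pairs subject to a minimum hairpin loop of 3
#' unpaired nucleotides (a pair i:j requires j - i > 3). This is a
#' structural plausibility check, not a thermodynamic fold -- no free
#' energies are computed. The traceback is deterministic, preferring to pair
#' the 5'-most base and, among optimal partners, the 5'-most partner.
#'
#' @param sequence character; ACGU/T, at least 10 nt.
#' @return A \linkS4class{HairpinFold}.
#' @export
#' @examples
#' foldMaxPairs("GGGAAAACCC")
foldMaxPairs <- function(sequence) {
  s <- canonicalizeSeq(sequence)
  .assertAcgt(s)
  n <- nchar(s)
  if (n < 10L) stop("sequence must be at least 10 nt")
  b <- strsplit(s, "")[[1]]
  P <- .pairableMatrix(b)
  dp <- matrix(0L, n, n)
  for (span in 4:(n - 1)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- dp[i + 1L, j]
      ks <- seq(i + 4L, j)
      ks <- ks[P[i, ks]]
      if (length(ks)) {
        right <- ifelse(ks == j, 0L, dp[cbind(pmin(ks + 1L, n), j)])
        left <- dp[cbind(i + 1L, ks - 1L)]
        best <- max(best, max(1L + left + right))
      }
      dp[i, j] <- best
    }
  }
  pairs <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  tb <- function(i, j) {
    while (j - i > 3L) {
      ks <- seq(i + 4L, j)
      ks <- ks[P[i, ks]]
      if (length(ks)) {
        right <- ifelse(ks == j, 0L, dp[cbind(pmin(ks + 1L, n), j)])
        left <- dp[cbind(i + 1L, ks - 1L)]
        vals <- 1L + left + right
        hit <- ks[vals == dp[i, j]]
        if (length(hit)) {
          k <- hit[1]
          pairs <<- rbind(pairs, c(i, k))
          tb(i + 1L, k - 1L)
          i <- k + 1L
          next
        }
      }
      i <- i + 1L
    }
  }
  tb(1L, n)
  new("HairpinFold", sequence = s, pairs = pairs,
      nPairs = as.integer(dp[1, n]))
}

#' Dot-bracket string of a fold
#'
#' @param fold a \linkS4class{HairpinFold}.
#' @return character dot-bracket notation.
#' @export
dotBracket <- function(fold) {
  db <- rep(".", nchar(fold@sequence))
  if (nrow(fold@pairs)) {
    db[fold@pairs[, 1]] <- "("
    db[fold@pairs[, 2]] <- ")"
  }
  paste(db, collapse = "")
}

#' Fraction of miRNA positions paired into the star arm
#'
#' @param fold a \linkS4class{HairpinFold}.
#' @param mirnaSpan,starSpan integer(2) 1-based inclusive intervals.
#' @return numeric fraction in [0, 1].
#' @export
duplexPairedFraction <- function(fold, mirnaSpan, starSpan) {
  p <- fold@pairs
  if (!nrow(p)) return(0)
  partner <- integer(nchar(fold@sequence))
  partner[p[, 1]] <- p[, 2]
  partner[p[, 2]] <- p[, 1]
  mir <- seq(mirnaSpan[1], mirnaSpan[2])
  hits <- partner[mir]
  mean(hits >= starSpan[1] & hits <= starSpan[2])
}

#' Validate a precursor hairpin
#'
#' A precursor is accepted when the mature miRNA and miRNA* occupy
#' non-overlapping spans and at least \code{minFraction} of the miRNA's
#' positions pair into the star span in the maximum-base-pair fold -- the
#' miRNA/miRNA* duplex sits in the stem, as in the printed precursor
#' structures.
#'
#' @param fold a \linkS4class{HairpinFold} of the precursor.
#' @param mirnaSpan,starSpan integer(2) 1-based inclusive spans of the
#'   mature miRNA and the star strand within the precursor.
#' @param minFraction minimum duplex-paired fraction (default 0.6).
#' @return list(valid, duplexPairedFraction, nPairs, minFraction).
#' @export
validateHairpin <- function(fold, mirnaSpan, starSpan, minFraction = 0.6) {
  n <- nchar(fold@sequence)
  spans <- rbind(mirnaSpan, starSpan)
  if (any(spans < 1L) || any(spans > n) || any(spans[, 1] > spans[, 2]))
    stop("spans must be increasing intervals within the sequence")
  if (mirnaSpan[1] <= starSpan[2] && starSpan[1] <= mirnaSpan[2])
    stop("miRNA and star spans overlap")
  frac <- duplexPairedFraction(fold, mirnaSpan, starSpan)
  list(valid = frac >= minFraction,
       duplexPairedFraction = frac,
       nPairs = fold@nPairs,
       minFraction = minFraction)
}

#' Build a synthetic precursor around a mature miRNA
#'
#' Concatenates the miRNA arm, an unpaired loop, and the exact reverse
#' complement as the star arm, yielding a perfect inverted repeat -- a
#' labelled synthetic stand-in used to exercise the folding and validation
#' code (real precursors carry bulges the simulator does not model).
#'
#' @param mirna character mature miRNA sequence.
#' @param loopLen loop length in nt (>= 4 so the innermost pair is legal).
#' @return list(sequence, mirnaSpan, starSpan).
#' @export
#' @examples
#' synthesizePrecursor("TGGAGCTCCCTTCATTCCAAT")
synthesizePrecursor <- function(mirna, loopLen = 6L) {
  m <- canonicalizeSeq(mirna)
  .assertAcgt(m)
  if (loopLen < 4L) stop("loopLen must be at least 4")
  L <- nchar(m)
  loop <- strrep("A", loopLen)   # unpairable spacer
  seqn <- paste0(m, loop, .revComp(m))
  list(sequence = seqn,
       mirnaSpan = c(1L, L),
       starSpan = c(L + loopLen + 1L, L + loopLen + L))
}
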
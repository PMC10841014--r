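#' Trim the 3' adapter from small-RNA reads
#'
#' The first 8 nt of the adapter act as an exact seed: the leftmost
#' occurrence of the seed marks the insert end, and everything from the seed
#' onward is removed. Reads without a seed occurrence are kept untrimmed;
#' reads whose seed starts at position 1 (empty insert) are dropped.
#'
#' @param reads a DNAStringSet or character vector of reads.
#' @param adapter adapter sequence, at least 8 nt.
#' @return character vector of trimmed reads (empty inserts removed), with
#'   attribute \code{"n_dropped"} giving the number of dropped reads.
#' @export
#' @examples
#' trimAdapter(c("ACGTACGTACGTACGTACGTAAGATCGGAAGAGC"), "AGATCGGAAGAGC")
trimAdapter <- function(reads, adapter) {
  reads <- canonicalizeSeq(as.character(reads))
  adapter <- canonicalizeSeq(adapter)
  if (nchar(adapter) < 8L)
    stop("configuration error: adapter must be at least 8 nt")
  seed <- substr(adapter, 1L, 8L)
  pos <- regexpr(seed, reads, fixed = TRUE)
  out <- ifelse(pos > 0L, substr(reads, 1L, pos - 1L), reads)
  keep <- nchar(out) > 0L
  res <- out[keep]
  attr(res, "n_dropped") <- sum(!keep)
  res
}

#' Select reads by length
#'
#' Retains reads whose post-trimming length lies in
#' \code{[minLen, maxLen]} (default 18-28 nt, the small-RNA window used for
#' miRNA quantification), preserving input order.
#'
#' @param reads character vector or DNAStringSet of trimmed reads.
#' @param minLen,maxLen inclusive length bounds in nt.
#' @return character vector of retained reads.
#' @export
filterByLength <- function(reads, minLen = 18L, maxLen = 28L) {
  if (minLen > maxLen)
    stop("configuration error: minLen must not exceed maxLen")
  reads <- as.character(reads)
  reads[nchar(reads) >= minLen & nchar(reads) <= maxLen]
}

#' Collapse identical reads into counted unique sequences
#'
#' One entry per distinct sequence, counts summing to the number of input
#' reads, sorted by count (descending) then sequence (lexicographic) --
#' the fastx_collapser-style counting step.
#'
#' @param reads character vector or DNAStringSet of length-selected reads.
#' @param organ,replicate library identity recorded on the result.
#' @return A \linkS4class{LibraryCounts}.
#' @export
collapseReads <- function(reads, organ = "NA", replicate = 1L) {
  reads <- as.character(reads)
  tab <- table(reads)
  cc <- data.frame(sequence = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  cc <- cc[order(-cc$count, cc$sequence), , drop = FALSE]
  rownames(cc) <- NULL
  new("LibraryCounts", organ = organ, replicate = as.integer(replicate),
      totalRetained = length(reads), collapsed = cc)
}

#' Count exact full-length miRNA matches in a collapsed library
#'
#' miRNA sequences are canonicalized to DNA (U to T, uppercase) and matched
#' exactly and full-length against the collapsed sequences; reads matching
#' no miRNA are ignored.
#'
#' @param lib a \linkS4class{LibraryCounts}.
#' @param mirnas named character vector or DNAStringSet of mature miRNA
#'   sequences.
#' @return named integer vector of raw counts, one per miRNA.
#' @export
quantifyMirnas <- function(lib, mirnas) {
  seqs <- canonicalizeSeq(mirnas)
  if (is.null(names(seqs))) stop("miRNAs must be named")
  if (anyDuplicated(seqs)) {
    dup <- seqs[duplicated(seqs)]
    stop("duplicate miRNA sequences under different names (ambiguous ",
         "attribution): ", paste(names(seqs)[seqs %in% dup], collapse = ", "))
  }
  idx <- match(seqs, lib@collapsed$sequence)
  counts <- ifelse(is.na(idx), 0L, lib@collapsed$count[idx])
  names(counts) <- names(seqs)
  counts
}

#' Reads-per-million normalisation
#'
#' RPM = 1e6 * count / total retained reads of the library.
#'
#' @param counts numeric vector of raw counts.
#' @param totalRetained total reads retained after trimming and length
#'   selection (> 0).
#' @return numeric vector of RPM values.
#' @export
normalizeRpm <- function(counts, totalRetained) {
  if (totalRetained <= 0) stop("totalRetained must be positive")
  1e6 * counts / totalRetained
}

#' Run the small-RNA processing chain on one library
#'
#' Adapter trimming, 18-28 nt selection and read collapsing, in the order
#' real libraries are processed.
#'
#' @param reads DNAStringSet or character vector of raw reads.
#' @param adapter 3' adapter sequence.
#' @param minLen,maxLen retained length window in nt.
#' @param organ,replicate library identity.
#' @return A \linkS4class{LibraryCounts}.
#' @export
processSrnaLibrary <- function(reads, adapter, minLen = 18L, maxLen = 28L,
                               organ = "NA", replicate = 1L) {
  trimmed <- trimAdapter(reads, adapter)
  kept <- filterByLength(trimmed, minLen, maxLen)
  collapseReads(kept, organ = organ, replicate = replicate)
}

#' Assemble an organ x replicate RPM matrix
#'
#' Quantifies each miRNA in each processed library and normalises to RPM,
#' returning a \link[SummarizedExperiment]{SummarizedExperiment} with one
#' assay (\code{"RPM"}), rows = miRNAs, columns = libraries, and colData
#' columns \code{organ} and \code{replicate}.
#'
#' @param libs list of \linkS4class{LibraryCounts}.
#' @param mirnas named character vector or DNAStringSet of miRNA sequences.
#' @return A SummarizedExperiment of RPM values.
#' @export
buildExpressionMatrix <- function(libs, mirnas) {
  rpm <- vapply(libs, function(l) {
    normalizeRpm(quantifyMirnas(l, mirnas), l@totalRetained)
  }, numeric(length(mirnas)))
  if (is.null(dim(rpm))) rpm <- matrix(rpm, nrow = length(mirnas))
  rownames(rpm) <- names(mirnas)
  organs <- vapply(libs, function(l) l@organ, character(1))
  reps <- vapply(libs, function(l) l@replicate, integer(1))
  colnames(rpm) <- paste0(organs, "_rep", reps)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(RPM = rpm),
    colData = S4Vectors::DataFrame(organ = organs, replicate = reps)
  )
}

#' Organ-mean RPM profiles
#'
#' @param se SummarizedExperiment from [buildExpressionMatrix()].
#' @return miRNA x organ matrix of replicate-mean RPM.
#' @export
organMeans <- function(se) {
  rpm <- SummarizedExperiment::assay(se, "RPM")
  organs <- SummarizedExperiment::colData(se)$organ
  out <- vapply(unique(organs), function(o) {
    rowMeans(rpm[, organs == o, drop = FALSE])
  }, numeric(nrow(rpm)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(rpm))
  rownames(out) <- rownames(rpm)
  colnames(out) <- unique(organs)
  out
}

#' Differential miRNA accumulation between two organs
#'
#' Per miRNA: log2 fold change of replicate-mean RPM (pseudocount 0.5 RPM on
#' both means) and a two-sided Welch t-test on the replicate RPM values,
#' starred at the three conventional significance levels (* p < 0.05,
#' ** p < 0.01, *** p < 0.001).
#'
#' @param se SummarizedExperiment from [buildExpressionMatrix()].
#' @param pair character(2): the two organ labels to compare (fold change is
#'   pair 1 over pair 2).
#' @param pseudocount RPM pseudocount for the fold change.
#' @return data.frame with columns mirna, mean_A, mean_B, log2FC, p, stars.
#' @export
differentialAccumulation <- function(se, pair, pseudocount = 0.5) {
  stopifnot(length(pair) == 2L)
  organs <- SummarizedExperiment::colData(se)$organ
  if (!all(pair %in% organs))
    stop("missing replicate columns for organ(s): ",
         paste(setdiff(pair, organs), collapse = ", "))
  rpm <- SummarizedExperiment::assay(se, "RPM")
  a <- rpm[, organs == pair[1], drop = FALSE]
  b <- rpm[, organs == pair[2], drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L)
    stop("need at least 2 replicates per organ")
  res <- lapply(rownames(rpm), function(m) {
    st <- starTest(a[m, ], b[m, ])
    data.frame(
      mirna = m,
      mean_A = mean(a[m, ]), mean_B = mean(b[m, ]),
      log2FC = log2((mean(a[m, ]) + pseudocount) /
                      (mean(b[m, ]) + pseudocount)),
      p = st$p, stars = st$stars,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  names(out)[names(out) == "mean_A"] <- paste0("mean_", pair[1])
  names(out)[names(out) == "mean_B"] <- paste0("mean_", pair[2])
  out
}
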
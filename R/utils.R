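#' @import methods
#' @importFrom stats cor median rbinom rmultinom rnorm rpois runif sd t.test
#' @importFrom utils read.delim write.table
NULL

ORGANS <- c("Mv", "Ma", "Fv", "Fa")

#' Organ labels used throughout the package
#'
#' Male vegetative thallus (Mv), antheridiophore (Ma), female vegetative
#' thallus (Fv) and archegoniophore (Fa) -- the four Marchantia organs the
#' simulated study design compares (Mv vs Ma, Fv vs Fa).
#'
#' @return Character vector of the four organ labels, in canonical order.
#' @export
#' @examples
#' organLabels()
organLabels <- function() ORGANS

#' Canonicalize a nucleotide sequence to the DNA alphabet
#'
#' Uppercases and converts U to T so that RNA-space miRNA sequences and
#' DNA-space reads compare directly.
#'
#' @param x character vector of sequences.
#' @return Character vector in uppercase ACGT space.
#' @export
#' @examples
#' canonicalizeSeq("ugacuAGG")
canonicalizeSeq <- function(x) {
  nm <- names(x)
  x <- chartr("U", "T", toupper(as.character(x)))
  names(x) <- nm
  x
}

.assertAcgt <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(what, " contains non-ACGT characters after canonicalization: ",
         paste(unique(unlist(strsplit(gsub("[ACGT]", "", x[bad]), ""))),
               collapse = ", "))
  }
  invisible(x)
}

# round-half-up: deterministic across platforms, unlike base round()
.roundHalfUp <- function(x) floor(x + 0.5)

# derive a reproducible sub-seed (< 2^31) from a base seed and a string key
.deriveSeed <- function(base, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)) * 131)
  as.integer((abs(base) %% 1000000L) * 1009L + h %% 1000003L)
}

# reverse complement on plain character strings (DNA space)
.revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.randomDna <- function(n, len) {
  if (n == 0L) return(character(0))
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# significance stars at the conventional three thresholds
.stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}
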
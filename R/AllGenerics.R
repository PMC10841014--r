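#' @rdname TranscriptModels-class
#' @param x a TranscriptModels object.
#' @return \code{transcriptSeqs} returns the DNAStringSet of sequences;
#'   \code{transcriptRegions} the region interval table.
#' @export
setGeneric("transcriptSeqs", function(x) standardGeneric("transcriptSeqs"))
#' @rdname TranscriptModels-class
#' @export
setGeneric("transcriptRegions", function(x) standardGeneric("transcriptRegions"))
#' @rdname GroundTruth-class
#' @param x a GroundTruth object.
#' @return Accessors return the corresponding slot: planted site table,
#'   organ x miRNA RPM matrix, organ x target relative-expression matrix, or
#'   miRNA sequence set.
#' @export
setGeneric("plantedSites", function(x) standardGeneric("plantedSites"))
#' @rdname GroundTruth-class
#' @export
setGeneric("trueAbundance", function(x) standardGeneric("trueAbundance"))
#' @rdname GroundTruth-class
#' @export
setGeneric("trueRq", function(x) standardGeneric("trueRq"))
#' @rdname GroundTruth-class
#' @export
setGeneric("mirnaSequences", function(x) standardGeneric("mirnaSequences"))
#' @rdname DegradomeProfiles-class
#' @param x a DegradomeProfiles object.
#' @param transcript transcript id.
#' @return \code{profileCounts}: raw per-position tag-start counts;
#'   \code{profileNorm}: the same in tags-per-ten-million (TP10M).
#' @export
setGeneric("profileCounts", function(x, transcript) standardGeneric("profileCounts"))
#' @rdname DegradomeProfiles-class
#' @export
setGeneric("profileNorm", function(x, transcript) standardGeneric("profileNorm"))
#' @rdname DuplexAlignment-class
#' @param x a DuplexAlignment object.
#' @return \code{penaltyTotal}: numeric mismatch/wobble penalty;
#'   \code{cleavagePosition}: transcript coordinate paired to miRNA
#'   nucleotide 10; \code{pairString}: the W/G/M classification string.
#' @export
setGeneric("penaltyTotal", function(x) standardGeneric("penaltyTotal"))
#' @rdname DuplexAlignment-class
#' @export
setGeneric("cleavagePosition", function(x) standardGeneric("cleavagePosition"))
#' @rdname DuplexAlignment-class
#' @export
setGeneric("pairString", function(x) standardGeneric("pairString"))

#' @rdname TranscriptModels-class
#' @export
setMethod("transcriptSeqs", "TranscriptModels", function(x) x@sequences)
#' @rdname TranscriptModels-class
#' @export
setMethod("transcriptRegions", "TranscriptModels", function(x) x@regions)
#' @rdname GroundTruth-class
#' @export
setMethod("plantedSites", "GroundTruth", function(x) x@plantedSites)
#' @rdname GroundTruth-class
#' @export
setMethod("trueAbundance", "GroundTruth", function(x) x@trueAbundance)
#' @rdname GroundTruth-class
#' @export
setMethod("trueRq", "GroundTruth", function(x) x@trueRq)
#' @rdname GroundTruth-class
#' @export
setMethod("mirnaSequences", "GroundTruth", function(x) x@mirnaSequences)
#' @rdname DegradomeProfiles-class
#' @export
setMethod("profileCounts", "DegradomeProfiles", function(x, transcript) {
  if (!transcript %in% names(x@counts))
    stop("no profile for transcript ", transcript)
  x@counts[[transcript]]
})
#' @rdname DegradomeProfiles-class
#' @export
setMethod("profileNorm", "DegradomeProfiles", function(x, transcript) {
  profileCounts(x, transcript) * 1e7 / x@mappedTotal
})
#' @rdname DuplexAlignment-class
#' @export
setMethod("penaltyTotal", "DuplexAlignment", function(x) x@penaltyTotal)
#' @rdname DuplexAlignment-class
#' @export
setMethod("cleavagePosition", "DuplexAlignment", function(x) x@cleavagePosition)
#' @rdname DuplexAlignment-class
#' @export
setMethod("pairString", "DuplexAlignment", function(x) x@pairString)

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat("  seed:", object@seed, " transcripts:", object@nTranscripts,
      " lengths:", paste(object@lengthRange, collapse = "-"), "nt\n")
  cat("  regions (utr5/cds/utr3):",
      paste(object@regionFracs, collapse = "/"), "\n")
  cat("  miRNAs:", nrow(object@mirnaSpecs), "(",
      sum(!is.na(object@mirnaSpecs$target_transcript)), "targeting,",
      sum(is.na(object@mirnaSpecs$target_transcript)), "decoy )\n")
  cat("  sRNA libraries:", object@librarySize, "reads x",
      object@nReplicates, "replicates x", length(ORGANS), "organs\n")
  cat("  degradome: tag", object@degradomeTagLength, "nt, spike",
      object@spikeFraction, ", background rate", object@backgroundRate,
      "/position\n")
})

setMethod("show", "TranscriptModels", function(object) {
  cat("TranscriptModels with", length(object@sequences), "transcripts (",
      min(Biostrings::width(object@sequences)), "-",
      max(Biostrings::width(object@sequences)), "nt )\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", length(object@mirnaSequences), "miRNAs,",
      nrow(object@plantedSites), "planted cleavage sites\n")
  if (nrow(object@plantedSites)) print(object@plantedSites, row.names = FALSE)
})

setMethod("show", "LibraryCounts", function(object) {
  cat("LibraryCounts", paste0(object@organ, "-", object@replicate), ":",
      object@totalRetained, "retained reads,",
      nrow(object@collapsed), "distinct sequences\n")
})

setMethod("show", "DegradomeProfiles", function(object) {
  cat("DegradomeProfiles [", object@libraryId, "]:",
      length(object@counts), "transcripts,",
      round(object@mappedTotal, 1), "mapped tags\n")
})

setMethod("show", "DuplexAlignment", function(object) {
  cat(duplexDiagram(object), sep = "\n")
})

setMethod("show", "HairpinFold", function(object) {
  cat("HairpinFold:", nchar(object@sequence), "nt,",
      object@nPairs, "base pairs\n")
  cat(dotBracket(object), "\n")
})
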
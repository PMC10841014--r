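#' @importClassesFrom Biostrings DNAStringSet
NULL

#' SimulationConfig: parameters of the synthetic dataset generator
#'
#' Holds every knob of the simulator: transcriptome geometry, the miRNA
#' specifications (per-organ abundance in RPM, target transcript and region),
#' sRNA library size and adapter, degradome tag parameters, and the Ct-scale
#' noise model. A single seed makes all outputs byte-identical across runs.
#'
#' @slot seed integer; master random seed.
#' @slot nTranscripts integer; number of transcripts to simulate.
#' @slot lengthRange integer(2); min/max transcript length (nt).
#' @slot regionFracs named numeric(3); fractions of each transcript allotted
#'   to \code{utr5}, \code{cds}, \code{utr3}; must sum to 1.
#' @slot mirnaSpecs data.frame with columns \code{name}, \code{length}
#'   (18-28 nt), \code{target_transcript} (NA for decoys with no planted
#'   site), \code{target_region} (\code{utr5}/\code{cds}/\code{utr3}), and
#'   \code{Mv}, \code{Ma}, \code{Fv}, \code{Fa} abundances in RPM.
#' @slot nReplicates integer; sRNA/qPCR replicates per organ.
#' @slot librarySize integer; reads per sRNA library.
#' @slot adapter character; 3' adapter appended to every simulated read.
#' @slot readLength integer; sequencer read length (nt).
#' @slot degradomeTagLength integer; PARE tag length (nt).
#' @slot spikeFraction numeric in [0,1]; probability that a target
#'   transcript's degradome tag starts exactly at the planted cleavage site.
#' @slot backgroundRate numeric; expected background degradome tags per
#'   transcript position.
#' @slot ctNoiseSd numeric; Gaussian noise sd on the Ct scale.
#' @slot inverseGain numeric; coefficient a in RQ = 1/(1 + a * RPM/1000).
#' @exportClass SimulationConfig
setClass("SimulationConfig", representation(
  seed = "integer",
  nTranscripts = "integer",
  lengthRange = "integer",
  regionFracs = "numeric",
  mirnaSpecs = "data.frame",
  nReplicates = "integer",
  librarySize = "integer",
  adapter = "character",
  readLength = "integer",
  degradomeTagLength = "integer",
  spikeFraction = "numeric",
  backgroundRate = "numeric",
  ctNoiseSd = "numeric",
  inverseGain = "numeric"
))

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  f <- object@regionFracs
  if (!identical(names(f), c("utr5", "cds", "utr3")))
    msg <- c(msg, "regionFracs must be named utr5, cds, utr3")
  else if (abs(sum(f) - 1) > 1e-9)
    msg <- c(msg, "regionFracs must sum to 1 (within 1e-9)")
  if (any(f < 0)) msg <- c(msg, "regionFracs must be non-negative")
  if (length(object@lengthRange) != 2L ||
      object@lengthRange[1] > object@lengthRange[2])
    msg <- c(msg, "lengthRange must be an increasing integer pair")
  ms <- object@mirnaSpecs
  need <- c("name", "length", "target_transcript", "target_region", ORGANS)
  if (!all(need %in% names(ms)))
    msg <- c(msg, paste("mirnaSpecs must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (any(ms$length < 18L | ms$length > 28L))
      msg <- c(msg, "every miRNA length must lie in [18, 28]")
    if (any(as.matrix(ms[, ORGANS]) < 0))
      msg <- c(msg, "miRNA abundances must be >= 0")
    if (anyDuplicated(ms$name)) msg <- c(msg, "miRNA names must be unique")
    tgt <- !is.na(ms$target_transcript)
    if (any(tgt & !ms$target_region %in% c("utr5", "cds", "utr3")))
      msg <- c(msg, "target_region must be utr5, cds or utr3")
  }
  if (object@spikeFraction < 0 || object@spikeFraction > 1)
    msg <- c(msg, "spikeFraction must lie in [0, 1]")
  if (object@librarySize < 1L) msg <- c(msg, "librarySize must be positive")
  if (nchar(object@adapter) < 8L)
    msg <- c(msg, "adapter must be at least 8 nt (the trimming seed length)")
  if (object@ctNoiseSd < 0) msg <- c(msg, "ctNoiseSd must be >= 0")
  if (object@inverseGain <= 0) msg <- c(msg, "inverseGain must be positive")
  if (length(msg)) msg else TRUE
})

#' TranscriptModels: simulated transcript sequences with region annotation
#'
#' Transcript sequences as a \link[Biostrings]{DNAStringSet} plus, per
#' transcript, contiguous 1-based 5'UTR/CDS/3'UTR intervals that tile
#' \code{[1, length]} (an empty region is allowed and has width 0).
#'
#' @slot sequences DNAStringSet of transcript sequences, named by id.
#' @slot regions data.frame with columns \code{transcript_id}, \code{region}
#'   (utr5/cds/utr3), \code{start}, \code{end} (1-based inclusive; width-0
#'   regions have end = start - 1).
#' @exportClass TranscriptModels
setClass("TranscriptModels", representation(
  sequences = "DNAStringSet",
  regions = "data.frame"
))

setValidity("TranscriptModels", function(object) {
  msg <- character(0)
  ids <- names(object@sequences)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "sequences must have unique names")
  r <- object@regions
  if (!all(c("transcript_id", "region", "start", "end") %in% names(r)))
    return("regions must have transcript_id, region, start, end columns")
  for (id in ids) {
    ri <- r[r$transcript_id == id, ]
    ri <- ri[match(c("utr5", "cds", "utr3"), ri$region), ]
    if (any(is.na(ri$start)))
      return(paste0("transcript ", id, " must have utr5, cds, utr3 rows"))
    len <- Biostrings::width(object@sequences[id])
    cov <- sum(pmax(0L, ri$end - ri$start + 1L))
    if (cov != len)
      msg <- c(msg, paste0("regions of ", id, " do not tile [1, ", len, "]"))
  }
  if (length(msg)) msg else TRUE
})

#' GroundTruth: planted structure of a simulated dataset
#'
#' Records everything the generator planted: the miRNA sequences, the
#' cleavage sites (with the exact transcript coordinate paired to miRNA
#' nucleotide 10), the per-organ true abundances (RPM), and the target
#' relative expression normalised to the calibrator organ (Mv = 1).
#'
#' @slot mirnaSequences DNAStringSet of mature miRNA sequences (DNA space).
#' @slot plantedSites data.frame: \code{mirna}, \code{transcript_id},
#'   \code{site_start}, \code{site_end}, \code{cleavage_position},
#'   \code{region}.
#' @slot trueAbundance organ x miRNA matrix of RPM.
#' @slot trueRq organ x target matrix of relative expression (calibrator
#'   organ Mv fixed at 1).
#' @slot rqRaw organ x target matrix of raw inverse-gain values
#'   1/(1 + a RPM/1000) before calibrator normalisation.
#' @exportClass GroundTruth
setClass("GroundTruth", representation(
  mirnaSequences = "DNAStringSet",
  plantedSites = "data.frame",
  trueAbundance = "matrix",
  trueRq = "matrix",
  rqRaw = "matrix"
))

#' LibraryCounts: collapsed reads of one sRNA library
#'
#' @slot organ character organ label.
#' @slot replicate integer replicate index.
#' @slot totalRetained integer; reads surviving trimming + length selection.
#' @slot collapsed data.frame with columns \code{sequence}, \code{count},
#'   sorted by count (desc) then sequence; counts sum to totalRetained.
#' @exportClass LibraryCounts
setClass("LibraryCounts", representation(
  organ = "character",
  replicate = "integer",
  totalRetained = "integer",
  collapsed = "data.frame"
))

setValidity("LibraryCounts", function(object) {
  cc <- object@collapsed
  if (!all(c("sequence", "count") %in% names(cc)))
    return("collapsed must have sequence and count columns")
  if (anyDuplicated(cc$sequence)) return("collapsed sequences must be unique")
  if (nrow(cc) && any(cc$count < 1)) return("collapsed counts must be >= 1")
  if (sum(cc$count) != object@totalRetained)
    return("totalRetained must equal the sum of collapsed counts")
  TRUE
})

#' DegradomeProfiles: per-transcript degradome 5'-end profiles of one library
#'
#' Raw per-position tag-start counts for every transcript, plus the library's
#' mapped-tag total. Normalised signal is tags-per-ten-million (TP10M):
#' \code{counts * 1e7 / mappedTotal}.
#'
#' @slot libraryId character; usually the organ label.
#' @slot counts named list; one numeric vector per transcript, length equal
#'   to the transcript length, entry i = (possibly fractional) tag starts at
#'   position i.
#' @slot mappedTotal numeric; total mapped tags in the library.
#' @exportClass DegradomeProfiles
setClass("DegradomeProfiles", representation(
  libraryId = "character",
  counts = "list",
  mappedTotal = "numeric"
))

setValidity("DegradomeProfiles", function(object) {
  if (length(object@counts) && is.null(names(object@counts)))
    return("counts must be a named list (transcript ids)")
  tot <- sum(vapply(object@counts, sum, numeric(1)))
  if (abs(tot - object@mappedTotal) > 1e-6)
    return("mappedTotal must equal the summed per-transcript counts")
  if (any(vapply(object@counts, function(x) any(x < 0), logical(1))))
    return("counts must be non-negative")
  TRUE
})

#' DuplexAlignment: one gapless antiparallel miRNA:mRNA duplex
#'
#' The miRNA is written 5'->3'; position i of the miRNA pairs transcript
#' position \code{site_end - i + 1}. The pair string classifies each miRNA
#' position as W (Watson-Crick), G (G:U wobble) or M (mismatch); the penalty
#' is 1 point per mismatch and 0.5 per wobble. The cleavage position is the
#' transcript base paired to miRNA nucleotide 10, i.e. \code{site_end - 9}.
#'
#' @slot mirnaName,transcriptId character identifiers.
#' @slot siteStart,siteEnd integer 1-based inclusive transcript coordinates.
#' @slot pairString character; one symbol per miRNA position, 5' to 3'.
#' @slot penaltyTotal numeric; 1.0 * #M + 0.5 * #G.
#' @slot cleavagePosition integer; siteEnd - 9.
#' @slot mirnaSeq,siteSeq character; the two strands (DNA space, site given
#'   5'->3' on the transcript).
#' @exportClass DuplexAlignment
setClass("DuplexAlignment", representation(
  mirnaName = "character",
  transcriptId = "character",
  siteStart = "integer",
  siteEnd = "integer",
  pairString = "character",
  penaltyTotal = "numeric",
  cleavagePosition = "integer",
  mirnaSeq = "character",
  siteSeq = "character"
))

setValidity("DuplexAlignment", function(object) {
  L <- nchar(object@mirnaSeq)
  msg <- character(0)
  if (nchar(object@pairString) != L)
    msg <- c(msg, "pairString length must equal miRNA length")
  if (object@siteStart != object@siteEnd - L + 1L)
    msg <- c(msg, "siteStart must equal siteEnd - miRNA length + 1")
  if (object@cleavagePosition != object@siteEnd - 9L)
    msg <- c(msg, "cleavagePosition must equal siteEnd - 9")
  sym <- strsplit(object@pairString, "")[[1]]
  if (any(!sym %in% c("W", "G", "M")))
    msg <- c(msg, "pairString symbols must be W, G or M")
  pen <- sum(sym == "M") + 0.5 * sum(sym == "G")
  if (abs(pen - object@penaltyTotal) > 1e-9)
    msg <- c(msg, "penaltyTotal must equal 1*#M + 0.5*#G")
  if (length(msg)) msg else TRUE
})

#' HairpinFold: a maximum-base-pair nested secondary structure
#'
#' @slot sequence character; folded sequence (DNA space internally).
#' @slot pairs integer matrix with columns i, j (1-based, i < j), nested
#'   (non-crossing), every loop at least 3 unpaired nt (j - i > 3).
#' @slot nPairs integer; number of pairs (the DP optimum).
#' @exportClass HairpinFold
setClass("HairpinFold", representation(
  sequence = "character",
  pairs = "matrix",
  nPairs = "integer"
))

setValidity("HairpinFold", function(object) {
  p <- object@pairs
  if (nrow(p) == 0L) return(TRUE)
  if (any(p[, 2] - p[, 1] <= 3L)) return("every pair must satisfy j - i > 3")
  idx <- c(p[, 1], p[, 2])
  if (anyDuplicated(idx)) return("each position may appear in at most one pair")
  # non-crossing check
  if (nrow(p) > 1L) {
    for (a in seq_len(nrow(p) - 1L)) {
      for (b in seq(a + 1L, nrow(p))) {
        i <- p[a, 1]; j <- p[a, 2]; k <- p[b, 1]; l <- p[b, 2]
        if ((i < k && k < j && j < l) || (k < i && i < l && l < j))
          return("pairs must be non-crossing (nested)")
      }
    }
  }
  TRUE
})
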
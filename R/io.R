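#' Write transcript models as GFF3
#'
#' Emits one five_prime_UTR / CDS / three_prime_UTR feature per non-empty
#' region, in transcript-local 1-based inclusive coordinates (seqid = the
#' transcript id).
#'
#' @param models a \linkS4class{TranscriptModels}.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
writeGff3Models <- function(models, path) {
  r <- transcriptRegions(models)
  r <- r[r$end >= r$start, , drop = FALSE]
  typeMap <- c(utr5 = "five_prime_UTR", cds = "CDS", utr3 = "three_prime_UTR")
  gr <- GenomicRanges::GRanges(
    seqnames = r$transcript_id,
    ranges = IRanges::IRanges(start = r$start, end = r$end),
    strand = "+",
    type = unname(typeMap[r$region]),
    source = "pareMir",
    phase = ifelse(r$region == "cds", 0L, NA_integer_),
    ID = paste0(r$transcript_id, ":", r$region)
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read transcript models from FASTA + GFF3
#'
#' Inverse of [writeGff3Models()]: reads transcript sequences and their
#' five_prime_UTR/CDS/three_prime_UTR features (transcript-local
#' coordinates). A region absent from the GFF3 is taken as empty and placed
#' at the appropriate boundary so the three regions tile the transcript.
#'
#' @param fastaPath transcript FASTA.
#' @param gffPath GFF3 with UTR/CDS features per transcript.
#' @return A \linkS4class{TranscriptModels}.
#' @export
readTranscriptModels <- function(fastaPath, gffPath) {
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gr <- rtracklayer::import(gffPath, format = "gff3")
  typeMap <- c(five_prime_UTR = "utr5", CDS = "cds",
               three_prime_UTR = "utr3")
  keep <- as.character(gr$type) %in% names(typeMap)
  gr <- gr[keep]
  tab <- data.frame(
    transcript_id = as.character(GenomicRanges::seqnames(gr)),
    region = unname(typeMap[as.character(gr$type)]),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  rows <- list()
  for (id in names(seqs)) {
    ti <- tab[tab$transcript_id == id, ]
    len <- Biostrings::width(seqs[id])
    u5e <- if ("utr5" %in% ti$region) ti$end[ti$region == "utr5"] else 0L
    u3s <- if ("utr3" %in% ti$region) ti$start[ti$region == "utr3"] else
      len + 1L
    full <- data.frame(
      transcript_id = id, region = c("utr5", "cds", "utr3"),
      start = c(1L, u5e + 1L, u3s),
      end = c(u5e, u3s - 1L, len),
      stringsAsFactors = FALSE
    )
    for (rg in c("utr5", "cds", "utr3"))
      if (rg %in% ti$region) {
        full[full$region == rg, c("start", "end")] <-
          ti[ti$region == rg, c("start", "end")]
      }
    rows[[id]] <- full
  }
  new("TranscriptModels", sequences = seqs, regions = do.call(rbind, rows))
}

#' Write simulated reads as Sanger FASTQ
#'
#' Constant Phred+33 quality 'I' (Q40); the simulator has no error model so
#' the qualities carry no information.
#'
#' @param reads a named DNAStringSet.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
writeSimFastq <- function(reads, path) {
  q <- Biostrings::PhredQuality(strrep("I", Biostrings::width(reads)))
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ or FASTA file as sequences
#'
#' @param path input file.
#' @param format "fastq" or "fasta".
#' @return A DNAStringSet.
#' @export
readSequenceFile <- function(path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  Biostrings::readDNAStringSet(path, format = format)
}

#' Write collapsed reads in the conventional collapsed-FASTA dialect
#'
#' Headers are \code{>seq{i}_x{count}}, ranked by count.
#'
#' @param lib a \linkS4class{LibraryCounts}.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
writeCollapsedFasta <- function(lib, path) {
  cc <- lib@collapsed
  dss <- Biostrings::DNAStringSet(cc$sequence)
  names(dss) <- sprintf("seq%d_x%d", seq_len(nrow(cc)), cc$count)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' Expects tab-separated columns organ, replicate, gene, ct.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readCtTable <- function(path) {
  tbl <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("organ", "replicate", "gene", "ct")
  if (!all(need %in% names(tbl)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  tbl
}

#' Import a precomputed degradome count table
#'
#' Aligner-import path: a TSV of (transcript_id, position, count) becomes a
#' \linkS4class{DegradomeProfiles}, bypassing [mapTags()].
#'
#' @param path TSV with columns transcript_id, position, count.
#' @param models a \linkS4class{TranscriptModels} giving transcript lengths.
#' @param libraryId label for the library.
#' @return A \linkS4class{DegradomeProfiles}.
#' @export
readDegradomeCounts <- function(path, models, libraryId = "library") {
  tbl <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "position", "count")
  if (!all(need %in% names(tbl)))
    stop("count table must have columns: ", paste(need, collapse = ", "))
  seqs <- transcriptSeqs(models)
  counts <- lapply(names(seqs), function(id) {
    v <- numeric(Biostrings::width(seqs[id]))
    ti <- tbl[tbl$transcript_id == id, ]
    if (nrow(ti)) v[ti$position] <- ti$count
    v
  })
  names(counts) <- names(seqs)
  new("DegradomeProfiles", libraryId = libraryId, counts = counts,
      mappedTotal = sum(unlist(counts)))
}
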
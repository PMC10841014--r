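#' Default miRNA specification table for the simulator
#'
#' Five targeting miRNAs (four with 3'UTR slice sites, one CDS site, lengths
#' 21-24 nt) with organ-differential abundance profiles echoing the
#' vegetative-vs-reproductive contrasts of a four-organ Marchantia design,
#' plus two decoy miRNAs that are present in the sRNA libraries but have no
#' planted target site (negative controls for target calling).
#'
#' @return data.frame with columns \code{name}, \code{length},
#'   \code{target_transcript}, \code{target_region} and per-organ RPM
#'   columns \code{Mv}, \code{Ma}, \code{Fv}, \code{Fa}.
#' @export
#' @examples
#' defaultMirnaSpecs()
defaultMirnaSpecs <- function() {
  data.frame(
    name = c("simR-1", "simR-2", "simR-3", "simR-4", "simR-5",
             "decoy-1", "decoy-2"),
    length = c(21L, 21L, 22L, 21L, 24L, 21L, 21L),
    target_transcript = c("TX001", "TX002", "TX003", "TX004", "TX005",
                          NA, NA),
    target_region = c("utr3", "utr3", "utr3", "utr3", "cds", NA, NA),
    Mv = c(1800, 600, 900, 500, 700, 800, 0),
    Ma = c(500, 1600, 2500, 2000, 1500, 800, 90),
    Fv = c(1500, 500, 700, 800, 900, 800, 0),
    Fa = c(600, 1400, 1200, 2500, 2200, 800, 80),
    stringsAsFactors = FALSE
  )
}

#' Build a simulation configuration
#'
#' Constructs and validates a \linkS4class{SimulationConfig}. Defaults
#' describe the study design the package emulates: four organs (Mv, Ma, Fv,
#' Fa) x 3 replicates, 1e6-read sRNA libraries with a 3' adapter, one PARE
#' library per organ with 20-nt tags and a 0.4 spike fraction at planted
#' cleavage sites, and qPCR Ct tables with 0.15-cycle noise whose target
#' expression is inversely coupled to cognate miRNA abundance through
#' RQ = 1/(1 + a RPM/1000).
#'
#' @param seed integer master seed; identical configs give byte-identical
#'   outputs.
#' @param nTranscripts number of transcripts.
#' @param lengthRange integer(2) transcript length range in nt.
#' @param regionFracs named numeric(3) (utr5, cds, utr3) summing to 1.
#' @param mirnaSpecs miRNA specification table; see [defaultMirnaSpecs()].
#' @param nReplicates replicates per organ (sRNA and qPCR).
#' @param librarySize reads per simulated sRNA library.
#' @param adapter 3' adapter sequence (>= 8 nt).
#' @param readLength sequencer read length in nt.
#' @param degradomeTagLength PARE tag length in nt.
#' @param spikeFraction probability a target transcript's tag starts at the
#'   planted cleavage position.
#' @param backgroundRate expected background degradome tags per position.
#' @param ctNoiseSd Gaussian sd on the Ct scale.
#' @param inverseGain coefficient a in RQ = 1/(1 + a RPM/1000).
#' @return A validated SimulationConfig.
#' @export
#' @examples
#' cfg <- simulationConfig(seed = 1, nTranscripts = 10)
#' cfg
simulationConfig <- function(seed = 1L,
                             nTranscripts = 30L,
                             lengthRange = c(400L, 900L),
                             regionFracs = c(utr5 = 0.15, cds = 0.60,
                                             utr3 = 0.25),
                             mirnaSpecs = defaultMirnaSpecs(),
                             nReplicates = 3L,
                             librarySize = 1000000L,
                             adapter = "AGATCGGAAGAGCACACGTCT",
                             readLength = 50L,
                             degradomeTagLength = 20L,
                             spikeFraction = 0.4,
                             backgroundRate = 0.5,
                             ctNoiseSd = 0.15,
                             inverseGain = 2) {
  cfg <- new("SimulationConfig",
             seed = as.integer(seed),
             nTranscripts = as.integer(nTranscripts),
             lengthRange = as.integer(lengthRange),
             regionFracs = regionFracs,
             mirnaSpecs = mirnaSpecs,
             nReplicates = as.integer(nReplicates),
             librarySize = as.integer(librarySize),
             adapter = canonicalizeSeq(adapter),
             readLength = as.integer(readLength),
             degradomeTagLength = as.integer(degradomeTagLength),
             spikeFraction = spikeFraction,
             backgroundRate = backgroundRate,
             ctNoiseSd = ctNoiseSd,
             inverseGain = inverseGain)
  validObject(cfg)
  # every targeted region must be able to hold its miRNA even in the
  # shortest transcript
  ms <- mirnaSpecs[!is.na(mirnaSpecs$target_transcript), , drop = FALSE]
  if (nrow(ms)) {
    idx <- suppressWarnings(as.integer(sub("^TX", "", ms$target_transcript)))
    if (any(!is.na(idx) & idx > nTranscripts))
      stop("configuration error: target transcript ",
           ms$target_transcript[which(!is.na(idx) & idx > nTranscripts)[1]],
           " exceeds nTranscripts = ", nTranscripts)
    minLen <- cfg@lengthRange[1]
    for (k in seq_len(nrow(ms))) {
      w <- floor(regionFracs[[ms$target_region[k]]] * minLen)
      if (w < ms$length[k])
        stop("configuration error: region '", ms$target_region[k],
             "' (>= ", w, " nt) cannot hold the ", ms$length[k],
             "-nt miRNA ", ms$name[k])
    }
  }
  cfg
}

.regionTable <- function(id, len, fracs) {
  u5 <- floor(fracs[["utr5"]] * len)
  u3 <- floor(fracs[["utr3"]] * len)
  cds <- len - u5 - u3
  data.frame(
    transcript_id = id,
    region = c("utr5", "cds", "utr3"),
    start = c(1L, u5 + 1L, u5 + cds + 1L),
    end = c(u5, u5 + cds, len),
    stringsAsFactors = FALSE
  )
}

#' Generate a random transcriptome with UTR/CDS annotation
#'
#' Draws \code{nTranscripts} transcripts of uniform random base composition,
#' with lengths uniform over \code{lengthRange}, and tiles each with
#' contiguous 1-based 5'UTR/CDS/3'UTR intervals in the configured
#' proportions.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{TranscriptModels} object; transcript ids are
#'   TX001, TX002, ...
#' @export
#' @examples
#' tm <- generateTranscriptome(simulationConfig(seed = 7, nTranscripts = 5))
#' transcriptRegions(tm)
generateTranscriptome <- function(cfg) {
  set.seed(.deriveSeed(cfg@seed, "transcriptome"))
  n <- cfg@nTranscripts
  ids <- sprintf("TX%03d", seq_len(n))
  lens <- sample(seq(cfg@lengthRange[1], cfg@lengthRange[2]), n,
                 replace = TRUE)
  seqs <- .randomDna(n, max(lens))
  seqs <- substr(seqs, 1L, lens)
  regions <- do.call(rbind, lapply(seq_len(n), function(i) {
    .regionTable(ids[i], lens[i], cfg@regionFracs)
  }))
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- ids
  new("TranscriptModels", sequences = dss, regions = regions)
}

#' Plant miRNA target sites into a transcriptome
#'
#' Generates a random mature sequence for each configured miRNA, then edits
#' each target transcript so that the reverse complement of the miRNA
#' occupies a site fully inside the declared region (an optional number of
#' planted mismatches can degrade the site). The recorded cleavage position
#' is the transcript base paired to miRNA nucleotide 10, i.e.
#' \code{site_end - 9} under the antiparallel convention (nucleotide 12 of
#' the site for a 21-nt miRNA).
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @param models a \linkS4class{TranscriptModels}; edited copies are
#'   returned.
#' @param nMismatches number of site positions to mutate after planting
#'   (default 0: perfect complementarity).
#' @return list with elements \code{models} (edited TranscriptModels) and
#'   \code{truth} (a \linkS4class{GroundTruth}).
#' @export
#' @examples
#' cfg <- simulationConfig(seed = 3, nTranscripts = 8)
#' tm <- generateTranscriptome(cfg)
#' planted <- plantTargetSites(cfg, tm)
#' plantedSites(planted$truth)
plantTargetSites <- function(cfg, models, nMismatches = 0L) {
  set.seed(.deriveSeed(cfg@seed, "plant"))
  ms <- cfg@mirnaSpecs
  seqs <- as.character(transcriptSeqs(models))
  regions <- transcriptRegions(models)

  mirseq <- .randomDna(nrow(ms), max(ms$length))
  mirseq <- substr(mirseq, 1L, ms$length)
  while (anyDuplicated(mirseq)) {         # vanishingly unlikely; keep unique
    dup <- duplicated(mirseq)
    mirseq[dup] <- substr(.randomDna(sum(dup), max(ms$length)), 1L,
                          ms$length[dup])
  }
  names(mirseq) <- ms$name

  sites <- list()
  for (k in seq_len(nrow(ms))) {
    if (is.na(ms$target_transcript[k])) next
    tx <- ms$target_transcript[k]
    if (!tx %in% names(seqs)) stop("target transcript ", tx, " not in models")
    reg <- regions[regions$transcript_id == tx &
                     regions$region == ms$target_region[k], ]
    L <- ms$length[k]
    # keep the cleavage position >= 15 nt from the transcript 3' end so the
    # downstream PARE fragment always yields a mappable tag
    maxEnd <- min(reg$end, nchar(seqs[tx]) - 5L)
    if (maxEnd - L + 1L < reg$start)
      stop("configuration error: region ", ms$target_region[k], " of ", tx,
           " cannot hold the ", L, "-nt miRNA ", ms$name[k])
    siteStart <- reg$start + sample.int(maxEnd - L + 1L - reg$start + 1L,
                                        1L) - 1L
    siteEnd <- siteStart + L - 1L
    site <- .revComp(mirseq[k])
    if (nMismatches > 0L) {
      mut <- sample.int(L, min(nMismatches, L))
      sc <- strsplit(site, "")[[1]]
      for (p in mut)
        sc[p] <- sample(setdiff(c("A", "C", "G", "T"), sc[p]), 1L)
      site <- paste(sc, collapse = "")
    }
    substr(seqs[tx], siteStart, siteEnd) <- site
    sites[[length(sites) + 1L]] <- data.frame(
      mirna = ms$name[k], transcript_id = tx,
      site_start = siteStart, site_end = siteEnd,
      cleavage_position = siteEnd - 9L,
      region = ms$target_region[k],
      stringsAsFactors = FALSE
    )
  }
  siteTab <- if (length(sites)) do.call(rbind, sites) else
    data.frame(mirna = character(0), transcript_id = character(0),
               site_start = integer(0), site_end = integer(0),
               cleavage_position = integer(0), region = character(0))

  abund <- t(as.matrix(ms[, ORGANS]))
  colnames(abund) <- ms$name

  tgt <- siteTab$transcript_id
  rqRaw <- matrix(NA_real_, nrow = length(ORGANS), ncol = length(tgt),
                  dimnames = list(ORGANS, tgt))
  for (j in seq_along(tgt)) {
    rpm <- abund[, siteTab$mirna[j]]
    rqRaw[, j] <- 1 / (1 + cfg@inverseGain * rpm / 1000)
  }
  trueRq <- sweep(rqRaw, 2, rqRaw["Mv", ], "/")

  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- names(seqs)
  mir <- Biostrings::DNAStringSet(mirseq)
  names(mir) <- ms$name
  list(
    models = new("TranscriptModels", sequences = dss, regions = regions),
    truth = new("GroundTruth", mirnaSequences = mir, plantedSites = siteTab,
                trueAbundance = abund, trueRq = trueRq, rqRaw = rqRaw)
  )
}

#' Simulate one small-RNA sequencing library
#'
#' Each of \code{librarySize} reads is either a mature miRNA (sampled with
#' probability RPM/1e6 for its organ, multinomially across the library) or a
#' background insert of uniform random length 15-35 nt; the 3' adapter is
#' appended and the read truncated/padded to the sequencer read length.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @param truth the \linkS4class{GroundTruth} from [plantTargetSites()].
#' @param organ one of Mv, Ma, Fv, Fa.
#' @param replicate replicate index (1-based).
#' @return A named \link[Biostrings]{DNAStringSet} of reads.
#' @export
simulateSrnaLibrary <- function(cfg, truth, organ, replicate = 1L) {
  organ <- match.arg(organ, ORGANS)
  set.seed(.deriveSeed(cfg@seed, paste("srna", organ, replicate)))
  n <- cfg@librarySize
  abund <- trueAbundance(truth)[organ, ]
  p <- abund / 1e6
  # RPM is defined over *retained* (18-28 nt) reads, but background inserts
  # span 15-35 nt, of which only 11/21 lengths survive selection; scale the
  # per-read miRNA probabilities so each miRNA's share of the retained reads
  # equals its configured RPM/1e6
  qKeep <- 11 / 21
  scale <- qKeep / (1 - sum(p) * (1 - qKeep))
  pi <- p * scale
  pBg <- 1 - sum(pi)
  if (pBg < 0) stop("configured miRNA RPMs exceed 1e6 in organ ", organ)
  counts <- as.vector(rmultinom(1L, n, c(pi, bg = pBg)))
  nBg <- counts[length(counts)]
  mirReads <- rep(as.character(mirnaSequences(truth)), counts[-length(counts)])

  # background inserts: random substrings of a large seeded base pool
  bg <- character(0)
  if (nBg > 0L) {
    poolLen <- 2000000L
    pool <- paste(sample(c("A", "C", "G", "T"), poolLen, replace = TRUE),
                  collapse = "")
    lens <- sample(15:35, nBg, replace = TRUE)
    starts <- sample.int(poolLen - 35L, nBg, replace = TRUE)
    bg <- substring(pool, starts, starts + lens - 1L)
  }
  inserts <- sample(c(mirReads, bg))
  full <- paste0(inserts, cfg@adapter,
                 strrep("A", cfg@readLength))
  reads <- substr(full, 1L, cfg@readLength)
  dss <- Biostrings::DNAStringSet(reads)
  names(dss) <- sprintf("%s_rep%d_read%07d", organ, replicate,
                        seq_along(reads))
  dss
}

#' Simulate a degradome (PARE) tag library for one organ
#'
#' For every transcript, draws a Poisson number of 5'-end tags
#' (\code{backgroundRate} per valid start position). On transcripts carrying
#' a planted site, each tag starts exactly at the planted cleavage position
#' with probability \code{spikeFraction} and otherwise uniformly over valid
#' positions; other transcripts are uniform throughout. Tags are
#' \code{degradomeTagLength} nt, shortened at the transcript 3' end but
#' never below 15 nt (start positions are restricted accordingly).
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @param models the planted \linkS4class{TranscriptModels}.
#' @param truth the matching \linkS4class{GroundTruth}.
#' @param organ one of Mv, Ma, Fv, Fa.
#' @return A named \link[Biostrings]{DNAStringSet} of tags.
#' @export
simulateDegradomeLibrary <- function(cfg, models, truth, organ) {
  organ <- match.arg(organ, ORGANS)
  set.seed(.deriveSeed(cfg@seed, paste("degradome", organ)))
  seqs <- as.character(transcriptSeqs(models))
  sites <- plantedSites(truth)
  tagLen <- cfg@degradomeTagLength
  out <- character(0)
  for (tx in names(seqs)) {
    len <- nchar(seqs[tx])
    nValid <- len - 15L + 1L
    if (nValid < 1L) next
    nTags <- rpois(1L, cfg@backgroundRate * nValid)
    if (nTags == 0L) next
    starts <- sample.int(nValid, nTags, replace = TRUE)
    pos <- sites$cleavage_position[sites$transcript_id == tx]
    if (length(pos)) {
      spiked <- runif(nTags) < cfg@spikeFraction
      starts[spiked] <- pos[sample.int(length(pos), sum(spiked),
                                       replace = TRUE)]
    }
    tags <- substr(rep(seqs[tx], nTags), starts,
                   pmin(starts + tagLen - 1L, len))
    names(tags) <- sprintf("%s_%s_tag%05d", organ, tx, seq_along(tags))
    out <- c(out, tags)
  }
  dss <- Biostrings::DNAStringSet(out)
  names(dss) <- names(out)
  dss
}

#' Simulate a qPCR Ct table
#'
#' Emits one Ct value per organ x replicate x gene. The reference gene
#' (default \code{"ACTIN7"}, after the MpACTIN 7 normaliser of organ-level
#' Marchantia qPCR) is constant across organs; each target's Ct is offset by
#' \code{-log2(RQ)} from a fixed baseline, with Gaussian noise of sd
#' \code{ctNoiseSd}, so that 2^-ddCt against the reference with calibrator
#' Mv recovers the ground-truth relative expression. Perfect doubling
#' efficiency is assumed.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @param truth the \linkS4class{GroundTruth}.
#' @param referenceGene name to give the reference gene.
#' @param ctReference baseline Ct of the reference gene.
#' @param ctTargetBase baseline Ct of targets at RQ = 1.
#' @return data.frame with columns organ, replicate, gene, ct.
#' @export
simulateCtTable <- function(cfg, truth, referenceGene = "ACTIN7",
                            ctReference = 20, ctTargetBase = 26) {
  set.seed(.deriveSeed(cfg@seed, "ct"))
  genes <- colnames(truth@rqRaw)
  rows <- list()
  for (organ in ORGANS) {
    for (rep in seq_len(cfg@nReplicates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        organ = organ, replicate = rep, gene = referenceGene,
        ct = ctReference, stringsAsFactors = FALSE)
      for (g in genes) {
        ct <- ctTargetBase - log2(truth@rqRaw[organ, g]) +
          rnorm(1L, 0, cfg@ctNoiseSd)
        rows[[length(rows) + 1L]] <- data.frame(
          organ = organ, replicate = rep, gene = g, ct = ct,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate and write a complete synthetic dataset
#'
#' Runs the whole generator at the configured settings and writes
#' transcriptome FASTA + GFF3, miRNA FASTA, per-organ/replicate sRNA FASTQ,
#' per-organ degradome FASTA, the Ct table, and the ground-truth tables.
#' Identical configurations produce byte-identical files.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @param outdir output directory (created if absent).
#' @return Invisibly, a list with \code{models}, \code{truth} and the paths
#'   written.
#' @export
simulateDataset <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tm <- generateTranscriptome(cfg)
  planted <- plantTargetSites(cfg, tm)
  models <- planted$models
  truth <- planted$truth

  paths <- list(
    transcripts = file.path(outdir, "transcripts.fa"),
    gff3 = file.path(outdir, "models.gff3"),
    mirnas = file.path(outdir, "mirnas.fa"),
    ct = file.path(outdir, "ct_table.tsv"),
    planted = file.path(outdir, "planted_sites.tsv"),
    abundance = file.path(outdir, "true_abundance.tsv")
  )
  Biostrings::writeXStringSet(transcriptSeqs(models), paths$transcripts)
  writeGff3Models(models, paths$gff3)
  Biostrings::writeXStringSet(mirnaSequences(truth), paths$mirnas)

  srnaDir <- file.path(outdir, "srna")
  degDir <- file.path(outdir, "degradome")
  dir.create(srnaDir, showWarnings = FALSE)
  dir.create(degDir, showWarnings = FALSE)
  for (organ in ORGANS) {
    for (rep in seq_len(cfg@nReplicates)) {
      lib <- simulateSrnaLibrary(cfg, truth, organ, rep)
      writeSimFastq(lib, file.path(srnaDir,
                                   sprintf("%s_rep%d.fastq", organ, rep)))
    }
    tags <- simulateDegradomeLibrary(cfg, models, truth, organ)
    Biostrings::writeXStringSet(tags, file.path(degDir,
                                                paste0(organ, ".fa")))
  }
  ct <- simulateCtTable(cfg, truth)
  write.table(ct, paths$ct, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(plantedSites(truth), paths$planted, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(organ = rownames(trueAbundance(truth)),
                         trueAbundance(truth), check.names = FALSE),
              paths$abundance, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(models = models, truth = truth, paths = paths))
}
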
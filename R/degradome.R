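#' Map degradome tags onto transcripts
#'
#' Each tag (a PARE 5'-end fragment, at least 15 nt; shorter tags are
#' discarded) is placed by exact substring search against every transcript.
#' Every match start increments that transcript's per-position count; a tag
#' matching k positions in total (across all transcripts) contributes 1/k at
#' each, so multi-mapping tags are split fractionally. Tags matching nowhere
#' are discarded. Normalised signal is tags-per-ten-million of the library's
#' mapped total.
#'
#' @param tags DNAStringSet or character vector of tag sequences.
#' @param transcripts DNAStringSet or named character vector.
#' @param libraryId label recorded on the profiles.
#' @return A \linkS4class{DegradomeProfiles} covering every transcript.
#' @export
mapTags <- function(tags, transcripts, libraryId = "library") {
  txs <- canonicalizeSeq(transcripts)
  if (length(txs) == 0L) stop("empty transcript set")
  if (is.null(names(txs))) names(txs) <- paste0("TX", seq_along(txs))
  tagSeq <- canonicalizeSeq(as.character(tags))
  tagSeq <- tagSeq[nchar(tagSeq) >= 15L]

  counts <- lapply(txs, function(s) numeric(nchar(s)))
  mapped <- 0
  addHits <- function(htx, hpos, total) {
    # one tag sequence matching k = length(htx) positions: 1/k each
    w <- total / length(htx)
    for (j in seq_along(htx))
      counts[[htx[j]]][hpos[j]] <<- counts[[htx[j]]][hpos[j]] + w
    mapped <<- mapped + total
  }
  if (length(tagSeq)) {
    mult <- table(tagSeq)
    uniq <- names(mult)
    lens <- nchar(txs)
    for (L in sort(unique(nchar(uniq)))) {
      tagsL <- uniq[nchar(uniq) == L]
      if (length(tagsL) < 50L) {
        # few tags of this length: scan each against every transcript
        for (tg in tagsL) {
          htx <- character(0); hpos <- integer(0)
          for (id in names(txs)) {
            m <- gregexpr(tg, txs[[id]], fixed = TRUE)[[1]]
            if (m[1] != -1L) {
              htx <- c(htx, rep(id, length(m)))
              hpos <- c(hpos, as.integer(m))
            }
          }
          if (length(htx)) addHits(htx, hpos, as.numeric(mult[[tg]]))
        }
        next
      }
      # many tags: index every L-mer of every transcript once
      kk <- character(0); ktx <- character(0); kpos <- integer(0)
      for (id in names(txs)) {
        nk <- lens[[id]] - L + 1L
        if (nk < 1L) next
        st <- seq_len(nk)
        kk <- c(kk, substring(txs[[id]], st, st + L - 1L))
        ktx <- c(ktx, rep(id, nk))
        kpos <- c(kpos, st)
      }
      if (!length(kk)) next
      grp <- split(seq_along(kk), kk)
      hits <- grp[tagsL]
      for (i in seq_along(tagsL)) {
        h <- hits[[i]]
        if (is.null(h)) next
        addHits(ktx[h], kpos[h], as.numeric(mult[[tagsL[i]]]))
      }
    }
  }
  new("DegradomeProfiles", libraryId = libraryId, counts = counts,
      mappedTotal = mapped)
}

#' Cutting power of a degradome position
#'
#' CP = round(10 * signal[position] / max(signal)), rounded half-up, giving
#' an integer 0-10 that measures how dominant the candidate peak is within
#' its transcript's profile (the scale-invariance of the ratio means raw or
#' normalised signal give the same value). A transcript with no signal
#' anywhere has no defined cutting power and the candidate is rejected:
#' \code{NA} is returned.
#'
#' @param signal numeric vector: per-position degradome signal of one
#'   transcript (raw or normalised).
#' @param position 1-based position to score.
#' @return integer 0-10, or NA for an all-zero profile.
#' @export
#' @examples
#' cuttingPower(c(0, 100, 0, 1), 2)  # 10
#' cuttingPower(c(0, 100, 0, 1), 4)  # 0
cuttingPower <- function(signal, position) {
  if (position < 1L || position > length(signal))
    stop("position outside transcript")
  mx <- max(signal)
  if (mx <= 0) return(NA_integer_)
  as.integer(.roundHalfUp(10 * signal[position] / mx))
}

#' Rank category of a cleavage position
#'
#' The five-level degradome convention on a transcript's raw tag counts:
#' 0 = unique transcript-wide maximum with raw count > 1; 1 = tied maximum,
#' count > 1; 2 = below the maximum but above the median of the nonzero
#' positions, count > 1; 3 = at or below that median, count > 1; 4 = raw
#' count exactly 1.
#'
#' @param counts numeric vector of raw per-position tag counts.
#' @param position 1-based position; must carry signal.
#' @return integer category 0-4.
#' @export
#' @examples
#' assignCategory(c(rep(0, 99), 9, rep(0, 99), 2), 100)  # 0
assignCategory <- function(counts, position) {
  if (position < 1L || position > length(counts))
    stop("position outside transcript")
  x <- counts[position]
  if (x <= 0) stop("no degradome evidence at position ", position)
  if (x == 1) return(4L)
  mx <- max(counts)
  if (x == mx) {
    if (sum(counts == mx) == 1L) return(0L) else return(1L)
  }
  med <- median(counts[counts > 0])
  if (x > med) 2L else 3L
}

#' The composite degradome score
#'
#' S = max(0, CP + (8 - penalty)): cutting power (0-10) plus the compliance
#' half (8 minus the duplex mismatch/wobble penalty), floored at 0 so the
#' reported range is [0, 18]. A perfectly complementary duplex at a unique
#' transcript-wide maximum attains 18; heavily mismatched candidates at weak
#' sites floor at 0.
#'
#' @param cp integer cutting power (0-10).
#' @param penalty duplex penalty total (1 per mismatch, 0.5 per wobble).
#' @return numeric score in [0, 18].
#' @export
#' @examples
#' degradomeScore(10, 0)   # 18
#' degradomeScore(0, 8)    # 0
#' degradomeScore(7, 2.5)  # 12.5
degradomeScore <- function(cp, penalty) {
  if (is.na(cp)) return(NA_real_)
  max(0, cp + 8 - penalty)
}

#' Annotate the transcript region of a cleavage position
#'
#' Returns the region (utr5/cds/utr3) whose 1-based inclusive interval
#' contains the cleavage position itself (not the whole site).
#'
#' @param position 1-based transcript coordinate.
#' @param models a \linkS4class{TranscriptModels}.
#' @param transcriptId transcript to look up.
#' @return "utr5", "cds" or "utr3".
#' @export
annotateRegion <- function(position, models, transcriptId) {
  r <- transcriptRegions(models)
  r <- r[r$transcript_id == transcriptId & r$end >= r$start, , drop = FALSE]
  if (!nrow(r)) stop("no region intervals for transcript ", transcriptId)
  hit <- r$region[position >= r$start & position <= r$end]
  if (!length(hit))
    stop("position ", position, " outside all region intervals of ",
         transcriptId)
  hit[1]
}

#' Call miRNA targets from degradome evidence
#'
#' Joins duplex candidate sites (penalty at most \code{maxPenalty}) with the
#' degradome profile of each transcript. For each site, the profile is
#' evaluated at the canonical cleavage position and one position downstream
#' (register tolerance +1 nt for off-by-one tag starts); the better-scoring
#' register is kept, ties resolved in favour of the canonical register.
#' Candidates with degradome score >= \code{minScore} and category <=
#' \code{maxCategory} are reported, sorted by (score desc, category asc,
#' penalty asc), together with T-plot data for every transcript carrying a
#' reported candidate.
#'
#' @param mirnas named character vector or DNAStringSet of mature miRNAs.
#' @param models a \linkS4class{TranscriptModels}.
#' @param profiles a \linkS4class{DegradomeProfiles} (one library).
#' @param maxPenalty duplex penalty ceiling (default 4).
#' @param minScore minimum degradome score to report (default 10).
#' @param maxCategory maximum category to report (default 2).
#' @param registerTolerance how many nt downstream of the canonical register
#'   to also examine (default 1).
#' @return list with \code{candidates} (data.frame of
#'   \code{CleavageCandidate} records) and \code{tplots} (named list of
#'   T-plot data.frames; see [tplotData()]).
#' @export
callTargets <- function(mirnas, models, profiles, maxPenalty = 4,
                        minScore = 10, maxCategory = 2,
                        registerTolerance = 1L) {
  if (missing(profiles) || is.null(profiles)) stop("no profiles supplied")
  mirnas <- canonicalizeSeq(mirnas)
  if (is.null(names(mirnas))) stop("miRNAs must be named")
  txSeqs <- as.character(transcriptSeqs(models))
  rows <- list()
  for (m in names(mirnas)) {
    for (tx in names(txSeqs)) {
      if (nchar(txSeqs[[tx]]) < nchar(mirnas[[m]])) next
      if (!tx %in% names(profiles@counts)) next
      cnt <- profiles@counts[[tx]]
      if (max(cnt) <= 0) next                  # no degradome evidence at all
      nrm <- cnt * 1e7 / profiles@mappedTotal
      sites <- findCandidateSites(mirnas[m], txSeqs[tx], maxPenalty,
                                  mirnaName = m, transcriptId = tx)
      for (dup in sites) {
        regs <- cleavagePosition(dup) + 0:registerTolerance
        regs <- regs[regs >= 1L & regs <= length(cnt)]
        regs <- regs[cnt[regs] > 0]
        if (!length(regs)) next
        best <- NULL
        for (p in regs) {
          cp <- cuttingPower(nrm, p)
          sc <- degradomeScore(cp, penaltyTotal(dup))
          if (is.null(best) || sc > best$score)
            best <- list(pos = p, cp = cp, score = sc)
        }
        cat_ <- assignCategory(cnt, best$pos)
        if (best$score < minScore || cat_ > maxCategory) next
        rows[[length(rows) + 1L]] <- data.frame(
          library_id = profiles@libraryId,
          mirna = m, transcript_id = tx,
          site_start = dup@siteStart, site_end = dup@siteEnd,
          pair_string = pairString(dup),
          penalty_total = penaltyTotal(dup),
          cleavage_position = best$pos,
          cutting_power = best$cp,
          category = cat_,
          degradome_score = best$score,
          region = annotateRegion(best$pos, models, tx),
          site_raw_reads = cnt[best$pos],
          site_norm_reads = nrm[best$pos],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  cand <- if (length(rows)) do.call(rbind, rows) else data.frame(
    library_id = character(0), mirna = character(0),
    transcript_id = character(0), site_start = integer(0),
    site_end = integer(0), pair_string = character(0),
    penalty_total = numeric(0), cleavage_position = integer(0),
    cutting_power = integer(0), category = integer(0),
    degradome_score = numeric(0), region = character(0),
    site_raw_reads = numeric(0), site_norm_reads = numeric(0))
  if (nrow(cand)) {
    cand <- cand[order(-cand$degradome_score, cand$category,
                       cand$penalty_total), , drop = FALSE]
    rownames(cand) <- NULL
  }
  tplots <- lapply(unique(cand$transcript_id), function(tx) {
    tplotData(profiles, tx, cand[cand$transcript_id == tx, , drop = FALSE])
  })
  names(tplots) <- unique(cand$transcript_id)
  list(candidates = cand, tplots = tplots)
}

#' T-plot data for one transcript
#'
#' All positions with nonzero degradome signal (normalised, TP10M) with the
#' reported candidate cleavage positions flagged, plus the candidate
#' annotations -- the numbers behind a target plot.
#'
#' @param profiles a \linkS4class{DegradomeProfiles}.
#' @param transcriptId transcript to extract.
#' @param candidates optional data.frame of reported candidates on that
#'   transcript (columns mirna, cleavage_position).
#' @return data.frame (position, norm_reads, is_candidate) with attribute
#'   \code{"annotations"}: data.frame (mirna, cleavage_position).
#' @export
tplotData <- function(profiles, transcriptId, candidates = NULL) {
  nrm <- profileNorm(profiles, transcriptId)
  pos <- which(nrm > 0)
  flagged <- if (!is.null(candidates) && nrow(candidates))
    unique(candidates$cleavage_position) else integer(0)
  out <- data.frame(position = pos, norm_reads = nrm[pos],
                    is_candidate = pos %in% flagged)
  attr(out, "annotations") <- if (!is.null(candidates) && nrow(candidates))
    candidates[, c("mirna", "cleavage_position")] else
    data.frame(mirna = character(0), cleavage_position = integer(0))
  out
}

#' Draw a T-plot
#'
#' Normalised degradome signal versus transcript position, with an arrow at
#' each reported candidate cleavage site.
#'
#' @param tplot data.frame from [tplotData()].
#' @param transcriptId title label.
#' @param ... further arguments to [graphics::plot()].
#' @return Invisibly, NULL.
#' @export
#' @importFrom graphics arrows segments plot
plotTplot <- function(tplot, transcriptId = "", ...) {
  plot(tplot$position, tplot$norm_reads, type = "h",
       xlab = "transcript position (nt)",
       ylab = "degradome signal (TP10M)",
       main = transcriptId, ...)
  hits <- tplot[tplot$is_candidate, , drop = FALSE]
  if (nrow(hits))
    arrows(hits$position, hits$norm_reads * 1.25, hits$position,
           hits$norm_reads * 1.05, length = 0.08, col = "red", lwd = 2)
  invisible(NULL)
}

#' Write called candidates as TSV
#'
#' @param candidates data.frame from [callTargets()].
#' @param path output file.
#' @return Invisibly, the path.
#' @export
writeCandidates <- function(candidates, path) {
  write.table(candidates, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
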
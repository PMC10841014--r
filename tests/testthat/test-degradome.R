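test_that("tag mapping places, splits and discards tags correctly", {
  set.seed(12)
  tx1 <- randomDnaString(200)
  tx2 <- paste0(randomDnaString(50), substr(tx1, 50, 69),
                randomDnaString(50))
  txs <- c(TXa = tx1, TXb = tx2)
  tagUnique <- substr(tx1, 120, 139)
  tagShared <- substr(tx1, 50, 69)       # present in both transcripts
  tagAbsent <- randomDnaString(20)
  prof <- mapTags(c(tagUnique, tagShared, tagAbsent), txs)
  expect_equal(profileCounts(prof, "TXa")[120], 1)
  expect_equal(profileCounts(prof, "TXa")[50], 0.5)
  expect_equal(profileCounts(prof, "TXb")[51], 0.5)
  expect_equal(prof@mappedTotal, 2)
  expect_error(mapTags(tagUnique, character(0)), "empty transcript")
})

test_that("tag mapping totals equal a brute-force substring-scan oracle", {
  set.seed(19)
  txs <- vapply(seq_len(5), function(i) randomDnaString(300), character(1))
  names(txs) <- paste0("T", seq_len(5))
  tags <- vapply(seq_len(300), function(i) {
    id <- sample(names(txs), 1)
    st <- sample(280, 1)
    substr(txs[[id]], st, st + sample(15:20, 1) - 1)
  }, character(1))
  prof <- mapTags(tags, txs)
  # oracle: per-tag gregexpr scan with 1/k weights
  counts <- lapply(txs, function(s) numeric(nchar(s)))
  mapped <- 0
  for (tg in tags) {
    htx <- character(0); hpos <- integer(0)
    for (id in names(txs)) {
      m <- gregexpr(tg, txs[[id]], fixed = TRUE)[[1]]
      if (m[1] != -1) {
        htx <- c(htx, rep(id, length(m)))
        hpos <- c(hpos, as.integer(m))
      }
    }
    if (length(htx)) {
      for (j in seq_along(htx))
        counts[[htx[j]]][hpos[j]] <- counts[[htx[j]]][hpos[j]] +
          1 / length(htx)
      mapped <- mapped + 1
    }
  }
  expect_equal(prof@mappedTotal, mapped)
  for (id in names(txs))
    expect_equal(profileCounts(prof, id), counts[[id]])
})

test_that("cutting power follows the peak-dominance formula", {
  v <- numeric(500); v[100] <- 80; v[200] <- 8
  expect_equal(cuttingPower(v, 100), 10L)
  expect_equal(cuttingPower(v, 200), 1L)
  v2 <- numeric(10); v2[3] <- 100; v2[7] <- 1
  expect_equal(cuttingPower(v2, 7), 0L)      # 1% of max rounds to 0
  expect_true(is.na(cuttingPower(numeric(10), 5)))
  set.seed(4)
  for (i in seq_len(200)) {
    v <- rpois(50, 2)
    if (max(v) == 0) next
    p <- sample(which(v > 0), 1)
    expect_identical(cuttingPower(v, p), oracleCuttingPower(v, p))
  }
})

test_that("categories follow the five-level ranking convention", {
  v <- numeric(300); v[100] <- 9; v[200] <- 2
  expect_equal(assignCategory(v, 100), 0L)
  v2 <- numeric(300); v2[100] <- 5; v2[200] <- 5
  expect_equal(assignCategory(v2, 100), 1L)
  v3 <- numeric(300); v3[50] <- 1
  expect_equal(assignCategory(v3, 50), 4L)
  expect_error(assignCategory(v, 150), "no degradome evidence")
  set.seed(14)
  for (i in seq_len(1000)) {
    v <- rpois(40, 1.2)
    if (max(v) == 0) next
    p <- sample(which(v > 0), 1)
    expect_identical(assignCategory(v, p), oracleCategory(v, p))
  }
})

test_that("degradome scores stay inside the printed 0-18 range", {
  expect_equal(degradomeScore(10, 0), 18)
  expect_equal(degradomeScore(0, 8), 0)
  expect_equal(degradomeScore(7, 2.5), 12.5)
  set.seed(5)
  for (i in seq_len(300)) {
    cp <- sample(0:10, 1)
    pen <- sample(seq(0, 15, 0.5), 1)
    s <- degradomeScore(cp, pen)
    expect_gte(s, 0); expect_lte(s, 18)
  }
})

test_that("region annotation matches an interval-membership oracle", {
  d <- smallDataset(25)
  r <- transcriptRegions(d$models)
  ids <- unique(r$transcript_id)
  set.seed(6)
  for (i in seq_len(500)) {
    id <- sample(ids, 1)
    len <- max(r$end[r$transcript_id == id])
    p <- sample(len, 1)
    expect_identical(annotateRegion(p, d$models, id),
                     oracleRegion(p, r[r$transcript_id == id, ]))
  }
  # inclusive boundary: the CDS start coordinate is cds
  ri <- r[r$transcript_id == ids[1] & r$region == "cds", ]
  expect_identical(annotateRegion(ri$start, d$models, ids[1]), "cds")
})

test_that("target calling recovers planted modules and rejects decoys", {
  d <- smallDataset(3)
  tags <- simulateDegradomeLibrary(d$cfg, d$models, d$truth, "Fv")
  prof <- mapTags(tags, transcriptSeqs(d$models), "Fv")
  res <- callTargets(mirnaSequences(d$truth), d$models, prof)
  cc <- res$candidates
  ps <- plantedSites(d$truth)
  for (i in seq_len(nrow(ps))) {
    hit <- cc[cc$mirna == ps$mirna[i] &
                cc$transcript_id == ps$transcript_id[i], ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$cleavage_position, ps$cleavage_position[i])
    expect_identical(hit$region, ps$region[i])
  }
  expect_false(any(grepl("decoy", cc$mirna)))
  # impossible threshold empties the output
  res19 <- callTargets(mirnaSequences(d$truth), d$models, prof,
                       minScore = 19)
  expect_equal(nrow(res19$candidates), 0L)
  expect_error(callTargets(mirnaSequences(d$truth), d$models, NULL),
               "no profiles")
  # T-plot rows cover exactly the nonzero positions, candidates flagged
  tp <- res$tplots[[ps$transcript_id[1]]]
  nrm <- profileNorm(prof, ps$transcript_id[1])
  expect_equal(tp$position, which(nrm > 0))
  expect_true(ps$cleavage_position[1] %in% tp$position[tp$is_candidate])
})

test_that("raising the spike fraction never lowers a planted site's score", {
  scores <- vapply(c(0.1, 0.3, 0.6), function(sp) {
    d <- smallDataset(7, spikeFraction = sp)
    tags <- simulateDegradomeLibrary(d$cfg, d$models, d$truth, "Mv")
    prof <- mapTags(tags, transcriptSeqs(d$models), "Mv")
    ps <- plantedSites(d$truth)[1, ]
    nrm <- profileNorm(prof, ps$transcript_id)
    cnt <- profileCounts(prof, ps$transcript_id)
    cp <- cuttingPower(nrm, ps$cleavage_position)
    degradomeScore(cp, 0)
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
})

test_that("category 0 implies maximal cutting power", {
  set.seed(23)
  for (i in seq_len(200)) {
    v <- rpois(60, 1.5)
    if (max(v) <= 1) next
    p <- sample(which(v > 0), 1)
    if (assignCategory(v, p) == 0L)
      expect_equal(cuttingPower(v, p), 10L)
  }
})

test_that("calling matches exhaustive per-site evaluation on small instances", {
  d <- smallDataset(37)
  tags <- simulateDegradomeLibrary(d$cfg, d$models, d$truth, "Fa")
  prof <- mapTags(tags, transcriptSeqs(d$models), "Fa")
  mirnas <- canonicalizeSeq(mirnaSequences(d$truth))
  res <- callTargets(mirnas, d$models, prof, maxPenalty = 4,
                     minScore = 10, maxCategory = 2)
  seqs <- as.character(transcriptSeqs(d$models))
  # brute force: every (miRNA, transcript, site_end, register)
  brute <- list()
  for (m in names(mirnas)) {
    L <- nchar(mirnas[[m]])
    for (tx in names(seqs)) {
      cnt <- profileCounts(prof, tx)
      if (max(cnt) <= 0) next
      nrm <- profileNorm(prof, tx)
      for (e in seq(L, nchar(seqs[[tx]]))) {
        dup <- alignSite(mirnas[m], seqs[tx], e,
                         mirnaName = m, transcriptId = tx)
        if (penaltyTotal(dup) > 4) next
        best <- NULL
        for (p in (e - 9L) + 0:1) {
          if (p < 1 || p > length(cnt) || cnt[p] <= 0) next
          sc <- degradomeScore(cuttingPower(nrm, p), penaltyTotal(dup))
          if (is.null(best) || sc > best$sc) best <- list(p = p, sc = sc)
        }
        if (is.null(best)) next
        if (best$sc >= 10 && assignCategory(cnt, best$p) <= 2)
          brute[[length(brute) + 1L]] <-
            data.frame(mirna = m, transcript_id = tx, site_end = e,
                       cleavage_position = best$p,
                       degradome_score = best$sc)
      }
    }
  }
  bruteTab <- do.call(rbind, brute)
  bruteTab <- bruteTab[order(bruteTab$mirna, bruteTab$transcript_id,
                             bruteTab$site_end), ]
  got <- res$candidates[order(res$candidates$mirna,
                              res$candidates$transcript_id,
                              res$candidates$site_end), ]
  expect_equal(nrow(got), nrow(bruteTab))
  expect_equal(got$cleavage_position, bruteTab$cleavage_position)
  expect_equal(got$degradome_score, bruteTab$degradome_score)
})

test_that("precomputed count tables import as profiles", {
  d <- smallDataset(29)
  tab <- data.frame(transcript_id = c("TX001", "TX001", "TX002"),
                    position = c(10L, 50L, 30L),
                    count = c(4, 2, 7))
  f <- tempfile(fileext = ".tsv")
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  prof <- readDegradomeCounts(f, d$models, "imp")
  expect_equal(profileCounts(prof, "TX001")[10], 4)
  expect_equal(profileCounts(prof, "TX002")[30], 7)
  expect_equal(prof@mappedTotal, 13)
  unlink(f)
})
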
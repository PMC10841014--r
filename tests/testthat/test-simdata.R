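test_that("generated transcript models tile [1, length] and are deterministic", {
  cfg <- simulationConfig(seed = 3, nTranscripts = 5,
                          lengthRange = c(300L, 600L))
  tm <- generateTranscriptome(cfg)
  expect_length(transcriptSeqs(tm), 5L)
  r <- transcriptRegions(tm)
  for (id in names(transcriptSeqs(tm))) {
    ri <- r[r$transcript_id == id, ]
    len <- Biostrings::width(transcriptSeqs(tm)[id])
    expect_equal(sum(pmax(0L, ri$end - ri$start + 1L)), len)
    expect_equal(min(ri$start), 1L)
    expect_equal(max(ri$end), len)
  }
  tm2 <- generateTranscriptome(cfg)
  expect_identical(as.character(transcriptSeqs(tm)),
                   as.character(transcriptSeqs(tm2)))
})

test_that("a configuration whose regions cannot hold a planted site errors", {
  expect_error(
    simulationConfig(seed = 1, regionFracs = c(utr5 = 0.2, cds = 0.8,
                                               utr3 = 0)),
    "configuration error")
})

test_that("region fractions must sum to one", {
  expect_error(
    simulationConfig(regionFracs = c(utr5 = 0.2, cds = 0.2, utr3 = 0.2)),
    "sum to 1")
})

test_that("planted sites sit inside their region with the antiparallel cleavage register", {
  d <- smallDataset(21)
  ps <- plantedSites(d$truth)
  expect_equal(nrow(ps), 5L)
  r <- transcriptRegions(d$models)
  seqs <- as.character(transcriptSeqs(d$models))
  mir <- as.character(mirnaSequences(d$truth))
  for (i in seq_len(nrow(ps))) {
    ri <- r[r$transcript_id == ps$transcript_id[i] &
              r$region == ps$region[i], ]
    expect_gte(ps$site_start[i], ri$start)
    expect_lte(ps$site_end[i], ri$end)
    expect_gte(ps$cleavage_position[i], ri$start)
    expect_lte(ps$cleavage_position[i], ri$end)
    # the site is the exact reverse complement of the miRNA (0 mismatches)
    site <- substr(seqs[ps$transcript_id[i]], ps$site_start[i],
                   ps$site_end[i])
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(mir[[ps$mirna[i]]])))
    expect_identical(unname(site), rc)
    # cleavage pairs miRNA nucleotide 10: siteEnd - 9
    expect_equal(ps$cleavage_position[i], ps$site_end[i] - 9L)
  }
  # for a 21-nt miRNA the cleavage base is nucleotide 12 of the site
  i21 <- which(nchar(mir[ps$mirna]) == 21L)[1]
  expect_equal(ps$cleavage_position[i21] - ps$site_start[i21] + 1L, 12L)
})

test_that("sRNA libraries carry planted miRNAs at their configured share of retained reads", {
  d <- smallDataset(5)
  lib <- simulateSrnaLibrary(d$cfg, d$truth, "Mv", 1)
  reads <- as.character(lib)
  # every read contains the adapter seed right after its insert
  expect_true(all(grepl(substr(d$cfg@adapter, 1, 8), reads, fixed = TRUE)))
  lc <- processSrnaLibrary(reads, d$cfg@adapter, organ = "Mv")
  counts <- quantifyMirnas(lc, mirnaSequences(d$truth))
  # absent miRNA stays absent
  expect_equal(unname(counts[["decoy-2"]]), 0L)
  # binomial oracle: expected count = retained * RPM/1e6, within 3 sd
  for (m in names(counts)) {
    expectCount <- lc@totalRetained * trueAbundance(d$truth)["Mv", m] / 1e6
    tol <- 3 * sqrt(max(expectCount, 1))
    expect_lte(abs(counts[[m]] - expectCount), tol)
  }
})

test_that("degradome tags spike at the planted cleavage position", {
  d <- smallDataset(9, spikeFraction = 1.0)
  tags <- simulateDegradomeLibrary(d$cfg, d$models, d$truth, "Ma")
  ps <- plantedSites(d$truth)
  seqs <- as.character(transcriptSeqs(d$models))
  for (i in seq_len(nrow(ps))) {
    tx <- ps$transcript_id[i]
    tt <- as.character(tags[grepl(paste0("_", tx, "_"), names(tags))])
    site5p <- substr(seqs[tx], ps$cleavage_position[i],
                     ps$cleavage_position[i] + d$cfg@degradomeTagLength - 1L)
    expect_true(all(tt == substr(site5p, 1, nchar(tt))))
  }

  d4 <- smallDataset(9, spikeFraction = 0.4)
  tags4 <- simulateDegradomeLibrary(d4$cfg, d4$models, d4$truth, "Ma")
  prof <- mapTags(tags4, transcriptSeqs(d4$models), "Ma")
  ps4 <- plantedSites(d4$truth)
  for (i in seq_len(nrow(ps4))) {
    cnt <- profileCounts(prof, ps4$transcript_id[i])
    # modal start is the planted position
    expect_equal(which.max(cnt), ps4$cleavage_position[i])
  }
  # non-target transcript: no dominant position at default background
  nonTarget <- setdiff(names(seqs), ps4$transcript_id)[1]
  cnt <- profileCounts(prof, nonTarget)
  expect_lte(max(cnt), 5 * mean(cnt[cnt > 0]))
})

test_that("Ct tables encode relative expression recoverable by 2^-ddCt", {
  d <- smallDataset(2, ctNoiseSd = 0)
  ct <- simulateCtTable(d$cfg, d$truth)
  tr <- trueRq(d$truth)
  for (g in colnames(tr)) {
    rq <- deltaDeltaCt(ct, g, "ACTIN7", "Mv")
    means <- tapply(rq$rq, rq$organ, mean)
    expect_equal(as.numeric(means[rownames(tr)]), as.numeric(tr[, g]),
                 tolerance = 1e-9)
  }
  # with noise, the recovered values stay close to truth
  dn <- smallDataset(2, ctNoiseSd = 0.15)
  ctn <- simulateCtTable(dn$cfg, dn$truth)
  g <- colnames(tr)[1]
  rqn <- deltaDeltaCt(ctn, g, "ACTIN7", "Mv")
  means <- tapply(rqn$rq, rqn$organ, mean)
  relErr <- abs(means[rownames(tr)] - tr[, g]) / tr[, g]
  expect_lt(mean(relErr), 0.15)
})

test_that("identical configurations write byte-identical datasets", {
  cfg <- simulationConfig(seed = 4, nTranscripts = 6, librarySize = 2000L,
                          nReplicates = 2L)
  d1 <- file.path(tempdir(), "simA")
  d2 <- file.path(tempdir(), "simB")
  simulateDataset(cfg, d1)
  simulateDataset(cfg, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  f2 <- sort(list.files(d2, recursive = TRUE))
  expect_identical(f1, f2)
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f2))
  expect_identical(unname(h1), unname(h2))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("transcript models survive a FASTA + GFF3 round trip", {
  d <- smallDataset(13)
  fa <- tempfile(fileext = ".fa")
  gff <- tempfile(fileext = ".gff3")
  Biostrings::writeXStringSet(transcriptSeqs(d$models), fa)
  writeGff3Models(d$models, gff)
  back <- readTranscriptModels(fa, gff)
  expect_identical(as.character(transcriptSeqs(back)),
                   as.character(transcriptSeqs(d$models)))
  a <- transcriptRegions(d$models)
  b <- transcriptRegions(back)
  key <- function(x) x[order(x$transcript_id, x$region), ]
  a <- key(a); b <- key(b)
  expect_equal(a$start, b$start)
  expect_equal(a$end, b$end)
  unlink(c(fa, gff))
})

test_that("ground truth couples target expression inversely to miRNA abundance", {
  d <- smallDataset(17)
  ps <- plantedSites(d$truth)
  ab <- trueAbundance(d$truth)
  tr <- trueRq(d$truth)
  raw <- d$truth@rqRaw
  for (i in seq_len(nrow(ps))) {
    prof <- ab[, ps$mirna[i]]
    # raw RQ strictly decreases as cognate abundance increases
    o <- order(prof)
    expect_true(all(diff(raw[o, ps$transcript_id[i]]) < 0 |
                      diff(prof[o]) == 0))
    expect_lt(cor(prof, tr[, ps$transcript_id[i]], method = "spearman"), 0)
  }
})
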
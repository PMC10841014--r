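# Small-scale configuration used by most unit tests (full-scale defaults are
# exercised in test-acceptance.R).
smallConfig <- function(seed = 11, ...) {
  simulationConfig(seed = seed, nTranscripts = 8L, librarySize = 20000L, ...)
}

smallDataset <- function(seed = 11, ...) {
  cfg <- smallConfig(seed, ...)
  pl <- plantTargetSites(cfg, generateTranscriptome(cfg))
  list(cfg = cfg, models = pl$models, truth = pl$truth)
}

randomDnaString <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# dictionary-count oracle for read collapsing
oracleCollapse <- function(reads) {
  env <- new.env()
  for (r in reads) {
    cur <- if (exists(r, envir = env, inherits = FALSE))
      get(r, envir = env) else 0L
    assign(r, cur + 1L, envir = env)
  }
  keys <- ls(env)
  data.frame(sequence = keys,
             count = vapply(keys, get, integer(1), envir = env),
             stringsAsFactors = FALSE)
}

# per-position re-classification oracle for duplex penalties
oraclePenalty <- function(mirna, site) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  mv <- strsplit(mirna, "")[[1]]
  sv <- strsplit(site, "")[[1]]
  pen <- 0
  L <- length(mv)
  for (i in seq_len(L)) {
    tb <- sv[L - i + 1]           # antiparallel partner of miRNA position i
    if (comp[[mv[i]]] == tb) {
      # Watson-Crick: 0
    } else if ((mv[i] == "G" && tb == "T") || (mv[i] == "T" && tb == "G")) {
      pen <- pen + 0.5
    } else {
      pen <- pen + 1
    }
  }
  pen
}

# direct-formula oracle for cutting power (round half up, written differently)
oracleCuttingPower <- function(signal, position) {
  x <- 10 * signal[position] / max(signal)
  as.integer(trunc(x + 0.5))
}

# rank-and-median oracle for the five-level category
oracleCategory <- function(counts, position) {
  x <- counts[position]
  if (x == 1) return(4L)
  nz <- sort(counts[counts > 0], decreasing = TRUE)
  if (x >= nz[1]) {
    if (sum(nz == nz[1]) == 1L) return(0L) else return(1L)
  }
  med <- stats::median(nz)
  if (x > med) 2L else 3L
}

# interval-membership oracle for region annotation
oracleRegion <- function(position, regionTab) {
  for (k in seq_len(nrow(regionTab))) {
    if (regionTab$end[k] >= regionTab$start[k] &&
        position >= regionTab$start[k] && position <= regionTab$end[k])
      return(regionTab$region[k])
  }
  NA_character_
}

# Spearman via explicit average ranks + Pearson product-moment formula
oracleSpearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# exhaustive enumeration of nested structures (loop >= 3) for short sequences
oracleMaxPairs <- function(seqn) {
  b <- strsplit(chartr("U", "T", toupper(seqn)), "")[[1]]
  canPair <- function(i, j) {
    p <- paste0(b[i], b[j])
    p %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }
  rec <- function(i, j) {
    if (j - i < 4L) return(0L)
    best <- rec(i + 1L, j)                 # i unpaired
    for (k in seq(i + 4L, j)) {
      if (canPair(i, k))
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
    }
    best
  }
  rec(1L, length(b))
}

# direct threshold comparison for significance stars
oracleStars <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}
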
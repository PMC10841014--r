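#' Relative expression by the 2^-ddCt method
#'
#' Per organ and replicate, dCt = Ct(gene) - Ct(reference) on the matched
#' replicate; ddCt = dCt - mean dCt of the calibrator organ; RQ = 2^-ddCt
#' (perfect doubling efficiency assumed). The calibrator organ's mean RQ is
#' 1 by construction when noise-free.
#'
#' @param ct data.frame with columns organ, replicate, gene, ct.
#' @param gene target gene to quantify.
#' @param referenceGene normaliser gene (must be measured for every organ x
#'   replicate in which the target is measured).
#' @param calibrator calibrator organ (default Mv).
#' @return data.frame with one row per organ x replicate: organ, replicate,
#'   rq; plus per-organ summary columns mean_rq, sd_rq merged on organ.
#' @export
#' @examples
#' ct <- expand.grid(organ = c("Mv", "Ma"), replicate = 1:3)
#' ct <- rbind(cbind(ct, gene = "ref", ct = 20),
#'             cbind(ct, gene = "g1", ct = 22))
#' deltaDeltaCt(ct, "g1", "ref", "Mv")
deltaDeltaCt <- function(ct, gene, referenceGene, calibrator = "Mv") {
  g <- ct[ct$gene == gene, ]
  r <- ct[ct$gene == referenceGene, ]
  if (!nrow(g)) stop("gene ", gene, " absent from the Ct table")
  key <- function(d) paste(d$organ, d$replicate)
  idx <- match(key(g), key(r))
  if (anyNA(idx)) {
    miss <- g[is.na(idx), c("organ", "replicate")]
    stop("missing reference measurement for (",
         paste(paste(miss$organ, miss$replicate, sep = ", rep "),
               collapse = "), ("), ")")
  }
  dct <- g$ct - r$ct[idx]
  calDct <- dct[g$organ == calibrator]
  if (!length(calDct)) stop("calibrator organ ", calibrator, " not measured")
  ddct <- dct - mean(calDct)
  out <- data.frame(organ = g$organ, replicate = g$replicate,
                    rq = 2^(-ddct), stringsAsFactors = FALSE)
  means <- tapply(out$rq, out$organ, mean)
  sds <- tapply(out$rq, out$organ, sd)
  out$mean_rq <- as.numeric(means[out$organ])
  out$sd_rq <- as.numeric(sds[out$organ])
  out
}

#' Two-group t-test with significance stars
#'
#' Two-sided Welch (unequal-variance) t-test with the three conventional
#' significance levels: * p < 0.05, ** p < 0.01, *** p < 0.001. If both
#' groups are constant the test statistic is undefined; equal constants give
#' p = 1 (no evidence of difference), different constants p = 0.
#'
#' @param groupA,groupB numeric vectors, each of length >= 2.
#' @return list(p = p-value, stars = "", "*", "**" or "***").
#' @export
#' @examples
#' starTest(c(1, 1.1, 0.9), c(4, 4.2, 3.9))
starTest <- function(groupA, groupB) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least 2 values")
  if (sd(groupA) == 0 && sd(groupB) == 0) {
    p <- if (mean(groupA) == mean(groupB)) 1 else 0
  } else {
    p <- t.test(groupA, groupB, var.equal = FALSE)$p.value
  }
  list(p = p, stars = .stars(p))
}

#' Relative expression of targets across organs, with replicate tests
#'
#' Convenience wrapper: runs [deltaDeltaCt()] for each gene and tests each
#' non-calibrator organ against the calibrator with [starTest()].
#'
#' @param ct Ct table (organ, replicate, gene, ct).
#' @param genes character vector of target genes.
#' @param referenceGene normaliser gene.
#' @param calibrator calibrator organ.
#' @return data.frame: gene, organ, mean_rq, sd_rq, p, stars.
#' @export
relativeExpression <- function(ct, genes, referenceGene,
                               calibrator = "Mv") {
  rows <- list()
  for (g in genes) {
    rq <- deltaDeltaCt(ct, g, referenceGene, calibrator)
    cal <- rq$rq[rq$organ == calibrator]
    for (o in unique(rq$organ)) {
      vals <- rq$rq[rq$organ == o]
      st <- if (o == calibrator) list(p = NA_real_, stars = "") else
        starTest(vals, cal)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, organ = o, mean_rq = mean(vals), sd_rq = sd(vals),
        p = st$p, stars = st$stars, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' miRNA-target inverse-correlation report
#'
#' Spearman correlation (average ranks on ties) between a miRNA's organ-mean
#' RPM profile and its putative target's organ-mean relative expression,
#' over the same organs. The module is flagged inverse when rho < 0. A
#' constant profile leaves rho undefined and the report is flagged not
#' evaluable.
#'
#' @param mirnaProfile named numeric: organ-mean RPM of the miRNA.
#' @param targetProfile named numeric: organ-mean RQ of the target, same
#'   organs.
#' @param mirna,target optional names for the report.
#' @return one-row data.frame: mirna, target, spearman_rho, inverse,
#'   evaluable, plus the two profiles as attribute \code{"profiles"}.
#' @export
#' @examples
#' inverseCorrelation(c(Mv = 1, Ma = 2, Fv = 3, Fa = 4),
#'                    c(Mv = 4, Ma = 3, Fv = 2, Fa = 1))
inverseCorrelation <- function(mirnaProfile, targetProfile,
                               mirna = "miRNA", target = "target") {
  if (!is.null(names(mirnaProfile)) && !is.null(names(targetProfile))) {
    if (!setequal(names(mirnaProfile), names(targetProfile)))
      stop("profiles must cover the same organs")
    targetProfile <- targetProfile[names(mirnaProfile)]
  } else if (length(mirnaProfile) != length(targetProfile)) {
    stop("profiles must have equal length")
  }
  evaluable <- sd(mirnaProfile) > 0 && sd(targetProfile) > 0
  rho <- if (evaluable)
    suppressWarnings(cor(mirnaProfile, targetProfile, method = "spearman"))
  else NA_real_
  out <- data.frame(mirna = mirna, target = target,
                    spearman_rho = rho,
                    inverse = isTRUE(rho < 0),
                    evaluable = evaluable,
                    stringsAsFactors = FALSE)
  attr(out, "profiles") <- rbind(mirna = mirnaProfile,
                                 target = targetProfile)
  out
}
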
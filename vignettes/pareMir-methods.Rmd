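---
title: "Degradome-supported miRNA target identification: models and methods"
author: "pareMir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degradome-supported miRNA target identification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pareMir)
```

# Scope

`pareMir` implements the computational core of an organ-resolved plant miRNA
study of the kind carried out in the liverwort *Marchantia polymorpha*:
small-RNA libraries from four organs — male vegetative thallus (Mv),
antheridiophore (Ma), female vegetative thallus (Fv) and archegoniophore
(Fa) — quantify mature miRNAs; a degradome (PARE) library per organ locates
miRNA-guided cleavage sites on transcripts; RT-qPCR measures target
expression; and the analysis reports cleavage candidates, T-plots and
miRNA–target inverse-correlation. Because real datasets of this kind need a
genome and deposited raw reads, the package ships a seeded synthetic-data
generator that emulates the full study design with known ground truth, so
every stage can be validated end to end.

# The duplex model

A candidate binding site is a gapless antiparallel alignment of the mature
miRNA (written 5'→3') against a transcript window of the same length:
miRNA position $i$ pairs transcript position $\mathrm{siteEnd} - i + 1$.
Each position is classified as Watson–Crick (W), G:U wobble (G) or mismatch
(M), with penalty

$$\mathrm{penalty} = 1.0\,\#M + 0.5\,\#G,$$

the de-facto plant target-prediction weighting. Alignment is gapless
(no bulges) so that the site scan is exhaustive and directly checkable
against a brute-force window enumeration; positional weighting (e.g. extra
cost in the seed or around positions 9–11) is deliberately not applied in
this version. The slice register follows the canonical AGO geometry: the
cleavage position is the transcript base paired to miRNA nucleotide 10,
i.e. $\mathrm{siteEnd} - 9$ (nucleotide 12 of the site for a 21-nt miRNA).
Candidate sites are kept when the penalty does not exceed `maxPenalty`
(default 4.0, a conventional plant cutoff; configurable).

# The degradome score

PARE tags are uncapped mRNA 5' ends; a genuine slice site shows up as a
pileup of tag starts exactly at the cleavage position. Tags (≥ 15 nt) are
mapped by exact substring search; a tag matching $k$ positions across the
transcriptome contributes $1/k$ to each (when a tag occurs more than once in
one transcript, every occurrence counts toward $k$). Per-library signal is
normalised to tags-per-ten-million (TP10M).

Each candidate site is scored from two halves:

* **Cutting power** $CP = \operatorname{round}\!\big(10\, s_p / \max_q
  s_q\big) \in \{0..10\}$, the dominance of the candidate position $p$
  within its transcript's profile (scale-invariant, so raw and normalised
  signal agree). Rounding is half-up (`floor(x + 0.5)`) for platform
  determinism. An all-zero profile leaves $CP$ undefined and the candidate
  is rejected rather than scored.
* **Compliance** $CO = 8 - \mathrm{penalty}$: a perfect duplex earns the
  full 8 points, each mismatch subtracts 1 and each wobble 0.5.

The reported score is $S = \max(0,\, CP + CO) \in [0, 18]$: a perfectly
complementary duplex at a unique transcript-wide maximum attains exactly 18,
and an over-penalised candidate at a marginal site floors at 0. This
decomposition is the simplest one that reproduces both printed extremes and
keeps the halves independently testable; the weights are exposed as
arguments rather than hidden constants.

Each position additionally receives the five-level rank **category** used in
degradome analysis: 0 = unique transcript-wide maximum (raw count > 1),
1 = tied maximum, 2 = above the median of the nonzero positions, 3 = at or
below that median, 4 = a singleton tag. `callTargets()` evaluates each
site at the canonical register and one nucleotide downstream (register
tolerance +1 for off-by-one tag starts, ties resolved toward the canonical
register), then reports candidates with $S \ge$ `minScore` (default 10) and
category $\le$ `maxCategory` (default 2), sorted by score, category and
penalty. These thresholds are explicit flags: they are reasonable defaults
for the synthetic data, not claims about any particular historical analysis.

# Small-RNA quantification

Processing mirrors the standard small-RNA chain: the leftmost exact
occurrence of the adapter's first 8 nt marks the insert end (reads without
the seed are kept untrimmed, empty inserts dropped); reads of 18–28 nt are
retained; identical reads are collapsed to (sequence, count) pairs; mature
miRNAs are counted by exact full-length match; and counts are normalised to
RPM = $10^6 \cdot \mathrm{count} / \mathrm{retained}$, with all retained
18–28 nt reads as the denominator. Exact seed trimming (rather than
error-tolerant alignment) is appropriate because the simulator has no
sequencing-error model; real libraries can be pre-trimmed externally, and
isomiR-tolerant counting is out of scope. All sequences are canonicalized
to the DNA alphabet (U→T, uppercase) on input.

Differential accumulation between two organs uses the replicate RPM values
in a two-sided Welch $t$-test — a robust default at $n = 3$ where equal
variances cannot be verified — starred at the three conventional levels
(* $p<0.05$, ** $p<0.01$, *** $p<0.001$), and a log2 fold change of
replicate-mean RPM with a 0.5-RPM pseudocount on both means so that organs
with zero counts give finite, sign-correct fold changes.

# Relative expression and inverse correlation

RT-qPCR is summarised by the comparative Ct method with perfect doubling
efficiency: $\Delta Ct = Ct_{gene} - Ct_{ref}$ per organ × replicate,
$\Delta\Delta Ct = \Delta Ct - \overline{\Delta Ct}_{\mathrm{calibrator}}$,
$RQ = 2^{-\Delta\Delta Ct}$. The calibrator organ defaults to Mv (the
left-most bar of the study design's panels) and is overridable. Each
miRNA–target module is then summarised by the Spearman correlation (average
ranks on ties) between the miRNA's four organ-mean RPM values and the
target's four organ-mean RQ values; the module is flagged *inverse* when
$\rho < 0$. Four points make $\rho$ coarse, so reports carry the raw
profiles alongside the flag; the claim being tested is direction, not
magnitude. Constant profiles leave $\rho$ undefined and are flagged not
evaluable.

# Hairpin plausibility

Precursor structure is checked by Nussinov-style base-pair maximisation:
the maximum number of nested Watson–Crick + G:U pairs with a minimum loop
of 3 unpaired nucleotides, with a deterministic traceback that prefers
pairing the 5'-most base and, among optimal partners, the 5'-most partner.
A precursor passes when the mature miRNA and star spans do not overlap and
at least `minFraction` (default 0.6) of the miRNA's positions pair into the
star span. This is a structural plausibility screen, not a thermodynamic
fold: no free energies are computed, and printed ΔG values from
nearest-neighbour folders are intentionally out of scope.

# The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which the pipeline is validated.

* **Transcriptome** — 30 transcripts of uniform base composition, 400–900 nt,
  tiled 15% 5'UTR / 60% CDS / 25% 3'UTR (1-based inclusive intervals,
  written as GFF3 `five_prime_UTR`/`CDS`/`three_prime_UTR`).
* **miRNAs and sites** — five targeting miRNAs (21–24 nt; four 3'UTR sites
  and one CDS site, echoing the predominance of 3'UTR slice sites in this
  kind of study) and two decoys with no planted site. Sites are the exact
  reverse complement of the miRNA (optionally degraded by planted
  mismatches) and are placed so the cleavage position lies at least 15 nt
  from the transcript 3' end — otherwise the downstream PARE fragment would
  be shorter than the 15-nt mapping minimum and the site unrecoverable by
  construction.
* **sRNA libraries** — 4 organs × 3 replicates × $10^6$ reads. Each read is
  a miRNA (multinomially, in proportion to its organ abundance) or a
  background insert of uniform random length 15–35 nt; the 3' adapter is
  appended and reads are truncated/padded to the 50-nt read length. Because
  only 11 of the 21 background lengths survive 18–28 nt selection, the
  per-read miRNA probabilities are scaled by the retained fraction so that
  each miRNA's share of *retained* reads equals its configured RPM/10⁶ —
  RPM is defined over retained reads, so this is the calibration that makes
  the configured abundances true values. There is no sequencing-error or
  isomiR model.
* **Default abundances** — chosen once, by statistical design: at $10^6$
  reads ≈ 52.4% are retained, so a miRNA at $R$ RPM yields ≈ $0.524R$
  reads per library and its 3-replicate mean RPM estimate has relative
  standard deviation $\approx 1/\sqrt{3 \cdot 0.524R}$. Nonzero targeting
  abundances are therefore set at 500–2500 RPM (recovery sd ≤ 3.6%, well
  inside the 10% validation tolerance), with organ-differential,
  non-constant profiles; one decoy is constant (800 RPM) and one sits below
  100 RPM to exercise the low-abundance regime.
* **Degradome libraries** — one per organ; per transcript the number of
  tags is Poisson(0.5 × valid start positions), and on target transcripts
  each tag starts at the planted cleavage position with probability
  `spikeFraction` (default 0.4) and uniformly otherwise. Tags are 20 nt
  (a conventional PARE tag length; the value is configurable because
  sequencing chemistry does not fix it), shortened near the 3' end. Tags are
  drawn only from annotated transcripts, forward strand — PARE captures 5'
  ends of cleaved mRNAs, and antisense signal is out of scope.
* **Ct tables** — the reference gene (named `ACTIN7`, after the MpACTIN 7
  normaliser used for organ-level Marchantia qPCR) is constant across
  organs; each target's Ct is offset by $-\log_2 RQ$ from a fixed baseline
  plus Gaussian noise (sd 0.15 cycles), with perfect doubling efficiency.
  Target expression is coupled to the cognate miRNA through
  $RQ_{raw} = 1/(1 + a\,\mathrm{RPM}/1000)$ with gain $a = 2$, which makes
  every miRNA–target pair inversely correlated by construction. Ground
  truth stores both the raw values and the calibrator-normalised values
  (Mv = 1), since $2^{-\Delta\Delta Ct}$ can only recover expression
  relative to the calibrator.

Identical configurations (including the seed) produce byte-identical files;
all per-stage random streams are derived deterministically from the master
seed.

## What passing tests do and do not show

The generator reproduces the statistical *structure* the analysis assumes —
organ-differential abundance, spiked 5'-end pileups, inverse coupling — but
not the texture of real data: no sequencing errors, no isomiRs, no RNA
secondary-structure accessibility effects, no partial degradation ladder,
no amplification-efficiency variation, and uniform background rather than
transcript-derived fragments. Recovery of planted truth therefore validates
the correctness of the computations, not the sensitivity or specificity of
the thresholds on real libraries.

# Numerical choices and degenerate inputs

* Cutting power uses round-half-up; R's banker's rounding would make
  0.5-boundary cases platform-convention-dependent.
* `callTargets()` keeps the canonical register on score ties with the +1
  register; candidate sorting is (score desc, category asc, penalty asc).
* All-zero degradome profiles reject the candidate with a signalled `NA`
  rather than an error; a zero-count position passed to `assignCategory()`
  is an error (no evidence of cleavage to rank).
* `starTest()` with two zero-variance groups returns $p = 1$ when the
  means are equal (no evidence of difference) and $p = 0$ otherwise, where
  the $t$ statistic is undefined.
* The Nussinov traceback tie-breaks toward 5'-most pairings, making
  dot-bracket output deterministic.
* Fractions in the region tiling use `floor` for the UTRs with the CDS
  absorbing the remainder, so the three intervals always tile exactly.

# Validation design and problem sizes

Unit tests run the generator at reduced scale (8 transcripts, 2 × 10⁴-read
libraries) and check every operation against an independent oracle:
dictionary counting for collapsing, per-position re-classification for
duplex penalties, exhaustive window scans for site search, brute-force
substring scans for tag mapping, rank-and-median re-derivation for
categories, enumeration of all nested structures for folding (≤ 18 nt), and
the explicit average-rank formula for Spearman. The end-to-end validation
uses the full default design: four-organ recovery of every planted module
at its exact cleavage position and region at seed 1, a 20-seed
recovery/decoy control on one degradome library per seed, RPM recovery on
three 10⁶-read libraries, and Ct recovery on the default tables. The ΔΔCt
tolerance (15%) is asserted per module as the mean absolute relative error
over the three non-calibrator organs: a per-organ assertion at these noise
settings (relative sd ≈ 8.5% = $0.15\sqrt{2/3}$ cycles on the log2 scale)
would be a ~1.6σ test that fails somewhere by chance in most runs, so the
module-level mean is the statistically sound reading of that tolerance.

# Known limitations

* Gapless duplexes only; bulged sites are invisible to the scan.
* Exact-match quantification and tag mapping; real data with errors or
  polymorphisms need external trimming/alignment (a per-position count TSV
  can be imported via `readDegradomeCounts()`).
* No multiple-testing correction (per-test stars only, as in the emulated
  design); no cleavage p-values.
* Spearman over four organ means has rank granularity; the inverse flag
  should be read together with the profiles it annotates.
* Base-pair maximisation can overestimate pairing relative to a
  thermodynamic fold; it screens plausibility, not stability.

# A worked example

```{r example}
cfg <- simulationConfig(seed = 7, nTranscripts = 10, librarySize = 50000L)
planted <- plantTargetSites(cfg, generateTranscriptome(cfg))
models <- planted$models
truth <- planted$truth

tags <- simulateDegradomeLibrary(cfg, models, truth, "Mv")
prof <- mapTags(tags, transcriptSeqs(models), "Mv")
res <- callTargets(mirnaSequences(truth), models, prof)
res$candidates[, c("mirna", "transcript_id", "cleavage_position",
                   "cutting_power", "category", "degradome_score", "region")]
```

```{r tplot, fig.width = 6, fig.height = 3.5}
tx <- res$candidates$transcript_id[1]
plotTplot(res$tplots[[tx]], tx)
```

```{r duplex}
ps <- plantedSites(truth)[1, ]
dup <- alignSite(as.character(mirnaSequences(truth))[ps$mirna],
                 transcriptSeqs(models)[[ps$transcript_id]],
                 ps$site_end, mirnaName = ps$mirna,
                 transcriptId = ps$transcript_id)
cat(duplexDiagram(dup), sep = "\n")
```
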
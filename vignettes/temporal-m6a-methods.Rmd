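---
title: "Methods: temporal m6A epitranscriptome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal m6A epitranscriptome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epitempo)
```

## The measurement and the model

MeRIP-seq quantifies m⁶A indirectly: methylated RNA fragments are
immunoprecipitated (IP) and sequenced alongside a matched input
library, and a transcript region is called methylated where the IP
read density exceeds the input density. `epitempo` treats the peak —
an interval called on this excess — as its unit of measurement and
computes, per peak *i* and biological sample *j*:

- IP FPKM `a = A·10⁹ / (B·C)` and input FPKM `b = D·10⁹ / (E·C)`,
  where `A`/`D` are the IP/input reads on the peak, `B`/`E` the total
  unique mapped reads of the respective library, and `C` the peak
  length in nt;
- the enrichment score `c = a / b`, the methylation-level proxy used
  throughout.

Both densities are normalized by library size and peak length, so `c`
is invariant to sequencing depth: scaling `(A, D, B, E)` by any factor
leaves it unchanged (a property the test suite asserts). When `D = 0`
the score is undefined; it is reported as `Inf` with a flag, kept for
presence calls but excluded from score distributions — input dropout
at a covered peak is evidence of enrichment, not of its absence.

A peak enters any comparative analysis only if it passes three strict
criteria: caller FDR < 0.05, IP FPKM > 1 and enrichment score > 1.5.
All inequalities in the package are strict exactly as written here;
boundary values (FDR = 0.05, score = 1.5, FPKM = 0.2, length = 70) are
rejected.

## Read preprocessing

Three criteria, applied per read in order: (1) truncation at the
leftmost occurrence of the adapter `AGATCGGAAG` with at most two
substitutions (Hamming distance; `N` never matches); (2) removal of
3′-terminal bases while their quality is below Q20; (3) retention iff
the remaining length exceeds 70 nt and more than 70% of remaining
bases exceed Q25 (`N` bases never count as high-quality). The
procedure is idempotent.

Whether the original filtering honored 3′ partial adapter overlaps is
not recoverable, so full-10-mer matching is the default and an
overlap mode (suffix of length k ≥ 5 matching an adapter prefix with
⌊2k/10⌋ mismatches) is available as an option.

## Transcript model and the two partitions

All positional analyses use a reference transcriptome of the longest
transcript per gene (summed exon length; ties break to the
lexicographically smaller transcript id, making selection
deterministic). Genomic intervals are handled as `GRanges` (1-based
closed, the Bioconductor convention); transcript-coordinate
arithmetic is 0-based half-open. CDS annotations are taken to include
the stop codon, so the stop-codon anchor is the third-from-last CDS
base.

Two different partitions serve two different analyses:

1. **Metagene profile**: 5′UTR, CDS and 3′UTR are each stretched into
   100 equal bins (bin = ⌊fraction·100⌋, capped at 99) and the
   percentage of peaks per bin is reported, summing to 100% (an
   optional per-profile max normalization is provided, since published
   "normalized distribution" curves are ambiguous between the two).
2. **Five-region counts**: 300-nt windows centered on the start and
   stop codons are carved out of the transcript, leaving 5′UTR, CDS
   and 3′UTR residues. "Centered on" a 3-nt codon needs an anchor
   convention: the window is anchored at the codon's first nucleotide
   (anchor−150 to anchor+150), which keeps the codon inside its window
   and matches common practice. When a short CDS (< 303 nt) makes the
   windows overlap, each position goes to the nearer anchor, ties to
   the start region, so the five regions are always disjoint and cover
   the transcript — an invariant asserted per partition and verified
   against a per-nucleotide brute-force labeler.

A peak is represented by its genomic midpoint projected through the
exon chain; an intronic midpoint moves to the nearest exonic position
within the peak's exonic overlap, and peaks without same-strand exonic
overlap are unassigned with a reason code. Non-coding transcripts are
excluded from metagene and region counting but keep their methylation
calls.

## Temporal comparison

Retained peaks from all stages are merged into an atlas by
strand-aware single-linkage union (overlapping or bookended intervals
merge, as `mergeBed` with default distance). A stage is *present* at a
merged peak iff ≥ 1 nt of a same-strand retained peak of that stage
overlaps it — the merge defines the interval, presence needs no
additional threshold. ON switches are absent→present transitions
between adjacent stages, OFF the reverse; a peak can switch at several
transitions. RNAs are classified from their per-stage methylation
profile (≥ 1 retained peak on the RNA): CMR at all stages, SMR at
exactly one, `other` in between, `unmethylated` at none — mutually
exclusive by construction.

The "significance" gate for a peak participating in switches is the
retention filter itself (caller FDR < 0.05 plus enrichment score >
1.5); the package reads the reported switch threshold "P < 0.05" as
the caller's significance rather than a second test.

## Differential methylation

Between conditions over a common atlas, the methylation change is
`log2(c_KO / c_WT)`; significance comes from Fisher's exact test on
the 2×2 table of IP and input counts with input counts scaled to the
IP library size (`D' = round(D·B/E)`), then BH adjustment. This is a
deliberately simple stand-in for a dedicated MeRIP GLM: the decision
thresholds (FDR < 0.05, |log₂FC| > 1) are unchanged, and the test's
job — ranking deep-count ratio changes — is one Fisher handles well.
Peaks retained in only one condition bypass the fold-change route and
are called gain (KO only) or loss (WT only); both peak-level and
RNA-level reports are emitted because a published gain/loss–DMR
intersection can be read at either level.

## Expression and the correlation screen

FPKM = count·10⁹/(library·length); transcripts are expressed at
FPKM > 0.2 (strict). The methylation level of an RNA at a stage is the
maximum enrichment score of its retained peaks (mean is available; max
is the default because a single strong site is what the IP measures
most reliably), and stages without a retained peak contribute 0 so
every RNA has a complete 4-point trajectory. Pearson r across the four
stages with two-sided P from t at 2 degrees of freedom; positive pairs
need r > 0.95 and P < 0.05, negative r < −0.95 and P < 0.05.
Zero-variance trajectories are skipped, not classified. At n = 4 the
null distribution of r is uniform on [−1, 1], so the analytic null
tail of the screen is exactly 0.05 — a calibration the tests check by
simulation.

## The synthetic study

The generator emulates the study design the analysis assumes: four
stages × two conditions, paired IP/input libraries, one library per
stage and condition (published MeRIP time courses often pool animals
per library; no replicate structure is modeled). Defaults, chosen once
as a realistic desk-scale study:

- 1,000 genes on 20 chromosomes, transcripts 0.9–3 kb with 1–4 exons
  (each ≥ 200 nt), 5% non-coding, 10% with a second shorter transcript
  to exercise longest-transcript selection, 2% below the expression
  cutoff at all stages;
- methylation classes: 35% CMR, 20% SMR (uniform over stages), 20%
  switching (one ON or OFF transition with ≥ 2 methylated stages —
  single-stage patterns are reserved for SMRs so the planted classes
  stay mutually exclusive), 25% unmethylated; the remainder, if
  proportions sum below 1, gets multi-switch patterns;
- enrichment factors uniform in 3–10 at methylated gene-stages, 1
  elsewhere; planted peaks 100–300 nt (MeRIP fragments are ~100–150
  nt, so peaks span a few fragment widths), placed within a single
  exon — the BED6 peak interface is single-block, so splice-spanning
  peak blocks are out of scope;
- knockout perturbations at P7: 5% each of hyper (×4), hypo (÷4, with
  the WT factor drawn high so the KO peak stays above the retention
  threshold), gain and loss;
- expression lognormal around 20 FPKM; 20% of CMR genes are planted as
  tracking genes (80% positive / 20% negative, echoing the observed
  predominance of positive correlations) whose FPKM is an affine
  function of their stage-varying enrichment factor with 2%
  multiplicative noise. Tracking genes are planted in the
  well-expressed tier (~200 FPKM): a 4-point screen at |r| > 0.95 is
  only powered where counting noise is a few percent, which is also
  true of real data.

Counts are Poisson by default (negative binomial optional): the input
count of a peak is proportional to expression and peak length
(calibrated so a reference-expression gene yields ~60 input reads per
peak, i.e. mean peak coverage above 50), and the IP count uses the
same rate times the planted factor. Library totals are recorded as the
configured nominal depth for IP and input alike — sequencing runs are
depth-matched by design — so the enrichment score is an unbiased
estimator of the planted factor, which is what makes factor-recovery
tests meaningful.

What the generator does **not** model: alignment artifacts, PCR
duplicates, sequence motifs (no UGGACU placement), splice-aware reads,
replicate variance, or antibody specificity. Passing recovery tests
therefore demonstrates that the analysis logic is correct under its
own statistical assumptions, not that those assumptions hold for any
particular real library.

## Numerical and edge-case choices

- `A = D = 0`: score undefined (NA); `A = 0, D > 0`: score 0;
  `A > 0, D = 0`: `Inf`, flagged.
- Read counting: a read counts toward a peak iff ≥ 50% of its length
  overlaps (inclusive, like bedtools `-F 0.50`) on the same strand;
  split reads contribute summed block overlaps.
- The internal sliding-window caller (100-nt windows, 50-nt step,
  one-sided conditional binomial per window with p₀ = B/(B+E), BH
  across windows, significant runs merged) is plumbing: it exists so
  the pipeline runs without an external caller, and externally called
  peaks with FDR are accepted everywhere.
- Problem sizes in the tests and the acceptance script — 1,000 genes
  for recovery, 50,000 reads for preprocessing, 200 transcripts for
  the partition oracle, 200 null replicates for calibration — are the
  package's validation defaults; they give Monte-Carlo error well
  below the 0.9 recovery margins while keeping a run in minutes on one
  core.

## Known limitations

Single-nucleotide m⁶A positions are beyond peak-level IP data; peak
calling itself (the GLM of dedicated callers) is out of scope, as are
differential expression testing, clustering/heatmaps and enrichment
annotation. The correlation screen with four time points has low power
and an appreciable false-positive rate at the 0.05 tail; it is a
screen, not an inference.
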
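#' Peak-level IP/input FPKM and enrichment score
#'
#' For peak i in library j, with A = IP reads on the peak, B = total
#' unique mapped IP reads, C = peak length (nt), D = input reads on the
#' peak and E = total unique mapped input reads:
#' \deqn{a = A \cdot 10^9 / (B C), \quad b = D \cdot 10^9 / (E C), \quad c = a / b}
#' `a` is the peak IP FPKM, `b` the input FPKM and `c` the enrichment
#' score (the methylation-level proxy). All arguments are vectorized.
#'
#' @param A,D Non-negative read counts on the peak (IP, input).
#' @param C Peak length in nt (> 0).
#' @param B,E Library totals of unique mapped reads (> 0).
#' @return data.frame with columns `a`, `b`, `c` and `c_defined`. When
#'   D = 0 and A > 0, `c` is `Inf` and `c_defined` is FALSE (the peak
#'   stays eligible for presence calls but is excluded from score
#'   distributions); when A = D = 0, `c` is NA and undefined.
#' @export
quantify_peak <- function(A, D, C, B, E) {
  n <- max(length(A), length(D), length(C), length(B), length(E))
  A <- rep_len(A, n); D <- rep_len(D, n); C <- rep_len(C, n)
  B <- rep_len(B, n); E <- rep_len(E, n)
  if (any(C <= 0)) stop("peak length C must be > 0")
  if (any(B <= 0) || any(E <= 0)) stop("library totals B and E must be > 0")
  if (any(A < 0) || any(D < 0)) stop("counts must be non-negative")
  a <- A * 1e9 / (B * C)
  b <- D * 1e9 / (E * C)
  c <- ifelse(D > 0, a / b, ifelse(A > 0, Inf, NA_real_))
  c[A == 0 & D > 0] <- 0
  data.frame(a = a, b = b, c = c, c_defined = D > 0)
}

#' One-sided enrichment test of IP vs input counts for a region
#'
#' Conditional binomial test: given n = A + D reads on the region, A is
#' Binomial(n, p0) under no enrichment, with p0 = B/(B+E) the IP share
#' of the combined library. Returns P(X >= A), one-sided toward
#' enrichment. Used both by the candidate caller (per window) and to
#' attach a per-sample significance to externally supplied peaks.
#'
#' @param A,D Read counts (IP, input) on the region; vectorized.
#' @param B,E Library totals.
#' @return Numeric vector of one-sided P values (1 where A + D = 0).
#' @export
test_peak_enrichment <- function(A, D, B, E) {
  n <- max(length(A), length(D), length(B), length(E))
  A <- rep_len(A, n); D <- rep_len(D, n)
  B <- rep_len(B, n); E <- rep_len(E, n)
  p0 <- B / (B + E)
  p <- stats::pbinom(A - 1, A + D, p0, lower.tail = FALSE)
  p[A + D == 0] <- 1
  p
}

#' Retain peaks by the three retention criteria
#'
#' A peak is kept iff (1) its caller FDR < 0.05, (2) its IP FPKM > 1
#' and (3) its enrichment score > 1.5 — all inequalities strict. Peaks
#' with missing FDR are rejected.
#'
#' @param quant data.frame with columns `fdr`, `a`, `c` (as from
#'   [quantify_peak()] plus an FDR column).
#' @param fdr_max,ip_fpkm_min,score_min Thresholds (defaults as stated).
#' @return The input with a logical `retained` column and a `reject`
#'   reason column; the per-criterion rejection tally is attached as
#'   `attr(, "tally")`.
#' @export
filter_peaks <- function(quant, fdr_max = 0.05, ip_fpkm_min = 1, score_min = 1.5) {
  fdr_ok <- !is.na(quant$fdr) & quant$fdr < fdr_max
  a_ok <- quant$a > ip_fpkm_min
  c_ok <- !is.na(quant$c) & quant$c > score_min
  quant$retained <- fdr_ok & a_ok & c_ok
  reason <- rep(NA_character_, nrow(quant))
  reason[!c_ok] <- "enrichment_score"
  reason[!a_ok] <- "ip_fpkm"
  reason[!fdr_ok] <- "fdr"
  reason[is.na(quant$fdr)] <- "missing_fdr"
  reason[quant$retained] <- NA_character_
  quant$reject <- reason
  attr(quant, "tally") <- c(
    n = nrow(quant),
    retained = sum(quant$retained),
    fail_fdr = sum(!fdr_ok),
    fail_ip_fpkm = sum(!a_ok),
    fail_score = sum(!c_ok)
  )
  quant
}

#' Count reads over intervals with coverageBed-like semantics
#'
#' A read is counted toward a peak iff at least `min_overlap_frac` of
#' the read's length overlaps the peak (inclusive, as bedtools
#' `-F 0.50`) and, when `same_strand`, the strands match (`-s`). Split
#' reads supplied as a `GRangesList` contribute their summed block-wise
#' overlap (`-split`). A read may count toward several peaks.
#'
#' @param peaks `GRanges` of peaks.
#' @param reads `GRanges` (one range per read) or `GRangesList` (blocks
#'   per read).
#' @param min_overlap_frac Minimum overlapping fraction of the read.
#' @param same_strand Require matching strands.
#' @return Integer vector of counts, one per peak.
#' @export
count_reads_in_intervals <- function(peaks, reads, min_overlap_frac = 0.5,
                                     same_strand = TRUE) {
  if (methods::is(reads, "GRangesList")) {
    blocks <- BiocGenerics::unlist(reads, use.names = FALSE)
    read_id <- rep(seq_along(reads), lengths(reads))
    read_len <- as.integer(sum(GenomicRanges::width(reads)))
  } else {
    blocks <- reads
    read_id <- seq_along(reads)
    read_len <- GenomicRanges::width(reads)
  }
  if (same_strand && any(BiocGenerics::strand(blocks) == "*")) {
    stop("strandless reads with same_strand = TRUE")
  }
  hits <- GenomicRanges::findOverlaps(blocks, peaks, ignore.strand = !same_strand)
  if (length(hits) == 0) return(integer(length(peaks)))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- pmin(GenomicRanges::end(blocks)[qh], GenomicRanges::end(peaks)[sh]) -
    pmax(GenomicRanges::start(blocks)[qh], GenomicRanges::start(peaks)[sh]) + 1L
  key <- paste(read_id[qh], sh)
  tot <- tapply(ov, key, sum)
  ids <- strsplit(names(tot), " ", fixed = TRUE)
  rid <- as.integer(vapply(ids, `[`, "", 1L))
  pid <- as.integer(vapply(ids, `[`, "", 2L))
  keep <- as.numeric(tot) >= min_overlap_frac * read_len[rid]
  counts <- tabulate(pid[keep], nbins = length(peaks))
  as.integer(counts)
}

#' Sliding-window candidate peak caller (plumbing)
#'
#' A deliberately simple stand-in for a dedicated MeRIP peak caller:
#' fixed windows are tiled along each reference transcript, IP and
#' input reads are counted per window with [count_reads_in_intervals()]
#' semantics, each window gets the one-sided conditional binomial P of
#' [test_peak_enrichment()], P values are BH-adjusted across all
#' windows, and runs of significant windows are merged into candidate
#' peaks (peak FDR = min window FDR). Externally called peaks
#' (BED6 + FDR) are accepted everywhere downstream as an alternative.
#'
#' @param ip_reads,input_reads Stranded `GRanges` of read intervals.
#' @param models Reference `transcript_models` (one transcript/gene).
#' @param window,step Window width and step in nt (transcript coords).
#' @param fdr_max Window significance cutoff after BH.
#' @param B,E Library totals; default the number of supplied reads.
#' @return `GRanges` of candidate peaks (genomic span of the merged
#'   windows) with mcols `transcript_id`, `fdr`, `n_windows`.
#' @export
call_candidate_peaks <- function(ip_reads, input_reads, models,
                                 window = 100L, step = 50L, fdr_max = 0.05,
                                 B = length(ip_reads), E = length(input_reads)) {
  if (length(ip_reads) == 0 || length(input_reads) == 0) {
    stop("empty IP or input library")
  }
  tx <- models$tx
  win_tab <- do.call(rbind, lapply(seq_len(nrow(tx)), function(i) {
    L <- tx$total_length[i]
    starts <- seq(0L, max(0L, L - window), by = step)
    data.frame(transcript_id = tx$transcript_id[i], tstart = starts,
               tend = pmin(starts + window, L), stringsAsFactors = FALSE)
  }))
  # genomic blocks per window
  blocks <- vector("list", nrow(win_tab))
  for (w in seq_len(nrow(win_tab))) {
    tid <- win_tab$transcript_id[w]
    e <- tx_exons(models, tid)
    lo <- win_tab$tstart[w]; hi <- win_tab$tend[w]
    ov_lo <- pmax(lo, e$toffset)
    ov_hi <- pmin(hi, e$toffset + e$width)
    k <- which(ov_hi > ov_lo)
    g1 <- vapply(k, function(j) tx_to_genomic(models, tid, ov_lo[j]), 1L)
    g2 <- vapply(k, function(j) tx_to_genomic(models, tid, ov_hi[j] - 1L), 1L)
    blocks[[w]] <- GenomicRanges::GRanges(
      e$chrom[1],
      IRanges::IRanges(pmin(g1, g2), pmax(g1, g2)),
      strand = e$strand[1]
    )
  }
  wgrl <- GenomicRanges::GRangesList(blocks)
  # count reads against window block sets (roles swapped: fraction is of the read)
  A <- count_blocks_reads(wgrl, ip_reads)
  D <- count_blocks_reads(wgrl, input_reads)
  p <- test_peak_enrichment(A, D, B, E)
  fdr <- stats::p.adjust(p, method = "BH")
  win_tab$A <- A; win_tab$D <- D; win_tab$p <- p; win_tab$fdr <- fdr
  sig <- win_tab[fdr < fdr_max, , drop = FALSE]
  if (nrow(sig) == 0) {
    return(GenomicRanges::GRanges(transcript_id = character(),
                                  fdr = numeric(), n_windows = integer()))
  }
  out <- list()
  for (tid in unique(sig$transcript_id)) {
    s <- sig[sig$transcript_id == tid, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(s$tstart + 1L, s$tend))
    e <- tx_exons(models, tid)
    for (k in seq_along(ir)) {
      lo <- IRanges::start(ir)[k] - 1L; hi <- IRanges::end(ir)[k]
      g1 <- tx_to_genomic(models, tid, lo)
      g2 <- tx_to_genomic(models, tid, hi - 1L)
      memb <- s$tstart >= lo - 1L & s$tend <= hi
      out[[length(out) + 1L]] <- GenomicRanges::GRanges(
        e$chrom[1], IRanges::IRanges(min(g1, g2), max(g1, g2)),
        strand = e$strand[1], transcript_id = tid,
        fdr = min(s$fdr[memb]), n_windows = sum(memb)
      )
    }
  }
  do.call(c, out)
}

# count reads (GRanges) against a GRangesList of window block sets:
# read counts for a window iff >= 50% of the read overlaps the union
# of the window's blocks on the same strand
count_blocks_reads <- function(window_blocks, reads, min_overlap_frac = 0.5) {
  blocks <- BiocGenerics::unlist(window_blocks, use.names = FALSE)
  win_id <- rep(seq_along(window_blocks), lengths(window_blocks))
  hits <- GenomicRanges::findOverlaps(reads, blocks, ignore.strand = FALSE)
  n <- length(window_blocks)
  if (length(hits) == 0) return(integer(n))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(reads[qh], blocks[sh]))
  key <- paste(qh, win_id[sh])
  tot <- tapply(ov, key, sum)
  ids <- strsplit(names(tot), " ", fixed = TRUE)
  rid <- as.integer(vapply(ids, `[`, "", 1L))
  wid <- as.integer(vapply(ids, `[`, "", 2L))
  keep <- as.numeric(tot) >= min_overlap_frac * GenomicRanges::width(reads)[rid]
  as.integer(tabulate(wid[keep], nbins = n))
}

#' Compare two enrichment-score distributions (Wilcoxon rank-sum)
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test with mid-ranked ties,
#' as used to compare peak enrichment-score (or log2 FPKM)
#' distributions between samples. Non-finite scores are dropped.
#'
#' @param scores_x,scores_y Numeric vectors (each >= 2 finite values).
#' @return list with `statistic` (W), `p.value`, `n_x`, `n_y`.
#' @export
compare_enrichment_distributions <- function(scores_x, scores_y) {
  x <- scores_x[is.finite(scores_x)]
  y <- scores_y[is.finite(scores_y)]
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 finite values per group")
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       n_x = length(x), n_y = length(y))
}
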
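#' Assign peaks to reference transcripts and transcript positions
#'
#' Each peak is paired with the same-strand reference transcript whose
#' exons it overlaps most (exonic overlap in nt). The peak's
#' representative point is its genomic midpoint projected through the
#' exon structure; a midpoint falling in an intron is moved to the
#' nearest exonic position within the peak's exonic overlap. Peaks with
#' no same-strand exonic overlap are unassigned.
#'
#' @param peaks `GRanges` of peaks (a `name`/`merged_id` column is
#'   carried through as `peak_id` when present).
#' @param models Reference `transcript_models` (one transcript per gene).
#' @return data.frame: peak_id, transcript_id, gene_id, tx_pos (0-based
#'   transcript offset; NA when unassigned), status
#'   ("assigned"/"unassigned"), reason.
#' @export
locate_peaks_on_transcripts <- function(peaks, models) {
  pid <- if (!is.null(peaks$peak_id)) as.character(peaks$peak_id)
         else if (!is.null(peaks$merged_id)) as.character(peaks$merged_id)
         else if (!is.null(peaks$name)) as.character(peaks$name)
         else paste0("peak_", seq_along(peaks))
  ex <- models$exons
  exg <- GenomicRanges::GRanges(ex$chrom,
                                IRanges::IRanges(ex$gstart, ex$gend),
                                strand = ex$strand)
  hits <- GenomicRanges::findOverlaps(peaks, exg, ignore.strand = FALSE)
  # wrong-strand exonic overlap gets its own reason
  wrong <- setdiff(
    S4Vectors::queryHits(GenomicRanges::findOverlaps(peaks, exg,
                                                     ignore.strand = TRUE)),
    S4Vectors::queryHits(hits))
  base_reason <- rep("no_exonic_overlap", length(peaks))
  base_reason[wrong] <- "strand_mismatch"
  if (length(hits) == 0) {
    return(data.frame(
      peak_id = pid, transcript_id = NA_character_, gene_id = NA_character_,
      tx_pos = NA_integer_, status = "unassigned",
      reason = base_reason, stringsAsFactors = FALSE
    ))
  }
  ov <- GenomicRanges::width(GenomicRanges::pintersect(
    peaks[S4Vectors::queryHits(hits)], exg[S4Vectors::subjectHits(hits)]))
  # best transcript per peak by total exonic overlap
  key <- paste(S4Vectors::queryHits(hits),
               ex$transcript_id[S4Vectors::subjectHits(hits)])
  tot <- tapply(ov, key, sum)
  parts <- strsplit(names(tot), " ", fixed = TRUE)
  cand <- data.frame(
    peak = as.integer(vapply(parts, `[`, "", 1L)),
    transcript_id = vapply(parts, `[`, "", 2L),
    overlap = as.numeric(tot), stringsAsFactors = FALSE
  )
  cand <- cand[order(cand$peak, -cand$overlap, cand$transcript_id), ]
  cand <- cand[!duplicated(cand$peak), ]

  out <- data.frame(
    peak_id = pid,
    transcript_id = NA_character_,
    gene_id = NA_character_,
    tx_pos = NA_integer_,
    status = "unassigned",
    reason = base_reason,
    stringsAsFactors = FALSE
  )
  gid <- models$tx$gene_id[match(cand$transcript_id, models$tx$transcript_id)]
  out$transcript_id[cand$peak] <- cand$transcript_id
  out$gene_id[cand$peak] <- gid

  for (r in seq_len(nrow(cand))) {
    i <- cand$peak[r]
    tid <- cand$transcript_id[r]
    mid <- GenomicRanges::start(peaks)[i] +
      (GenomicRanges::width(peaks)[i] - 1L) %/% 2L
    tp <- genomic_to_tx(models, tid, mid)
    if (is.na(tp)) {
      # intronic midpoint: nearest exonic genomic position inside the
      # peak's exonic overlap
      e <- tx_exons(models, tid)
      exr <- IRanges::IRanges(e$gstart, e$gend)
      pkr <- IRanges::IRanges(GenomicRanges::start(peaks)[i],
                              GenomicRanges::end(peaks)[i])
      ovr <- IRanges::intersect(exr, pkr)
      if (length(ovr) == 0) next
      cands <- c(IRanges::start(ovr), IRanges::end(ovr))
      g <- cands[which.min(abs(cands - mid))]
      tp <- genomic_to_tx(models, tid, g)
    }
    out$tx_pos[i] <- tp
    out$status[i] <- "assigned"
    out$reason[i] <- NA_character_
  }
  out
}

#' Metagene bin of a transcript position (0..299)
#'
#' 5'UTR, CDS and 3'UTR are each stretched to 100 equal bins
#' (segment-relative binning); the bin index is
#' floor(fraction * 100) capped at 99, offset by 0/100/200 for
#' 5'UTR/CDS/3'UTR. Zero-length segments contain no positions and so
#' contribute empty bins.
#'
#' @param tpos 0-based transcript offsets.
#' @param utr5_len,cds_len,utr3_len Segment lengths (same length as
#'   `tpos` or scalars).
#' @return Integer bin in 0..299.
#' @export
metagene_bin <- function(tpos, utr5_len, cds_len, utr3_len) {
  n <- length(tpos)
  u5 <- rep_len(utr5_len, n); cd <- rep_len(cds_len, n); u3 <- rep_len(utr3_len, n)
  if (any(tpos < 0 | tpos >= u5 + cd + u3)) stop("position outside transcript")
  seg <- ifelse(tpos < u5, 0L, ifelse(tpos < u5 + cd, 1L, 2L))
  off <- ifelse(seg == 0L, tpos, ifelse(seg == 1L, tpos - u5, tpos - u5 - cd))
  len <- ifelse(seg == 0L, u5, ifelse(seg == 1L, cd, u3))
  as.integer(seg * 100L + pmin(99L, floor(off / len * 100)))
}

#' Metagene peak-distribution profile over 300 bins
#'
#' Computes the percentage of assigned peaks per bin across the
#' 5'UTR/CDS/3'UTR segments of coding reference transcripts (100 bins
#' each). Peaks on non-coding transcripts are excluded.
#'
#' @param located Output of [locate_peaks_on_transcripts()] (assigned
#'   rows are used).
#' @param models Reference `transcript_models`.
#' @param normalize `"sum"` (default; bins sum to 100%) or `"max"`
#'   (per-profile peak normalization to 100 at the modal bin).
#' @return list with `profile` (data.frame: bin 0..299, segment,
#'   percent) and `n_peaks`.
#' @export
metagene_distribution <- function(located, models, normalize = c("sum", "max")) {
  normalize <- match.arg(normalize)
  ok <- located$status == "assigned"
  loc <- located[ok, , drop = FALSE]
  i <- match(loc$transcript_id, models$tx$transcript_id)
  coding <- models$tx$coding[i]
  loc <- loc[coding, , drop = FALSE]; i <- i[coding]
  bins <- metagene_bin(loc$tx_pos, models$tx$utr5_len[i],
                       models$tx$cds_len[i], models$tx$utr3_len[i])
  counts <- tabulate(bins + 1L, nbins = 300L)
  n <- sum(counts)
  pct <- if (n == 0) rep(0, 300) else counts / n * 100
  if (normalize == "max" && max(pct) > 0) pct <- pct / max(pct) * 100
  seg <- rep(c("utr5", "cds", "utr3"), each = 100)
  list(profile = data.frame(bin = 0:299, segment = seg, percent = pct),
       n_peaks = n)
}

#' Count peaks in the five transcript regions
#'
#' Labels each assigned peak position with the carved five-region
#' partition (5'UTR, start codon region, CDS, stop codon region,
#' 3'UTR) of its host transcript and tallies counts, optionally per
#' group (stage, methylation class, ...). Peaks on non-coding
#' transcripts are excluded and reported.
#'
#' @param located Output of [locate_peaks_on_transcripts()].
#' @param partition Output of [partition_regions()].
#' @param group Optional grouping vector parallel to `located` rows.
#' @return list with `counts` (data.frame: group, region, n),
#'   `region` (factor per input row; NA for excluded rows), and
#'   `n_excluded`.
#' @export
count_region_peaks <- function(located, partition, group = NULL) {
  if (is.null(group)) group <- rep("all", nrow(located))
  region <- factor(rep(NA_character_, nrow(located)), levels = REGION_LEVELS)
  use <- located$status == "assigned" &
    located$transcript_id %in% partition$transcript_id
  for (i in which(use)) {
    region[i] <- label_tx_positions(partition, located$tx_pos[i],
                                    located$transcript_id[i])
  }
  tab <- table(group = group[use], region = region[use])
  counts <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(counts) <- c("group", "region", "n")
  list(counts = counts, region = region, n_excluded = sum(!use))
}
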
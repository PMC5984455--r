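#' Build transcript models from a GTF annotation
#'
#' Groups `exon` and `CDS` features by transcript and derives, for each
#' transcript, its exon structure in transcript (5'->3') order plus the
#' UTR/CDS segmentation in transcript coordinates. CDS features are
#' expected to include the stop codon, so the stop-codon anchor is the
#' third-from-last CDS base.
#'
#' Genomic coordinates are 1-based closed (`GRanges` convention);
#' transcript coordinates are 0-based half-open throughout.
#'
#' @param gtf A `GRanges` from [read_gtf()] or a GTF file path.
#' @return An object of class `transcript_models`: a list with
#'   \describe{
#'     \item{tx}{data.frame: transcript_id, gene_id, chrom, strand,
#'       n_exons, total_length, utr5_len, cds_len, utr3_len, coding.}
#'     \item{exons}{data.frame: transcript_id, rank (transcript order),
#'       gstart, gend, width, toffset (transcript offset of the exon's
#'       first base).}
#'   }
#' @export
transcript_models <- function(gtf) {
  if (is.character(gtf)) gtf <- read_gtf(gtf)
  ex <- gtf[gtf$type == "exon"]
  if (length(ex) == 0) stop("annotation contains no exon features")
  cds <- gtf[gtf$type == "CDS"]

  exd <- data.frame(
    transcript_id = as.character(ex$transcript_id),
    gene_id = as.character(ex$gene_id),
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(BiocGenerics::strand(ex)),
    gstart = GenomicRanges::start(ex),
    gend = GenomicRanges::end(ex),
    stringsAsFactors = FALSE
  )
  exd <- exd[order(exd$transcript_id, exd$gstart), ]
  # validate non-overlap within transcript
  by_tx <- split(seq_len(nrow(exd)), exd$transcript_id)
  for (idx in by_tx) {
    if (length(idx) > 1) {
      s <- exd$gstart[idx]; e <- exd$gend[idx]
      if (any(s[-1] <= e[-length(e)])) {
        stop("overlapping exons in transcript ", exd$transcript_id[idx[1]])
      }
    }
  }
  # transcript order: minus strand reverses genomic order
  ord <- unlist(lapply(by_tx, function(idx) {
    if (exd$strand[idx[1]] == "-") rev(idx) else idx
  }), use.names = FALSE)
  exd <- exd[ord, ]
  exd$width <- exd$gend - exd$gstart + 1L
  exd$rank <- unlist(lapply(split(exd$transcript_id, exd$transcript_id)[unique(exd$transcript_id)],
                            seq_along), use.names = FALSE)
  # toffset: cumulative width within transcript, in transcript order
  exd$toffset <- unlist(lapply(split(exd$width, factor(exd$transcript_id, levels = unique(exd$transcript_id))),
                               function(w) cumsum(c(0L, w[-length(w)]))), use.names = FALSE)

  first <- !duplicated(exd$transcript_id)
  tx <- data.frame(
    transcript_id = exd$transcript_id[first],
    gene_id = exd$gene_id[first],
    chrom = exd$chrom[first],
    strand = exd$strand[first],
    stringsAsFactors = FALSE
  )
  tl <- tapply(exd$width, exd$transcript_id, sum)
  ne <- tapply(exd$width, exd$transcript_id, length)
  tx$n_exons <- as.integer(ne[tx$transcript_id])
  tx$total_length <- as.integer(tl[tx$transcript_id])

  tx$utr5_len <- 0L; tx$cds_len <- 0L; tx$utr3_len <- tx$total_length
  tx$coding <- FALSE
  if (length(cds) > 0) {
    cdd <- data.frame(
      transcript_id = as.character(cds$transcript_id),
      gstart = GenomicRanges::start(cds),
      gend = GenomicRanges::end(cds),
      stringsAsFactors = FALSE
    )
    models_stub <- list(tx = tx, exons = exd)
    for (tid in unique(cdd$transcript_id)) {
      i <- which(tx$transcript_id == tid)
      if (!length(i)) next
      rows <- cdd[cdd$transcript_id == tid, ]
      clen <- sum(rows$gend - rows$gstart + 1L)
      # transcript offset of the CDS 5' end
      g5 <- if (tx$strand[i] == "+") min(rows$gstart) else max(rows$gend)
      off <- genomic_to_tx(models_stub, tid, g5)
      if (is.na(off)) stop("CDS outside exons for transcript ", tid)
      tx$utr5_len[i] <- as.integer(off)
      tx$cds_len[i] <- as.integer(clen)
      tx$utr3_len[i] <- tx$total_length[i] - tx$utr5_len[i] - tx$cds_len[i]
      tx$coding[i] <- TRUE
      if (tx$utr3_len[i] < 0) stop("CDS longer than transcript ", tid)
    }
  }
  structure(list(tx = tx, exons = exd), class = "transcript_models")
}

#' @export
print.transcript_models <- function(x, ...) {
  cat("transcript_models:", nrow(x$tx), "transcripts,",
      length(unique(x$tx$gene_id)), "genes,",
      sum(x$tx$coding), "coding\n")
  invisible(x)
}

#' Select the reference (longest) transcript of each gene
#'
#' The reference transcriptome keeps, per gene, the transcript with the
#' largest summed exon length; ties break to the lexicographically
#' smallest transcript_id. Genes whose transcripts have no exons never
#' reach this point (rejected at model building).
#'
#' @param models A `transcript_models` object.
#' @return A `transcript_models` containing one transcript per gene.
#' @export
select_reference_transcripts <- function(models) {
  tx <- models$tx
  tx <- tx[order(tx$gene_id, -tx$total_length, tx$transcript_id), ]
  keep <- tx$transcript_id[!duplicated(tx$gene_id)]
  subset_models(models, keep)
}

subset_models <- function(models, transcript_ids) {
  structure(list(
    tx = models$tx[models$tx$transcript_id %in% transcript_ids, , drop = FALSE],
    exons = models$exons[models$exons$transcript_id %in% transcript_ids, , drop = FALSE]
  ), class = "transcript_models")
}

tx_row <- function(models, transcript_id) {
  i <- match(transcript_id, models$tx$transcript_id)
  if (is.na(i)) stop("unknown transcript ", transcript_id)
  models$tx[i, ]
}

tx_exons <- function(models, transcript_id) {
  e <- models$exons[models$exons$transcript_id == transcript_id, , drop = FALSE]
  e[order(e$rank), , drop = FALSE]
}

#' Project genomic positions onto transcript coordinates
#'
#' @param models A `transcript_models` object.
#' @param transcript_id One transcript id.
#' @param gpos Vector of genomic positions (1-based).
#' @return Integer vector of 0-based transcript offsets; NA where a
#'   position falls outside the transcript's exons.
#' @export
genomic_to_tx <- function(models, transcript_id, gpos) {
  e <- tx_exons(models, transcript_id)
  minus <- e$strand[1] == "-"
  out <- rep(NA_integer_, length(gpos))
  for (k in seq_len(nrow(e))) {
    hit <- which(gpos >= e$gstart[k] & gpos <= e$gend[k])
    if (length(hit)) {
      out[hit] <- if (minus) e$toffset[k] + (e$gend[k] - gpos[hit])
                  else e$toffset[k] + (gpos[hit] - e$gstart[k])
    }
  }
  as.integer(out)
}

#' Project transcript offsets onto genomic positions
#'
#' @param models A `transcript_models` object.
#' @param transcript_id One transcript id.
#' @param tpos Vector of 0-based transcript offsets.
#' @return Integer vector of genomic positions (1-based); NA where the
#'   offset exceeds the transcript length.
#' @export
tx_to_genomic <- function(models, transcript_id, tpos) {
  e <- tx_exons(models, transcript_id)
  minus <- e$strand[1] == "-"
  out <- rep(NA_integer_, length(tpos))
  for (k in seq_len(nrow(e))) {
    hit <- which(tpos >= e$toffset[k] & tpos < e$toffset[k] + e$width[k])
    if (length(hit)) {
      d <- tpos[hit] - e$toffset[k]
      out[hit] <- if (minus) e$gend[k] - d else e$gstart[k] + d
    }
  }
  as.integer(out)
}

#' Carve the five-region partition of coding transcripts
#'
#' The start (stop) codon region is the 300-nt transcript window centered
#' on the first base of the start (stop) codon, truncated at transcript
#' ends. When a short CDS makes the two windows overlap, positions are
#' assigned to the window with the nearer anchor, ties to the start
#' region. 5'UTR, CDS and 3'UTR are the residues left after carving.
#' All bounds are 0-based half-open transcript coordinates.
#'
#' @param models A `transcript_models` object (coding transcripts only
#'   are partitioned; non-coding transcripts are dropped with a message).
#' @param window Total codon-window width in nt (default 300).
#' @return data.frame with one row per coding transcript: bounds
#'   `utr5_lo/hi`, `start_lo/hi`, `cds_lo/hi`, `stop_lo/hi`,
#'   `utr3_lo/hi`, plus `cds_start` and `stop_anchor`.
#' @export
partition_regions <- function(models, window = 300L) {
  tx <- models$tx
  nc <- sum(!tx$coding)
  if (nc > 0) message(nc, " non-coding transcript(s) excluded from region partition")
  tx <- tx[tx$coding, , drop = FALSE]
  half <- window %/% 2L
  L <- tx$total_length
  u5 <- tx$utr5_len
  sa <- tx$utr5_len + tx$cds_len - 3L   # first base of the stop codon
  start_lo <- pmax(0L, u5 - half)
  start_hi <- pmin(L, u5 + half)
  stop_lo <- pmax(0L, sa - half)
  stop_hi <- pmin(L, sa + half)
  # overlapping windows: boundary at nearest anchor, tie -> start region
  ov <- start_hi > stop_lo
  m <- (u5 + sa) %/% 2L + 1L
  start_hi[ov] <- pmin(start_hi, m)[ov]
  stop_lo[ov] <- pmax(stop_lo, m)[ov]
  start_hi <- pmax(start_hi, start_lo)
  stop_lo <- pmin(pmax(stop_lo, start_hi), stop_hi)
  data.frame(
    transcript_id = tx$transcript_id,
    total_length = L,
    cds_start = u5,
    stop_anchor = sa,
    utr5_lo = integer(nrow(tx)), utr5_hi = start_lo,
    start_lo = start_lo, start_hi = start_hi,
    cds_lo = start_hi, cds_hi = stop_lo,
    stop_lo = stop_lo, stop_hi = stop_hi,
    utr3_lo = stop_hi, utr3_hi = L,
    stringsAsFactors = FALSE
  )
}

REGION_LEVELS <- c("utr5", "start_codon", "cds", "stop_codon", "utr3")

#' Label transcript positions with the carved five-region partition
#'
#' @param partition One row of [partition_regions()] output (or the full
#'   frame plus a `transcript_id`).
#' @param tpos 0-based transcript offsets (must lie in `[0, L)`).
#' @param transcript_id Needed when `partition` has several rows.
#' @return factor with levels utr5, start_codon, cds, stop_codon, utr3.
#' @export
label_tx_positions <- function(partition, tpos, transcript_id = NULL) {
  p <- partition
  if (nrow(p) > 1) {
    if (is.null(transcript_id)) stop("transcript_id required")
    p <- p[p$transcript_id == transcript_id, , drop = FALSE]
    if (nrow(p) != 1) stop("transcript not in partition: ", transcript_id)
  }
  if (any(tpos < 0 | tpos >= p$total_length)) stop("position outside transcript")
  lab <- rep(NA_character_, length(tpos))
  lab[tpos >= p$utr5_lo & tpos < p$utr5_hi] <- "utr5"
  lab[tpos >= p$start_lo & tpos < p$start_hi] <- "start_codon"
  lab[tpos >= p$cds_lo & tpos < p$cds_hi] <- "cds"
  lab[tpos >= p$stop_lo & tpos < p$stop_hi] <- "stop_codon"
  lab[tpos >= p$utr3_lo & tpos < p$utr3_hi] <- "utr3"
  factor(lab, levels = REGION_LEVELS)
}
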
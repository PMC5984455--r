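# hand-built annotation: one GRanges in the dialect read_gtf() returns
make_annotation <- function(rows) {
  GenomicRanges::GRanges(
    rows$chrom,
    IRanges::IRanges(rows$start, rows$end),
    strand = rows$strand,
    type = rows$type,
    gene_id = rows$gene_id,
    transcript_id = rows$transcript_id
  )
}

# single-exon coding transcript: exon genomic [1, L]; CDS occupies
# transcript coords [u5, u5 + cds) incl. stop codon, plus strand
simple_tx <- function(gene = "g1", tx = "g1.t1", L = 1000, u5 = 200,
                      cds = 600, chrom = "chr1", strand = "+") {
  rows <- data.frame(
    chrom = chrom,
    start = c(1L, if (strand == "+") u5 + 1L else L - u5 - cds + 1L),
    end = c(L, if (strand == "+") u5 + cds else L - u5),
    strand = strand,
    type = c("exon", "CDS"),
    gene_id = gene, transcript_id = tx,
    stringsAsFactors = FALSE
  )
  make_annotation(rows)
}

# fabricate a transcript_models object directly from segment lengths
# (single-exon transcripts on the plus strand); used to drive the
# partition arithmetic over many random length combinations
fake_models <- function(u5, cds, u3, ids = NULL) {
  n <- length(u5)
  if (is.null(ids)) ids <- paste0("t", seq_len(n))
  L <- u5 + cds + u3
  tx <- data.frame(
    transcript_id = ids, gene_id = paste0("g", seq_len(n)),
    chrom = "chr1", strand = "+", n_exons = 1L, total_length = L,
    utr5_len = u5, cds_len = cds, utr3_len = u3, coding = cds > 0,
    stringsAsFactors = FALSE
  )
  ex <- data.frame(
    transcript_id = ids, gene_id = tx$gene_id, chrom = "chr1",
    strand = "+", gstart = 1L, gend = L, width = L, rank = 1L,
    toffset = 0L, stringsAsFactors = FALSE
  )
  structure(list(tx = tx, exons = ex), class = "transcript_models")
}

# independent per-nucleotide labeler for the carved five-region
# partition: start/stop windows are anchor-150..anchor+150 clipped to
# the transcript; a position inside both windows goes to the nearer
# anchor, ties to the start region
brute_label <- function(L, u5, cds, pos) {
  sa <- u5 + cds - 3L
  in_start <- pos >= u5 - 150 & pos < u5 + 150
  in_stop <- pos >= sa - 150 & pos < sa + 150
  lab <- character(length(pos))
  both <- in_start & in_stop
  lab[in_start & !in_stop] <- "start_codon"
  lab[!in_start & in_stop] <- "stop_codon"
  lab[both] <- ifelse(abs(pos[both] - u5) <= abs(pos[both] - sa),
                      "start_codon", "stop_codon")
  rest <- !in_start & !in_stop
  lab[rest & pos < u5] <- "utr5"
  lab[rest & pos >= u5 & pos < u5 + cds] <- "cds"
  lab[rest & pos >= u5 + cds] <- "utr3"
  lab
}

# exhaustive columnwise adapter scan: leftmost offset (0-based) with
# Hamming distance <= max_mm, NA if none; N never matches
brute_adapter_scan <- function(seqs, adapter = "AGATCGGAAG", max_mm = 2L) {
  a <- strsplit(adapter, "")[[1]]
  alen <- length(a)
  vapply(strsplit(seqs, ""), function(s) {
    L <- length(s)
    if (L < alen) return(NA_integer_)
    for (o in 0:(L - alen)) {
      if (sum(s[(o + 1):(o + alen)] != a) <= max_mm) return(as.integer(o))
    }
    NA_integer_
  }, 1L)
}

# read-by-read reimplementation of the three filtering criteria
brute_preprocess <- function(seqs, quals, max_mm = 2L, trim_q = 20L,
                             min_len = 70L, frac = 0.70, frac_q = 25L) {
  apos <- brute_adapter_scan(seqs, max_mm = max_mm)
  n <- length(seqs)
  kept <- logical(n); len_out <- integer(n)
  for (i in seq_len(n)) {
    L1 <- if (is.na(apos[i])) nchar(seqs[i]) else apos[i]
    q <- quals[[i]][seq_len(L1)]
    while (length(q) && q[length(q)] < trim_q) q <- q[-length(q)]
    len_out[i] <- length(q)
    s <- strsplit(substr(seqs[i], 1, length(q)), "")[[1]]
    good <- sum(q > frac_q & s != "N")
    kept[i] <- length(q) > min_len && good > frac * length(q)
  }
  data.frame(adapter_pos = apos, len_out = len_out, kept = kept)
}

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_genes = 60, low_expr_frac = 0, noncoding_frac = 0)
  for (nm in names(defaults)) {
    if (is.null(args[[nm]])) args[[nm]] <- defaults[[nm]]
  }
  do.call(sim_config, args)
}
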
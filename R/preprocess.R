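#' Locate the adapter in reads (leftmost match with mismatches)
#'
#' Finds the leftmost occurrence of the adapter 10-mer allowing up to
#' `max_mismatch` substitutions (Hamming distance; no indels). `N`
#' bases never match and therefore count as mismatches. Optionally a
#' 3'-terminal partial adapter is honored: a read suffix of length
#' k >= 5 matching a prefix of the adapter with <= floor(max_mismatch *
#' k / nchar(adapter)) mismatches is trimmed when no full match exists.
#'
#' @param seqs `DNAStringSet` or character vector of read sequences.
#' @param adapter Adapter sequence (default `AGATCGGAAG`).
#' @param max_mismatch Maximum substitutions for a full match.
#' @param allow_partial_3p Also trim 3' partial adapter overlaps
#'   (default FALSE: full-match-only).
#' @return Integer vector of 0-based trim offsets (position of the
#'   first adapter base); NA where no match.
#' @export
find_adapter <- function(seqs, adapter = "AGATCGGAAG", max_mismatch = 2L,
                         allow_partial_3p = FALSE) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  m <- Biostrings::vmatchPattern(adapter, seqs, max.mismatch = max_mismatch,
                                 with.indels = FALSE, fixed = TRUE)
  st <- Biostrings::startIndex(m)
  pos <- vapply(st, function(s) if (is.null(s) || !length(s)) NA_integer_
                else min(s), 1L)
  pos <- pos - 1L  # 0-based offset
  if (allow_partial_3p) {
    alen <- nchar(adapter)
    widths <- Biostrings::width(seqs)
    need <- which(is.na(pos))
    for (k in seq(alen - 1L, 5L)) {
      if (!length(need)) break
      allowed <- floor(max_mismatch * k / alen)
      idx <- need[widths[need] >= k]
      if (!length(idx)) next
      suff <- as.character(Biostrings::subseq(seqs[idx], start = widths[idx] - k + 1L))
      pch <- strsplit(substr(adapter, 1L, k), "")[[1]]
      mm <- vapply(strsplit(suff, ""), function(s) sum(s != pch), 1L)
      hit <- idx[mm <= allowed]
      pos[hit] <- widths[hit] - k
      need <- setdiff(need, hit)
    }
  }
  pos
}

#' Preprocess reads by the three filtering criteria
#'
#' Per read: (1) truncate at the leftmost adapter occurrence with at
#' most `max_mismatch` substitutions; (2) trim 3'-terminal bases while
#' their quality is `< trim_q`; (3) retain the read iff its remaining
#' length is strictly greater than `min_len` AND strictly more than
#' `frac` of its bases have quality strictly greater than `frac_q`.
#' `N` bases count as quality <= `frac_q` bases. The procedure is
#' idempotent.
#'
#' @param seqs `DNAStringSet` or character vector.
#' @param quals List (or `IntegerList`) of per-base Phred scores, or a
#'   `BStringSet` of Phred+33 strings.
#' @param adapter,max_mismatch See [find_adapter()].
#' @param trim_q Quality below which 3' bases are trimmed (default 20).
#' @param min_len Retention length threshold, strict (default 70).
#' @param frac Retention fraction threshold, strict (default 0.70).
#' @param frac_q Quality threshold for the fraction, strict (default 25).
#' @param allow_partial_3p Passed to [find_adapter()].
#' @return data.frame audit with one row per read: `adapter_pos`
#'   (0-based; NA if none), `len_in`, `len_after_adapter`, `len_out`,
#'   `n_q_gt` (bases with Q > frac_q among kept bases), `kept`,
#'   `reason` (NA, "short", "quality", "empty"). The trimmed sequences
#'   and qualities are attached as attributes `seq` and `qual`.
#' @export
preprocess_reads <- function(seqs, quals, adapter = "AGATCGGAAG",
                             max_mismatch = 2L, trim_q = 20L, min_len = 70L,
                             frac = 0.70, frac_q = 25L,
                             allow_partial_3p = FALSE) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (methods::is(quals, "XStringSet")) {
    quals <- as(Biostrings::PhredQuality(quals), "IntegerList")
  }
  quals <- as.list(quals)
  n <- length(seqs)
  stopifnot(length(quals) == n)
  len_in <- Biostrings::width(seqs)
  apos <- find_adapter(seqs, adapter, max_mismatch, allow_partial_3p)
  len1 <- ifelse(is.na(apos), len_in, apos)

  sq <- as.character(seqs)
  len2 <- integer(n); nq <- integer(n)
  out_seq <- character(n); out_q <- vector("list", n)
  for (i in seq_len(n)) {
    q <- quals[[i]][seq_len(len1[i])]
    # N bases never count as high-quality
    if (len1[i] > 0) {
      s_chars <- substr(sq[i], 1L, len1[i])
      ok <- q >= trim_q
      last <- if (any(ok)) max(which(ok)) else 0L
    } else last <- 0L
    len2[i] <- last
    q <- q[seq_len(last)]
    s <- substr(sq[i], 1L, last)
    isN <- if (last > 0) strsplit(s, "")[[1]] == "N" else logical(0)
    nq[i] <- sum(q > frac_q & !isN)
    out_seq[i] <- s
    out_q[[i]] <- q
  }
  kept <- len2 > min_len & nq > frac * len2
  reason <- rep(NA_character_, n)
  reason[!kept] <- ifelse(len2[!kept] > min_len, "quality", "short")
  reason[len2 == 0] <- "empty"
  audit <- data.frame(
    adapter_pos = apos, len_in = len_in, len_after_adapter = len1,
    len_out = len2, n_q_gt = nq, kept = kept, reason = reason,
    stringsAsFactors = FALSE
  )
  attr(audit, "seq") <- out_seq
  attr(audit, "qual") <- out_q
  audit
}

#' Preprocess a FASTQ file
#'
#' Applies [preprocess_reads()] to a Phred+33 FASTQ file and writes the
#' retained, trimmed reads.
#'
#' @param fastq_in Input FASTQ path.
#' @param fastq_out Output FASTQ path (omitted if NULL).
#' @param ... Passed to [preprocess_reads()].
#' @return list with `audit` (the per-read data.frame, with read ids)
#'   and `report` (reads in/out, adapters trimmed, mean output length).
#' @export
preprocess_fastq <- function(fastq_in, fastq_out = NULL, ...) {
  seqs <- Biostrings::readDNAStringSet(fastq_in, format = "fastq",
                                       with.qualities = TRUE)
  quals <- S4Vectors::mcols(seqs)$qualities
  audit <- preprocess_reads(seqs, quals, ...)
  out_seq <- attr(audit, "seq"); out_qual <- attr(audit, "qual")
  audit <- cbind(read_id = names(seqs), audit, stringsAsFactors = FALSE)
  attr(audit, "seq") <- out_seq
  attr(audit, "qual") <- out_qual
  if (!is.null(fastq_out)) {
    keep <- which(audit$kept)
    out <- Biostrings::DNAStringSet(attr(audit, "seq")[keep])
    names(out) <- audit$read_id[keep]
    qn <- vapply(attr(audit, "qual")[keep],
                 function(q) rawToChar(as.raw(q + 33L)), "")
    Biostrings::writeXStringSet(out, fastq_out, format = "fastq",
                                qualities = Biostrings::BStringSet(qn))
  }
  report <- list(
    reads_in = nrow(audit),
    reads_out = sum(audit$kept),
    adapters_trimmed = sum(!is.na(audit$adapter_pos)),
    mean_len_out = if (any(audit$kept)) mean(audit$len_out[audit$kept]) else NA_real_
  )
  list(audit = audit, report = report)
}
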
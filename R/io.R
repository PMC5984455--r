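#' Read a BED6 (optionally BED6+1 with an FDR column) peak file
#'
#' BED coordinates are 0-based half-open on disk; the returned
#' \link[GenomicRanges]{GRanges} uses 1-based closed coordinates.
#'
#' @param path Path to a BED file with at least 6 columns
#'   (chrom, start, end, name, score, strand).
#' @param fdr_col If `TRUE`, a 7th column is read as a per-peak FDR
#'   and stored in `mcols()$fdr`.
#' @return A `GRanges` with `name`, `score` and optionally `fdr` metadata.
#' @export
read_bed_peaks <- function(path, fdr_col = FALSE) {
  extra <- if (fdr_col) c(fdr = "numeric") else character()
  gr <- rtracklayer::import(path, format = "BED", extraCols = extra)
  if (any(BiocGenerics::strand(gr) == "*")) {
    stop("strandless intervals in ", path, "; BED6 with strand is required")
  }
  gr
}

#' Write intervals as BED6 (+ optional extra numeric columns)
#'
#' @param gr A stranded `GRanges`; `mcols()$name` used if present.
#' @param path Output path.
#' @param extra_cols Character vector of `mcols()` columns appended
#'   after the sixth BED field.
#' @export
write_bed_peaks <- function(gr, path, extra_cols = character()) {
  nm <- if (!is.null(gr$name)) as.character(gr$name) else paste0("peak_", seq_along(gr))
  sc <- if (!is.null(gr$score)) gr$score else 0L
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = nm,
    score = sc,
    strand = as.character(BiocGenerics::strand(gr)),
    stringsAsFactors = FALSE
  )
  for (col in extra_cols) df[[col]] <- S4Vectors::mcols(gr)[[col]]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a feature table as GTF
#'
#' Emits `exon` and `CDS` rows with `gene_id`/`transcript_id` attributes.
#' Coordinates in `features` are 1-based closed (GTF convention).
#'
#' @param features data.frame with columns chrom, source, feature, start,
#'   end, strand, gene_id, transcript_id.
#' @param path Output path.
#' @export
write_gtf <- function(features, path) {
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                   features$gene_id, features$transcript_id)
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   features$chrom, features$source, features$feature,
                   features$start, features$end, features$strand, attrs)
  writeLines(lines, path)
  invisible(path)
}

#' Read a GTF annotation into a GRanges
#'
#' Thin wrapper over [rtracklayer::import()]; tolerant of quoted or
#' unquoted `gene_id`/`transcript_id` attributes.
#'
#' @param path GTF file path.
#' @return `GRanges` with `type`, `gene_id`, `transcript_id` metadata.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  need <- c("type", "gene_id", "transcript_id")
  miss <- setdiff(need, names(S4Vectors::mcols(gr)))
  if (length(miss)) stop("GTF lacks attributes: ", paste(miss, collapse = ", "))
  gr
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
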
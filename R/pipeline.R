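#' Quantify and filter the peaks of every library
#'
#' Joins per-peak counts with library statistics, computes IP FPKM,
#' input FPKM and enrichment score per peak and sample, attaches the
#' per-sample enrichment FDR (one-sided conditional binomial, BH over
#' peaks within each sample) and applies the three retention criteria.
#'
#' @param counts Long data.frame: peak_id, sample_id, C, ip_count,
#'   input_count (as `merip_counts$counts`).
#' @param libstats data.frame: sample_id, ip_total, input_total.
#' @return `counts` with added columns a, b, c, c_defined, p, fdr,
#'   retained, reject.
#' @export
quantify_samples <- function(counts, libstats) {
  i <- match(counts$sample_id, libstats$sample_id)
  if (anyNA(i)) stop("library stats missing for some samples")
  B <- libstats$ip_total[i]; E <- libstats$input_total[i]
  q <- quantify_peak(counts$ip_count, counts$input_count, counts$C, B, E)
  counts <- cbind(counts, q)
  counts$p <- test_peak_enrichment(counts$ip_count, counts$input_count, B, E)
  counts$fdr <- NA_real_
  for (sid in unique(counts$sample_id)) {
    sel <- counts$sample_id == sid
    counts$fdr[sel] <- stats::p.adjust(counts$p[sel], method = "BH")
  }
  filter_peaks(counts)
}

#' Run the full temporal methylation analysis on a simulated study
#'
#' End-to-end pipeline over a [simulate_study()] object: per-sample
#' quantification and retention, baseline-condition merged peak atlas
#' with per-stage presence, ON/OFF switches, CMR/SMR classification,
#' WT-vs-KO differential methylation at the comparison stage, metagene
#' profile and five-region counts, expression FPKM and the
#' methylation-expression correlation screen. Deterministic given the
#' study.
#'
#' @param study A `merip_study`.
#' @param outdir Optional directory; when given, all result tables are
#'   written as TSV/BED there.
#' @return list of class `epitempo_run` with elements `quant`,
#'   `retained`, `atlas`, `presence`, `switches`, `classes`,
#'   `profiles`, `dmr`, `dmr_rna`, `located`, `metagene`,
#'   `region_counts`, `fpkm`, `correlation`, `report`.
#' @export
run_pipeline <- function(study, outdir = NULL) {
  config <- study$config
  truth <- study$truth
  stages <- config$stages
  base_cond <- config$conditions[1]

  quant <- quantify_samples(study$counts$counts, study$counts$libstats)
  retained <- quant[quant$retained, , drop = FALSE]

  # baseline-condition atlas, switches, classes
  rw <- retained[retained$condition == base_cond, , drop = FALSE]
  pk <- truth$peaks[match(rw$peak_id, truth$peaks$peak_id), ]
  rw_gr <- GenomicRanges::GRanges(pk$chrom, IRanges::IRanges(pk$start, pk$end),
                                  strand = pk$strand, stage = rw$stage,
                                  sample_id = rw$sample_id,
                                  rna_id = rw$gene_id, peak_id = rw$peak_id)
  atlas <- merge_peak_atlas(rw_gr, stages)
  pres <- presence_matrix(atlas, stages)
  switches <- detect_switches(pres, stages, rna_id = atlas$rna_id)
  profiles <- rna_methylation_profiles(rw$gene_id, rw$stage, stages)
  classes <- classify_cmr_smr(profiles)

  # metagene over the atlas (baseline condition)
  S4Vectors::mcols(atlas)$peak_id <- atlas$merged_id
  located <- locate_peaks_on_transcripts(atlas, truth$ref)
  metagene <- metagene_distribution(located, truth$ref)
  spec_stage <- rep(NA_character_, length(atlas))
  one <- rowSums(pres) == 1
  spec_stage[one] <- stages[apply(pres[one, , drop = FALSE], 1, which)]
  region_counts <- count_region_peaks(located, truth$partition,
                                      group = ifelse(is.na(spec_stage),
                                                     "shared", spec_stage))

  # differential methylation at the comparison stage
  dmr <- dmr_rna <- NULL
  if (length(config$conditions) >= 2) {
    ko_cond <- config$conditions[2]
    ds <- config$dmr_stage
    qw <- quant[quant$condition == base_cond & quant$stage == ds, ]
    qk <- quant[quant$condition == ko_cond & quant$stage == ds, ]
    qk <- qk[match(qw$peak_id, qk$peak_id), ]
    lw <- study$counts$libstats
    lwi <- lw[lw$condition == base_cond & lw$stage == ds, ]
    lki <- lw[lw$condition == ko_cond & lw$stage == ds, ]
    atlas_df <- data.frame(
      merged_id = qw$peak_id, rna_id = qw$gene_id, C = qw$C,
      A_wt = qw$ip_count, D_wt = qw$input_count,
      A_ko = qk$ip_count, D_ko = qk$input_count,
      retained_wt = qw$retained, retained_ko = qk$retained,
      stringsAsFactors = FALSE
    )
    lib <- list(B_wt = lwi$ip_total, E_wt = lwi$input_total,
                B_ko = lki$ip_total, E_ko = lki$input_total)
    dmr <- detect_dmrs(atlas_df, lib)
    dmr_rna <- dmrs_by_rna(dmr)
  }

  # expression and the correlation screen (baseline condition)
  ecb <- study$counts$expr_counts
  ecb <- ecb[ecb$condition == base_cond, ]
  lib_of <- study$counts$libstats$input_total[
    match(ecb$sample_id, study$counts$libstats$sample_id)]
  fp <- compute_fpkm(ecb$count, ecb$length, lib_of)
  ecb$fpkm <- fp$fpkm; ecb$expressed <- fp$expressed
  fpkm_mat <- matrix(0, config$n_genes, length(stages),
                     dimnames = list(truth$genes$gene_id, stages))
  fpkm_mat[cbind(match(ecb$gene_id, truth$genes$gene_id),
                 match(ecb$stage, stages))] <- ecb$fpkm
  meth_mat <- methylation_level_matrix(rw$gene_id, rw$stage, rw$c, stages,
                                       all_rnas = truth$genes$gene_id)
  eligible <- rowSums(meth_mat > 0) >= 1 & rowSums(fpkm_mat > 0.2) >= 1
  correlation <- correlate_methylation_expression(
    meth_mat[eligible, , drop = FALSE], fpkm_mat[eligible, , drop = FALSE])

  report <- list(
    peaks_per_sample = table(retained$sample_id),
    switch_counts = if (nrow(switches)) table(switches$transition,
                                              switches$direction) else NULL,
    class_tally = classes$tally,
    dmr_tally = if (!is.null(dmr)) table(dmr$category, useNA = "ifany") else NULL,
    region_counts = region_counts$counts,
    correlation_tally = correlation$tally
  )
  run <- structure(list(
    quant = quant, retained = retained, atlas = atlas, presence = pres,
    switches = switches, classes = classes, profiles = profiles,
    located = located, metagene = metagene, region_counts = region_counts,
    dmr = dmr, dmr_rna = dmr_rna, fpkm = ecb, fpkm_matrix = fpkm_mat,
    meth_matrix = meth_mat, correlation = correlation, report = report
  ), class = "epitempo_run")
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

#' @export
print.epitempo_run <- function(x, ...) {
  cat("epitempo_run\n")
  cat("  retained peaks per sample:\n")
  print(x$report$peaks_per_sample)
  if (!is.null(x$report$switch_counts)) {
    cat("  switches:\n"); print(x$report$switch_counts)
  }
  cat("  classes:\n"); print(x$report$class_tally)
  if (!is.null(x$report$dmr_tally)) {
    cat("  DMR categories:\n"); print(x$report$dmr_tally)
  }
  cat("  correlation screen:\n"); print(x$report$correlation_tally)
  invisible(x)
}

#' Write the result tables of a pipeline run
#'
#' @param run An `epitempo_run`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_tsv(run$quant, p("peak_quant.tsv"))
  write_bed_peaks(run$atlas, p("merged_atlas.bed"))
  pres <- as.data.frame(run$presence)
  pres <- cbind(merged_id = rownames(pres), pres)
  write_tsv(pres, p("atlas_presence.tsv"))
  write_tsv(run$switches, p("switches.tsv"))
  cl <- data.frame(rna_id = names(run$classes$labels),
                   class = unname(run$classes$labels))
  write_tsv(cl, p("rna_classes.tsv"))
  write_tsv(run$metagene$profile, p("metagene_profile.tsv"))
  write_tsv(run$region_counts$counts, p("region_counts.tsv"))
  if (!is.null(run$dmr)) {
    write_tsv(run$dmr, p("dmr_peaks.tsv"))
    write_tsv(run$dmr_rna, p("dmr_rnas.tsv"))
  }
  write_tsv(run$fpkm, p("expression_fpkm.tsv"))
  write_tsv(run$correlation$pairs, p("correlation_pairs.tsv"))
  invisible(outdir)
}
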
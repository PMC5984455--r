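#!/usr/bin/env Rscript
# Simulate the synthetic MeRIP-seq study: a 4-stage developmental time
# course (P7, P14, P21, P60) in wild-type and knockout conditions, with
# planted methylation classes, enrichment factors and expression
# trajectories. Writes the annotation, truth tables and per-sample
# count/library files. Later steps rebuild the same study
# deterministically from the seed.

suppressPackageStartupMessages(library(epitempo))

outdir <- "results/sim"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
tsv <- function(df, f) write.table(df, file.path(outdir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)

cfg <- sim_config(seed = 1)
study <- simulate_study(cfg)
truth <- study$truth

write_gtf(truth$features, file.path(outdir, "annotation.gtf"))
tsv(truth$genes, "truth_genes.tsv")
tsv(truth$peaks, "truth_peaks.tsv")
tsv(study$counts$counts, "peak_counts.tsv")
tsv(study$counts$libstats, "libstats.tsv")
tsv(study$counts$expr_counts, "expr_counts.tsv")

cat("Simulated", nrow(truth$genes), "genes on",
    length(unique(truth$genes$chrom)), "chromosomes\n")
cat("Planted methylation classes:\n")
print(table(truth$genes$class))
cat("Knockout perturbations at", cfg$dmr_stage, ":\n")
print(table(truth$genes$dmr_category, useNA = "ifany"))
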
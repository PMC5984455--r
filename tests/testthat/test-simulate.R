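test_that("config validation rejects inconsistent designs", {
  expect_error(sim_config(class_proportions = c(cmr = 0.6, smr = 0.3,
                                                switching = 0.2,
                                                unmethylated = 0.2)),
               "sum to > 1")
  expect_error(sim_config(mean_depth = 0), "mean_depth")
  expect_error(sim_config(enrichment_range = c(0.5, 3)), "> 1")
  expect_error(sim_config(dmr_stage = "P99"), "dmr_stage")
})

test_that("planted truth respects class definitions and the seed contract", {
  cfg <- tiny_config(seed = 101)
  truth <- suppressWarnings(generate_truth(cfg))
  g <- truth$genes; st <- truth$status
  # CMR genes methylated at every stage; SMR at exactly one;
  # switching changes status at exactly one transition
  expect_true(all(rowSums(st[g$class == "cmr", , drop = FALSE]) == 4))
  expect_true(all(rowSums(st[g$class == "smr", , drop = FALSE]) == 1))
  sw <- st[g$class == "switching", , drop = FALSE]
  expect_true(all(apply(sw, 1, function(v) sum(abs(diff(v)))) == 1))
  expect_true(all(rowSums(sw) >= 2))
  expect_true(all(rowSums(st[g$class == "unmethylated", , drop = FALSE]) == 0))
  # factors > 1 exactly at methylated gene-stages
  expect_true(all(truth$factor_wt[st] > 1))
  expect_true(all(truth$factor_wt[!st] == 1))
  # annotation is self-consistent: every gene has a coding or exon-only model
  expect_setequal(unique(truth$models$tx$gene_id), g$gene_id)
  expect_equal(sum(truth$ref$tx$coding), sum(g$coding))

  # determinism: same seed reproduces annotation and truth exactly
  truth2 <- suppressWarnings(generate_truth(tiny_config(seed = 101)))
  expect_identical(truth$features, truth2$features)
  expect_identical(truth$status, truth2$status)
  expect_identical(truth$factor_ko, truth2$factor_ko)
  expect_identical(truth$peaks, truth2$peaks)

  # forced single class: CMR fraction 1 makes every gene methylated always
  cfg_all <- tiny_config(class_proportions = c(cmr = 1, smr = 0,
                                               switching = 0,
                                               unmethylated = 0), seed = 5)
  t_all <- suppressWarnings(generate_truth(cfg_all))
  expect_true(all(t_all$status))
})

test_that("class counts at n = 1000 sit within multinomial sampling error", {
  cfg <- sim_config(n_genes = 1000, seed = 13)
  truth <- suppressWarnings(generate_truth(cfg))
  counts <- table(factor(truth$genes$class,
                         levels = c("cmr", "smr", "switching",
                                    "unmethylated")))
  p <- cfg$class_proportions[c("cmr", "smr", "switching", "unmethylated")]
  expected <- 1000 * p
  tol <- 4 * sqrt(1000 * p * (1 - p))
  expect_true(all(abs(counts - expected) <= tol))
})

test_that("planted peaks sit inside one exon of their planted region", {
  cfg <- tiny_config(seed = 19, n_genes = 80)
  truth <- suppressWarnings(generate_truth(cfg))
  pk <- truth$peaks
  for (i in seq_len(nrow(pk))) {
    e <- truth$ref$exons[truth$ref$exons$transcript_id == pk$transcript_id[i], ]
    inside <- any(pk$start[i] >= e$gstart & pk$end[i] <= e$gend)
    expect_true(inside, info = pk$peak_id[i])
    if (!is.na(pk$region[i])) {
      mid <- pk$tx_start[i] + (pk$tx_end[i] - pk$tx_start[i]) %/% 2
      lab <- label_tx_positions(truth$partition, mid, pk$transcript_id[i])
      expect_equal(as.character(lab), pk$region[i], info = pk$peak_id[i])
    }
  }
})

test_that("count model recovers the planted factor and normalizes depth away", {
  # planted factor 6 at deep coverage: mean score near 6 over replicates
  cfg <- tiny_config(n_genes = 50, enrichment_range = c(6, 6),
                     mean_peak_reads = 200,
                     class_proportions = c(cmr = 1, smr = 0, switching = 0,
                                           unmethylated = 0), seed = 23)
  truth <- suppressWarnings(generate_truth(cfg))
  cs <- simulate_counts(truth, cfg)
  q <- quantify_samples(cs$counts, cs$libstats)
  expect_equal(mean(q$c[is.finite(q$c)]), 6, tolerance = 0.1)

  # factor 1 everywhere: mean score near 1
  cfg0 <- tiny_config(n_genes = 50, mean_peak_reads = 200,
                      class_proportions = c(cmr = 0, smr = 0, switching = 0,
                                            unmethylated = 1), seed = 24)
  t0 <- generate_truth(cfg0)
  cs0 <- simulate_counts(t0, cfg0)
  q0 <- quantify_samples(cs0$counts, cs0$libstats)
  expect_equal(mean(q0$c[is.finite(q0$c)]), 1, tolerance = 0.05)

  # doubling the library depth leaves every enrichment score unchanged
  ls2 <- cs$libstats
  ls2$ip_total <- ls2$ip_total * 2; ls2$input_total <- ls2$input_total * 2
  q2 <- quantify_samples(cs$counts, ls2)
  expect_equal(q2$c, q$c, tolerance = 1e-12)

  # counts are deterministic given the seed
  cs_b <- simulate_counts(truth, cfg)
  expect_identical(cs$counts, cs_b$counts)
})

test_that("FASTQ generator plants unambiguous adapters and is deterministic", {
  fq <- simulate_fastq(400, adapter_rate = 0.5,
                       mismatch_weights = c(0.3, 0.3, 0.2, 0.2), seed = 33)
  tr <- fq$truth
  scan <- brute_adapter_scan(fq$seq)
  le2 <- tr$planted & tr$n_mismatch <= 2
  expect_true(all(scan[le2] == tr$offset[le2]))
  # beyond two mismatches (and unplanted reads): no occurrence at all
  expect_true(all(is.na(scan[!le2])))
  # adapter_rate 0: no read carries a planted record
  fq0 <- simulate_fastq(50, adapter_rate = 0, seed = 1)
  expect_false(any(fq0$truth$planted))
  expect_error(simulate_fastq(10, adapter_rate = 1.5), "adapter_rate")
  # determinism
  fq_b <- simulate_fastq(400, adapter_rate = 0.5,
                         mismatch_weights = c(0.3, 0.3, 0.2, 0.2), seed = 33)
  expect_identical(fq$seq, fq_b$seq)
  expect_identical(fq$qual, fq_b$qual)
})

test_that("GTF round trip preserves the planted annotation", {
  cfg <- tiny_config(n_genes = 20, seed = 55)
  truth <- suppressWarnings(generate_truth(cfg))
  path <- tempfile(fileext = ".gtf")
  write_gtf(truth$features, path)
  back <- read_gtf(path)
  m2 <- transcript_models(back)
  expect_equal(m2$tx[order(m2$tx$transcript_id), ],
               truth$models$tx[order(truth$models$tx$transcript_id), ],
               ignore_attr = TRUE)
})
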
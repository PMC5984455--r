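test_that("peak FPKM and enrichment score follow the normalization formulas", {
  q <- quantify_peak(A = 100, D = 0, C = 200, B = 1e7, E = 1e7)
  expect_equal(q$a, 50)            # 100 * 1e9 / (1e7 * 200)
  expect_equal(q$c, Inf)           # D = 0 with A > 0: flagged infinite
  expect_false(q$c_defined)

  # symmetry: equal counts and totals give score 1
  q <- quantify_peak(A = 37, D = 37, C = 151, B = 2e6, E = 2e6)
  expect_equal(q$c, 1)

  # A = 0 gives zero densities and zero score
  q <- quantify_peak(A = 0, D = 10, C = 100, B = 1e6, E = 1e6)
  expect_equal(q$a, 0)
  expect_equal(q$c, 0)

  expect_error(quantify_peak(1, 1, 0, 1e6, 1e6), "length")
  expect_error(quantify_peak(1, 1, 100, 0, 1e6), "totals")
})

test_that("quantification matches an independent evaluator and is scale invariant", {
  set.seed(11)
  n <- 2000
  A <- rpois(n, 50); D <- rpois(n, 40) + 1L
  C <- sample(100:300, n, TRUE)
  B <- runif(n, 1e6, 5e7); E <- runif(n, 1e6, 5e7)
  q <- quantify_peak(A, D, C, B, E)
  # independent single-expression evaluator
  expect_equal(q$a, A * 1e9 / (B * C), tolerance = 1e-14)
  expect_equal(q$b, D * 1e9 / (E * C), tolerance = 1e-14)
  expect_equal(q$c, (A * 1e9 / (B * C)) / (D * 1e9 / (E * C)), tolerance = 1e-14)
  # scaling all counts and totals by k leaves a, b, c unchanged
  k <- 3.7
  qk <- quantify_peak(k * A, k * D, C, k * B, k * E)
  expect_equal(qk$a, q$a, tolerance = 1e-12)
  expect_equal(qk$c, q$c, tolerance = 1e-12)
})

test_that("enrichment test equals the exact binomial tail", {
  # single window: A = 30 IP vs D = 5 input reads, equal library sizes
  p <- test_peak_enrichment(A = 30, D = 5, B = 1e6, E = 1e6)
  expect_equal(p, sum(dbinom(30:35, 35, 0.5)), tolerance = 1e-12)
  # unequal depths shift the null proportion
  p2 <- test_peak_enrichment(A = 30, D = 5, B = 3e6, E = 1e6)
  expect_equal(p2, sum(dbinom(30:35, 35, 0.75)), tolerance = 1e-12)
  expect_equal(test_peak_enrichment(0, 0, 1e6, 1e6), 1)
})

test_that("retention applies the three strict criteria", {
  q <- data.frame(
    fdr = c(0.01, 0.049, 0.05, 0.01, 0.01, NA),
    a = c(2.0, 1.01, 5, 1.0, 2, 2),
    c = c(1.6, 100, 5, 3, 1.5, 3)
  )
  f <- filter_peaks(q)
  expect_equal(f$retained,
               c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(f$reject[3], "fdr")        # FDR = 0.05 not < 0.05
  expect_equal(f$reject[4], "ip_fpkm")    # a = 1 not > 1
  expect_equal(f$reject[5], "enrichment_score")  # c = 1.5 not > 1.5
  expect_equal(f$reject[6], "missing_fdr")
  expect_equal(unname(attr(f, "tally")["retained"]), 2L)
})

test_that("read counting uses inclusive 50% overlap and strand matching", {
  peak <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1200),
                                 strand = "+")
  reads <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(start = c(952, 951, 1050, 1050, 1, 1150),
                     width = 100),
    strand = c("+", "+", "+", "-", "+", "+")
  )
  # overlaps: 51, 50, 100, 100(-), 0, 51
  n <- count_reads_in_intervals(peak, reads)
  expect_equal(n, 4L)  # read at 951 has exactly 50% -> counted (inclusive)
  n49 <- count_reads_in_intervals(
    peak, GenomicRanges::GRanges("chr1", IRanges::IRanges(950, 1049),
                                 strand = "+"))
  expect_equal(n49, 0L)  # 49% overlap
  # strand ignored on request
  n_us <- count_reads_in_intervals(peak, reads, same_strand = FALSE)
  expect_equal(n_us, 5L)
  # split read: blocks contribute jointly
  spl <- GenomicRanges::GRangesList(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1001, 1181), width = c(30, 30)),
    strand = "+"))
  expect_equal(count_reads_in_intervals(peak, spl), 1L)
  expect_error(count_reads_in_intervals(
    peak, GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1100))),
    "strandless")
})

test_that("rank-sum comparison matches exact enumeration and handles identity", {
  r <- compare_enrichment_distributions(c(1, 2, 3), c(11, 12, 13))
  expect_equal(r$p.value, 2 / choose(6, 3), tolerance = 1e-12)  # 2/20
  expect_equal(r$statistic, 0)
  # symmetry under swapping groups
  r2 <- compare_enrichment_distributions(c(11, 12, 13), c(1, 2, 3))
  expect_equal(r2$p.value, r$p.value)
  # identical multisets: P = 1 (ties mid-ranked)
  ri <- compare_enrichment_distributions(c(1, 2, 2, 3), c(1, 2, 2, 3))
  expect_equal(ri$p.value, 1, tolerance = 1e-6)
  expect_error(compare_enrichment_distributions(1, c(1, 2)), "finite values")
})

test_that("candidate caller recovers a planted peak and respects the null", {
  cfg <- tiny_config(n_genes = 30, multi_transcript_frac = 0,
                     enrichment_range = c(6, 6),
                     class_proportions = c(cmr = 0.5, smr = 0, switching = 0,
                                           unmethylated = 0.5),
                     seed = 21)
  truth <- suppressWarnings(generate_truth(cfg))
  rd <- simulate_read_intervals(truth, stage = "P7", gene_depth = 400, seed = 77)
  peaks <- call_candidate_peaks(rd$ip, rd$input, truth$ref)
  expect_true(length(peaks) > 0)
  # planted methylated loci with adequate coverage (>= 50 expected
  # background reads per gene at depth 400) should be recovered
  meth <- intersect(
    truth$genes$gene_id[truth$status[, "P7"] & truth$expr[, "P7"] >= 15],
    rd$gene_ids)   # only single-exon genes receive simulated reads
  pt <- truth$peaks[truth$peaks$gene_id %in% meth, ]
  ptg <- GenomicRanges::GRanges(pt$chrom, IRanges::IRanges(pt$start, pt$end),
                                strand = pt$strand)
  hits <- GenomicRanges::findOverlaps(peaks, ptg)
  expect_true(length(hits) > 0)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(
    peaks[S4Vectors::queryHits(hits)], ptg[S4Vectors::subjectHits(hits)]))
  un <- GenomicRanges::width(peaks[S4Vectors::queryHits(hits)]) +
    GenomicRanges::width(ptg[S4Vectors::subjectHits(hits)]) - ov
  jac <- tapply(ov / un, S4Vectors::subjectHits(hits), max)
  expect_gte(mean(jac >= 0.5), 0.8)
  # most planted methylated loci are recovered
  expect_gte(length(unique(S4Vectors::subjectHits(hits))) / length(ptg), 0.8)
})
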
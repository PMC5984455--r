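test_that("peak midpoints project onto transcripts like a per-base oracle", {
  # two-exon plus-strand transcript: exons [1001,1300], [2001,2400]
  ann <- make_annotation(data.frame(
    chrom = "chr1", start = c(1001, 2001), end = c(1300, 2400), strand = "+",
    type = "exon", gene_id = "g", transcript_id = "t"))
  m <- transcript_models(ann)

  pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1101, 1200),
                               strand = "+", peak_id = "p1")
  loc <- locate_peaks_on_transcripts(pk, m)
  expect_equal(loc$status, "assigned")
  # per-base projection oracle: midpoint 1150 -> offset 149
  expect_equal(loc$tx_pos, 149L)
  expect_equal(loc$gene_id, "g")

  # peak spanning the intron: genomic midpoint intronic, snapped to the
  # nearest exonic base within the peak
  pk2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1251, 2050),
                                strand = "+", peak_id = "p2")
  loc2 <- locate_peaks_on_transcripts(pk2, m)
  expect_equal(loc2$status, "assigned")
  # midpoint 1650 is intronic; nearest covered exonic base is 1300 -> 299
  expect_equal(loc2$tx_pos, 299L)

  # opposite strand and fully intronic peaks are unassigned
  pk3 <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(1101, 1400), c(1200, 1600)),
                                strand = c("-", "+"),
                                peak_id = c("p3", "p4"))
  loc3 <- locate_peaks_on_transcripts(pk3, m)
  expect_equal(loc3$status, c("unassigned", "unassigned"))
  expect_equal(loc3$reason, c("strand_mismatch", "no_exonic_overlap"))
})

test_that("segment-relative binning follows the fraction arithmetic", {
  # CDS fractional position 0.5 -> global bin 150 (CDS bin 50)
  expect_equal(metagene_bin(200L + 300L, 200L, 600L, 200L), 150L)
  expect_equal(metagene_bin(0L, 200L, 600L, 200L), 0L)
  # last base of the transcript lands in bin 299, not 300 (cap)
  expect_equal(metagene_bin(999L, 200L, 600L, 200L), 299L)
  # zero-length 5'UTR: position 0 is CDS bin 100
  expect_equal(metagene_bin(0L, 0L, 600L, 400L), 100L)
  # brute-force fraction arithmetic on random positions
  set.seed(7)
  u5 <- 137L; cd <- 903L; u3 <- 260L
  pos <- sample(0:(u5 + cd + u3 - 1L), 400)
  oracle <- vapply(pos, function(p) {
    if (p < u5) floor(p / u5 * 100)
    else if (p < u5 + cd) 100 + floor((p - u5) / cd * 100)
    else 200 + floor((p - u5 - cd) / u3 * 100)
  }, 1.0)
  expect_equal(metagene_bin(pos, u5, cd, u3), as.integer(oracle))
})

test_that("metagene profile normalizes to 100% and excludes non-coding hosts", {
  set.seed(8)
  n <- 40
  u5 <- sample(50:300, n, TRUE); cds <- 3L * sample(60:400, n, TRUE)
  u3 <- sample(50:400, n, TRUE)
  m <- fake_models(u5, cds, u3)
  m$tx$coding[1:5] <- FALSE  # treat some hosts as non-coding
  loc <- data.frame(
    peak_id = paste0("p", 1:n), transcript_id = m$tx$transcript_id,
    gene_id = m$tx$gene_id,
    tx_pos = as.integer(floor((u5 + cds + u3) * runif(n, 0, 0.999))),
    status = "assigned", reason = NA_character_, stringsAsFactors = FALSE
  )
  prof <- metagene_distribution(loc, m)
  expect_equal(prof$n_peaks, n - 5L)
  expect_equal(sum(prof$profile$percent), 100, tolerance = 1e-9)
  expect_true(all(prof$profile$percent >= 0))
  expect_equal(nrow(prof$profile), 300L)
  # all peaks at the transcript 5' end concentrate in bin 0
  loc0 <- loc[6:10, ]; loc0$tx_pos <- 0L
  prof0 <- metagene_distribution(loc0, m)
  expect_equal(prof0$profile$percent[1], 100)
  # max normalization rescales the modal bin to 100
  profm <- metagene_distribution(loc, m, normalize = "max")
  expect_equal(max(profm$profile$percent), 100)
})

test_that("region counting conserves assigned peaks and matches planted labels", {
  set.seed(9)
  n <- 50
  u5 <- sample(100:300, n, TRUE); cds <- 3L * sample(150:400, n, TRUE)
  u3 <- sample(100:400, n, TRUE)
  m <- fake_models(u5, cds, u3)
  p <- partition_regions(m)
  loc <- data.frame(
    peak_id = paste0("p", 1:n), transcript_id = m$tx$transcript_id,
    gene_id = m$tx$gene_id,
    tx_pos = as.integer(floor((u5 + cds + u3) * runif(n, 0, 0.999))),
    status = "assigned", reason = NA_character_, stringsAsFactors = FALSE
  )
  rc <- count_region_peaks(loc, p)
  expect_equal(sum(rc$counts$n), n)            # conservation
  expect_equal(rc$n_excluded, 0L)
  # per-position brute-force labels agree
  oracle <- vapply(seq_len(n), function(i)
    brute_label(u5[i] + cds[i] + u3[i], u5[i], cds[i], loc$tx_pos[i]), "")
  expect_equal(as.character(rc$region), oracle)
  # a position 10 nt downstream of the start anchor is a start-codon region
  loc1 <- loc[1, ]; loc1$tx_pos <- u5[1] + 10L
  rc1 <- count_region_peaks(loc1, p)
  expect_equal(as.character(rc1$region), "start_codon")
})

test_that("uniform peak positions give a near-flat metagene profile", {
  set.seed(10)
  n <- 6000
  m <- fake_models(rep(1000L, 10), rep(3000L, 10), rep(1000L, 10))
  loc <- data.frame(
    peak_id = paste0("p", 1:n),
    transcript_id = sample(m$tx$transcript_id, n, TRUE),
    gene_id = "g", tx_pos = 0L, status = "assigned",
    reason = NA_character_, stringsAsFactors = FALSE
  )
  # uniform within each segment so every bin has equal expectation
  seg <- sample(1:3, n, TRUE)
  loc$tx_pos <- as.integer(ifelse(seg == 1, floor(runif(n, 0, 1000)),
                           ifelse(seg == 2, 1000 + floor(runif(n, 0, 3000)),
                                  4000 + floor(runif(n, 0, 1000)))))
  prof <- metagene_distribution(loc, m)
  counts <- prof$profile$percent / 100 * prof$n_peaks
  chi <- chisq.test(counts, p = rep(1 / 300, 300))
  expect_gt(chi$p.value, 1e-4)
})
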
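stages4 <- c("P7", "P14", "P21", "P60")

peaks_gr <- function(start, end, strand, stage) {
  GenomicRanges::GRanges("chr1", IRanges::IRanges(start, end),
                         strand = strand, stage = stage)
}

test_that("atlas merging is strand-aware single linkage with bookended joins", {
  # [100,200)+ in P7 and [150,250)+ in P14 (0-based half-open) merge
  pk <- peaks_gr(c(101, 151), c(200, 250), "+", c("P7", "P14"))
  m <- merge_peak_atlas(pk, stages4)
  expect_equal(length(m), 1L)
  expect_equal(GenomicRanges::start(m), 101L)
  expect_equal(GenomicRanges::end(m), 250L)
  pres <- presence_matrix(m, stages4)
  expect_equal(unname(pres[1, ]), c(TRUE, TRUE, FALSE, FALSE))

  # same intervals on opposite strands never merge
  pk2 <- peaks_gr(c(101, 151), c(200, 250), c("+", "-"), c("P7", "P14"))
  expect_equal(length(merge_peak_atlas(pk2, stages4)), 2L)

  # bookended intervals ([100,200) then [200,300)) merge like mergeBed -d 0
  pk3 <- peaks_gr(c(101, 201), c(200, 300), "+", c("P7", "P7"))
  expect_equal(length(merge_peak_atlas(pk3, stages4)), 1L)
  # with a 1-nt gap they stay apart
  pk4 <- peaks_gr(c(101, 202), c(200, 300), "+", c("P7", "P7"))
  expect_equal(length(merge_peak_atlas(pk4, stages4)), 2L)

  # singleton peak yields a singleton merged peak
  m5 <- merge_peak_atlas(peaks_gr(500, 600, "+", "P21"), stages4)
  expect_equal(length(m5), 1L)
  expect_equal(unname(presence_matrix(m5, stages4)[1, ]),
               c(FALSE, FALSE, TRUE, FALSE))
})

test_that("switch detection equals the exhaustive pairwise-diff oracle", {
  # forced examples
  pres <- rbind(c(FALSE, TRUE, TRUE, TRUE), c(TRUE, FALSE, TRUE, FALSE))
  colnames(pres) <- stages4; rownames(pres) <- c("a", "b")
  sw <- detect_switches(pres)
  sa <- sw[sw$merged_id == "a", ]
  expect_equal(nrow(sa), 1L)
  expect_equal(sa$transition, "P7-P14"); expect_equal(sa$direction, "ON")
  sb <- sw[sw$merged_id == "b", ]
  expect_equal(paste(sb$transition, sb$direction),
               c("P7-P14 OFF", "P14-P21 ON", "P21-P60 OFF"))

  # 1000 random presence vectors vs brute-force oracle
  set.seed(41)
  m <- matrix(runif(4000) < 0.5, ncol = 4,
              dimnames = list(paste0("mp", 1:1000), stages4))
  got <- detect_switches(m)
  key_got <- sort(paste(got$merged_id, got$transition, got$direction))
  exp_keys <- character()
  for (r in seq_len(nrow(m))) for (i in 1:3) {
    if (!m[r, i] && m[r, i + 1]) exp_keys <- c(exp_keys,
      paste(rownames(m)[r], paste0(stages4[i], "-", stages4[i + 1]), "ON"))
    if (m[r, i] && !m[r, i + 1]) exp_keys <- c(exp_keys,
      paste(rownames(m)[r], paste0(stages4[i], "-", stages4[i + 1]), "OFF"))
  }
  expect_equal(key_got, sort(exp_keys))
  # ON and OFF are disjoint per transition
  for (tr in unique(got$transition)) {
    on <- got$merged_id[got$transition == tr & got$direction == "ON"]
    off <- got$merged_id[got$transition == tr & got$direction == "OFF"]
    expect_length(intersect(on, off), 0)
  }
  expect_error(detect_switches(m[, 1, drop = FALSE]), ">= 2")
})

test_that("CMR/SMR classification is exclusive and exhaustive", {
  pres <- rbind(
    c(TRUE, TRUE, TRUE, TRUE),
    c(FALSE, FALSE, FALSE, TRUE),
    c(TRUE, FALSE, TRUE, FALSE),
    c(FALSE, FALSE, FALSE, FALSE)
  )
  colnames(pres) <- stages4; rownames(pres) <- paste0("r", 1:4)
  cl <- classify_cmr_smr(pres)
  expect_equal(unname(cl$labels),
               c("CMR", "SMR:P60", "other", "unmethylated"))
  # random vectors: oracle by definition, classes mutually exclusive
  set.seed(42)
  m <- matrix(runif(2000) < 0.5, ncol = 4,
              dimnames = list(paste0("r", 1:500), stages4))
  cl2 <- classify_cmr_smr(m)
  oracle <- apply(m, 1, function(v) {
    if (all(v)) "CMR"
    else if (sum(v) == 1) paste0("SMR:", stages4[which(v)])
    else if (sum(v) == 0) "unmethylated"
    else "other"
  })
  expect_equal(cl2$labels, oracle)
  expect_equal(sum(cl2$tally), 500L)
})

test_that("RNA methylation profiles reflect retained peaks per stage", {
  prof <- rna_methylation_profiles(
    rna_id = c("g1", "g1", "g2"), stage = c("P7", "P60", "P14"),
    stages = stages4, all_rnas = c("g1", "g2", "g3"))
  expect_equal(unname(prof["g1", ]), c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(unname(prof["g2", ]), c(FALSE, TRUE, FALSE, FALSE))
  expect_false(any(prof["g3", ]))
})

test_that("differential methylation categories follow thresholds and presence", {
  lib <- list(B_wt = 1e6, E_wt = 1e6, B_ko = 1e6, E_ko = 1e6)
  atlas <- data.frame(
    merged_id = paste0("m", 1:4), rna_id = paste0("g", 1:4), C = 200,
    A_wt = c(100, 400, 0, 200), D_wt = c(100, 100, 10, 50),
    A_ko = c(400, 400, 300, 210), D_ko = c(100, 100, 50, 52),
    retained_wt = c(TRUE, TRUE, FALSE, TRUE),
    retained_ko = c(TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  d <- detect_dmrs(atlas, lib)
  expect_equal(d$category, c("hyper", "loss", "gain", "unchanged"))
  expect_equal(d$log2fc[1], 2)
  # exact Fisher oracle (hypergeometric, two-sided by probability mass)
  fisher_oracle <- function(a, b, c_, d_) {
    m <- a + b; n <- c_ + d_; k <- a + c_
    x <- max(0, k - n):min(k, m)
    pr <- dhyper(x, m, n, k)
    sum(pr[pr <= dhyper(a, m, n, k) * (1 + 1e-7)])
  }
  expect_equal(d$p[1], fisher_oracle(400, 100, 100, 100), tolerance = 1e-9)
  expect_lt(d$fdr[1], 0.05)

  # identical counts: log2FC = 0, unchanged
  at2 <- atlas[1, ]; at2$A_ko <- at2$A_wt <- 150; at2$D_ko <- at2$D_wt <- 150
  at2$retained_ko <- TRUE
  d2 <- detect_dmrs(at2, lib)
  expect_equal(d2$log2fc, 0)
  expect_equal(d2$category, "unchanged")

  # input scaling under unequal library sizes keeps a null peak null
  lib3 <- list(B_wt = 1e6, E_wt = 2e6, B_ko = 1e6, E_ko = 1e6)
  at3 <- atlas[1, ]; at3$A_wt <- 150; at3$D_wt <- 300
  at3$A_ko <- 150; at3$D_ko <- 150
  d3 <- detect_dmrs(at3, lib3)
  expect_equal(d3$category, "unchanged")
  expect_gt(d3$p, 0.5)

  # RNA-level aggregation
  dr <- dmrs_by_rna(d)
  expect_equal(dr$category[match(c("g1", "g2", "g3"), dr$rna_id)],
               c("hyper", "loss", "gain"))
})
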
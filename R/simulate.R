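#' Configuration for the synthetic MeRIP-seq study
#'
#' Defines the simulated study design: a developmental time course
#' (4 stages) in two conditions (wild type and knockout) with paired
#' IP/input libraries, one library per stage and condition. Per-gene
#' methylation dynamics are planted from four classes plus an "other"
#' remainder: continuously methylated (all stages), stage-specific
#' (exactly one stage), switching (one ON or OFF transition with at
#' least two methylated stages), and unmethylated; expression
#' trajectories of a fraction of continuously methylated genes are
#' forced to track (+) or oppose (-) their methylation level.
#'
#' @param n_genes Number of genes.
#' @param stages Ordered stage labels.
#' @param conditions Condition labels; the first is the baseline.
#' @param mean_depth Nominal unique-mapped reads per library; also the
#'   recorded library totals B and E.
#' @param mean_peak_reads Expected input reads on a 200-nt peak of a
#'   gene at reference expression (`fpkm_ref`); sets peak coverage.
#' @param fpkm_ref Reference expression level (FPKM) at which
#'   `mean_peak_reads` is calibrated.
#' @param enrichment_range Range of IP fold enrichment at methylated
#'   peaks (> 1).
#' @param class_proportions Named fractions for cmr, smr, switching,
#'   unmethylated; must sum to <= 1, remainder becomes "other"
#'   (multi-switch) patterns.
#' @param corr_fraction Fraction of CMR genes whose expression is
#'   forced to track or oppose methylation.
#' @param corr_pos_share Share of tracking genes with positive sign.
#' @param dmr_proportions Named fractions (of genes) perturbed in the
#'   knockout at `dmr_stage`: hyper (x4 methylation), hypo (/4), gain
#'   (methylated in KO only), loss (WT only).
#' @param dmr_stage Stage at which the conditions are compared.
#' @param noncoding_frac Fraction of genes without CDS.
#' @param multi_transcript_frac Fraction of genes with a second,
#'   shorter transcript (exercises longest-transcript selection).
#' @param low_expr_frac Fraction of genes with FPKM below the expressed
#'   cutoff at all stages.
#' @param peak_length_range Planted peak length range in nt.
#' @param read_length Read length for read-level output.
#' @param count_model "poisson" (default) or "nb".
#' @param nb_size Negative-binomial size (dispersion) when
#'   `count_model = "nb"`.
#' @param seed Integer seed; all generators are deterministic given it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000L,
                       stages = c("P7", "P14", "P21", "P60"),
                       conditions = c("WT", "KO"),
                       mean_depth = 2e6,
                       mean_peak_reads = 60,
                       fpkm_ref = 20,
                       enrichment_range = c(3, 10),
                       class_proportions = c(cmr = 0.35, smr = 0.20,
                                             switching = 0.20,
                                             unmethylated = 0.25),
                       corr_fraction = 0.20,
                       corr_pos_share = 0.8,
                       dmr_proportions = c(hyper = 0.05, hypo = 0.05,
                                           gain = 0.05, loss = 0.05),
                       dmr_stage = "P7",
                       noncoding_frac = 0.05,
                       multi_transcript_frac = 0.10,
                       low_expr_frac = 0.02,
                       peak_length_range = c(100L, 300L),
                       read_length = 100L,
                       count_model = c("poisson", "nb"),
                       nb_size = 10,
                       seed = 1L) {
  count_model <- match.arg(count_model)
  need <- c("cmr", "smr", "switching", "unmethylated")
  if (!all(need %in% names(class_proportions))) {
    stop("class_proportions needs names: ", paste(need, collapse = ", "))
  }
  if (any(class_proportions < 0)) stop("class proportions must be >= 0")
  if (sum(class_proportions) > 1 + 1e-8) stop("class proportions sum to > 1")
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  if (any(enrichment_range <= 1)) stop("enrichment factors must be > 1")
  if (length(stages) < 2) stop("need >= 2 stages")
  if (!dmr_stage %in% stages) stop("dmr_stage must be one of the stages")
  structure(list(
    n_genes = as.integer(n_genes), stages = stages, conditions = conditions,
    mean_depth = mean_depth, mean_peak_reads = mean_peak_reads,
    fpkm_ref = fpkm_ref, enrichment_range = enrichment_range,
    class_proportions = class_proportions, corr_fraction = corr_fraction,
    corr_pos_share = corr_pos_share, dmr_proportions = dmr_proportions,
    dmr_stage = dmr_stage, noncoding_frac = noncoding_frac,
    multi_transcript_frac = multi_transcript_frac,
    low_expr_frac = low_expr_frac,
    peak_length_range = as.integer(peak_length_range),
    read_length = as.integer(read_length),
    count_model = count_model, nb_size = nb_size, seed = as.integer(seed)
  ), class = "sim_config")
}

# one-flip status patterns with >= 2 methylated stages (classify as "other"
# would be wrong: they are the switching class; single-TRUE and all-TRUE
# patterns are reserved for SMR/CMR so classes stay mutually exclusive)
switch_patterns <- function(k) {
  pats <- list()
  for (t in seq_len(k - 1)) {
    on <- c(rep(FALSE, t), rep(TRUE, k - t))
    off <- c(rep(TRUE, t), rep(FALSE, k - t))
    if (sum(on) >= 2) pats[[length(pats) + 1]] <- list(p = on, t = t, d = "ON")
    if (sum(off) >= 2) pats[[length(pats) + 1]] <- list(p = off, t = t, d = "OFF")
  }
  pats
}

# multi-flip patterns for the "other" remainder class
other_patterns <- function(k) {
  pats <- list()
  for (m in 0:(2^k - 1)) {
    p <- as.logical(bitwAnd(bitwShiftR(m, 0:(k - 1)), 1L))
    s <- sum(p)
    flips <- sum(abs(diff(p)))
    if (s >= 2 && s < k && flips >= 2) pats[[length(pats) + 1]] <- p
  }
  pats
}

#' Generate the planted ground truth and annotation
#'
#' Builds a synthetic transcriptome (GTF-style annotation with exons
#' and CDS), plants one candidate peak locus per gene inside a single
#' exon of its reference transcript, and draws methylation schedules,
#' enrichment factors, expression trajectories and knockout
#' perturbations. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return list of class `merip_truth`: `config`, `annotation`
#'   (`GRanges`), `models`, `ref` (reference transcript models),
#'   `partition`, `genes` (per-gene table incl. class and expected
#'   label), `status`/`status_ko` (gene x stage logical), `factor_wt`/
#'   `factor_ko` (gene x stage), `expr` (gene x stage FPKM), `peaks`
#'   (per-peak table with transcript placement and planted region).
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  k <- length(config$stages)
  gene_id <- sprintf("g%04d", seq_len(n))
  tx_id <- paste0(gene_id, ".1")
  strand <- sample(c("+", "-"), n, replace = TRUE)
  chrom <- paste0("chr", (seq_len(n) - 1L) %/% 50L + 1L)
  coding <- stats::runif(n) >= config$noncoding_frac
  multi <- stats::runif(n) < config$multi_transcript_frac

  L <- sample(900:3000, n, replace = TRUE)
  u5 <- integer(n); cd <- integer(n); u3 <- integer(n)
  u5[coding] <- round(L[coding] * stats::runif(sum(coding), 0.08, 0.20))
  u3tmp <- round(L[coding] * stats::runif(sum(coding), 0.20, 0.35))
  cds0 <- L[coding] - u5[coding] - u3tmp
  cds0 <- cds0 - cds0 %% 3L
  cd[coding] <- cds0
  u3[coding] <- L[coding] - u5[coding] - cd[coding]
  u3[!coding] <- L[!coding]

  # exon structure and genomic layout
  n_ex <- sample(1:4, n, replace = TRUE, prob = c(0.55, 0.2, 0.15, 0.1))
  n_ex[n_ex * 200L > L] <- 1L
  feat <- vector("list", n)
  cursor <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    w <- if (n_ex[i] == 1) L[i] else {
      # each exon >= 200 nt: 200 + a random split of the excess
      excess <- L[i] - 200L * n_ex[i]
      cuts <- sort(sample.int(excess + 1L, n_ex[i] - 1L, replace = TRUE) - 1L)
      200L + diff(c(0L, cuts, excess))
    }
    introns <- if (n_ex[i] > 1) sample(200:2000, n_ex[i] - 1L, replace = TRUE) else integer()
    gap <- sample(1000:5000, 1L)
    base <- if (is.null(cursor[[chrom[i]]])) 1L else cursor[[chrom[i]]]
    gstart0 <- base + gap
    # genomic order exon widths: transcript order reversed on minus strand
    wg <- if (strand[i] == "-") rev(w) else w
    gs <- gstart0 + c(0L, cumsum(wg[-length(wg)] + introns))
    ge <- gs + wg - 1L
    cursor[[chrom[i]]] <- max(ge)
    rows <- data.frame(chrom = chrom[i], source = "epitempo_sim",
                       feature = "exon", start = gs, end = ge,
                       strand = strand[i], gene_id = gene_id[i],
                       transcript_id = tx_id[i], stringsAsFactors = FALSE)
    if (coding[i]) {
      # CDS occupies transcript interval [u5, u5 + cd) incl. stop codon
      toff <- cumsum(c(0L, w[-length(w)]))
      lo <- u5[i]; hi <- u5[i] + cd[i]
      cds_rows <- list()
      for (e in seq_len(n_ex[i])) {
        a <- max(lo, toff[e]); b <- min(hi, toff[e] + w[e])
        if (b <= a) next
        # exon e in transcript order; genomic coords of that exon
        eg_i <- if (strand[i] == "-") n_ex[i] - e + 1L else e
        if (strand[i] == "+") {
          g1 <- gs[eg_i] + (a - toff[e]); g2 <- gs[eg_i] + (b - 1L - toff[e])
        } else {
          g1 <- ge[eg_i] - (b - 1L - toff[e]); g2 <- ge[eg_i] - (a - toff[e])
        }
        cds_rows[[length(cds_rows) + 1L]] <- data.frame(
          chrom = chrom[i], source = "epitempo_sim", feature = "CDS",
          start = g1, end = g2, strand = strand[i], gene_id = gene_id[i],
          transcript_id = tx_id[i], stringsAsFactors = FALSE)
      }
      rows <- rbind(rows, do.call(rbind, cds_rows))
    }
    if (multi[i]) {
      # a shorter second transcript: drop the last exon, or 70% of a
      # single exon; exon-only (non-coding isoform)
      if (n_ex[i] > 1) {
        keep <- seq_len(n_ex[i] - 1L)
        eg_keep <- if (strand[i] == "-") n_ex[i] - keep + 1L else keep
        r2 <- data.frame(chrom = chrom[i], source = "epitempo_sim",
                         feature = "exon", start = gs[eg_keep],
                         end = ge[eg_keep], strand = strand[i],
                         gene_id = gene_id[i],
                         transcript_id = paste0(gene_id[i], ".2"),
                         stringsAsFactors = FALSE)
      } else {
        short <- as.integer(floor(0.7 * L[i]))
        if (strand[i] == "+") {
          r2 <- data.frame(chrom = chrom[i], source = "epitempo_sim",
                           feature = "exon", start = gs[1],
                           end = gs[1] + short - 1L, strand = strand[i],
                           gene_id = gene_id[i],
                           transcript_id = paste0(gene_id[i], ".2"),
                           stringsAsFactors = FALSE)
        } else {
          r2 <- data.frame(chrom = chrom[i], source = "epitempo_sim",
                           feature = "exon", start = ge[1] - short + 1L,
                           end = ge[1], strand = strand[i],
                           gene_id = gene_id[i],
                           transcript_id = paste0(gene_id[i], ".2"),
                           stringsAsFactors = FALSE)
        }
      }
      rows <- rbind(rows, r2)
    }
    feat[[i]] <- rows
  }
  features <- do.call(rbind, feat)
  annotation <- GenomicRanges::GRanges(
    features$chrom,
    IRanges::IRanges(features$start, features$end),
    strand = features$strand,
    type = features$feature,
    gene_id = features$gene_id,
    transcript_id = features$transcript_id,
    source = features$source
  )
  models <- transcript_models(annotation)
  ref <- select_reference_transcripts(models)
  partition <- suppressMessages(partition_regions(ref))

  # methylation classes
  cp <- config$class_proportions
  probs <- c(cp["cmr"], cp["smr"], cp["switching"], cp["unmethylated"],
             other = max(0, 1 - sum(cp)))
  cls <- sample(c("cmr", "smr", "switching", "unmethylated", "other"),
                n, replace = TRUE, prob = probs)
  status <- matrix(FALSE, n, k, dimnames = list(gene_id, config$stages))
  sw_t <- rep(NA_integer_, n); sw_d <- rep(NA_character_, n)
  sp <- switch_patterns(k); op <- other_patterns(k)
  label <- character(n)
  for (i in seq_len(n)) {
    if (cls[i] == "cmr") {
      status[i, ] <- TRUE; label[i] <- "CMR"
    } else if (cls[i] == "smr") {
      s <- sample.int(k, 1L)
      status[i, s] <- TRUE; label[i] <- paste0("SMR:", config$stages[s])
    } else if (cls[i] == "switching") {
      pp <- sp[[sample.int(length(sp), 1L)]]
      status[i, ] <- pp$p; sw_t[i] <- pp$t; sw_d[i] <- pp$d
      label[i] <- "other"
    } else if (cls[i] == "other") {
      status[i, ] <- op[[sample.int(length(op), 1L)]]
      label[i] <- "other"
    } else label[i] <- "unmethylated"
  }

  # enrichment factors (baseline condition)
  er <- config$enrichment_range
  factor_wt <- matrix(1, n, k, dimnames = list(gene_id, config$stages))
  draw <- which(status)
  factor_wt[draw] <- stats::runif(length(draw), er[1], er[2])

  # expression trajectories; tracking genes are drawn from the
  # continuously methylated, well-expressed tier (the screen is only
  # powered there)
  expr <- matrix(0, n, k, dimnames = list(gene_id, config$stages))
  base <- pmin(pmax(stats::rlnorm(n, log(20), 0.6), 2), 150)
  for (i in seq_len(n)) expr[i, ] <- base[i] * exp(stats::rnorm(k, 0, 0.25))
  corr_sign <- rep("none", n)
  cmr_idx <- which(cls == "cmr")
  n_corr <- round(config$corr_fraction * length(cmr_idx))
  if (n_corr > 0) {
    ci <- sample(cmr_idx, n_corr)
    pos <- stats::runif(n_corr) < config$corr_pos_share
    corr_sign[ci] <- ifelse(pos, "positive", "negative")
    for (j in seq_along(ci)) {
      i <- ci[j]
      f <- sample(seq(er[1], er[2], length.out = k))
      factor_wt[i, ] <- f
      noise <- exp(stats::rnorm(k, 0, 0.02))
      expr[i, ] <- if (pos[j]) 200 * f / mean(f) * noise
                   else 200 * (er[1] + er[2] + 3 - f) / mean(er[1] + er[2] + 3 - f) * noise
    }
  }
  low_idx <- sample(setdiff(seq_len(n), which(corr_sign != "none")),
                    round(config$low_expr_frac * n))
  for (i in low_idx) expr[i, ] <- stats::runif(k, 0.02, 0.15)
  if (any(status[low_idx, ])) {
    warning(sum(rowSums(status[low_idx, , drop = FALSE]) > 0),
            " methylated gene(s) have near-zero expression; their peaks",
            " may be undetectable (kept in truth)")
  }

  # knockout perturbation at dmr_stage
  ds <- match(config$dmr_stage, config$stages)
  status_ko <- status
  factor_ko <- factor_wt
  dmr_cat <- rep(NA_character_, n)
  dmr_cat[status[, ds]] <- "unchanged"
  dp <- config$dmr_proportions
  meth_pool <- setdiff(which(status[, ds]), which(corr_sign != "none"))
  unmeth_pool <- setdiff(which(!status[, ds]), low_idx)
  take <- function(pool, m) if (m > length(pool)) pool else sample(pool, m)
  hy <- take(meth_pool, round(dp["hyper"] * n)); meth_pool <- setdiff(meth_pool, hy)
  ho <- take(meth_pool, round(dp["hypo"] * n)); meth_pool <- setdiff(meth_pool, ho)
  lo_ <- take(meth_pool, round(dp["loss"] * n))
  ga <- take(unmeth_pool, round(dp["gain"] * n))
  factor_ko[hy, ds] <- factor_wt[hy, ds] * 4
  factor_wt[ho, ds] <- stats::runif(length(ho), 7, 10)  # keep KO level above retention
  factor_ko[ho, ds] <- factor_wt[ho, ds] / 4
  factor_ko[lo_, ds] <- 1; status_ko[lo_, ds] <- FALSE
  status_ko[ga, ds] <- TRUE
  factor_ko[ga, ds] <- stats::runif(length(ga), er[1], er[2])
  dmr_cat[hy] <- "hyper"; dmr_cat[ho] <- "hypo"
  dmr_cat[lo_] <- "loss"; dmr_cat[ga] <- "gain"

  # plant one peak locus per gene inside a single exon
  region_w <- c(utr5 = 0.08, start_codon = 0.15, cds = 0.30,
                stop_codon = 0.30, utr3 = 0.17)
  pk <- vector("list", n)
  for (i in seq_len(n)) {
    tid <- tx_id[i]
    e <- tx_exons(ref, tid)
    spans <- cbind(lo = e$toffset, hi = e$toffset + e$width)
    if (coding[i]) {
      p <- partition[partition$transcript_id == tid, ]
      regs <- list(utr5 = c(p$utr5_lo, p$utr5_hi),
                   start_codon = c(p$start_lo, p$start_hi),
                   cds = c(p$cds_lo, p$cds_hi),
                   stop_codon = c(p$stop_lo, p$stop_hi),
                   utr3 = c(p$utr3_lo, p$utr3_hi))
    } else {
      regs <- list(any = c(0L, L[i]))
    }
    # exon-intersected pieces per region
    pieces <- lapply(regs, function(r) {
      lo <- pmax(r[1], spans[, "lo"]); hi <- pmin(r[2], spans[, "hi"])
      ok <- hi - lo >= 60
      cbind(lo = lo[ok], hi = hi[ok])
    })
    avail <- names(pieces)[vapply(pieces, nrow, 1L) > 0]
    if (!length(avail)) {  # no region piece hosts a peak: place anywhere exonic
      pieces <- list(any = cbind(lo = spans[, "lo"], hi = spans[, "hi"]))
      avail <- "any"
    }
    wts <- if (coding[i] && avail[1] != "any") region_w[avail] else rep(1, length(avail))
    reg <- if (length(avail) == 1) avail else sample(avail, 1L, prob = wts)
    pc <- pieces[[reg]]
    row <- if (nrow(pc) == 1) 1L else sample(nrow(pc), 1L, prob = pc[, "hi"] - pc[, "lo"])
    plo <- pc[row, "lo"]; phi <- pc[row, "hi"]
    plen <- min(sample(config$peak_length_range[1]:config$peak_length_range[2], 1L),
                phi - plo)
    ps <- plo + sample.int(phi - plo - plen + 1L, 1L) - 1L
    g1 <- tx_to_genomic(ref, tid, ps)
    g2 <- tx_to_genomic(ref, tid, ps + plen - 1L)
    pk[[i]] <- data.frame(
      peak_id = paste0("pk_", gene_id[i]), gene_id = gene_id[i],
      transcript_id = tid, chrom = chrom[i], start = min(g1, g2),
      end = max(g1, g2), strand = strand[i], tx_start = ps,
      tx_end = ps + plen, length = plen,
      region = if (coding[i] && reg != "any") reg else NA_character_,
      stringsAsFactors = FALSE
    )
  }
  peaks <- do.call(rbind, pk)

  genes <- data.frame(
    gene_id = gene_id, transcript_id = tx_id, chrom = chrom,
    strand = strand, coding = coding, total_length = L,
    class = cls, label = label, switch_transition = sw_t,
    switch_direction = sw_d, corr_sign = corr_sign,
    dmr_category = dmr_cat, low_expr = seq_len(n) %in% low_idx,
    stringsAsFactors = FALSE
  )
  structure(list(
    config = config, annotation = annotation, features = features,
    models = models, ref = ref, partition = partition, genes = genes,
    status = status, status_ko = status_ko, factor_wt = factor_wt,
    factor_ko = factor_ko, expr = expr, peaks = peaks
  ), class = "merip_truth")
}

#' @export
print.merip_truth <- function(x, ...) {
  cat("merip_truth:", nrow(x$genes), "genes;",
      sum(x$status), "methylated gene-stages (baseline)\n")
  print(table(x$genes$class))
  invisible(x)
}

#' Simulate per-peak IP/input counts and library statistics
#'
#' Input counts on each peak locus are Poisson (or negative binomial)
#' with rate proportional to expression and peak length; IP counts use
#' the same rate multiplied by the planted enrichment factor (1 at
#' unmethylated stages). Library totals are recorded as the configured
#' nominal depth for both IP and input so the enrichment score (Eq.
#' ratio of normalized densities) recovers the planted factor in
#' expectation. Per-transcript input counts for expression analysis
#' are drawn to match the planted FPKM.
#'
#' @param truth A `merip_truth`.
#' @param config The same [sim_config()] (defaults to `truth$config`).
#' @param seed Seed (default `config$seed + 1`).
#' @return list of class `merip_counts`: `counts` (long data.frame:
#'   peak_id, gene_id, sample_id, condition, stage, C, ip_count,
#'   input_count, true_factor), `libstats` (sample_id, condition,
#'   stage, ip_total, input_total), `expr_counts` (gene_id,
#'   transcript_id, sample_id, condition, stage, length, count).
#' @export
simulate_counts <- function(truth, config = truth$config,
                            seed = config$seed + 1L) {
  set.seed(seed)
  n <- config$n_genes
  stages <- config$stages
  conds <- config$conditions
  draw <- function(lambda) {
    if (config$count_model == "poisson") stats::rpois(length(lambda), lambda)
    else stats::rnbinom(length(lambda), mu = lambda, size = config$nb_size)
  }
  Ltx <- truth$genes$total_length
  C <- truth$peaks$length
  out <- list(); lib <- list(); ec <- list()
  for (cond in conds) {
    fac <- if (cond == conds[1]) truth$factor_wt else truth$factor_ko
    for (s in stages) {
      sid <- paste(cond, s, sep = "_")
      lam_in <- config$mean_peak_reads * (truth$expr[, s] / config$fpkm_ref) *
        (C / 200)
      D <- draw(lam_in)
      A <- draw(lam_in * fac[, s])
      out[[sid]] <- data.frame(
        peak_id = truth$peaks$peak_id, gene_id = truth$peaks$gene_id,
        sample_id = sid, condition = cond, stage = s, C = C,
        ip_count = A, input_count = D, true_factor = fac[, s],
        stringsAsFactors = FALSE
      )
      lib[[sid]] <- data.frame(sample_id = sid, condition = cond, stage = s,
                               ip_total = config$mean_depth,
                               input_total = config$mean_depth,
                               stringsAsFactors = FALSE)
      lam_e <- truth$expr[, s] * config$mean_depth * Ltx / 1e9
      ec[[sid]] <- data.frame(
        gene_id = truth$genes$gene_id,
        transcript_id = truth$genes$transcript_id,
        sample_id = sid, condition = cond, stage = s, length = Ltx,
        count = draw(lam_e), stringsAsFactors = FALSE
      )
    }
  }
  structure(list(counts = do.call(rbind, out),
                 libstats = do.call(rbind, lib),
                 expr_counts = do.call(rbind, ec)),
            class = "merip_counts")
}

#' Simulate read intervals (BED6-style) for one library pair
#'
#' Generates IP and input read intervals along single-exon reference
#' transcripts: background reads uniform over the transcript at an
#' expression-proportional rate, plus IP-only extra reads over the
#' planted peak so the in-peak IP rate is `factor` times the input
#' rate. Multi-exon genes are skipped (read intervals are single-block;
#' splice-aware reads are not modeled).
#'
#' @param truth A `merip_truth`.
#' @param stage,condition Library to simulate.
#' @param gene_depth Expected background reads per gene at reference
#'   expression.
#' @param config,seed As in [simulate_counts()].
#' @return list with `ip`, `input` (`GRanges` of reads) and the gene
#'   ids used.
#' @export
simulate_read_intervals <- function(truth, stage, condition = "WT",
                                    gene_depth = 200,
                                    config = truth$config,
                                    seed = config$seed + 2L) {
  set.seed(seed)
  single <- truth$ref$tx$transcript_id[truth$ref$tx$n_exons == 1]
  use <- which(truth$genes$transcript_id %in% single & !truth$genes$low_expr)
  rl <- config$read_length
  fac <- if (condition == config$conditions[1]) truth$factor_wt else truth$factor_ko
  ipr <- list(chrom = character(), start = integer(), strand = character())
  inr <- ipr
  add <- function(acc, chrom, start, strand) {
    if (!length(start)) return(acc)
    list(chrom = c(acc$chrom, rep(chrom, length(start))),
         start = c(acc$start, start),
         strand = c(acc$strand, rep(strand, length(start))))
  }
  for (j in seq_along(use)) {
    i <- use[j]
    tid <- truth$genes$transcript_id[i]
    e <- tx_exons(truth$ref, tid)
    L <- e$width[1]
    if (L <= rl) next
    lam <- gene_depth * truth$expr[i, stage] / config$fpkm_ref
    n_in <- stats::rpois(1, lam)
    n_ip_bg <- stats::rpois(1, lam)
    ps <- truth$peaks$tx_start[i]; pe <- truth$peaks$tx_end[i]
    f <- fac[i, stage]
    n_extra <- stats::rpois(1, lam * (pe - ps) / L * (f - 1))
    pos_in <- sample.int(L - rl + 1L, n_in, replace = TRUE) - 1L
    pos_bg <- sample.int(L - rl + 1L, n_ip_bg, replace = TRUE) - 1L
    lo <- max(0L, ps - rl %/% 2L)
    hi <- min(L - rl, pe - rl %/% 2L)
    pos_ex <- if (n_extra > 0 && hi >= lo) lo + sample.int(hi - lo + 1L, n_extra, replace = TRUE) - 1L else integer()
    gpos <- function(tpos) {
      if (e$strand[1] == "+") e$gstart[1] + tpos else e$gend[1] - tpos - rl + 1L
    }
    inr <- add(inr, e$chrom[1], gpos(pos_in), e$strand[1])
    ipr <- add(ipr, e$chrom[1], gpos(c(pos_bg, pos_ex)), e$strand[1])
  }
  to_gr <- function(acc) GenomicRanges::GRanges(
    acc$chrom, IRanges::IRanges(acc$start, width = rl), strand = acc$strand)
  list(ip = to_gr(ipr), input = to_gr(inr),
       gene_ids = truth$genes$gene_id[use])
}

#' Simulate a synthetic MeRIP-seq study
#'
#' Convenience wrapper: [generate_truth()] then [simulate_counts()].
#'
#' @param config A [sim_config()].
#' @return list of class `merip_study` with `truth` and `counts`.
#' @export
simulate_study <- function(config) {
  truth <- generate_truth(config)
  counts <- simulate_counts(truth, config)
  structure(list(truth = truth, counts = counts, config = config),
            class = "merip_study")
}

#' Simulate FASTQ reads with planted adapter contamination
#'
#' A fraction of reads carries the adapter starting at a recorded
#' offset, with 0-3 planted substitutions; bases downstream of the
#' adapter are random (read-through). Background sequence is
#' rejection-sampled so that no read contains a spurious <= 2-mismatch
#' adapter occurrence outside its planted site -- the planted truth is
#' therefore unambiguous. Qualities decline along the read; a fraction
#' of reads gets a low-quality 3' tail to exercise quality trimming.
#'
#' @param n_reads Number of reads.
#' @param read_length Read length (uniform).
#' @param adapter_rate Fraction of reads with a planted adapter.
#' @param mismatch_weights Weights for 0, 1, 2, 3 planted
#'   substitutions among adapter-bearing reads.
#' @param adapter Adapter sequence.
#' @param low_tail_rate Fraction of reads with a low-quality 3' tail.
#' @param fastq_out Optional output FASTQ path (Phred+33).
#' @param seed Integer seed.
#' @return list with `truth` (read_id, planted, offset (0-based),
#'   n_mismatch), `seq` (character), `qual` (list of integer vectors),
#'   and `path` (or NULL).
#' @export
simulate_fastq <- function(n_reads, read_length = 100L, adapter_rate = 0.3,
                           mismatch_weights = c(0.5, 0.3, 0.2, 0),
                           adapter = "AGATCGGAAG", low_tail_rate = 0.3,
                           fastq_out = NULL, seed = 1L) {
  if (adapter_rate < 0 || adapter_rate > 1) stop("adapter_rate must be in [0, 1]")
  set.seed(seed)
  alen <- nchar(adapter)
  achars <- strsplit(adapter, "")[[1]]
  bases <- c("A", "C", "G", "T")
  planted <- stats::runif(n_reads) < adapter_rate
  nmm <- rep(NA_integer_, n_reads)
  nmm[planted] <- sample(0:3, sum(planted), replace = TRUE,
                         prob = mismatch_weights)
  offset <- rep(NA_integer_, n_reads)
  offset[planted] <- sample(20:(read_length - alen), sum(planted),
                            replace = TRUE)
  rand_seq <- function(len) paste(sample(bases, len, replace = TRUE),
                                  collapse = "")
  mutate_adapter <- function(m) {
    a <- achars
    if (m > 0) {
      at <- sample.int(alen, m)
      for (p in at) a[p] <- sample(setdiff(bases, a[p]), 1L)
    }
    paste(a, collapse = "")
  }
  gen_one <- function(i) {
    if (planted[i]) paste0(rand_seq(offset[i]), mutate_adapter(nmm[i]),
                           rand_seq(read_length - offset[i] - alen))
    else rand_seq(read_length)
  }
  seqs <- vapply(seq_len(n_reads), gen_one, "")
  todo <- seq_len(n_reads)
  while (length(todo)) {
    m <- Biostrings::vmatchPattern(adapter, Biostrings::DNAStringSet(seqs[todo]),
                                   max.mismatch = 2L, with.indels = FALSE,
                                   fixed = TRUE)
    st <- Biostrings::startIndex(m)
    ok <- vapply(seq_along(todo), function(j) {
      i <- todo[j]; s <- st[[j]]
      if (planted[i] && nmm[i] <= 2L) {
        !is.null(s) && length(s) >= 1 && min(s) == offset[i] + 1L
      } else is.null(s) || length(s) == 0
    }, TRUE)
    todo <- todo[!ok]
    if (length(todo)) seqs[todo] <- vapply(todo, gen_one, "")
  }
  qual <- vector("list", n_reads)
  decline <- 38 - 8 * (seq_len(read_length) - 1) / (read_length - 1)
  for (i in seq_len(n_reads)) {
    q <- pmin(40L, pmax(2L, as.integer(round(decline + stats::rnorm(read_length, 0, 3)))))
    if (stats::runif(1) < low_tail_rate) {
      t <- sample(3:15, 1L)
      q[(read_length - t + 1L):read_length] <- sample(2:19, t, replace = TRUE)
    }
    qual[[i]] <- q
  }
  ids <- sprintf("read_%06d", seq_len(n_reads))
  truth <- data.frame(read_id = ids, planted = planted, offset = offset,
                      n_mismatch = nmm, stringsAsFactors = FALSE)
  path <- NULL
  if (!is.null(fastq_out)) {
    qs <- vapply(qual, function(q) rawToChar(as.raw(q + 33L)), "")
    lines <- character(4L * n_reads)
    lines[seq(1, by = 4, length.out = n_reads)] <- paste0("@", ids)
    lines[seq(2, by = 4, length.out = n_reads)] <- seqs
    lines[seq(3, by = 4, length.out = n_reads)] <- "+"
    lines[seq(4, by = 4, length.out = n_reads)] <- qs
    writeLines(lines, fastq_out)
    path <- fastq_out
  }
  list(truth = truth, seq = seqs, qual = qual, path = path)
}
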
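#' Transcript FPKM and the expressed-transcript flag
#'
#' FPKM = count * 1e9 / (library size * transcript length). A
#' transcript is expressed iff FPKM is strictly greater than the cutoff
#' (default 0.2).
#'
#' @param count Fragment counts (vectorized).
#' @param length Transcript lengths in nt (> 0).
#' @param lib_size Total mapped fragments in the library (> 0).
#' @param expressed_cutoff Strict FPKM threshold (default 0.2).
#' @return data.frame with `fpkm` and logical `expressed`.
#' @export
compute_fpkm <- function(count, length, lib_size, expressed_cutoff = 0.2) {
  n <- max(base::length(count), base::length(length), base::length(lib_size))
  count <- rep_len(count, n); length <- rep_len(length, n)
  lib_size <- rep_len(lib_size, n)
  if (any(length <= 0)) stop("transcript length must be > 0")
  if (any(lib_size <= 0)) stop("library size must be > 0")
  fpkm <- count * 1e9 / (lib_size * length)
  data.frame(fpkm = fpkm, expressed = fpkm > expressed_cutoff)
}

#' Methylation-expression correlation screen
#'
#' Per RNA, the Pearson correlation between its per-stage methylation
#' level (enrichment scores) and per-stage expression (FPKM) across the
#' four stages; two-sided P from the t distribution with n - 2 = 2
#' degrees of freedom. High-confidence pairs: positive iff r > r_cut
#' and P < p_cut; negative iff r < -r_cut and P < p_cut. RNAs with zero
#' variance in either vector are skipped.
#'
#' @param meth Numeric matrix RNAs x stages of methylation levels.
#' @param expr Numeric matrix (same shape) of FPKM.
#' @param r_cut,p_cut Thresholds (defaults 0.95 and 0.05, strict).
#' @return list with `pairs` (data.frame: rna_id, r, p, class in
#'   positive/negative/none/skipped) and `tally` (named counts of
#'   positive and negative pairs).
#' @export
correlate_methylation_expression <- function(meth, expr, r_cut = 0.95,
                                             p_cut = 0.05) {
  stopifnot(all(dim(meth) == dim(expr)), ncol(meth) >= 3)
  nst <- ncol(meth)
  rna <- rownames(meth)
  if (is.null(rna)) rna <- paste0("rna_", seq_len(nrow(meth)))
  r <- rep(NA_real_, nrow(meth)); p <- rep(NA_real_, nrow(meth))
  cls <- rep("skipped", nrow(meth))
  for (i in seq_len(nrow(meth))) {
    x <- meth[i, ]; y <- expr[i, ]
    if (any(!is.finite(x)) || any(!is.finite(y))) next
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    ri <- stats::cor(x, y)
    r[i] <- ri
    tt <- ri * sqrt(nst - 2) / sqrt(pmax(1 - ri^2, .Machine$double.eps))
    p[i] <- 2 * stats::pt(-abs(tt), df = nst - 2)
    cls[i] <- if (ri > r_cut && p[i] < p_cut) "positive"
      else if (ri < -r_cut && p[i] < p_cut) "negative"
      else "none"
  }
  pairs <- data.frame(rna_id = rna, r = r, p = p, class = cls,
                      stringsAsFactors = FALSE)
  tally <- c(positive = sum(cls == "positive"), negative = sum(cls == "negative"))
  list(pairs = pairs, tally = tally)
}

#' Per-RNA per-stage methylation level from retained peaks
#'
#' Aggregates retained-peak enrichment scores to one methylation level
#' per RNA and stage: the maximum score by default (mean optional).
#' Stages where the RNA has no retained peak contribute 0 so every RNA
#' has a complete trajectory.
#'
#' @param rna_id,stage,score Parallel vectors over retained peaks
#'   (non-finite scores dropped).
#' @param stages Ordered stage labels.
#' @param aggregate `"max"` (default) or `"mean"`.
#' @param all_rnas Optional universe of RNA ids.
#' @return Numeric matrix RNAs x stages.
#' @export
methylation_level_matrix <- function(rna_id, stage, score, stages,
                                     aggregate = c("max", "mean"),
                                     all_rnas = NULL) {
  aggregate <- match.arg(aggregate)
  ok <- is.finite(score)
  rna_id <- rna_id[ok]; stage <- stage[ok]; score <- score[ok]
  if (is.null(all_rnas)) all_rnas <- sort(unique(rna_id))
  m <- matrix(0, length(all_rnas), length(stages),
              dimnames = list(all_rnas, stages))
  if (length(score)) {
    fun <- if (aggregate == "max") max else mean
    agg <- tapply(score, list(rna_id, stage), fun)
    ri <- match(rownames(agg), all_rnas)
    ci <- match(colnames(agg), stages)
    keep_r <- !is.na(ri); keep_c <- !is.na(ci)
    sub <- agg[keep_r, keep_c, drop = FALSE]
    sub[is.na(sub)] <- 0
    m[ri[keep_r], ci[keep_c]] <- sub
  }
  m
}
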
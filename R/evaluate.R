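#' Recovery of planted truth by a pipeline run
#'
#' Compares an [run_pipeline()] result against the generating
#' `merip_truth`:
#' \describe{
#'   \item{class_f1}{macro F1 over the CMR and per-stage SMR labels
#'     (truth label from the planted status pattern vs the recovered
#'     class; RNAs missing from the recovered profiles count as
#'     unmethylated).}
#'   \item{switch_sensitivity}{fraction of truth-implied ON/OFF events
#'     (pairwise diffs of the planted status patterns across adjacent
#'     stages) detected at a merged peak hosted by the same RNA.}
#'   \item{dmr_accuracy}{fraction of atlas peaks with a planted
#'     differential category (incl. unchanged) recovered exactly, among
#'     peaks retained in at least one condition at the comparison
#'     stage.}
#'   \item{region_recovery}{fraction of detected coding-gene peaks
#'     whose five-region label matches the planted region.}
#'   \item{spearman_factor_score}{Spearman correlation between planted
#'     enrichment factor and the computed enrichment score over all
#'     peak-sample quantifications with finite scores.}
#'   \item{corr_sign_recovery}{fraction of planted tracking RNAs
#'     recovered with the correct correlation sign.}
#' }
#'
#' @param run An `epitempo_run`.
#' @param truth The `merip_truth` that generated the study.
#' @return Named list of the six recovery statistics, each a list with
#'   `value` and `n`.
#' @export
evaluate_recovery <- function(run, truth) {
  stages <- truth$config$stages
  genes <- truth$genes

  # CMR/SMR macro F1
  truth_label <- genes$label
  names(truth_label) <- genes$gene_id
  pred <- rep("unmethylated", nrow(genes))
  names(pred) <- genes$gene_id
  got <- run$classes$labels
  pred[names(got)] <- got
  f1s <- vapply(c("CMR", paste0("SMR:", stages)), function(lb) {
    tp <- sum(pred == lb & truth_label == lb)
    fp <- sum(pred == lb & truth_label != lb)
    fn <- sum(pred != lb & truth_label == lb)
    if (tp == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, 1.0)
  class_f1 <- mean(f1s)

  # switch sensitivity against truth-implied events
  expected <- list()
  st <- truth$status
  for (i in seq_len(length(stages) - 1L)) {
    d_on <- which(!st[, i] & st[, i + 1L])
    d_off <- which(st[, i] & !st[, i + 1L])
    trans <- paste0(stages[i], "-", stages[i + 1L])
    if (length(d_on)) expected[[length(expected) + 1L]] <-
      data.frame(rna_id = rownames(st)[d_on], transition = trans,
                 direction = "ON", stringsAsFactors = FALSE)
    if (length(d_off)) expected[[length(expected) + 1L]] <-
      data.frame(rna_id = rownames(st)[d_off], transition = trans,
                 direction = "OFF", stringsAsFactors = FALSE)
  }
  expected <- do.call(rbind, expected)
  key_exp <- paste(expected$rna_id, expected$transition, expected$direction)
  key_got <- paste(run$switches$rna_id, run$switches$transition,
                   run$switches$direction)
  switch_sens <- mean(key_exp %in% key_got)

  # DMR category accuracy
  dmr_acc <- NA_real_; n_dmr <- 0L
  if (!is.null(run$dmr)) {
    d <- run$dmr[!is.na(run$dmr$category), , drop = FALSE]
    tcat <- genes$dmr_category[match(d$rna_id, genes$gene_id)]
    use <- !is.na(tcat)
    dmr_acc <- mean(d$category[use] == tcat[use])
    n_dmr <- sum(use)
  }

  # planted metagene region recovery
  reg <- run$region_counts$region
  loc <- run$located
  treg <- truth$peaks$region[match(loc$gene_id, truth$peaks$gene_id)]
  use <- !is.na(treg) & !is.na(reg)
  region_rec <- mean(as.character(reg[use]) == treg[use])
  n_region <- sum(use)

  # enrichment factor vs score
  q <- run$quant
  fin <- is.finite(q$c)
  sp <- stats::cor(q$true_factor[fin], q$c[fin], method = "spearman")

  # correlation sign recovery
  planted <- genes[genes$corr_sign != "none", ]
  cls <- run$correlation$pairs
  got_cls <- cls$class[match(planted$gene_id, cls$rna_id)]
  corr_rec <- mean(!is.na(got_cls) & got_cls == planted$corr_sign)

  list(
    class_f1 = list(value = class_f1, n = nrow(genes)),
    switch_sensitivity = list(value = switch_sens, n = nrow(expected)),
    dmr_accuracy = list(value = dmr_acc, n = n_dmr),
    region_recovery = list(value = region_rec, n = n_region),
    spearman_factor_score = list(value = sp, n = sum(fin)),
    corr_sign_recovery = list(value = corr_rec, n = nrow(planted))
  )
}
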
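#' Merge retained peaks across samples into a peak atlas
#'
#' Strand-aware single-linkage union of overlapping or bookended peak
#' intervals across all samples (mergeBed-style), with per-stage
#' presence: a stage is present at a merged peak iff at least one of
#' that stage's retained peaks overlaps the union interval by >= 1 nt
#' on the same strand.
#'
#' @param peaks `GRanges` of retained peaks with a `stage` metadata
#'   column (and optionally `sample_id`, `rna_id`).
#' @param stages Ordered character vector of stage labels.
#' @return `GRanges` of merged peaks with mcols `merged_id`, a logical
#'   presence column per stage, `n_members`, and `rna_id` (the most
#'   frequent member annotation, when available).
#' @export
merge_peak_atlas <- function(peaks, stages) {
  if (is.null(peaks$stage)) stop("peaks need a 'stage' metadata column")
  merged <- GenomicRanges::reduce(peaks, ignore.strand = FALSE)
  S4Vectors::mcols(merged)$merged_id <- paste0("mp_", seq_along(merged))
  for (s in stages) {
    S4Vectors::mcols(merged)[[paste0("present_", s)]] <-
      IRanges::overlapsAny(merged, peaks[peaks$stage == s],
                           ignore.strand = FALSE)
  }
  hits <- GenomicRanges::findOverlaps(merged, peaks, ignore.strand = FALSE)
  S4Vectors::mcols(merged)$n_members <-
    tabulate(S4Vectors::queryHits(hits), nbins = length(merged))
  if (!is.null(peaks$rna_id)) {
    rna <- rep(NA_character_, length(merged))
    qh <- S4Vectors::queryHits(hits)
    memb <- split(as.character(peaks$rna_id[S4Vectors::subjectHits(hits)]), qh)
    for (nm in names(memb)) {
      tab <- sort(table(memb[[nm]]), decreasing = TRUE)
      rna[as.integer(nm)] <- names(tab)[1]
    }
    S4Vectors::mcols(merged)$rna_id <- rna
  }
  merged
}

#' Extract the stage-presence matrix of a merged atlas
#'
#' @param merged Output of [merge_peak_atlas()].
#' @param stages Ordered stage labels.
#' @return Logical matrix, merged peaks x stages.
#' @export
presence_matrix <- function(merged, stages) {
  cols <- paste0("present_", stages)
  miss <- setdiff(cols, names(S4Vectors::mcols(merged)))
  if (length(miss)) stop("missing presence columns: ", paste(miss, collapse = ", "))
  m <- as.matrix(as.data.frame(S4Vectors::mcols(merged)[cols]))
  colnames(m) <- stages
  rownames(m) <- merged$merged_id
  m
}

#' Detect ON/OFF methylation switches across adjacent stages
#'
#' For each adjacent stage pair, a merged peak absent at the former
#' stage but present at the later is an ON switch; present then absent
#' is an OFF switch. A peak can yield events at several transitions.
#'
#' @param presence Logical matrix (peaks x ordered stages), as from
#'   [presence_matrix()], or a merged atlas `GRanges`.
#' @param stages Ordered stage labels (required for a `GRanges` input;
#'   defaults to the matrix column names).
#' @param rna_id Optional per-peak host RNA ids.
#' @return data.frame: merged_id, transition (e.g. "P7-P14"),
#'   direction ("ON"/"OFF"), rna_id.
#' @export
detect_switches <- function(presence, stages = colnames(presence), rna_id = NULL) {
  if (methods::is(presence, "GRanges")) {
    if (is.null(stages)) stop("stages required")
    if (is.null(rna_id) && !is.null(presence$rna_id)) rna_id <- presence$rna_id
    presence <- presence_matrix(presence, stages)
  }
  if (length(stages) < 2) stop("need >= 2 ordered stages")
  if (is.null(rna_id)) rna_id <- rep(NA_character_, nrow(presence))
  out <- list()
  for (i in seq_len(length(stages) - 1L)) {
    s1 <- stages[i]; s2 <- stages[i + 1L]
    trans <- paste0(s1, "-", s2)
    on <- which(!presence[, s1] & presence[, s2])
    off <- which(presence[, s1] & !presence[, s2])
    if (length(on)) out[[length(out) + 1L]] <- data.frame(
      merged_id = rownames(presence)[on], transition = trans,
      direction = "ON", rna_id = rna_id[on], stringsAsFactors = FALSE)
    if (length(off)) out[[length(out) + 1L]] <- data.frame(
      merged_id = rownames(presence)[off], transition = trans,
      direction = "OFF", rna_id = rna_id[off], stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(merged_id = character(), transition = character(),
                      direction = character(), rna_id = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Per-RNA methylation profiles from retained peaks
#'
#' An RNA is methylated at a stage iff it hosts >= 1 retained peak in
#' that stage's sample.
#'
#' @param rna_id,stage Parallel vectors over retained peaks.
#' @param stages Ordered stage labels.
#' @param all_rnas Optional universe of RNA ids (rows); defaults to the
#'   RNAs seen among retained peaks.
#' @return Logical matrix, RNAs x stages.
#' @export
rna_methylation_profiles <- function(rna_id, stage, stages, all_rnas = NULL) {
  if (is.null(all_rnas)) all_rnas <- sort(unique(rna_id))
  m <- matrix(FALSE, length(all_rnas), length(stages),
              dimnames = list(all_rnas, stages))
  keep <- rna_id %in% all_rnas & stage %in% stages
  m[cbind(match(rna_id[keep], all_rnas), match(stage[keep], stages))] <- TRUE
  m
}

#' Classify RNAs as continuously / specifically methylated
#'
#' CMR: methylated at all stages. SMR(s): methylated at exactly one
#' stage s. "other": methylated at 2..(k-1) stages. "unmethylated":
#' no stage. Classes are mutually exclusive by construction.
#'
#' @param profiles Logical matrix RNAs x stages
#'   ([rna_methylation_profiles()]).
#' @return list with `labels` (character vector named by RNA; "CMR",
#'   "SMR:<stage>", "other", "unmethylated") and `tally` (named counts).
#' @export
classify_cmr_smr <- function(profiles) {
  k <- ncol(profiles)
  nm <- rowSums(profiles)
  labels <- rep("other", nrow(profiles))
  labels[nm == k] <- "CMR"
  labels[nm == 0] <- "unmethylated"
  one <- which(nm == 1)
  if (length(one)) {
    st <- colnames(profiles)[apply(profiles[one, , drop = FALSE], 1, which)]
    labels[one] <- paste0("SMR:", st)
  }
  names(labels) <- rownames(profiles)
  lev <- c("CMR", paste0("SMR:", colnames(profiles)), "other", "unmethylated")
  tally <- table(factor(labels, levels = lev))
  list(labels = labels, tally = tally)
}

#' Differential methylation between two conditions over a common atlas
#'
#' Per merged peak, the methylation log2 fold change is
#' log2(c_KO / c_WT) of the enrichment scores, and significance comes
#' from Fisher's exact test on the 2x2 table (A_KO, D'_KO; A_WT, D'_WT)
#' where input counts are scaled to the IP library size
#' (D' = round(D * B / E)) so unequal sequencing depths do not bias the
#' odds ratio; P values are BH-adjusted. Categories: peaks retained in
#' both conditions are "hyper" (FDR < 0.05 and log2FC > 1), "hypo"
#' (FDR < 0.05 and log2FC < -1) or "unchanged"; peaks retained in
#' exactly one condition are "gain" (KO only) or "loss" (WT only) and
#' bypass the fold-change route.
#'
#' @param atlas data.frame with one row per merged peak: `merged_id`,
#'   optional `rna_id`, counts `A_wt`, `D_wt`, `A_ko`, `D_ko`, peak
#'   length `C`, and logicals `retained_wt`, `retained_ko`.
#' @param lib data.frame/list with `B_wt`, `E_wt`, `B_ko`, `E_ko`.
#' @param fdr_max,lfc_min Thresholds (defaults 0.05 and 1).
#' @return The atlas with `c_wt`, `c_ko`, `log2fc`, `p`, `fdr`,
#'   `category`; peaks retained in neither condition get category NA.
#' @export
detect_dmrs <- function(atlas, lib, fdr_max = 0.05, lfc_min = 1) {
  qw <- quantify_peak(atlas$A_wt, atlas$D_wt, atlas$C, lib$B_wt, lib$E_wt)
  qk <- quantify_peak(atlas$A_ko, atlas$D_ko, atlas$C, lib$B_ko, lib$E_ko)
  atlas$c_wt <- qw$c
  atlas$c_ko <- qk$c
  atlas$log2fc <- ifelse(is.finite(qw$c) & is.finite(qk$c) & qw$c > 0,
                         log2(qk$c / qw$c), NA_real_)
  Dw <- as.integer(round(atlas$D_wt * lib$B_wt / lib$E_wt))
  Dk <- as.integer(round(atlas$D_ko * lib$B_ko / lib$E_ko))
  atlas$p <- vapply(seq_len(nrow(atlas)), function(i) {
    tab <- matrix(c(atlas$A_ko[i], Dk[i], atlas$A_wt[i], Dw[i]), nrow = 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
    stats::fisher.test(tab)$p.value
  }, 1.0)
  atlas$fdr <- stats::p.adjust(atlas$p, method = "BH")
  cat_ <- rep(NA_character_, nrow(atlas))
  both <- atlas$retained_wt & atlas$retained_ko
  cat_[both] <- "unchanged"
  cat_[both & atlas$fdr < fdr_max & !is.na(atlas$log2fc) & atlas$log2fc > lfc_min] <- "hyper"
  cat_[both & atlas$fdr < fdr_max & !is.na(atlas$log2fc) & atlas$log2fc < -lfc_min] <- "hypo"
  cat_[atlas$retained_ko & !atlas$retained_wt] <- "gain"
  cat_[atlas$retained_wt & !atlas$retained_ko] <- "loss"
  atlas$category <- cat_
  atlas
}

#' Aggregate peak-level DMR calls to RNA level
#'
#' An RNA gains methylation if it hosts >= 1 gain peak and no retained
#' WT peak; loses it if it hosts >= 1 loss peak and no retained KO
#' peak; otherwise it is labeled by the strongest peak-level category
#' present (hyper > hypo > unchanged).
#'
#' @param dmr Output of [detect_dmrs()] with an `rna_id` column.
#' @return data.frame: rna_id, category.
#' @export
dmrs_by_rna <- function(dmr) {
  dmr <- dmr[!is.na(dmr$rna_id) & !is.na(dmr$category), , drop = FALSE]
  out <- lapply(split(dmr, dmr$rna_id), function(d) {
    cat_ <- if (any(d$category == "gain") && !any(d$retained_wt)) "gain"
    else if (any(d$category == "loss") && !any(d$retained_ko)) "loss"
    else if (any(d$category == "hyper")) "hyper"
    else if (any(d$category == "hypo")) "hypo"
    else "unchanged"
    data.frame(rna_id = d$rna_id[1], category = cat_, stringsAsFactors = FALSE)
  })
  ans <- do.call(rbind, out)
  rownames(ans) <- NULL
  ans
}
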
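# Housekeeping / tissue-specific classification of an FPKM matrix.
#
# A transcript is housekeeping-consistent when (i) it is detected in every
# tissue, (ii) a Kolmogorov-Smirnov test of its min-max-normalized tissue
# profile against Uniform(0,1) gives P > ks_cutoff, and (iii) every tissue
# value lies within [mean/fold, fold*mean]. A gene is HK only if ALL of its
# transcripts pass (criterion iv). A gene is TS when it has at least one
# expressed transcript and every expressed transcript is restricted to at
# most ts_max_tissues tissues.

#' Number of tissues in which a transcript is detected
#'
#' @param values Numeric FPKM vector across tissues.
#' @param threshold Detection threshold (FPKM, > 0); a tissue counts as
#'   detected when its value is `>= threshold`.
#' @return Integer count.
#' @export
expressed_tissue_count <- function(values, threshold = 1) {
  if (length(values) == 0L) stop("empty expression vector")
  stopifnot(threshold > 0)
  sum(values >= threshold)
}

#' Kolmogorov-Smirnov uniformity P-value of a tissue profile
#'
#' Min-max normalizes the profile to \[0, 1\] and tests it against
#' Uniform(0, 1) with a two-sided one-sample KS test. Scale-free: rescaling
#' all values by a positive constant leaves the result unchanged. A constant
#' profile (zero variance) is perfectly uniform by convention and returns 1.
#'
#' @param values Numeric FPKM vector, length >= 4.
#' @return P-value in \[0, 1\].
#' @export
ks_uniformity_pvalue <- function(values) {
  if (length(values) < 4L) stop("need >= 4 tissues for the uniformity test")
  r <- range(values)
  if (diff(r) == 0) return(1.0)
  u <- (values - r[1]) / diff(r)
  suppressWarnings(stats::ks.test(u, "punif")$p.value)
}

#' Fourfold-range check of a tissue profile
#'
#' TRUE when every value lies within `[mean/fold, fold*mean]` of the
#' arithmetic tissue average, i.e. no single tissue shows abnormal
#' expression. An all-zero vector returns FALSE (nothing is expressed).
#'
#' @param values Numeric FPKM vector (non-negative).
#' @param fold Fold-range bound (> 1), default 4.
#' @return Logical scalar.
#' @export
fold_range_check <- function(values, fold = 4) {
  stopifnot(fold > 1, all(values >= 0))
  m <- mean(values)
  if (m == 0) return(FALSE)
  all(values >= m / fold & values <= fold * m)
}

#' Classify genes as housekeeping, tissue-specific or other
#'
#' Applies the four housekeeping criteria and the 1-to-`ts_max_tissues`
#' tissue-specific definition per gene. Labels are mutually exclusive and
#' exhaustive: HK requires every transcript of the gene to pass all
#' per-transcript criteria; TS requires at least one expressed transcript and
#' every expressed transcript restricted to `<= ts_max_tissues` tissues (and
#' the gene not HK); everything else is `other`.
#'
#' @param m An [expression_matrix()] object.
#' @param threshold Detection threshold, FPKM.
#' @param ks_cutoff Uniformity P-value cutoff (transcript passes when
#'   P > `ks_cutoff`), default 0.1.
#' @param fold Fold-range bound, default 4.
#' @param ts_max_tissues Maximum expressed-tissue count for the TS label,
#'   default 3.
#' @return Object of class `gene_classification`: list with `genes` (data
#'   frame: `gene_id`, `label`, `n_transcripts`, `min_ks_pvalue`,
#'   `all_detected`, `all_fold_ok`) and `transcripts` (data frame of
#'   per-transcript evidence: `transcript_id`, `gene_id`,
#'   `expressed_tissue_count`, `ks_pvalue`, `fold_range_ok`, `hk_pass`,
#'   `ts_transcript`).
#' @export
classify_genes <- function(m, threshold = 1, ks_cutoff = 0.1, fold = 4,
                           ts_max_tissues = 3L) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  v <- m$values
  n_tissues <- ncol(v)
  etc <- apply(v, 1L, expressed_tissue_count, threshold = threshold)
  ksp <- apply(v, 1L, ks_uniformity_pvalue)
  fok <- apply(v, 1L, fold_range_check, fold = fold)
  hk_pass <- etc == n_tissues & ksp > ks_cutoff & fok
  ts_tx <- etc >= 1L & etc <= ts_max_tissues
  tx <- data.frame(
    transcript_id = rownames(v),
    gene_id = unname(m$gene_of),
    expressed_tissue_count = as.integer(etc),
    ks_pvalue = as.numeric(ksp),
    fold_range_ok = as.logical(fok),
    hk_pass = as.logical(hk_pass),
    ts_transcript = as.logical(ts_tx),
    stringsAsFactors = FALSE
  )
  by_gene <- split(seq_len(nrow(tx)), tx$gene_id)
  genes <- do.call(rbind, lapply(names(by_gene), function(g) {
    i <- by_gene[[g]]
    all_hk <- all(tx$hk_pass[i])
    expressed <- tx$expressed_tissue_count[i] >= 1L
    is_ts <- !all_hk && any(expressed) && all(tx$ts_transcript[i][expressed])
    data.frame(
      gene_id = g,
      label = if (all_hk) "HK" else if (is_ts) "TS" else "other",
      n_transcripts = length(i),
      min_ks_pvalue = min(tx$ks_pvalue[i]),
      all_detected = all(tx$expressed_tissue_count[i] == n_tissues),
      all_fold_ok = all(tx$fold_range_ok[i]),
      stringsAsFactors = FALSE
    )
  }))
  genes <- genes[order(genes$gene_id, method = "radix"), ]
  rownames(genes) <- NULL
  structure(list(genes = genes, transcripts = tx),
            class = "gene_classification")
}

#' @export
print.gene_classification <- function(x, ...) {
  tab <- table(x$genes$label)
  cat("gene_classification:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      sprintf("(%d transcripts)\n", nrow(x$transcripts)))
  invisible(x)
}
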
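# Group-comparison statistics and the end-to-end pipeline driver:
# classify -> scan per class -> densities -> evolution (optional) ->
# Mann-Whitney comparison tables, with deterministic TSV/BED outputs.

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' U statistic with midrank tie handling. The P-value is exact (by
#' enumeration over label assignments) when `length(x) + length(y) <= 12`
#' and there are no ties, otherwise the normal approximation with tie and
#' continuity correction is used. Two-sided.
#'
#' @param x,y Nonempty numeric vectors.
#' @return List with `U` (for `x`) and `pvalue`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("empty group")
  stopifnot(is.numeric(x), is.numeric(y), all(is.finite(c(x, y))))
  r <- rank(c(x, y))
  U <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  no_ties <- !anyDuplicated(c(x, y))
  exact <- (length(x) + length(y) <= 12L) && no_ties
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
  )
  list(U = U, pvalue = min(1, p))
}

#' Mean, SEM and Mann-Whitney comparison per feature
#'
#' One row per feature, in input order. A feature whose comparison fails
#' (e.g. an empty group) yields `NA` statistics and a warning rather than
#' aborting the remaining features.
#'
#' @param features Named list; each element a list/pair of two numeric
#'   vectors (group A, e.g. housekeeping, and group B, e.g. tissue-specific).
#' @return Data frame: `feature`, `n_a`, `mean_a`, `sem_a`, `n_b`, `mean_b`,
#'   `sem_b`, `U`, `pvalue`.
#' @export
summarize_groups <- function(features) {
  sem <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
  rows <- lapply(names(features), function(f) {
    a <- features[[f]][[1L]]
    b <- features[[f]][[2L]]
    mw <- tryCatch(mann_whitney(a, b), error = function(e) {
      warning("feature '", f, "': ", conditionMessage(e))
      list(U = NA_real_, pvalue = NA_real_)
    })
    data.frame(feature = f,
               n_a = length(a), mean_a = mean(a), sem_a = sem(a),
               n_b = length(b), mean_b = mean(b), sem_b = sem(b),
               U = mw$U, pvalue = mw$pvalue, stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(feature = character(0), n_a = integer(0),
                      mean_a = numeric(0), sem_a = numeric(0),
                      n_b = integer(0), mean_b = numeric(0),
                      sem_b = numeric(0), U = numeric(0), pvalue = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a plain-text motif list
#'
#' One IUPAC consensus per line; blank lines and `#` comments ignored.
#'
#' @param path Path to the motif file.
#' @return Character vector of motifs.
#' @export
read_motif_list <- function(path) {
  if (!file.exists(path)) stop("motif file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toupper(lines)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full promoter-characterization pipeline
#'
#' Stages: classify genes from the expression table; scan the promoters of
#' each class for CpG islands, STRs, PQS and (optionally) motifs; summarize
#' element densities; estimate evolutionary rates if orthologous CDS and
#' promoter pairs are supplied; and write Mann-Whitney comparison tables.
#' Rerunning with the same config and seed reproduces every TSV/BED output
#' byte for byte (only the run log carries a timestamp).
#'
#' @param config Path to a YAML file or an equivalent named list with
#'   entries: `expression` (TSV path), `promoters` (FASTA path, one record
#'   per gene id), optional `motifs` (plain-text motif list), optional
#'   `orthologs` (list with `cds_a`, `cds_b`, `prom_a`, `prom_b` FASTA paths
#'   with matching record ids), `out_dir`, and optional thresholds
#'   `fpkm_threshold` (1), `ks_cutoff` (0.1), `fold` (4), `ts_max_tissues`
#'   (3), `min_copies` (7), `pqs` / `cpg` parameter lists, `reps` (500),
#'   `seed` (1).
#' @return Invisibly, a list with the classification, per-class hits,
#'   summary tables and output paths.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  for (field in c("expression", "promoters", "out_dir")) {
    if (is.null(cfg[[field]])) stop("config missing required field: ", field)
  }
  for (field in c("expression", "promoters")) {
    if (!file.exists(cfg[[field]])) stop("config input not found: ", cfg[[field]])
  }
  if (!is.null(cfg$motifs) && !file.exists(cfg$motifs)) {
    stop("config input not found: ", cfg$motifs)
  }
  if (!is.null(cfg$orthologs)) {
    for (f in c("cds_a", "cds_b", "prom_a", "prom_b")) {
      if (is.null(cfg$orthologs[[f]]) || !file.exists(cfg$orthologs[[f]])) {
        stop("config ortholog input missing or not found: ", f)
      }
    }
  }
  thr <- function(name, default) if (is.null(cfg[[name]])) default else cfg[[name]]
  fpkm_threshold <- thr("fpkm_threshold", 1)
  ks_cutoff <- thr("ks_cutoff", 0.1)
  fold <- thr("fold", 4)
  ts_max <- thr("ts_max_tissues", 3L)
  min_copies <- thr("min_copies", 7L)
  reps <- thr("reps", 500L)
  seed <- thr("seed", 1L)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("promevo run, %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                 sprintf("parameters: fpkm_threshold=%g ks_cutoff=%g fold=%g ts_max_tissues=%d min_copies=%d reps=%d seed=%d",
                         fpkm_threshold, ks_cutoff, fold, ts_max, min_copies, reps, seed))

  m <- read_expression_table(cfg$expression)
  cls <- classify_genes(m, threshold = fpkm_threshold, ks_cutoff = ks_cutoff,
                        fold = fold, ts_max_tissues = ts_max)
  write_tsv(cls$genes, file.path(out_dir, "genes.tsv"))
  write_tsv(cls$transcripts, file.path(out_dir, "transcripts.tsv"))
  log_lines <- c(log_lines, sprintf(
    "classified %d genes: HK=%d TS=%d other=%d",
    nrow(cls$genes), sum(cls$genes$label == "HK"),
    sum(cls$genes$label == "TS"), sum(cls$genes$label == "other")))

  promoters <- read_fasta(cfg$promoters)
  motifs <- if (!is.null(cfg$motifs)) read_motif_list(cfg$motifs) else character(0)
  classes <- c("HK", "TS")
  hits_by_class <- list()
  density_rows <- list()
  str_unit_rows <- list()
  feature_values <- list()
  for (cl in classes) {
    ids <- intersect(cls$genes$gene_id[cls$genes$label == cl], names(promoters))
    if (length(ids) == 0L) {
      log_lines <- c(log_lines, sprintf("no promoters for class %s; skipped", cl))
      next
    }
    proms <- promoters[ids]
    hits <- scan_promoters(proms, motifs = motifs,
                           str = list(min_copies = min_copies),
                           pqs = if (is.null(cfg$pqs)) list() else cfg$pqs,
                           cpg = if (is.null(cfg$cpg)) list() else cfg$cpg)
    hits_by_class[[cl]] <- hits
    bed <- rbind(
      if (nrow(hits$cpg)) data.frame(seq_id = hits$cpg$seq_id, start = hits$cpg$start,
                                     end = hits$cpg$end, name = "CpG", score = 0L,
                                     strand = "."),
      if (nrow(hits$str)) data.frame(seq_id = hits$str$seq_id, start = hits$str$start,
                                     end = hits$str$end,
                                     name = paste0("STR_", hits$str$canonical_unit),
                                     score = hits$str$copies, strand = "."),
      if (nrow(hits$pqs)) data.frame(seq_id = hits$pqs$seq_id, start = hits$pqs$start,
                                     end = hits$pqs$end, name = "PQS",
                                     score = hits$pqs$g_score,
                                     strand = hits$pqs$strand),
      if (nrow(hits$motif)) data.frame(seq_id = hits$motif$seq_id,
                                       start = hits$motif$start,
                                       end = hits$motif$end,
                                       name = paste0("motif_", hits$motif$motif),
                                       score = 0L, strand = hits$motif$strand)
    )
    write_bed(bed, file.path(out_dir, sprintf("elements_%s.bed", cl)))
    for (el in c("cpg", "str", "pqs", "motif")) {
      d <- element_density(hits[[el]], length(proms))
      density_rows[[length(density_rows) + 1L]] <- data.frame(
        class = cl, element = el, n_promoters = length(proms),
        total = d$total, per_promoter = d$per_promoter)
    }
    if (nrow(hits$str)) {
      tab <- table(hits$str$canonical_unit)
      str_unit_rows[[length(str_unit_rows) + 1L]] <- data.frame(
        class = cl, canonical_unit = names(tab), count = as.integer(tab),
        per_promoter = as.integer(tab) / length(proms))
    }
    # per-promoter features for the group-comparison table
    count_per <- function(df) {
      v <- table(factor(df$seq_id, levels = ids))
      as.numeric(v)
    }
    gc_per <- vapply(proms, function(s) {
      x <- strsplit(s, "")[[1]]
      mean(x[x != "N"] %in% c("G", "C"))
    }, numeric(1))
    feature_values[[cl]] <- list(
      gc_content = unname(gc_per),
      cpg_islands_per_promoter = count_per(hits$cpg),
      strs_per_promoter = count_per(hits$str),
      pqs_per_promoter = count_per(hits$pqs),
      motifs_per_promoter = count_per(hits$motif)
    )
  }
  if (length(density_rows)) {
    write_tsv(do.call(rbind, density_rows), file.path(out_dir, "element_density.tsv"))
  }
  if (length(str_unit_rows)) {
    su <- do.call(rbind, str_unit_rows)
    su <- su[order(su$class, nchar(su$canonical_unit), su$canonical_unit,
                   method = "radix"), ]
    write_tsv(su, file.path(out_dir, "str_units.tsv"))
  }
  comparison <- NULL
  if (all(classes %in% names(feature_values))) {
    feats <- lapply(names(feature_values$HK), function(f) {
      list(feature_values$HK[[f]], feature_values$TS[[f]])
    })
    names(feats) <- names(feature_values$HK)
    comparison <- summarize_groups(feats)
    names(comparison)[names(comparison) %in%
      c("n_a", "mean_a", "sem_a", "n_b", "mean_b", "sem_b")] <-
      c("n_hk", "mean_hk", "sem_hk", "n_ts", "mean_ts", "sem_ts")
    write_tsv(comparison, file.path(out_dir, "group_comparison.tsv"))
  }

  rates <- NULL
  if (!is.null(cfg$orthologs)) {
    cds_a <- read_fasta(cfg$orthologs$cds_a)
    cds_b <- read_fasta(cfg$orthologs$cds_b)
    prom_a <- read_fasta(cfg$orthologs$prom_a)
    prom_b <- read_fasta(cfg$orthologs$prom_b)
    ids <- Reduce(intersect, list(names(cds_a), names(cds_b),
                                  names(prom_a), names(prom_b)))
    if (length(ids) == 0L) stop("no shared ids across ortholog files")
    rates <- do.call(rbind, lapply(ids, function(id) {
      ng <- nei_gojobori(cds_a[[id]], cds_b[[id]])
      zt <- selection_z_test(cds_a[[id]], cds_b[[id]], reps = reps, seed = seed)
      dp <- promoter_distance(prom_a[[id]], prom_b[[id]])
      data.frame(gene_id = id, dN = ng$dN, dS = ng$dS, omega = ng$omega,
                 Z = zt$Z, z_pvalue = zt$pvalue, dP = dp,
                 stringsAsFactors = FALSE)
    }))
    write_tsv(rates, file.path(out_dir, "rates.tsv"))
    log_lines <- c(log_lines, sprintf("estimated rates for %d ortholog pairs", nrow(rates)))
  } else {
    log_lines <- c(log_lines, "no ortholog files: evolution stage skipped")
  }
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(classification = cls, hits = hits_by_class,
                 densities = if (length(density_rows)) do.call(rbind, density_rows),
                 comparison = comparison, rates = rates, out_dir = out_dir))
}
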
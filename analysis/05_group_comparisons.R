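#!/usr/bin/env Rscript
# Stage 5 — housekeeping vs tissue-specific comparison table.
#
# Assembles per-promoter and per-gene features from stages 3-4 and compares
# the two classes with the Mann-Whitney test (mean +/- SEM per group, U, P),
# mirroring the structural-comparison table layout of the study.

suppressMessages(library(promevo))

data_dir <- "results/data"
tab_dir <- "results/tables"

counts_per_promoter <- function(cl) {
  proms <- read_fasta(file.path(data_dir, sprintf("promoters_%s.fa", cl)))
  bed <- utils::read.delim(file.path(tab_dir, sprintf("elements_%s.bed", cl)),
                           header = FALSE,
                           col.names = c("seq_id", "start", "end", "name",
                                         "score", "strand"))
  per <- function(pattern) {
    sel <- bed[grepl(pattern, bed$name), ]
    as.numeric(table(factor(sel$seq_id, levels = names(proms))))
  }
  gc <- vapply(proms, function(s) {
    x <- strsplit(s, "")[[1]]
    mean(x[x != "N"] %in% c("G", "C"))
  }, numeric(1))
  list(gc_content = unname(gc),
       cpg_islands = per("^CpG$"),
       strs = per("^STR_"),
       pqs = per("^PQS$"),
       motifs = per("^motif_"))
}

hk <- counts_per_promoter("HK")
ts <- counts_per_promoter("TS")
rates <- utils::read.delim(file.path(tab_dir, "rates.tsv"))

features <- list(
  gc_content = list(hk$gc_content, ts$gc_content),
  cpg_islands_per_promoter = list(hk$cpg_islands, ts$cpg_islands),
  strs_per_promoter = list(hk$strs, ts$strs),
  pqs_per_promoter = list(hk$pqs, ts$pqs),
  motifs_per_promoter = list(hk$motifs, ts$motifs),
  dN = list(rates$dN[rates$class == "HK"], rates$dN[rates$class == "TS"]),
  dS = list(rates$dS[rates$class == "HK"], rates$dS[rates$class == "TS"]),
  omega = list(rates$omega[rates$class == "HK"],
               rates$omega[rates$class == "TS"]),
  dP = list(rates$dP[rates$class == "HK"], rates$dP[rates$class == "TS"])
)
tab <- summarize_groups(features)
names(tab)[names(tab) %in% c("n_a", "mean_a", "sem_a", "n_b", "mean_b", "sem_b")] <-
  c("n_hk", "mean_hk", "sem_hk", "n_ts", "mean_ts", "sem_ts")
utils::write.table(tab, file.path(tab_dir, "group_comparison.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat("stage 5 complete; HK vs TS comparison:\n")
print(format(tab, digits = 3), row.names = FALSE)
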
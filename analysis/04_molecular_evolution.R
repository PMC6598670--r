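#!/usr/bin/env Rscript
# Stage 4 — evolutionary rates of orthologous CDS and promoter pairs.
#
# Per gene: Nei-Gojobori dN, dS, dN/dS with the codon-bootstrap Z-test of
# selection, and the promoter substitution rate dP (pairwise deletion).
# Then per class: group means and the dP ~ dN / dS / dN/dS Pearson
# correlations that link promoter and coding divergence.

suppressMessages(library(promevo))

data_dir <- "results/data"
tab_dir <- "results/tables"
dir.create(tab_dir, showWarnings = FALSE, recursive = TRUE)
boot_seed <- 11L

rates <- NULL
for (cl in c("HK", "TS")) {
  cds_a <- read_fasta(file.path(data_dir, sprintf("cds_a_%s.fa", cl)))
  cds_b <- read_fasta(file.path(data_dir, sprintf("cds_b_%s.fa", cl)))
  pr_a <- read_fasta(file.path(data_dir, sprintf("prom_a_%s.fa", cl)))
  pr_b <- read_fasta(file.path(data_dir, sprintf("prom_b_%s.fa", cl)))
  for (id in names(cds_a)) {
    ng <- nei_gojobori(cds_a[[id]], cds_b[[id]])
    zt <- selection_z_test(cds_a[[id]], cds_b[[id]], reps = 500,
                           seed = boot_seed)
    dp <- promoter_distance(pr_a[[id]], pr_b[[id]])
    rates <- rbind(rates, data.frame(
      gene_id = id, class = cl, dN = ng$dN, dS = ng$dS, omega = ng$omega,
      Z = zt$Z, z_pvalue = zt$pvalue, significant = zt$pvalue < 0.05,
      dP = dp))
  }
}
utils::write.table(rates, file.path(tab_dir, "rates.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

summary_rows <- NULL
cor_rows <- NULL
for (cl in c("HK", "TS")) {
  r <- rates[rates$class == cl, ]
  summary_rows <- rbind(summary_rows, data.frame(
    class = cl, n = nrow(r),
    mean_dN = mean(r$dN), mean_dS = mean(r$dS),
    mean_omega = mean(r$omega, na.rm = TRUE), mean_dP = mean(r$dP),
    frac_selected = mean(r$significant)))
  for (y in c("dN", "dS", "omega")) {
    ct <- rate_correlation(r$dP, r[[y]])
    cor_rows <- rbind(cor_rows, data.frame(
      class = cl, pair = paste0("dP~", y), r = ct$r, pvalue = ct$pvalue,
      n = ct$n))
  }
}
utils::write.table(summary_rows, file.path(tab_dir, "rates_summary.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(cor_rows, file.path(tab_dir, "rate_correlations.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat("stage 4 complete\n")
print(summary_rows, row.names = FALSE)
print(cor_rows, row.names = FALSE)
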
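#!/usr/bin/env Rscript
# Stage 1 — build the synthetic study inputs with recorded ground truth.
#
# The bundle emulates the real study's substrate: a 21-tissue FPKM matrix
# (200 housekeeping-like, 200 tissue-specific-like, 200 'other' transcripts
# around the published HK mean of 17.1 FPKM); 2-kb promoters per class with
# CpG islands and STRs planted at the published per-promoter densities
# (CpG 0.47 vs 0.30, island lengths 352 vs 234 bp; STR 0.31 vs 0.15) on a
# CpG-depleted background; and orthologous CDS/promoter pairs whose per-gene
# divergences share a latent factor, so promoter and coding rates correlate
# as the real data do. HK pairs are simulated under stronger constraint
# (omega 0.1, promoter rate centred on 0.45) than TS pairs (omega 0.25,
# promoter rate centred on the published dP of 0.64).

suppressMessages(library(promevo))

seed <- 101L
data_dir <- "results/data"
dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)

## expression matrix ---------------------------------------------------------
expr <- simulate_expression_matrix(200, 200, 200, n_tissues = 21L,
                                   base_level = 17.1, noise_cv = 0.1,
                                   seed = seed)
write_expression_table(expr$matrix, file.path(data_dir, "expression.tsv"))
utils::write.table(expr$truth, file.path(data_dir, "expression_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

## promoters per class, planted at published densities -----------------------
plant_for <- function(n, cpg_density, cpg_len, str_density) {
  units <- c("AC", "AG", "AT", "AAC", "AAG", "AAT", "AAAC", "AAAG", "AAAT")
  plant <- list()
  for (i in seq_len(round(cpg_density * n))) {
    plant <- c(plant, list(list(type = "cpg", length = cpg_len, at = 1200,
                                promoter = i)))
  }
  for (i in seq_len(round(str_density * n))) {
    plant <- c(plant, list(list(
      type = "str", unit = units[(i - 1L) %% length(units) + 1L],
      copies = 7L + i %% 3L, at = 200, promoter = i)))
  }
  plant
}
genes <- split(expr$truth$gene_id, expr$truth$true_label)
for (cl in c("HK", "TS")) {
  n <- length(genes[[cl]])
  dens <- if (cl == "HK") c(0.47, 352, 0.31) else c(0.30, 234, 0.15)
  sim <- simulate_promoter_set(n, length = 2000, gc_background = 0.45,
                               cpg_depletion = 0.25,
                               plant = plant_for(n, dens[1], dens[2], dens[3]),
                               seed = seed + match(cl, c("HK", "TS")))
  names(sim$sequences) <- genes[[cl]]
  sim$truth$promoter <- genes[[cl]][as.integer(sub("prom", "", sim$truth$promoter))]
  write_fasta(sim$sequences, file.path(data_dir, sprintf("promoters_%s.fa", cl)))
  utils::write.table(sim$truth,
                     file.path(data_dir, sprintf("promoter_truth_%s.tsv", cl)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
writeLines(c("# IUPAC consensus motifs scanned in stage 3",
             "GCYRCAGC", "GCCHGGGA", "GCTGTRGC", "AAAAWAAA", "CATATGS",
             "TCSTTAAC", "TACACCAC", "TATWTAT"),
           file.path(data_dir, "motifs.txt"))

## orthologous CDS and promoter pairs ----------------------------------------
set.seed(seed)
n_pairs <- 60L
for (cl in c("HK", "TS")) {
  omega <- if (cl == "HK") 0.1 else 0.25
  p_centre <- if (cl == "HK") 0.45 else 0.64
  ids <- genes[[cl]][seq_len(n_pairs)]
  cds_a <- cds_b <- pr_a <- pr_b <- character(0)
  truth <- NULL
  for (i in seq_along(ids)) {
    z <- stats::runif(1)  # shared divergence factor links dP to dN/dS
    t_i <- 0.25 + 0.35 * z
    p_i <- p_centre * (0.7 + 0.6 * (0.7 * z + 0.3 * stats::runif(1)))
    pc <- simulate_divergent_pair(n_codons = 300, omega = omega, t = t_i,
                                  seed = seed + 1000L + i * 7L +
                                    1000L * match(cl, c("HK", "TS")))
    pp <- simulate_divergent_pair(mode = "promoter", n_sites = 2000,
                                  p_site = min(p_i, 0.72),
                                  seed = seed + 5000L + i * 7L +
                                    1000L * match(cl, c("HK", "TS")))
    cds_a[ids[i]] <- pc$a; cds_b[ids[i]] <- pc$b
    pr_a[ids[i]] <- pp$a; pr_b[ids[i]] <- pp$b
    truth <- rbind(truth, data.frame(gene_id = ids[i], class = cl,
                                     omega = omega, t = t_i,
                                     p_site = min(p_i, 0.72)))
  }
  for (nm in c("cds_a", "cds_b", "prom_a", "prom_b")) {
    obj <- switch(nm, cds_a = cds_a, cds_b = cds_b, prom_a = pr_a, prom_b = pr_b)
    write_fasta(obj, file.path(data_dir, sprintf("%s_%s.fa", nm, cl)))
  }
  utils::write.table(truth, file.path(data_dir, sprintf("rate_truth_%s.tsv", cl)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

cat("stage 1 complete:", length(list.files(data_dir)), "files in", data_dir, "\n")
cat("  600 transcripts x 21 tissues;", "400 promoters; 120 ortholog pairs\n")
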
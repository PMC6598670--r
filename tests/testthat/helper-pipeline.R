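# Build a complete synthetic input bundle (expression TSV, promoter FASTA,
# motif list, optional ortholog FASTA pairs) plus a pipeline config.

make_pipeline_config <- function(dir, seed = 7L, with_orthologs = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_expression_matrix(25, 25, 10, noise_cv = 0.1, seed = seed)
  expr_path <- file.path(dir, "expression.tsv")
  write_expression_table(sim$matrix, expr_path)
  genes <- unique(sim$truth$gene_id)
  proms <- simulate_promoter_set(length(genes), length = 1000,
                                 gc_background = 0.45, seed = seed + 1)$sequences
  names(proms) <- genes
  prom_path <- file.path(dir, "promoters.fa")
  write_fasta(proms, prom_path)
  motif_path <- file.path(dir, "motifs.txt")
  writeLines(c("# consensus motifs", "GCYRCAGC", "AAAAWAAA", "CATATGS"),
             motif_path)
  cfg <- list(expression = expr_path, promoters = prom_path,
              motifs = motif_path, out_dir = file.path(dir, "out"),
              reps = 200L, seed = seed)
  if (with_orthologs) {
    ids <- genes[1:8]
    cds_a <- character(0); cds_b <- character(0)
    pr_a <- character(0); pr_b <- character(0)
    for (i in seq_along(ids)) {
      pc <- simulate_divergent_pair(n_codons = 150, omega = 0.4, t = 0.4,
                                    seed = seed + 10 + i)
      pp <- simulate_divergent_pair(mode = "promoter", n_sites = 1000,
                                    p_site = 0.3, seed = seed + 50 + i)
      cds_a[ids[i]] <- pc$a; cds_b[ids[i]] <- pc$b
      pr_a[ids[i]] <- pp$a; pr_b[ids[i]] <- pp$b
    }
    paths <- file.path(dir, c("cds_a.fa", "cds_b.fa", "prom_a.fa", "prom_b.fa"))
    write_fasta(cds_a, paths[1]); write_fasta(cds_b, paths[2])
    write_fasta(pr_a, paths[3]); write_fasta(pr_b, paths[4])
    cfg$orthologs <- list(cds_a = paths[1], cds_b = paths[2],
                          prom_a = paths[3], prom_b = paths[4])
  }
  cfg
}
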
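test_that("codon site counts match code-table enumeration for all 61 codons", {
  expect_equal(codon_site_counts("TTT"),
               c(syn_sites = 1 / 3, nonsyn_sites = 8 / 3))
  expect_equal(codon_site_counts("GGG"), c(syn_sites = 1, nonsyn_sites = 2))
  expect_equal(codon_site_counts("TGG"), c(syn_sites = 0, nonsyn_sites = 3))
  expect_error(codon_site_counts("TAA"), "stop")
  expect_error(codon_site_counts("ANT"), "codon")

  for (policy in c("nonsyn", "exclude")) {
    for (codon in sense_codon_list()) {
      sc <- codon_site_counts(codon, stop_policy = policy)
      expect_equal(sum(sc), 3)  # sites always partition the codon
      expect_equal(unname(sc), oracle_site_counts(codon, policy))
    }
  }
})

test_that("embedded genetic code agrees with the Biostrings reference", {
  ref <- Biostrings::GENETIC_CODE
  expect_equal(promevo:::GENETIC_CODE_TABLE[names(ref)], ref,
               ignore_attr = TRUE)
})

test_that("pairwise codon counting follows NG86 with pathway averaging", {
  a <- strrep("TTT", 10)
  expect_equal(pairwise_codon_differences(a, a),
               list(Sd = 0, Nd = 0, S = 10 / 3, N = 80 / 3, n_codons = 10L))

  b <- paste0(strrep("TTT", 9), "TTC")
  d <- pairwise_codon_differences(a, b)
  expect_equal(d$Sd, 1); expect_equal(d$Nd, 0)
  expect_equal(d$S, 10 / 3); expect_equal(d$N, 80 / 3)

  # TTT <-> CTC: both 2-step pathways carry one synonymous, one nonsynonymous
  d <- pairwise_codon_differences("TTT", "CTC")
  expect_equal(d$Sd, 1); expect_equal(d$Nd, 1)

  # pairwise deletion drops codons with gaps or N in either sequence
  d <- pairwise_codon_differences("TTTA-GGCA", "TTCNCGGCA")
  expect_identical(d$n_codons, 2L)
  expect_equal(d$Sd, 1)

  expect_error(pairwise_codon_differences("---", "AAA"), "no comparable")
  expect_error(pairwise_codon_differences("TAA", "TAA"), "stop")
})

test_that("Jukes-Cantor correction is exact, monotone and saturating", {
  expect_equal(jukes_cantor(0), 0)
  expect_equal(jukes_cantor(0.3), -0.75 * log(0.6))
  expect_error(jukes_cantor(0.75), "saturation")
  grid <- seq(0, 0.74, length.out = 500)
  d <- jukes_cantor(grid)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= grid))
})

test_that("nei_gojobori composes counting and correction, symmetrically", {
  a <- strrep("TTT", 10)
  ng <- nei_gojobori(a, a)
  expect_equal(ng$dN, 0); expect_equal(ng$dS, 0)
  expect_true(is.na(ng$omega))
  expect_identical(unname(ng$status["omega"]), "undefined")

  b <- paste0(strrep("TTT", 9), "TTC")
  ng <- nei_gojobori(a, b)
  expect_equal(ng$dS, jukes_cantor(0.3))
  expect_equal(ng$dN, 0)
  expect_equal(ng$omega, 0)

  # symmetry in the two sequences
  set.seed(61)
  for (i in 1:5) {
    p <- simulate_divergent_pair(n_codons = 80, omega = 0.7, t = 0.5,
                                 seed = sample.int(1e6, 1))
    expect_equal(nei_gojobori(p$a, p$b)[c("dN", "dS")],
                 nei_gojobori(p$b, p$a)[c("dN", "dS")])
  }

  # parameter recovery at purifying selection
  p <- simulate_divergent_pair(n_codons = 2000, omega = 0.2, t = 0.4, seed = 17)
  ng <- nei_gojobori(p$a, p$b)
  expect_gt(ng$omega, 0.1); expect_lt(ng$omega, 0.35)

  # recovery error shrinks with more codons
  errs <- vapply(c(100L, 3000L), function(n) {
    med <- vapply(1:5, function(s) {
      p <- simulate_divergent_pair(n_codons = n, omega = 0.3, t = 0.4,
                                   seed = 100 + s)
      nei_gojobori(p$a, p$b)$omega
    }, numeric(1))
    median(abs(med - 0.3))
  }, numeric(1))
  expect_lt(errs[2], errs[1])
})

test_that("bootstrap Z-test handles degenerate and selected pairs", {
  a <- strrep("ATGGCT", 30)
  z <- selection_z_test(a, a, reps = 200, seed = 1)
  expect_equal(z$pvalue, 1)

  expect_error(selection_z_test("ATGGCT", "ATGGCT", reps = 200), "10 comparable")

  # strong purifying selection at decent divergence is detected
  p <- simulate_divergent_pair(n_codons = 500, omega = 0.1, t = 0.5, seed = 5)
  z <- selection_z_test(p$a, p$b, reps = 500, seed = 2)
  expect_lt(z$Z, 0)
  expect_lt(z$pvalue, 0.05)
})

test_that("promoter distance uses pairwise deletion", {
  s <- strrep("ACGT", 25)
  expect_equal(promoter_distance(s, s), 0)
  s2 <- paste0("T", substr(s, 2, 100))
  expect_equal(promoter_distance(s, s2), 0.01)

  a <- paste0("AC--", strrep("A", 96))
  b <- paste0("ACGT", strrep("A", 94), "TT")
  expect_equal(promoter_distance(a, b), 2 / 98)

  expect_error(promoter_distance("----", "AAAA"), "no comparable")
  expect_error(promoter_distance("AC", "ACG"), "length")

  # recovery: dP within 3 binomial SE of the simulated rate
  p <- simulate_divergent_pair(mode = "promoter", n_sites = 10000,
                               p_site = 0.1, seed = 8)
  expect_lt(abs(promoter_distance(p$a, p$b) - 0.1), 3 * sqrt(0.1 * 0.9 / 1e4))
  # JC correction only inflates
  expect_gt(promoter_distance(p$a, p$b, correction = "jukes_cantor"),
            promoter_distance(p$a, p$b))
})

test_that("global alignment is optimal under the linear gap score", {
  al <- align_global("ACGT", "ACGT")
  expect_identical(al$a, "ACGT"); expect_identical(al$b, "ACGT")
  expect_equal(al$score, 4)

  al <- align_global("ACGT", "ACT")
  expect_equal(al$score, 1)  # 3 matches + 1 gap
  expect_identical(nchar(al$a), 4L)

  al <- align_global("A", "G")
  expect_equal(al$score, -1)  # single mismatch beats two gaps

  # score cross-check against an independent affine aligner with
  # gapOpening = 0 (linear gaps)
  set.seed(71)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (i in 1:10) {
    a <- random_dna(sample(5:30, 1)); b <- random_dna(sample(5:30, 1))
    ref <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = mat,
                                         gapOpening = 0, gapExtension = 2,
                                         type = "global", scoreOnly = TRUE)
    expect_equal(align_global(a, b)$score, ref)
  }
})

test_that("rate correlation drops undefined pairs and matches Pearson", {
  x <- c(1, 2, 3, 4)
  expect_equal(rate_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(rate_correlation(x, -x)$r, -1)
  expect_equal(rate_correlation(c(1, 2, 3), c(1, 3, 2))$r, 0.5)
  r <- rate_correlation(c(1, 2, 3, NA, 5), c(1, 3, 2, 4, NA))
  expect_identical(r$n, 3L)
  expect_error(rate_correlation(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})
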
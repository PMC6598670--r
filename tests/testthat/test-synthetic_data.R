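test_that("expression generator honors labels, counts and determinism", {
  # zero noise: a single HK transcript is constant across tissues
  sim <- simulate_expression_matrix(1, 0, 0, noise_cv = 0, seed = 1)
  expect_equal(unname(sim$matrix$values[1, ]), rep(17.1, 21))

  # a scalar ts_tissues fixes the expressed-tissue count exactly
  sim <- simulate_expression_matrix(0, 1, 0, ts_tissues = 2, seed = 7)
  expect_identical(sum(sim$matrix$values[1, ] >= 1), 2L)

  # default ts_tissues: counts within 1..3, off tissues below threshold
  sim <- simulate_expression_matrix(0, 50, 0, seed = 3)
  on_counts <- rowSums(sim$matrix$values >= 1)
  expect_true(all(on_counts >= 1 & on_counts <= 3))

  # seed determinism, bitwise
  a <- simulate_expression_matrix(5, 5, 5, seed = 42)
  b <- simulate_expression_matrix(5, 5, 5, seed = 42)
  expect_identical(a, b)

  expect_error(simulate_expression_matrix(1, 0, 0, n_tissues = 3), "n_tissues")

  # HK noise level: multiplicative cv close to requested
  sim <- simulate_expression_matrix(200, 0, 0, noise_cv = 0.1, seed = 5)
  cvs <- apply(sim$matrix$values, 1, function(v) sd(v) / mean(v))
  expect_equal(mean(cvs), 0.1, tolerance = 0.05)
})

test_that("promoter generator plants elements verbatim at recorded intervals", {
  sim <- simulate_promoter_set(
    1, plant = list(list(type = "str", unit = "AC", copies = 8, at = 100)),
    seed = 2)
  expect_identical(sim$truth$start, 100L)
  expect_identical(sim$truth$end, 116L)
  expect_identical(substr(sim$sequences[[1]], 101, 116), strrep("AC", 8))

  # zero-GC background stays on the A/T alphabet
  sim <- simulate_promoter_set(2, length = 500, gc_background = 0, seed = 4)
  expect_false(any(grepl("[GC]", sim$sequences)))

  # planted telomeric PQS recovered verbatim
  tel <- "GGGTTAGGGTTAGGGTTAGGG"
  sim <- simulate_promoter_set(
    1, plant = list(list(type = "pqs", seq = tel, at = 700)), seed = 9)
  expect_identical(substr(sim$sequences[[1]], 701, 721), tel)

  # motif instances satisfy their consensus
  sim <- simulate_promoter_set(
    1, plant = list(list(type = "motif", motif = "GCYRCAGC", at = 50)), seed = 6)
  inst <- substr(sim$sequences[[1]], 51, 58)
  expect_match(inst, "^GC[CT][AG]CAGC$")

  expect_error(
    simulate_promoter_set(1, plant = list(
      list(type = "str", unit = "AC", copies = 8, at = 100),
      list(type = "str", unit = "AG", copies = 8, at = 110))),
    "overlap")
  expect_error(
    simulate_promoter_set(1, length = 100, plant = list(
      list(type = "str", unit = "AC", copies = 60, at = 10))),
    "outside")

  expect_identical(simulate_promoter_set(3, seed = 8),
                   simulate_promoter_set(3, seed = 8))

  # CpG depletion suppresses background CpG dinucleotides (O/E well below
  # the undepleted value of ~1); overall GC drops only modestly
  oe_of <- function(s) {
    x <- strsplit(s, "")[[1]]
    n <- sum(x[-length(x)] == "C" & x[-1] == "G")
    n * length(x) / (sum(x == "C") * sum(x == "G"))
  }
  plain <- simulate_promoter_set(5, gc_background = 0.45, seed = 14)$sequences
  depl <- simulate_promoter_set(5, gc_background = 0.45, cpg_depletion = 0.25,
                                seed = 14)$sequences
  expect_gt(mean(sapply(plain, oe_of)), 0.8)
  expect_lt(mean(sapply(depl, oe_of)), 0.5)
  gc_of <- function(s) mean(strsplit(s, "")[[1]] %in% c("G", "C"))
  expect_gt(mean(sapply(depl, gc_of)), 0.38)
  expect_lt(mean(sapply(depl, gc_of)), 0.47)
})

test_that("divergent-pair generator matches its stated substitution model", {
  # zero-rate cases give identical pairs
  p <- simulate_divergent_pair(mode = "promoter", n_sites = 300, p_site = 0,
                               seed = 1)
  expect_identical(p$a, p$b)
  p <- simulate_divergent_pair(n_codons = 100, omega = 0.5, t = 0, seed = 1)
  expect_identical(p$a, p$b)
  expect_identical(nchar(p$a), 300L)

  expect_error(simulate_divergent_pair(n_codons = 0, t = 1), "n_codons")

  # promoter mode: observed mismatch fraction within 3 binomial SE of p_site
  p <- simulate_divergent_pair(mode = "promoter", n_sites = 10000,
                               p_site = 0.1, seed = 5)
  xa <- strsplit(p$a, "")[[1]]; xb <- strsplit(p$b, "")[[1]]
  expect_lt(abs(mean(xa != xb) - 0.1), 3 * sqrt(0.1 * 0.9 / 10000))
  # every substituted site differs from the ancestor by construction
  expect_identical(sum(xa != xb), p$truth$n_sub)

  # codon mode: no stops, sequences remain in frame
  p <- simulate_divergent_pair(n_codons = 500, omega = 1, t = 0.5, seed = 3)
  codons <- substring(p$b, seq(1, nchar(p$b), 3), seq(3, nchar(p$b), 3))
  expect_false(any(codons %in% c("TAA", "TAG", "TGA")))

  expect_identical(simulate_divergent_pair(n_codons = 50, t = 0.3, seed = 12),
                   simulate_divergent_pair(n_codons = 50, t = 0.3, seed = 12))
})
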
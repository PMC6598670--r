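test_that("gc_profile tracks window composition relative to the TSS", {
  proms <- c(a = strrep("G", 400), b = strrep("G", 400))
  prof <- gc_profile(proms, window = 100, step = 50)
  expect_true(all(prof$mean_gc == 1))
  expect_true(all(gc_profile(c(a = strrep("AT", 200)), 100, 50)$mean_gc == 0))

  # distal half AT, proximal half GC: windows fully within a half are 0 or 1
  p <- c(x = paste0(strrep("AT", 500), strrep("GC", 500)))
  prof <- gc_profile(p, window = 100, step = 50)
  distal <- prof$mean_gc[prof$dist_to_tss > 1100]
  proximal <- prof$mean_gc[prof$dist_to_tss < 900]
  expect_true(all(distal == 0))
  expect_true(all(proximal == 1))
  # distances measured from window center to the TSS at the 3' end
  expect_equal(max(prof$dist_to_tss), 2000 - 50)

  expect_error(gc_profile(character(0)), "empty")
  # N bases drop out of numerator and denominator
  p <- c(x = paste0(strrep("N", 50), strrep("G", 50), strrep("A", 100)))
  prof <- gc_profile(p, window = 100, step = 100)
  expect_equal(prof$mean_gc[prof$dist_to_tss == 150], 1)
})

test_that("CpG islands obey the window, length and O/E rules", {
  isl <- find_cpg_islands(c(c1 = strrep("CG", 300)))
  expect_identical(nrow(isl), 1L)
  expect_identical(c(isl$start, isl$end), c(0L, 600L))
  expect_equal(isl$gc_fraction, 1)
  expect_equal(isl$obs_exp, 2)  # 300 * 600 / (300 * 300)

  expect_identical(nrow(find_cpg_islands(c(a = strrep("A", 2000)))), 0L)

  # a 150-bp CG-rich block fails the minimum length
  s <- c(a = paste0(strrep("A", 900), strrep("CG", 75), strrep("A", 950)))
  expect_identical(nrow(find_cpg_islands(s)), 0L)

  # GC-rich but CpG-free sequence has O/E = 0: no island
  s <- c(a = paste0(strrep("G", 300), strrep("C", 300)))
  expect_identical(nrow(find_cpg_islands(s)), 0L)

  # reported islands satisfy all three invariants on recomputation
  set.seed(31)
  sim <- simulate_promoter_set(
    10, plant = list(list(type = "cpg", length = 320, at = 800)), seed = 31)
  for (id in names(sim$sequences)) {
    isl <- find_cpg_islands(sim$sequences[id])
    if (nrow(isl) == 0) next
    for (r in seq_len(nrow(isl))) {
      x <- strsplit(substr(sim$sequences[[id]], isl$start[r] + 1, isl$end[r]),
                    "")[[1]]
      L <- length(x)
      cc <- sum(x == "C"); gg <- sum(x == "G")
      nn <- sum(x[-L] == "C" & x[-1] == "G")
      expect_gte(L, 200)
      expect_gt((cc + gg) / L, 0.5)
      expect_gt(nn * L / (cc * gg), 0.6)
      expect_equal((cc + gg) / L, isl$gc_fraction[r])
      expect_equal(nn * L / (cc * gg), isl$obs_exp[r])
    }
  }
})

test_that("STR scanner reports maximal primitive perfect repeats", {
  s <- c(x = paste0("TT", strrep("AC", 7), "GG"))
  hits <- find_strs(s)
  expect_identical(nrow(hits), 1L)
  expect_identical(c(hits$start, hits$end), c(2L, 16L))
  expect_identical(hits$unit, "AC")
  expect_identical(hits$copies, 7L)

  # six copies do not reach the 'more than six units' rule
  expect_identical(nrow(find_strs(c(x = paste0("TT", strrep("AC", 6), "GG")))), 0L)

  # a long AC array is never reported for the non-primitive unit ACAC
  s <- c(x = paste0("G", strrep("AC", 20), "G"))
  hits <- find_strs(s)
  expect_identical(hits$unit, "AC")

  # mononucleotide runs are never reported at any unit size
  expect_identical(nrow(find_strs(c(x = strrep("A", 60)))), 0L)

  expect_identical(canonical_unit("AC"), "AC")
  expect_identical(canonical_unit("TG"), "AC")
  expect_identical(canonical_unit("GAA"), "AAG")

  # overlapping loci of different primitive units are counted separately
  s <- c(x = paste0(strrep("AC", 7), strrep("CCG", 7)))
  hits <- find_strs(s)
  expect_setequal(hits$unit, c("AC", "CCG"))

  # oracle equivalence on a handful of random sequences
  set.seed(41)
  for (i in 1:10) {
    str <- random_dna(400, gc = 0.5)
    impl <- find_strs(setNames(str, "s"), min_copies = 3L)
    orac <- oracle_find_strs(str, min_copies = 3L)
    expect_identical(str_hit_key(impl), str_hit_key(orac))
  }
})

test_that("STR hits mirror correctly under reverse complement", {
  # same loci with identical canonical units and copy numbers; reported
  # intervals may shift by up to unit-size - 1 when the maximal region
  # carries a partial copy (full-copy truncation cuts opposite ends on the
  # two strands)
  set.seed(43)
  for (i in 1:5) {
    str <- paste0(random_dna(150), strrep("TG", 8), random_dna(150))
    n <- nchar(str)
    fwd <- find_strs(setNames(str, "s"), min_copies = 4L)
    rev <- find_strs(setNames(reverse_complement(str), "s"), min_copies = 4L)
    expect_identical(nrow(fwd), nrow(rev))
    fwd <- fwd[order(n - fwd$end), ]
    rev <- rev[order(rev$start), ]
    expect_identical(fwd$canonical_unit, rev$canonical_unit)
    expect_identical(fwd$copies, rev$copies)
    k <- nchar(fwd$unit)
    expect_true(all(abs((n - fwd$end) - rev$start) < k))
    expect_true(all(abs((n - fwd$start) - rev$end) < k))
  }
})

test_that("PQS detection matches the four-G-run definition", {
  hit <- find_pqs(c(p = "GGGTTAGGGTTAGGGTTAGGG"))
  expect_identical(nrow(hit), 1L)
  expect_identical(c(hit$start, hit$end), c(0L, 21L))
  expect_identical(hit$g_run_length, 3L)
  expect_identical(c(hit$loop1, hit$loop2, hit$loop3), c(3L, 3L, 3L))
  expect_identical(hit$g_score, 40L)

  expect_identical(nrow(find_pqs(c(p = strrep("A", 100)))), 0L)

  hit <- find_pqs(c(p = "GGAGGAGGAGG"), both_strands = FALSE)
  expect_identical(nrow(hit), 1L)
  expect_identical(c(hit$start, hit$end), c(0L, 11L))
  expect_identical(hit$g_run_length, 2L)

  # candidates on the minus strand land in forward coordinates
  s <- c(p = paste0("AAAA", reverse_complement("GGGTTAGGGTTAGGGTTAGGG"), "AAAA"))
  hit <- find_pqs(s)
  expect_identical(hit$strand, "-")
  expect_identical(c(hit$start, hit$end), c(4L, 25L))

  # span cap: four G3 runs with long loops exceed max_len and are dropped
  s <- c(p = paste0("GGG", strrep("A", 9), "GGG", strrep("A", 9),
                    "GGG", strrep("A", 9), "GGG"))
  expect_identical(nrow(pqs_candidates(s, max_len = 30)), 0L)
  expect_gt(nrow(pqs_candidates(s, max_len = 40)), 0L)

  # resolved hits never overlap
  set.seed(47)
  for (i in 1:5) {
    str <- random_dna(800, gc = 0.6)
    hits <- find_pqs(setNames(str, "s"))
    if (nrow(hits) > 1) {
      o <- hits[order(hits$start), ]
      expect_true(all(o$start[-1] >= o$end[-nrow(o)]))
    }
  }
})

test_that("motif scanning expands IUPAC classes on both strands", {
  expect_identical(scan_motif(c(s = "GCCACAGC"), "GCYRCAGC")$start, 0L)
  expect_identical(scan_motif(c(s = "AAAATAAA"), "AAAAWAAA",
                              both_strands = FALSE)$start, 0L)
  expect_identical(nrow(scan_motif(c(s = ""), "GCYRCAGC")), 0L)
  expect_error(scan_motif(c(s = "ACGT"), "ACZT"), "invalid IUPAC")

  # overlapping occurrences are all reported
  hits <- scan_motif(c(s = "AAAAAAAA"), "AAAA", both_strands = FALSE)
  expect_identical(hits$start, 0:4)

  # oracle equivalence incl. reverse strand
  set.seed(53)
  for (m in c("GCYRCAGC", "CATATGS", "TCSTTAAC")) {
    str <- random_dna(3000, gc = 0.5)
    impl <- scan_motif(setNames(str, "s"), m)
    orac <- oracle_scan_motif(str, m)
    expect_identical(paste(impl$start, impl$strand),
                     paste(orac$start, orac$strand))
  }

  # strand symmetry: hits on the reverse complement mirror with strands swapped
  str <- random_dna(2000, gc = 0.5)
  n <- nchar(str)
  fwd <- scan_motif(setNames(str, "s"), "GCYRCAGC")
  rev <- scan_motif(setNames(reverse_complement(str), "s"), "GCYRCAGC")
  expect_setequal(paste(n - fwd$end, n - fwd$start, chartr("+-", "-+", fwd$strand)),
                  paste(rev$start, rev$end, rev$strand))
})

test_that("element density is count over promoters", {
  expect_equal(element_density(0L, 10), list(total = 0L, per_promoter = 0))
  expect_equal(element_density(3L, 2), list(total = 3L, per_promoter = 1.5))
  expect_equal(element_density(1556L, 3310)$per_promoter, 0.47, tolerance = 0.01)
  expect_error(element_density(5L, 0), "n_promoters")
})
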
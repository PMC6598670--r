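# Independent brute-force oracles used to validate the scanners and
# statistics. Deliberately naive: per-offset while-loops and exhaustive
# enumeration, sharing no code with the package implementations.

sense_codon_list <- function() {
  b <- c("T", "C", "A", "G")
  all3 <- paste0(rep(b, each = 16), rep(rep(b, each = 4), 4), rep(b, 16))
  all3[!all3 %in% c("TAA", "TAG", "TGA")]
}

random_dna <- function(n, gc = 0.45) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

oracle_is_primitive <- function(u) {
  k <- nchar(u)
  !any(vapply(seq_len(k - 1L), function(d) {
    k %% d == 0L && paste(rep(substr(u, 1, d), k / d), collapse = "") == u
  }, logical(1)))
}

# STR oracle: offset-by-offset. A locus starts at i (1-based) for unit size k
# when the period-k property fails just before (or i == 1); copies counted by
# direct chunk comparison.
oracle_find_strs <- function(str, unit_sizes = 2:6, min_copies = 7L) {
  x <- strsplit(str, "")[[1]]
  n <- length(x)
  out <- list()
  for (k in unit_sizes) {
    i <- 1L
    while (i + 2L * k - 1L <= n) {
      starts_here <- (i == 1L) || (x[i - 1L] != x[i - 1L + k])
      if (starts_here) {
        unit <- substr(str, i, i + k - 1L)
        if (!grepl("N", unit, fixed = TRUE) && oracle_is_primitive(unit)) {
          copies <- 1L
          while (i + (copies + 1L) * k - 1L <= n &&
                 substr(str, i + copies * k, i + (copies + 1L) * k - 1L) == unit) {
            copies <- copies + 1L
          }
          if (copies >= min_copies) {
            out[[length(out) + 1L]] <- data.frame(
              start = i - 1L, end = i - 1L + copies * k, unit = unit,
              copies = copies, stringsAsFactors = FALSE)
          }
        }
      }
      i <- i + 1L
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(start = integer(0), end = integer(0),
                  unit = character(0), copies = integer(0))
}

# PQS candidate oracle: four nested loops over G-run start positions of a
# common run length, each position certified character by character.
oracle_pqs_candidates <- function(str, max_len = 30L, min_run = 2L,
                                  min_loop = 0L) {
  x <- strsplit(str, "")[[1]]
  n <- length(x)
  out <- list()
  g <- min_run
  repeat {
    P <- which(vapply(seq_len(max(0L, n - g + 1L)), function(p) {
      all(x[p:(p + g - 1L)] == "G")
    }, logical(1)))
    if (length(P) == 0L) break
    for (p1 in P) {
      lim <- p1 + max_len - g
      for (p2 in P[P >= p1 + g + min_loop & P <= lim]) {
        for (p3 in P[P >= p2 + g + min_loop & P <= lim]) {
          for (p4 in P[P >= p3 + g + min_loop & P <= lim]) {
            out[[length(out) + 1L]] <- c(p1, p2, p3, p4, g)
          }
        }
      }
    }
    g <- g + 1L
  }
  if (length(out) == 0L) {
    return(data.frame(p1 = integer(0), p2 = integer(0), p3 = integer(0),
                      p4 = integer(0), g = integer(0)))
  }
  as.data.frame(do.call(rbind, out)) |> setNames(c("p1", "p2", "p3", "p4", "g"))
}

# IUPAC motif oracle: expand the consensus to the full set of concrete
# strings and fixed-string match at every offset.
oracle_expand_iupac <- function(motif) {
  classes <- list(A = "A", C = "C", G = "G", T = "T",
                  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                  W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                  B = c("C", "G", "T"), D = c("A", "G", "T"),
                  H = c("A", "C", "T"), V = c("A", "C", "G"),
                  N = c("A", "C", "G", "T"), X = c("A", "C", "G", "T"))
  ch <- strsplit(motif, "")[[1]]
  grid <- expand.grid(lapply(ch, function(x) classes[[x]]),
                      stringsAsFactors = FALSE)
  apply(grid, 1L, paste, collapse = "")
}

oracle_scan_motif <- function(str, motif, both_strands = TRUE) {
  w <- nchar(motif)
  n <- nchar(str)
  find_set <- function(set) {
    hits <- integer(0)
    for (i in seq_len(max(0L, n - w + 1L))) {
      if (substr(str, i, i + w - 1L) %in% set) hits <- c(hits, i - 1L)
    }
    hits
  }
  fwd <- find_set(oracle_expand_iupac(motif))
  res <- data.frame(start = fwd, strand = rep("+", length(fwd)))
  if (both_strands) {
    rc <- find_set(oracle_expand_iupac(reverse_complement(motif)))
    res <- rbind(res, data.frame(start = rc, strand = rep("-", length(rc))))
  }
  res[order(res$start, res$strand), , drop = FALSE]
}

# exact two-sided Mann-Whitney p by enumerating all label assignments
oracle_mw_exact_p <- function(x, y) {
  nx <- length(x)
  pool <- c(x, y)
  u_of <- function(idx) {
    r <- rank(pool)
    sum(r[idx]) - nx * (nx + 1) / 2
  }
  u_obs <- u_of(seq_len(nx))
  combos <- utils::combn(length(pool), nx)
  us <- apply(combos, 2L, u_of)
  mu <- nx * length(y) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# NG86 site-count oracle against an independent genetic code source
oracle_site_counts <- function(codon, stop_policy = "nonsyn") {
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  syn <- 0
  for (pos in 1:3) {
    n_syn <- 0L; n_tot <- 0L
    for (b in setdiff(bases, substr(codon, pos, pos))) {
      cand <- codon
      substr(cand, pos, pos) <- b
      if (code[[cand]] == "*") {
        if (stop_policy == "nonsyn") n_tot <- n_tot + 1L
      } else {
        n_tot <- n_tot + 1L
        if (code[[cand]] == code[[codon]]) n_syn <- n_syn + 1L
      }
    }
    denom <- if (stop_policy == "nonsyn") 3L else n_tot
    syn <- syn + n_syn / denom
  }
  c(syn, 3 - syn)
}

str_hit_key <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  sort(sprintf("%d:%d:%s", df$start, df$end, df$unit))
}

pqs_cand_key_impl <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  sort(sprintf("%d:%d:%d:%d:%d", df$run1, df$run2, df$run3, df$run4,
               df$g_run_length))
}

pqs_cand_key_oracle <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  sort(sprintf("%d:%d:%d:%d:%d", df$p1 - 1L, df$p2 - 1L, df$p3 - 1L,
               df$p4 - 1L, df$g))
}
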
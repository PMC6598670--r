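# Rule-based promoter element scanners: CpG islands (windowed
# observed/expected CpG rule), perfect short tandem repeats, potential
# G-quadruplex-forming sequences (PQS) and degenerate IUPAC consensus motifs,
# plus GC profiling and density summaries.
#
# All coordinates are 0-based half-open in promoter space (offset 0 distal,
# TSS immediately 3' of the last base).

seq_id_of <- function(s) {
  if (!is.null(names(s)) && nzchar(names(s)[1])) names(s)[1] else "seq"
}

#' Positional GC profile of a promoter set
#'
#' Slides a window along each promoter and averages the GC fraction across
#' promoters per window position, indexed by the distance of the window
#' center to the TSS (taken to sit immediately 3' of the last base).
#' `N` bases are excluded from both numerator and denominator.
#'
#' @param promoters Named character vector of promoter sequences.
#' @param window Window size, bp.
#' @param step Step between window starts, bp.
#' @return Data frame with `dist_to_tss` (bp, window center to TSS),
#'   `mean_gc`, `sem`, `n` (promoters contributing).
#' @export
gc_profile <- function(promoters, window = 100L, step = 50L) {
  if (length(promoters) == 0L) stop("empty promoter set")
  if (any(nchar(promoters) < window)) stop("window longer than a promoter")
  rows <- lapply(seq_along(promoters), function(i) {
    x <- strsplit(promoters[[i]], "")[[1]]
    n <- length(x)
    gc <- cumsum(x %in% c("G", "C"))
    ok <- cumsum(x != "N")
    starts <- seq.int(1L, n - window + 1L, by = step)
    denom <- ok[starts + window - 1L] - c(0L, ok)[starts]
    num <- gc[starts + window - 1L] - c(0L, gc)[starts]
    data.frame(
      dist_to_tss = n - (starts - 1L + window / 2),
      gc = ifelse(denom > 0L, num / denom, NA_real_)
    )
  })
  all <- do.call(rbind, rows)
  agg <- split(all$gc, all$dist_to_tss)
  out <- data.frame(
    dist_to_tss = as.numeric(names(agg)),
    mean_gc = vapply(agg, function(v) mean(v, na.rm = TRUE), numeric(1)),
    sem = vapply(agg, function(v) {
      v <- v[!is.na(v)]
      if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
    }, numeric(1)),
    n = vapply(agg, function(v) sum(!is.na(v)), numeric(1))
  )
  out <- out[order(-out$dist_to_tss), ]
  rownames(out) <- NULL
  out
}

#' Find CpG islands by the windowed observed/expected rule
#'
#' A 100-bp window is island-like when its GC fraction exceeds `min_gc` and
#' its observed/expected CpG ratio exceeds `min_oe` (O/E of a region of
#' length L with c C's, g G's and n CpG dinucleotides is `n*L/(c*g)`, defined
#' as 0 when `c*g = 0`). Runs of overlapping island-like windows are merged,
#' each merged region is trimmed to its outermost CpG dinucleotides, and a
#' region is reported when its length is at least `min_len` and the
#' whole-region GC and O/E still exceed the thresholds.
#'
#' @param s A single (optionally named) promoter sequence.
#' @param window Window size, bp (default 100).
#' @param min_len Minimum island length, bp (default 200).
#' @param min_gc Minimum GC fraction (default 0.5, exclusive).
#' @param min_oe Minimum observed/expected CpG ratio (default 0.6, exclusive).
#' @return Data frame: `seq_id`, `start`, `end` (0-based half-open),
#'   `length`, `gc_fraction`, `obs_exp`.
#' @export
find_cpg_islands <- function(s, window = 100L, min_len = 200L,
                             min_gc = 0.5, min_oe = 0.6) {
  id <- seq_id_of(s)
  x <- strsplit(toupper(s[[1]]), "")[[1]]
  n <- length(x)
  empty <- data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      gc_fraction = numeric(0), obs_exp = numeric(0))
  if (n < window) return(empty)
  cC <- cumsum(x == "C")
  cG <- cumsum(x == "G")
  cpg <- c(x[-n] == "C" & x[-1L] == "G", FALSE)
  cCpG <- cumsum(cpg)
  region_stats <- function(a, b) {  # 1-based inclusive
    L <- b - a + 1L
    cc <- cC[b] - c(0L, cC)[a]
    gg <- cG[b] - c(0L, cG)[a]
    nn <- if (b - 1L >= a) cCpG[b - 1L] - c(0L, cCpG)[a] else 0L
    list(L = L, gc = (cc + gg) / L,
         oe = if (cc * gg > 0) nn * L / (cc * gg) else 0)
  }
  starts <- seq_len(n - window + 1L)
  wc <- cC[starts + window - 1L] - c(0L, cC)[starts]
  wg <- cG[starts + window - 1L] - c(0L, cG)[starts]
  wn <- cCpG[starts + window - 2L] - c(0L, cCpG)[starts]
  w_gc <- (wc + wg) / window
  w_oe <- ifelse(wc * wg > 0, wn * window / (wc * wg), 0)
  good <- which(w_gc > min_gc & w_oe > min_oe)
  if (length(good) == 0L) return(empty)
  # overlapping island-like windows chain when starts differ by < window
  grp <- cumsum(c(1L, diff(good) >= window))
  out <- list()
  for (g in split(good, grp)) {
    a <- g[1L]
    b <- g[length(g)] + window - 1L
    cpg_pos <- which(cpg[seq.int(a, b - 1L)]) + a - 1L
    if (length(cpg_pos) == 0L) next
    a2 <- cpg_pos[1L]
    b2 <- cpg_pos[length(cpg_pos)] + 1L
    st <- region_stats(a2, b2)
    if (st$L >= min_len && st$gc > min_gc && st$oe > min_oe) {
      out[[length(out) + 1L]] <- data.frame(
        seq_id = id, start = a2 - 1L, end = b2, length = st$L,
        gc_fraction = st$gc, obs_exp = st$oe, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else empty
}

# is u a repetition of a strictly shorter unit?
is_primitive_unit <- function(u) {
  k <- nchar(u)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L && strrep(substr(u, 1L, d), k %/% d) == u) return(FALSE)
  }
  TRUE
}

#' Canonical form of an STR unit
#'
#' The lexicographically smallest string among all rotations of the unit and
#' all rotations of its reverse complement, so equivalent repeats (e.g. AC,
#' CA, GT, TG) aggregate under one name.
#'
#' @param u Repeat unit, 2-6 bp.
#' @return Canonical unit string.
#' @examples
#' canonical_unit("TG")  # "AC"
#' canonical_unit("GAA") # "AAG"
#' @export
canonical_unit <- function(u) {
  u <- toupper(u)
  k <- nchar(u)
  stopifnot(k >= 2L, k <= 6L)
  rots <- function(w) vapply(seq_len(k) - 1L, function(i) {
    paste0(substr(w, i + 1L, k), substr(w, 1L, i))
  }, character(1))
  min(c(rots(u), rots(reverse_complement(u))))
}

#' Find perfect short tandem repeats
#'
#' Reports every maximal perfect tandem array of a primitive unit of size
#' 2-6 bp with at least `min_copies` full copies. A locus is the maximal
#' period-`k` region; the reported interval starts at the region start and
#' spans `copies * k` bases (full copies only). Arrays whose unit is a power
#' of a shorter unit are reported only for the primitive unit, so
#' mononucleotide runs are never reported; overlapping loci of different
#' primitive units are each reported separately. Units containing `N` are
#' not reported (an unknown base cannot be certified a perfect repeat).
#'
#' @param s A single (optionally named) sequence.
#' @param unit_sizes Unit sizes to scan (subset of 2:6).
#' @param min_copies Minimum number of full copies (default 7, i.e. more
#'   than six repeat units).
#' @return Data frame: `seq_id`, `start`, `end` (0-based half-open), `unit`,
#'   `canonical_unit`, `copies`.
#' @export
find_strs <- function(s, unit_sizes = 2:6, min_copies = 7L) {
  stopifnot(all(unit_sizes >= 2L), all(unit_sizes <= 6L))
  id <- seq_id_of(s)
  x <- strsplit(toupper(s[[1]]), "")[[1]]
  n <- length(x)
  out <- list()
  for (k in sort(unique(as.integer(unit_sizes)))) {
    if (n < 2L * k) next
    eq <- x[seq_len(n - k)] == x[seq.int(k + 1L, n)]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      a <- starts[j]                     # first offset with period-k match
      L <- r$lengths[j] + k              # region length
      copies <- L %/% k
      if (copies < min_copies) next
      unit <- paste(x[seq.int(a, a + k - 1L)], collapse = "")
      if (grepl("N", unit, fixed = TRUE)) next
      if (!is_primitive_unit(unit)) next
      out[[length(out) + 1L]] <- data.frame(
        seq_id = id, start = a - 1L, end = a - 1L + copies * k,
        unit = unit, canonical_unit = canonical_unit(unit),
        copies = copies, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) {
    res <- do.call(rbind, out)
    res[order(res$start, res$end, res$unit, method = "radix"), , drop = FALSE]
  } else {
    data.frame(seq_id = character(0), start = integer(0), end = integer(0),
               unit = character(0), canonical_unit = character(0),
               copies = integer(0))
  }
}

# all raw PQS candidates on the given strand of a plain string.
# A candidate is a choice of 4 G-runs of a common length g >= min_run at
# positions p1<p2<p3<p4 with loops >= min_loop and total span <= max_len.
pqs_candidates_one_strand <- function(str, max_len = 30L, min_run = 2L,
                                      min_loop = 0L) {
  x <- strsplit(str, "")[[1]]
  n <- length(x)
  if (n == 0L) return(NULL)
  r <- rle(x == "G")
  run_ends <- cumsum(r$lengths)
  run_starts <- run_ends - r$lengths + 1L
  g_runs <- which(r$values)
  if (length(g_runs) == 0L) return(NULL)
  max_g <- min(max(r$lengths[g_runs]), (max_len - 3L * min_loop) %/% 4L)
  out <- list()
  for (g in seq.int(min_run, length.out = max(0L, max_g - min_run + 1L))) {
    pos <- unlist(lapply(g_runs, function(j) {
      if (r$lengths[j] >= g) seq.int(run_starts[j], run_ends[j] - g + 1L)
      else integer(0)
    }), use.names = FALSE)
    if (length(pos) < 4L) next
    pos <- sort(pos)
    gap <- g + min_loop
    for (i1 in seq_along(pos)) {
      p1 <- pos[i1]
      lim <- p1 + max_len - g   # p4 may not start after this
      if (p1 + 3L * gap + g - 1L > n) break
      for (i2 in which(pos >= p1 + gap & pos <= lim - 2L * gap)) {
        p2 <- pos[i2]
        for (i3 in which(pos >= p2 + gap & pos <= lim - gap)) {
          p3 <- pos[i3]
          for (i4 in which(pos >= p3 + gap & pos <= lim)) {
            p4 <- pos[i4]
            loops <- c(p2 - p1 - g, p3 - p2 - g, p4 - p3 - g)
            med <- sort(loops)[2L]
            out[[length(out) + 1L]] <- c(p1, p2, p3, p4, g,
                                         loops,
                                         sum(10 - abs(loops - med)) + 10L * (g - 2L))
          }
        }
      }
    }
  }
  if (length(out) == 0L) return(NULL)
  m <- do.call(rbind, out)
  data.frame(p1 = m[, 1], p2 = m[, 2], p3 = m[, 3], p4 = m[, 4],
             g_run_length = m[, 5], loop1 = m[, 6], loop2 = m[, 7],
             loop3 = m[, 8], g_score = m[, 9])
}

pqs_empty <- function() {
  data.frame(seq_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), g_run_length = integer(0),
             run1 = integer(0), run2 = integer(0), run3 = integer(0),
             run4 = integer(0), loop1 = integer(0), loop2 = integer(0),
             loop3 = integer(0), g_score = integer(0))
}

#' Raw PQS candidate set of one strand
#'
#' Exposes the candidate enumeration behind [find_pqs()] (before overlap
#' resolution), mainly for validation: every choice of four G-runs of a
#' common length `>= min_run`, loops `>= min_loop`, total span `<= max_len`.
#'
#' @inheritParams find_pqs
#' @param strand `"+"` scans `s` as given; `"-"` scans its reverse
#'   complement and reports promoter coordinates.
#' @return Data frame: `seq_id`, `start`, `end`, `strand`, `g_run_length`,
#'   `run1`..`run4` (0-based G-run starts), `loop1`..`loop3`, `g_score`.
#' @export
pqs_candidates <- function(s, max_len = 30L, min_run = 2L, min_loop = 0L,
                           strand = "+") {
  id <- seq_id_of(s)
  str <- toupper(s[[1]])
  n <- nchar(str)
  cand <- pqs_candidates_one_strand(
    if (strand == "+") str else reverse_complement(str),
    max_len, min_run, min_loop)
  if (is.null(cand)) return(pqs_empty())
  g <- cand$g_run_length
  if (strand == "+") {
    runs <- cbind(cand$p1, cand$p2, cand$p3, cand$p4) - 1L
    start <- cand$p1 - 1L
    end <- cand$p4 + g - 1L
    loops <- cbind(cand$loop1, cand$loop2, cand$loop3)
  } else {
    # rc coordinate q (1-based, run of length g) -> promoter start n - q - g + 1
    runs <- cbind(n - cand$p4 - g + 1L, n - cand$p3 - g + 1L,
                  n - cand$p2 - g + 1L, n - cand$p1 - g + 1L)
    start <- n - (cand$p4 + g - 1L)
    end <- n - cand$p1 + 1L
    loops <- cbind(cand$loop3, cand$loop2, cand$loop1)
  }
  data.frame(seq_id = id, start = as.integer(start), end = as.integer(end),
             strand = strand, g_run_length = as.integer(g),
             run1 = as.integer(runs[, 1]), run2 = as.integer(runs[, 2]),
             run3 = as.integer(runs[, 3]), run4 = as.integer(runs[, 4]),
             loop1 = as.integer(loops[, 1]), loop2 = as.integer(loops[, 2]),
             loop3 = as.integer(loops[, 3]),
             g_score = as.integer(cand$g_score), stringsAsFactors = FALSE)
}

#' Find potential G-quadruplex-forming sequences (PQS)
#'
#' Candidates are four G-runs of a common length (at least `min_run`)
#' separated by loops of at least `min_loop` bases with total span at most
#' `max_len`, on the given strand and on the reverse complement (reported in
#' promoter coordinates). Overlapping candidates are resolved greedily:
#' hits are kept by descending `g_score`, then ascending start, ascending
#' end, descending run length, `+` strand first, discarding any candidate
#' overlapping an already-kept hit.
#'
#' The score rewards long G-runs and equal loop lengths:
#' `g_score = sum over loops of (10 - |loop - median loop|) + 10*(g - 2)`.
#'
#' @param s A single (optionally named) sequence.
#' @param max_len Maximum total span, bp (default 30).
#' @param min_run Minimum G-run length (default 2).
#' @param min_loop Minimum loop length (default 0).
#' @param both_strands Also scan the reverse complement (default TRUE).
#' @return Data frame as in [pqs_candidates()], mutually non-overlapping.
#' @export
find_pqs <- function(s, max_len = 30L, min_run = 2L, min_loop = 0L,
                     both_strands = TRUE) {
  cand <- pqs_candidates(s, max_len, min_run, min_loop, strand = "+")
  if (both_strands) {
    cand <- rbind(cand, pqs_candidates(s, max_len, min_run, min_loop,
                                       strand = "-"))
  }
  if (nrow(cand) == 0L) return(cand)
  ord <- order(-cand$g_score, cand$start, cand$end, -cand$g_run_length,
               cand$strand, method = "radix")
  cand <- cand[ord, ]
  kept <- logical(nrow(cand))
  kept_iv <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(cand))) {
    st <- cand$start[i]; en <- cand$end[i]
    if (nrow(kept_iv) == 0L ||
        all(en <= kept_iv[, 1] | st >= kept_iv[, 2])) {
      kept[i] <- TRUE
      kept_iv <- rbind(kept_iv, c(st, en))
    }
  }
  res <- cand[kept, , drop = FALSE]
  res <- res[order(res$start, res$end, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

iupac_regex <- function(motif) {
  ch <- strsplit(toupper(motif), "")[[1]]
  bad <- setdiff(ch, names(IUPAC_CLASSES))
  if (length(bad)) stop("invalid IUPAC symbol: ", bad[1])
  paste(vapply(ch, function(x) {
    cls <- IUPAC_CLASSES[[x]]
    if (nchar(cls) == 1L) cls else paste0("[", cls, "]")
  }, character(1)), collapse = "")
}

#' Scan a sequence for a degenerate IUPAC consensus motif
#'
#' Every offset where the promoter substring matches the motif's expanded
#' character classes is reported; overlapping hits are all reported.
#' Reverse-strand hits are found by matching the reverse complement of the
#' motif against the forward sequence and are reported with strand `-` in
#' forward coordinates.
#'
#' @param s A single (optionally named) sequence.
#' @param motif IUPAC consensus string (e.g. `"GCYRCAGC"`).
#' @param both_strands Also search the reverse complement (default TRUE).
#' @return Data frame: `seq_id`, `start`, `end` (0-based half-open),
#'   `motif`, `strand`.
#' @export
scan_motif <- function(s, motif, both_strands = TRUE) {
  id <- seq_id_of(s)
  str <- toupper(s[[1]])
  motif <- toupper(motif)
  hits_for <- function(pat, strand) {
    re <- sprintf("(?=%s)", iupac_regex(pat))
    m <- gregexpr(re, str, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    data.frame(seq_id = id, start = as.integer(m) - 1L,
               end = as.integer(m) - 1L + nchar(motif),
               motif = motif, strand = strand, stringsAsFactors = FALSE)
  }
  out <- list(hits_for(motif, "+"))
  if (both_strands) out <- c(out, list(hits_for(reverse_complement(motif), "-")))
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L || nchar(str) == 0L) {
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), motif = character(0),
                      strand = character(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$strand, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Element density per promoter
#'
#' @param hits Data frame of hits (or an integer count).
#' @param n_promoters Number of promoters scanned (> 0).
#' @return List with `total` and `per_promoter`.
#' @export
element_density <- function(hits, n_promoters) {
  if (n_promoters <= 0L) stop("n_promoters must be > 0")
  total <- if (is.data.frame(hits)) nrow(hits) else as.integer(hits)
  list(total = total, per_promoter = total / n_promoters)
}

#' Scan a promoter set for all element classes
#'
#' Applies [find_cpg_islands()], [find_strs()], [find_pqs()] and
#' [scan_motif()] (for each motif supplied) to every promoter.
#'
#' @param promoters Named character vector of promoter sequences.
#' @param motifs Character vector of IUPAC consensus motifs (optional).
#' @param cpg,str,pqs Named lists of parameter overrides for the three
#'   scanners (e.g. `str = list(min_copies = 7)`).
#' @return List of data frames: `cpg`, `str`, `pqs`, `motif`.
#' @export
scan_promoters <- function(promoters, motifs = character(0),
                           cpg = list(), str = list(), pqs = list()) {
  stopifnot(length(promoters) >= 1L, !is.null(names(promoters)))
  per <- function(fun, extra) {
    do.call(rbind, lapply(names(promoters), function(id) {
      do.call(fun, c(list(setNames(promoters[id], id)), extra))
    }))
  }
  motif_hits <- if (length(motifs)) {
    do.call(rbind, lapply(motifs, function(m) per(scan_motif, list(motif = m))))
  } else {
    data.frame(seq_id = character(0), start = integer(0), end = integer(0),
               motif = character(0), strand = character(0))
  }
  list(cpg = per(find_cpg_islands, cpg),
       str = per(find_strs, str),
       pqs = per(find_pqs, pqs),
       motif = motif_hits)
}
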
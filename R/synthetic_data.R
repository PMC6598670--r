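# Seed-deterministic generators for every input the analysis consumes:
# an FPKM matrix with known housekeeping / tissue-specific / other labels,
# promoter sequences with planted elements at recorded intervals, and
# divergent sequence pairs with known substitution parameters.

# stratified mean-preserving multiplicative noise factors.
# Marginally Uniform(1 - cv*sqrt(3), 1 + cv*sqrt(3)) (so sd/mean = cv), but
# spread evenly across the vector (one draw per stratum, randomly permuted):
# the min-max-normalized profile is then close to an ideal uniform grid, the
# property the housekeeping uniformity screen selects for.
stratified_factors <- function(n, cv) {
  a <- cv * sqrt(3)
  if (a >= 1) stop("noise_cv too large: factors would go negative")
  if (a == 0) return(rep(1, n))
  u <- (sample.int(n) - stats::runif(n)) / n  # one point per stratum
  1 - a + 2 * a * u
}

#' Simulate a transcript-by-tissue FPKM matrix with known labels
#'
#' Generates three kinds of transcripts (one transcript per gene):
#' housekeeping-like (`HK`: detected in every tissue, uniform profile within a
#' narrow multiplicative band around `base_level`), tissue-specific-like
#' (`TS`: above the detection threshold in a small set of tissues, below it
#' elsewhere) and `other` transcripts that each violate one housekeeping
#' criterion (recorded per transcript: detected in only a subset of tissues;
#' a strongly bimodal profile that fails the uniformity test; or a single
#' tissue outside the fourfold range).
#'
#' HK noise is stratified mean-preserving uniform multiplicative noise with
#' coefficient of variation `noise_cv` (see the methods vignette for why the
#' spread is stratified rather than i.i.d.).
#'
#' @param n_hk,n_ts,n_other Number of transcripts of each kind.
#' @param n_tissues Number of tissues (default 21, a whole-body panel).
#' @param base_level Mean expression of expressed transcripts, FPKM.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param ts_tissues Admissible expressed-tissue counts for TS transcripts;
#'   the count is drawn uniformly from this set (default `1:3`). A scalar
#'   fixes the count exactly.
#' @param threshold Detection threshold in FPKM; "off" tissues are drawn
#'   strictly below it.
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with `matrix` (an [expression_matrix()]) and `truth`, a data
#'   frame with columns `transcript_id`, `gene_id`, `true_label`, `detail`.
#' @export
simulate_expression_matrix <- function(n_hk, n_ts, n_other, n_tissues = 21L,
                                       base_level = 17.1, noise_cv = 0.1,
                                       ts_tissues = 1:3, threshold = 1,
                                       seed = 1L) {
  stopifnot(n_hk >= 0, n_ts >= 0, n_other >= 0, noise_cv >= 0, threshold > 0)
  if (n_tissues < 4L) stop("n_tissues must be >= 4 (fold-range rule degenerate)")
  if (any(ts_tissues < 1L) || any(ts_tissues >= n_tissues)) {
    stop("ts_tissues counts must lie in [1, n_tissues)")
  }
  with_seed(seed, {
    n <- n_hk + n_ts + n_other
    tissues <- sprintf("tissue%02d", seq_len(n_tissues))
    values <- matrix(0, nrow = n, ncol = n_tissues)
    labels <- character(n)
    detail <- character(n)
    off_level <- function(k) stats::runif(k, 0, 0.9 * threshold)
    row_i <- 0L
    for (i in seq_len(n_hk)) {
      row_i <- row_i + 1L
      values[row_i, ] <- base_level * stratified_factors(n_tissues, noise_cv)
      labels[row_i] <- "HK"
      detail[row_i] <- "uniform across all tissues"
    }
    for (i in seq_len(n_ts)) {
      row_i <- row_i + 1L
      k <- if (length(ts_tissues) == 1L) ts_tissues else sample(ts_tissues, 1L)
      on <- sample.int(n_tissues, k)
      v <- off_level(n_tissues)
      v[on] <- base_level * stratified_factors(k, noise_cv)
      # keep "on" tissues genuinely detected even at extreme noise
      v[on] <- pmax(v[on], threshold * 1.5)
      values[row_i, ] <- v
      labels[row_i] <- "TS"
      detail[row_i] <- sprintf("expressed in %d tissue(s)", k)
    }
    viol <- c("detected_subset", "ks_skew", "fold_outlier")
    for (i in seq_len(n_other)) {
      row_i <- row_i + 1L
      type <- viol[(i - 1L) %% 3L + 1L]
      if (type == "detected_subset") {
        # detected in >3 but <all tissues: neither HK nor TS
        k_off <- sample(2:(n_tissues - 5L), 1L)
        v <- base_level * stratified_factors(n_tissues, max(noise_cv, 0.05))
        v[sample.int(n_tissues, k_off)] <- off_level(k_off)
      } else if (type == "ks_skew") {
        # bimodal two-level profile inside the fourfold band: uniformity fails
        n_hi <- max(2L, round(0.2 * n_tissues))
        v <- rep(0.7 * base_level, n_tissues)
        v[sample.int(n_tissues, n_hi)] <- 2.1 * base_level
        v <- v * (1 + stats::runif(n_tissues, -0.02, 0.02))
      } else {
        # one tissue far above the fourfold range of the average
        v <- base_level * stratified_factors(n_tissues, max(noise_cv, 0.02))
        v[sample.int(n_tissues, 1L)] <- 8 * base_level
      }
      values[row_i, ] <- v
      labels[row_i] <- "other"
      detail[row_i] <- type
    }
    ids <- sprintf("t%04d", seq_len(max(n, 1L)))[seq_len(n)]
    genes <- sub("^t", "g", ids)
    rownames(values) <- ids
    colnames(values) <- tissues
    truth <- data.frame(transcript_id = ids, gene_id = genes,
                        true_label = labels, detail = detail,
                        stringsAsFactors = FALSE)
    list(matrix = expression_matrix(values, setNames(genes, ids)),
         truth = truth)
  })
}

# concrete instance of an IUPAC consensus (one base sampled per class)
concretize_iupac <- function(motif) {
  ch <- strsplit(toupper(motif), "")[[1]]
  bad <- setdiff(ch, names(IUPAC_CLASSES))
  if (length(bad)) stop("invalid IUPAC symbol: ", bad[1])
  paste(vapply(ch, function(x) {
    cls <- strsplit(IUPAC_CLASSES[[x]], "")[[1]]
    cls[sample.int(length(cls), 1L)]
  }, character(1)), collapse = "")
}

# CG-rich block used for planted CpG islands: high GC, high observed/expected
# CpG. Emits "CG" dinucleotides with probability cg_rate, else a single
# GC-biased base.
cpg_block <- function(len, cg_rate = 0.35) {
  out <- character(0)
  total <- 0L
  while (total < len) {
    if (stats::runif(1) < cg_rate && total + 2L <= len) {
      out <- c(out, "C", "G"); total <- total + 2L
    } else {
      out <- c(out, sample(c("A", "C", "G", "T"), 1L, prob = c(.2, .3, .3, .2)))
      total <- total + 1L
    }
  }
  paste(out, collapse = "")
}

#' Simulate promoter sequences with planted elements
#'
#' Background bases are i.i.d. with per-base GC probability `gc_background`;
#' planted elements are written verbatim at their recorded intervals so truth
#' is exactly recoverable by string comparison.
#'
#' Each entry of `plant` is a list with `type` (one of `"str"`, `"pqs"`,
#' `"cpg"`, `"motif"`), `at` (0-based offset), `promoter` (index, default 1)
#' and type-specific fields: `unit` + `copies` (str), `seq` (pqs, literal
#' quadruplex string), `length` (cpg block length, >= 200 recommended),
#' `motif` (IUPAC consensus; a concrete instance is sampled).
#'
#' One guard base flanking planted STRs (period broken) and PQS (non-G) is
#' forced so the planted interval is exactly the maximal locus a scanner
#' reports; guards only touch background positions.
#'
#' @param n Number of promoters.
#' @param length Promoter length in bp (default 2000, the 2-kb upstream
#'   convention).
#' @param gc_background Background per-base GC probability (default 0.45,
#'   matching genome-average promoter GC).
#' @param cpg_depletion Relative CpG dinucleotide frequency of the background
#'   (default 1 = independent bases, no depletion). Values below 1 suppress
#'   a G following a C by this factor (first-order Markov), emulating the
#'   methylation-driven CpG depletion of real genomic DNA; an undepleted
#'   background has observed/expected CpG near 1 and saturates the island
#'   rule at GC near 0.5.
#' @param plant List of element specifications (see Details); may be empty.
#' @param seed Integer seed.
#' @return List with `sequences` (named character vector) and `truth`, a data
#'   frame with columns `promoter`, `type`, `start`, `end`, `detail`
#'   (planted string or unit/motif).
#' @export
simulate_promoter_set <- function(n, length = 2000L, gc_background = 0.45,
                                  cpg_depletion = 1, plant = list(),
                                  seed = 1L) {
  stopifnot(n >= 1L, length >= 1L, gc_background >= 0, gc_background <= 1,
            cpg_depletion >= 0, cpg_depletion <= 1)
  with_seed(seed, {
    ids <- sprintf("prom%03d", seq_len(n))
    p <- c((1 - gc_background) / 2, gc_background / 2,
           gc_background / 2, (1 - gc_background) / 2)
    bases4 <- c("A", "C", "G", "T")
    draw_background <- function() {
      x <- sample(bases4, length, replace = TRUE, prob = p)
      if (cpg_depletion < 1 && length >= 2L) {
        # resample each G that follows a C, keeping it with the depletion
        # factor; left-to-right so new CpGs cannot slip in unexamined
        p_nog <- p; p_nog[3] <- p[3] * cpg_depletion
        for (i in which(x[-length] == "C" & x[-1L] == "G") + 1L) {
          if (x[i - 1L] == "C") x[i] <- sample(bases4, 1L, prob = p_nog)
        }
      }
      x
    }
    mats <- lapply(seq_len(n), function(i) draw_background())
    truth <- list()
    occupied <- lapply(seq_len(n), function(i) integer(0))
    for (el in plant) {
      stopifnot(is.list(el), !is.null(el$type), !is.null(el$at))
      idx <- if (is.null(el$promoter)) 1L else as.integer(el$promoter)
      at <- as.integer(el$at)  # 0-based
      txt <- switch(el$type,
        str = {
          stopifnot(nchar(el$unit) >= 2L, nchar(el$unit) <= 6L, el$copies >= 1L)
          strrep(toupper(el$unit), el$copies)
        },
        pqs = toupper(el$seq),
        cpg = cpg_block(as.integer(el$length)),
        motif = concretize_iupac(el$motif),
        stop("unknown plant type: ", el$type)
      )
      L <- nchar(txt)
      if (at < 0L || at + L > length) stop("planted element outside promoter")
      span <- seq.int(at + 1L, at + L)
      if (any(span %in% occupied[[idx]])) stop("overlapping planted elements")
      occupied[[idx]] <- c(occupied[[idx]], span)
      mats[[idx]][span] <- strsplit(txt, "")[[1]]
      # guards: break any chance continuation of the planted pattern
      if (el$type == "str") {
        k <- nchar(el$unit)
        g_left <- at            # 1-based position of base before the plant
        g_right <- at + L + 1L  # 1-based position of base after the plant
        if (g_left >= 1L && !(g_left %in% occupied[[idx]])) {
          avoid <- mats[[idx]][g_left + k]
          mats[[idx]][g_left] <- sample(setdiff(c("A", "C", "G", "T"), avoid), 1L)
        }
        if (g_right <= length && !(g_right %in% occupied[[idx]])) {
          avoid <- mats[[idx]][g_right - k]
          mats[[idx]][g_right] <- sample(setdiff(c("A", "C", "G", "T"), avoid), 1L)
        }
      } else if (el$type == "pqs") {
        # G-free margin so no background G-run can join or outrank the
        # planted quadruplex within loop distance
        margin <- c(seq.int(at - 6L, at), seq.int(at + L + 1L, at + L + 7L))
        for (g in margin) {
          if (g >= 1L && g <= length && !(g %in% occupied[[idx]])) {
            if (mats[[idx]][g] == "G") {
              mats[[idx]][g] <- sample(c("A", "C", "T"), 1L)
            }
          }
        }
      }
      truth[[length(truth) + 1L]] <- data.frame(
        promoter = ids[idx], type = el$type, start = at, end = at + L,
        detail = if (el$type == "str") toupper(el$unit)
                 else if (el$type == "motif") toupper(el$motif)
                 else txt,
        stringsAsFactors = FALSE
      )
    }
    seqs <- setNames(vapply(mats, paste, character(1), collapse = ""), ids)
    truth_df <- if (length(truth)) do.call(rbind, truth) else
      data.frame(promoter = character(0), type = character(0),
                 start = integer(0), end = integer(0), detail = character(0))
    list(sequences = seqs, truth = truth_df)
  })
}

SENSE_CODONS <- NULL  # populated lazily via sense_codons()

sense_codons <- function() {
  all3 <- as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                paste0), c("T", "C", "A", "G"), paste0))
  all3[GENETIC_CODE_TABLE[all3] != "*"]
}

#' Simulate a divergent, aligned sequence pair with known parameters
#'
#' Two modes. In `codon` mode an ancestor of `n_codons` sense codons is
#' mutated by an accept/reject scheme: single-nucleotide changes are proposed
#' at expected rate `t` per codon; a nonsynonymous candidate is accepted with
#' relative probability `omega` : 1 against synonymous candidates
#' (`min(1, omega)` vs `min(1, 1/omega)`), and changes creating stop codons
#' are rejected. This is not a full codon substitution model: it is designed
#' so Nei-Gojobori estimation can recover the sign and approximate magnitude
#' of `omega`. In `promoter` mode each site is substituted to a uniformly
#' chosen different base with probability `p_site` (so the expected
#' p-distance equals `p_site`).
#'
#' @param n_codons Number of codons (codon mode).
#' @param omega Target dN/dS acceptance ratio (codon mode; > 0).
#' @param t Expected number of proposed changes per codon (codon mode).
#' @param mode `"codon"` or `"promoter"`.
#' @param p_site Per-site substitution probability (promoter mode).
#' @param n_sites Number of sites (promoter mode; defaults to `3 * n_codons`).
#' @param seed Integer seed.
#' @return List with `a` (ancestor), `b` (derived), both plain strings of
#'   equal length, and `truth` (list of the generating parameters and the
#'   realized substitution count).
#' @export
simulate_divergent_pair <- function(n_codons = NULL, omega = 1, t = 0,
                                    mode = c("codon", "promoter"),
                                    p_site = 0, n_sites = NULL, seed = 1L) {
  mode <- match.arg(mode)
  with_seed(seed, {
    if (mode == "promoter") {
      if (is.null(n_sites)) {
        if (is.null(n_codons) || n_codons < 1L) stop("n_sites (or n_codons) required")
        n_sites <- 3L * n_codons
      }
      stopifnot(n_sites >= 1L, p_site >= 0, p_site <= 1)
      bases <- c("A", "C", "G", "T")
      anc <- sample(bases, n_sites, replace = TRUE)
      der <- anc
      hit <- stats::runif(n_sites) < p_site
      if (any(hit)) {
        der[hit] <- vapply(anc[hit], function(b) sample(setdiff(bases, b), 1L),
                           character(1))
      }
      return(list(a = paste(anc, collapse = ""), b = paste(der, collapse = ""),
                  truth = list(mode = "promoter", p_site = p_site,
                               n_sub = sum(hit))))
    }
    if (is.null(n_codons) || n_codons < 1L) stop("n_codons must be >= 1")
    stopifnot(omega > 0, t >= 0)
    codons <- sense_codons()
    anc <- sample(codons, n_codons, replace = TRUE)
    der <- anc
    acc_nonsyn <- min(1, omega)
    acc_syn <- min(1, 1 / omega)
    n_prop <- stats::rpois(1L, t * n_codons)
    n_acc <- 0L
    bases <- c("A", "C", "G", "T")
    for (i in seq_len(n_prop)) {
      ci <- sample.int(n_codons, 1L)
      pos <- sample.int(3L, 1L)
      cur <- der[ci]
      old_base <- substr(cur, pos, pos)
      new_base <- sample(setdiff(bases, old_base), 1L)
      cand <- cur
      substr(cand, pos, pos) <- new_base
      if (GENETIC_CODE_TABLE[[cand]] == "*") next
      syn <- GENETIC_CODE_TABLE[[cand]] == GENETIC_CODE_TABLE[[cur]]
      p_acc <- if (syn) acc_syn else acc_nonsyn
      if (stats::runif(1) < p_acc) {
        der[ci] <- cand
        n_acc <- n_acc + 1L
      }
    }
    list(a = paste(anc, collapse = ""), b = paste(der, collapse = ""),
         truth = list(mode = "codon", omega = omega, t = t, n_sub = n_acc))
  })
}
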
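# Nei-Gojobori (1986) evolutionary-rate estimation with Jukes-Cantor
# correction, a codon-bootstrap Z-test of selection, the promoter
# substitution rate dP under pairwise deletion, and a global aligner for
# unaligned input pairs.

# Standard genetic code, codons ordered first position slowest over T,C,A,G.
GENETIC_CODE_TABLE <- local({
  b <- c("T", "C", "A", "G")
  codons <- paste0(rep(b, each = 16L), rep(rep(b, each = 4L), 4L), rep(b, 16L))
  aas <- strsplit("FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG", "")[[1]]
  setNames(aas, codons)
})

is_stop <- function(codon) GENETIC_CODE_TABLE[codon] == "*"

#' Synonymous and nonsynonymous site counts of a codon
#'
#' Classifies each of the nine single-nucleotide changes of a sense codon
#' against the standard genetic code. Each codon position contributes one
#' site, split by the fraction of its changes that are synonymous, so
#' `syn_sites + nonsyn_sites = 3` exactly. Changes creating stop codons are
#' counted as nonsynonymous under the default policy, or dropped from both
#' numerator and denominator under `stop_policy = "exclude"`.
#'
#' @param codon A 3-letter sense codon over A, C, G, T.
#' @param stop_policy `"nonsyn"` (default) or `"exclude"`.
#' @return Named numeric vector `c(syn_sites, nonsyn_sites)`.
#' @examples
#' codon_site_counts("TTT") # 1/3 synonymous site
#' codon_site_counts("GGG") # fourfold-degenerate third position: 1 and 2
#' @export
codon_site_counts <- function(codon, stop_policy = c("nonsyn", "exclude")) {
  stop_policy <- match.arg(stop_policy)
  codon <- toupper(codon)
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon)) {
    stop("codon must be a 3-mer over A, C, G, T: ", codon)
  }
  if (is_stop(codon)) stop("stop codon has no site counts: ", codon)
  aa <- GENETIC_CODE_TABLE[[codon]]
  bases <- c("A", "C", "G", "T")
  syn <- 0
  for (pos in 1:3) {
    old <- substr(codon, pos, pos)
    n_syn <- 0L
    n_total <- 0L
    for (b in setdiff(bases, old)) {
      cand <- codon
      substr(cand, pos, pos) <- b
      if (is_stop(cand)) {
        if (stop_policy == "nonsyn") n_total <- n_total + 1L
        # "exclude": dropped entirely
      } else {
        n_total <- n_total + 1L
        if (GENETIC_CODE_TABLE[[cand]] == aa) n_syn <- n_syn + 1L
      }
    }
    denom <- if (stop_policy == "nonsyn") 3L else n_total
    syn <- syn + n_syn / denom
  }
  c(syn_sites = syn, nonsyn_sites = 3 - syn)
}

# pathway-averaged synonymous / nonsynonymous difference counts between two
# sense codons: average over all orderings of the single changes, excluding
# pathways through stop codons (if every pathway hits a stop, average over
# all pathways with stop steps counted nonsynonymous).
codon_path_diffs <- function(c1, c2) {
  diffpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  d <- length(diffpos)
  if (d == 0L) return(c(sd = 0, nd = 0))
  perms <- if (d == 1L) list(diffpos)
           else if (d == 2L) list(diffpos, rev(diffpos))
           else {
    idx <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
    lapply(idx, function(o) diffpos[o])
  }
  walk <- function(order, allow_stops) {
    cur <- c1
    sd <- 0; nd <- 0
    for (pos in order) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (is_stop(nxt) && nxt != c2 && !allow_stops) return(NULL)
      if (!is_stop(cur) && !is_stop(nxt) &&
          GENETIC_CODE_TABLE[[cur]] == GENETIC_CODE_TABLE[[nxt]]) {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- Filter(Negate(is.null), lapply(perms, walk, allow_stops = FALSE))
  if (length(res) == 0L) res <- lapply(perms, walk, allow_stops = TRUE)
  m <- do.call(rbind, res)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

.ng_cache <- new.env(parent = emptyenv())

# lookup tables over the 61 sense codons: per-codon site counts and
# pathway-averaged pairwise difference counts; built once per stop policy
ng_tables <- function(stop_policy = "nonsyn") {
  key <- paste0("tab_", stop_policy)
  if (!is.null(.ng_cache[[key]])) return(.ng_cache[[key]])
  codons <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE != "*"]
  sites <- t(vapply(codons, codon_site_counts, numeric(2),
                    stop_policy = stop_policy))
  nc <- length(codons)
  sd <- matrix(0, nc, nc, dimnames = list(codons, codons))
  nd <- sd
  for (i in seq_len(nc)) {
    for (j in seq_len(nc)) {
      if (i < j) {
        pd <- codon_path_diffs(codons[i], codons[j])
        sd[i, j] <- sd[j, i] <- pd[["sd"]]
        nd[i, j] <- nd[j, i] <- pd[["nd"]]
      }
    }
  }
  .ng_cache[[key]] <- list(codons = codons, sites = sites, sd = sd, nd = nd)
  .ng_cache[[key]]
}

split_codons <- function(s) {
  n <- nchar(s)
  if (n %% 3L != 0L) stop("aligned CDS length not divisible by 3")
  substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
}

# per-codon NG86 contributions for an aligned pair, after pairwise deletion
# of codons containing a gap or ambiguous base in either sequence.
# Columns: sd, nd, sbar (mean syn sites of the two codons), nbar.
codon_contributions <- function(a, b, stop_policy = "nonsyn") {
  ca <- split_codons(toupper(a))
  cb <- split_codons(toupper(b))
  if (length(ca) != length(cb)) stop("aligned sequences differ in length")
  ok <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  ca <- ca[ok]; cb <- cb[ok]
  if (length(ca) == 0L) stop("no comparable codons after pairwise deletion")
  if (any(is_stop(ca)) || any(is_stop(cb))) {
    stop("internal stop codon in comparable positions")
  }
  tab <- ng_tables(stop_policy)
  ia <- match(ca, tab$codons)
  ib <- match(cb, tab$codons)
  cbind(sd = tab$sd[cbind(ia, ib)],
        nd = tab$nd[cbind(ia, ib)],
        sbar = (tab$sites[ia, 1] + tab$sites[ib, 1]) / 2,
        nbar = (tab$sites[ia, 2] + tab$sites[ib, 2]) / 2)
}

#' Pairwise codon difference and site counts (Nei-Gojobori counting)
#'
#' Codons containing a gap or ambiguous base in either sequence are skipped
#' (pairwise deletion). Multi-position codon differences are averaged over
#' all orderings of the single changes, excluding pathways through stop
#' codons. `S` and `N` are the means of the two per-sequence site totals.
#'
#' @param a,b Aligned CDS strings of equal length divisible by 3.
#' @param stop_policy Stop-codon policy for site counting (see
#'   [codon_site_counts()]).
#' @return List with `Sd`, `Nd`, `S`, `N`, `n_codons` (comparable codons).
#' @export
pairwise_codon_differences <- function(a, b, stop_policy = "nonsyn") {
  co <- codon_contributions(a, b, stop_policy)
  list(Sd = sum(co[, "sd"]), Nd = sum(co[, "nd"]),
       S = sum(co[, "sbar"]), N = sum(co[, "nbar"]),
       n_codons = nrow(co))
}

#' Jukes-Cantor distance from a proportion of differences
#'
#' `d = -(3/4) * log(1 - 4p/3)`; strictly increasing on `[0, 3/4)` and
#' always at least its argument.
#'
#' @param p Proportion(s) of observed differences, in `[0, 3/4)`.
#' @return Corrected distance(s).
#' @export
jukes_cantor <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0))
  if (any(p >= 0.75)) stop("saturation: p >= 3/4, Jukes-Cantor distance undefined")
  -0.75 * log(1 - 4 * p / 3)
}

jc_safe <- function(p) ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)

#' Nei-Gojobori dN, dS and dN/dS of an aligned codon pair
#'
#' `pS = Sd/S`, `pN = Nd/N`, each Jukes-Cantor corrected. `omega = dN/dS`
#' when `dS > 0`. Saturated or undefined rates are returned as `NA` with a
#' named status (`"ok"`, `"saturated"`, `"undefined"`).
#'
#' @inheritParams pairwise_codon_differences
#' @return List with `dN`, `dS`, `omega`, `pN`, `pS`, `Sd`, `Nd`, `S`, `N`,
#'   `n_codons` and `status` (named character vector for dN, dS, omega).
#' @export
nei_gojobori <- function(a, b, stop_policy = "nonsyn") {
  d <- pairwise_codon_differences(a, b, stop_policy)
  pS <- d$Sd / d$S
  pN <- d$Nd / d$N
  dS <- jc_safe(pS)
  dN <- jc_safe(pN)
  status <- c(dN = if (is.na(dN)) "saturated" else "ok",
              dS = if (is.na(dS)) "saturated" else "ok")
  if (!is.na(dN) && !is.na(dS) && dS > 0) {
    omega <- dN / dS
    status["omega"] <- "ok"
  } else {
    omega <- NA_real_
    status["omega"] <- "undefined"
  }
  c(list(dN = dN, dS = dS, omega = omega, pN = pN, pS = pS),
    d, list(status = status))
}

#' Codon-bootstrap Z-test of selection (dN vs dS)
#'
#' Variances of dN and dS are estimated by resampling codon columns with
#' replacement; `Z = (dN - dS) / sqrt(Var(dN) + Var(dS))` with a two-sided
#' normal P-value. If the bootstrap variance is zero (e.g. identical
#' sequences) the P-value is 1 by convention.
#'
#' @inheritParams pairwise_codon_differences
#' @param reps Bootstrap replicates (>= 100).
#' @param seed Integer seed for the resampling.
#' @return List with `Z`, `pvalue`, `dN`, `dS`.
#' @export
selection_z_test <- function(a, b, reps = 500L, seed = 1L,
                             stop_policy = "nonsyn") {
  stopifnot(reps >= 100L)
  co <- codon_contributions(a, b, stop_policy)
  n <- nrow(co)
  if (n < 10L) stop("fewer than 10 comparable codons")
  dN <- jc_safe(sum(co[, "nd"]) / sum(co[, "nbar"]))
  dS <- jc_safe(sum(co[, "sd"]) / sum(co[, "sbar"]))
  if (is.na(dN) || is.na(dS)) stop("saturated rates: Z-test undefined")
  sums <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * reps, replace = TRUE), nrow = n)
    counts <- apply(idx, 2L, tabulate, nbins = n)
    t(counts) %*% co  # reps x 4: resampled Sd, Nd, S, N
  })
  dn_r <- jc_safe(sums[, "nd"] / sums[, "nbar"])
  ds_r <- jc_safe(sums[, "sd"] / sums[, "sbar"])
  keep <- is.finite(dn_r) & is.finite(ds_r)
  v <- stats::var(dn_r[keep]) + stats::var(ds_r[keep])
  if (!is.finite(v) || v == 0) {
    return(list(Z = 0, pvalue = 1, dN = dN, dS = dS))
  }
  Z <- (dN - dS) / sqrt(v)
  list(Z = Z, pvalue = 2 * stats::pnorm(-abs(Z)), dN = dN, dS = dS)
}

#' Promoter substitution rate dP with pairwise deletion
#'
#' Columns containing a gap or ambiguous base in either sequence are
#' excluded; dP is the mismatch fraction over the remaining columns,
#' optionally Jukes-Cantor corrected.
#'
#' @param a,b Aligned promoter strings of equal length.
#' @param correction `"raw"` (default) or `"jukes_cantor"`.
#' @return dP, a non-negative scalar.
#' @export
promoter_distance <- function(a, b, correction = c("raw", "jukes_cantor")) {
  correction <- match.arg(correction)
  xa <- strsplit(toupper(a), "")[[1]]
  xb <- strsplit(toupper(b), "")[[1]]
  if (length(xa) != length(xb)) stop("aligned sequences differ in length")
  bases <- c("A", "C", "G", "T")
  ok <- xa %in% bases & xb %in% bases
  if (!any(ok)) stop("no comparable columns after pairwise deletion")
  p <- sum(xa[ok] != xb[ok]) / sum(ok)
  if (correction == "raw") p else jukes_cantor(p)
}

#' Global (Needleman-Wunsch) alignment with linear gap penalty
#'
#' Deterministic tie-breaking: diagonal preferred, then a gap in `b`
#' (consuming `a`), then a gap in `a`.
#'
#' @param a,b Sequences to align (nonempty strings).
#' @param match,mismatch,gap Scoring parameters (defaults +1, -1, -2).
#' @return List with `a`, `b` (aligned strings with `-` gaps) and `score`.
#' @export
align_global <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  xa <- strsplit(a, "")[[1]]
  xb <- strsplit(b, "")[[1]]
  n <- length(xa); m <- length(xb)
  stopifnot(n > 0L, m > 0L)
  F <- matrix(0, n + 1L, m + 1L)
  P <- matrix(0L, n + 1L, m + 1L)  # 1 diag, 2 up (gap in b), 3 left (gap in a)
  F[, 1L] <- gap * (0:n); P[-1L, 1L] <- 2L
  F[1L, ] <- gap * (0:m); P[1L, -1L] <- 3L
  for (i in seq_len(n)) {
    sub <- ifelse(xa[i] == xb, match, mismatch)
    for (j in seq_len(m)) {
      s_diag <- F[i, j] + sub[j]
      s_up <- F[i, j + 1L] + gap
      s_left <- F[i + 1L, j] + gap
      best <- max(s_diag, s_up, s_left)
      F[i + 1L, j + 1L] <- best
      P[i + 1L, j + 1L] <- if (s_diag == best) 1L else if (s_up == best) 2L else 3L
    }
  }
  ai <- character(0); bi <- character(0)
  i <- n + 1L; j <- m + 1L
  while (i > 1L || j > 1L) {
    p <- P[i, j]
    if (p == 1L) {
      ai <- c(xa[i - 1L], ai); bi <- c(xb[j - 1L], bi); i <- i - 1L; j <- j - 1L
    } else if (p == 2L) {
      ai <- c(xa[i - 1L], ai); bi <- c("-", bi); i <- i - 1L
    } else {
      ai <- c("-", ai); bi <- c(xb[j - 1L], bi); j <- j - 1L
    }
  }
  list(a = paste(ai, collapse = ""), b = paste(bi, collapse = ""),
       score = F[n + 1L, m + 1L])
}

#' Pearson correlation between promoter and CDS rates
#'
#' Pairs with a non-finite value in either vector (e.g. undefined omega) are
#' dropped before the test.
#'
#' @param x,y Numeric vectors of equal length (>= 3 finite pairs).
#' @return List with `r` (Pearson coefficient), `pvalue` (two-sided
#'   t-distribution) and `n` (pairs used).
#' @export
rate_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need >= 3 finite pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in a rate vector")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), pvalue = ct$p.value, n = length(x))
}
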
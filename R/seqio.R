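# Sequence and expression-table I/O.
#
# Conventions used throughout the package:
#  * sequences are named character strings over {A,C,G,T,N}, uppercase;
#  * intervals are 0-based half-open (BED convention); human-readable reports
#    convert to 1-based inclusive;
#  * a "promoter" is the 2-kb sequence 5'->3' upstream of a TSS: offset 0 is
#    the distal end and the TSS sits immediately 3' of the last base, so the
#    distance of position p to the TSS is length - p.

IUPAC_CLASSES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG",
  N = "ACGT", X = "ACGT"
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B",
  N = "N", X = "X"
)

#' Read a FASTA file of promoter (or any DNA) sequences
#'
#' Residues are uppercased and any character outside `{A,C,G,T,N}` is replaced
#' by `N` with a single warning reporting how many characters were converted
#' (Ensembl dumps contain soft-masked and ambiguous bases, so these are
#' normalized rather than rejected).
#'
#' @param path Path to a FASTA file (wrapped or unwrapped records).
#' @return Named character vector of sequences; names are the first
#'   whitespace-delimited token of each header.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">p1", "ACGTacgt", ">p2", "GGCC"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) return(setNames(character(0), character(0)))
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop("malformed FASTA: line ", nonblank[1], " is not a header")
  }
  header_at <- which(startsWith(lines, ">"))
  ids <- vapply(lines[header_at],
                function(h) strsplit(trimws(sub("^>", "", h)), "\\s+")[[1]][1],
                character(1), USE.NAMES = FALSE)
  if (anyNA(ids) || any(!nzchar(ids))) {
    bad <- header_at[which(is.na(ids) | !nzchar(ids))[1]]
    stop("malformed FASTA: empty header at line ", bad)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
  }
  bounds <- c(header_at, length(lines) + 1L)
  seqs <- character(length(ids))
  for (i in seq_along(ids)) {
    body <- lines[seq.int(bounds[i] + 1L, bounds[i + 1L] - 1L)]
    body <- body[!startsWith(body, ">")]
    seqs[i] <- gsub("\\s", "", paste(body, collapse = ""))
    if (!nzchar(seqs[i])) {
      stop("malformed FASTA: empty record '", ids[i], "' at line ", header_at[i])
    }
  }
  seqs <- toupper(seqs)
  n_bad <- sum(vapply(strsplit(seqs, ""), function(ch) sum(!ch %in% c("A", "C", "G", "T", "N")), integer(1)))
  if (n_bad > 0L) {
    seqs <- vapply(seqs, function(s) gsub("[^ACGTN]", "N", s), character(1), USE.NAMES = FALSE)
    warning(n_bad, " non-ACGTN character(s) converted to N")
  }
  setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  out <- character(0)
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    starts <- seq.int(1L, nchar(s), by = width)
    out <- c(out, paste0(">", names(seqs)[i]),
             substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }
  writeLines(out, path)
  invisible(path)
}

#' Construct a transcript-by-tissue expression matrix
#'
#' @param values Numeric matrix, transcripts in rows (rownames = transcript
#'   ids), tissues in columns (colnames = tissue ids); FPKM, non-negative.
#' @param gene_of Named character vector mapping each transcript id to its
#'   gene id.
#' @return An object of class `ExpressionMatrix` (list with `values`,
#'   `gene_of`).
#' @export
expression_matrix <- function(values, gene_of) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have transcript rownames and tissue colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate transcript id")
  if (anyDuplicated(colnames(values))) stop("duplicate tissue id")
  if (anyNA(values)) stop("missing expression values")
  if (any(values < 0)) stop("negative FPKM value")
  missing_map <- setdiff(rownames(values), names(gene_of))
  if (length(missing_map)) {
    stop("transcripts without a gene mapping: ", missing_map[1])
  }
  structure(
    list(values = values, gene_of = gene_of[rownames(values)]),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf(
    "ExpressionMatrix: %d transcripts (%d genes) x %d tissues\n",
    nrow(x$values), length(unique(x$gene_of)), ncol(x$values)
  ))
  invisible(x)
}

#' Read a transcript-by-tissue FPKM table
#'
#' Expects a TSV whose header row names the tissues and whose first two
#' columns are the transcript id and gene id.
#'
#' @param path Path to the TSV file.
#' @return An [expression_matrix()] object.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("expression table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", fill = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("expression table needs transcript, gene and >=1 tissue column")
  tx <- df[[1L]]
  gene <- df[[2L]]
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  if (anyNA(vals)) stop("non-numeric or missing expression value")
  rownames(vals) <- tx
  if (anyDuplicated(tx)) stop("duplicate transcript id: ", tx[duplicated(tx)][1])
  expression_matrix(vals, setNames(gene, tx))
}

#' Write an ExpressionMatrix to TSV
#'
#' @param m An [expression_matrix()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(m, path) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  df <- data.frame(transcript_id = rownames(m$values),
                   gene_id = unname(m$gene_of),
                   m$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write element hits as BED6
#'
#' @param hits Data frame with at least `seq_id`, `start`, `end` columns
#'   (0-based half-open); optional `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly. Rows are sorted by (seq_id, start, end).
#' @export
write_bed <- function(hits, path) {
  if (is.null(hits) || nrow(hits) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  stopifnot(all(c("seq_id", "start", "end") %in% names(hits)))
  if (any(hits$start < 0) || any(hits$end <= hits$start)) {
    stop("invalid interval: require 0 <= start < end")
  }
  name <- if ("name" %in% names(hits)) hits$name else "."
  score <- if ("score" %in% names(hits)) as.integer(round(hits$score)) else 0L
  strand <- if ("strand" %in% names(hits)) hits$strand else "."
  bed <- data.frame(chrom = hits$seq_id, start = hits$start, end = hits$end,
                    name = name, score = score, strand = strand,
                    stringsAsFactors = FALSE)
  bed <- bed[order(bed$chrom, bed$start, bed$end, method = "radix"), ]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Reverse complement of a DNA string (IUPAC-aware)
#'
#' An involution on all IUPAC strings: degenerate codes map to their
#' complementary class (Y<->R, K<->M, B<->V, D<->H; W, S, N fixed).
#'
#' @param s Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("AAGG") # "CCTT"
#' reverse_complement("GCYR") # "YRGC"
#' @export
reverse_complement <- function(s) {
  su <- toupper(s)
  bad <- regmatches(su, regexpr(sprintf("[^%s]", paste(names(IUPAC_COMPLEMENT), collapse = "")), su))
  if (any(nzchar(bad))) stop("unknown symbol in sequence: ", bad[nzchar(bad)][1])
  comp <- chartr(paste(names(IUPAC_COMPLEMENT), collapse = ""),
                 paste(unname(IUPAC_COMPLEMENT), collapse = ""), su)
  vapply(comp, function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

# run code with a private, restored RNG state: generators stay
# seed-deterministic without clobbering the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
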
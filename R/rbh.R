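#' Optimal local alignment of two sequences
#'
#' Smith-Waterman local alignment with simple match/mismatch scoring and
#' affine gaps (a linear gap penalty is `gap_open = 0`). Works for DNA or
#' protein as long as both sequences share an alphabet. Identity is
#' `matches / alignment columns * 100`, with gap columns counted in the
#' denominator. This is the built-in stand-in for an external similarity
#' search at test scale; precomputed hit tables can be supplied to
#' [reciprocal_best_hits()] instead.
#'
#' @param a,b sequences (single character strings).
#' @param match,mismatch substitution scores (match > 0 > mismatch).
#' @param gap_open,gap_extend non-negative gap costs; a gap of length L
#'   costs `gap_open + L * gap_extend`.
#' @return list of class `similarity_hit` with `identity` (percent),
#'   `aln_len` (alignment columns), `score`, `query_len`, `subject_len`.
#' @examples
#' align_pair("ACGTACGT", "ACGTTCGT")
#' @export
align_pair <- function(a, b, match = 1, mismatch = -1, gap_open = 0,
                       gap_extend = 2) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  smat <- alignment_matrix(c(a, b), match, mismatch)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::BString(a), subject = Biostrings::BString(b),
    type = "local", substitutionMatrix = smat,
    gapOpening = gap_open, gapExtension = gap_extend)
  aln_len <- Biostrings::nchar(aln)
  ident <- if (aln_len == 0) 0 else
    100 * Biostrings::nmatch(aln) / aln_len
  structure(list(identity = ident,
                 aln_len = aln_len,
                 score = Biostrings::score(aln),
                 query_len = nchar(a), subject_len = nchar(b)),
            class = "similarity_hit")
}

# substitution matrix over the letters present in the sequences
alignment_matrix <- function(seqs, match, mismatch) {
  letters <- sort(unique(strsplit(paste(seqs, collapse = ""), "")[[1]]))
  smat <- matrix(mismatch, length(letters), length(letters),
                 dimnames = list(letters, letters))
  diag(smat) <- match
  smat
}

#' Best similarity hit for every query against a subject set
#'
#' Aligns each query locally against every subject and keeps the top-scoring
#' subject. Ties are broken deterministically: higher identity first, then
#' lexicographically smaller subject id.
#'
#' @param queries,subjects named character vectors of sequences.
#' @inheritParams align_pair
#' @return data.frame with one row per query: `query_id`, `subject_id`,
#'   `score`, `identity`, `aln_len`, `query_len`, `subject_len`.
#' @export
best_hits <- function(queries, subjects, match = 1, mismatch = -1,
                      gap_open = 0, gap_extend = 2) {
  stopifnot(length(queries) > 0, length(subjects) > 0,
            !is.null(names(queries)), !is.null(names(subjects)))
  smat <- alignment_matrix(c(queries, subjects), match, mismatch)
  subj_set <- Biostrings::BStringSet(subjects)
  rows <- lapply(names(queries), function(q) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = subj_set, subject = Biostrings::BString(queries[[q]]),
      type = "local", substitutionMatrix = smat,
      gapOpening = gap_open, gapExtension = gap_extend)
    sc <- Biostrings::score(aln)
    ident <- 100 * Biostrings::nmatch(aln) / Biostrings::nchar(aln)
    ident[!is.finite(ident)] <- 0
    ord <- order(-sc, -ident, names(subjects))
    i <- ord[1]
    data.frame(query_id = q, subject_id = names(subjects)[i],
               score = sc[i], identity = ident[i], aln_len = Biostrings::nchar(aln)[i],
               query_len = nchar(queries[[q]]),
               subject_len = nchar(subjects[[i]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Best hits from a precomputed tabular similarity search
#'
#' Accepts a BLAST "outfmt 6"-style table with columns `qseqid`, `sseqid`,
#' `pident`, `length`, `qlen`, `slen`, `bitscore` and reduces it to one top
#' hit per query (max bitscore, ties by identity then subject id).
#'
#' @param hits data.frame with the columns above (see [read_hit_table()]).
#' @return data.frame in the same shape as [best_hits()].
#' @export
best_hits_from_table <- function(hits) {
  need <- c("qseqid", "sseqid", "pident", "length", "qlen", "slen",
            "bitscore")
  if (!all(need %in% names(hits)))
    stop("hit table must have columns: ", paste(need, collapse = ", "))
  rows <- lapply(split(hits, hits$qseqid), function(h) {
    h <- h[order(-h$bitscore, -h$pident, h$sseqid), , drop = FALSE]
    data.frame(query_id = h$qseqid[1], subject_id = h$sseqid[1],
               score = h$bitscore[1], identity = h$pident[1],
               aln_len = h$length[1], query_len = h$qlen[1],
               subject_len = h$slen[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname best_hits_from_table
#' @param path tab-separated file (no header) with the seven columns above.
#' @export
read_hit_table <- function(path) {
  h <- read.table(path, header = FALSE, sep = "\t",
                  stringsAsFactors = FALSE)
  if (ncol(h) != 7)
    stop("expected 7 tab-separated columns: qseqid sseqid pident length ",
         "qlen slen bitscore")
  names(h) <- c("qseqid", "sseqid", "pident", "length", "qlen", "slen",
                "bitscore")
  h
}

#' Reciprocal-best-hit orthologs under dual identity/coverage criteria
#'
#' A pair (i, j) is reported as orthologous iff gene i's top hit in set B is
#' j, gene j's top hit in set A is i, both directional identities strictly
#' exceed `min_identity` percent, and the alignment covers strictly more
#' than `min_coverage` of each gene's own length ("more than 80%" is
#' implemented as a strict inequality). Coverage of gene a is taken from the
#' a-to-b alignment length over a's length, and of gene b from the b-to-a
#' alignment; `coverage_mode = "query"` checks only the set-A side.
#'
#' Either provide two sequence sets (the built-in aligner is used) or two
#' precomputed directional hit tables.
#'
#' @param set_a,set_b named character vectors of gene sequences.
#' @param hits_ab,hits_ba optional precomputed hit tables (A vs B and B vs
#'   A, "outfmt 6" dialect); when given, the sequence sets are not aligned.
#' @param min_identity identity threshold in percent (default 80).
#' @param min_coverage coverage threshold as a fraction (default 0.8).
#' @param coverage_mode check coverage of `"both"` genes (default) or of
#'   the query (set A) gene only.
#' @inheritParams align_pair
#' @return data.frame sorted by `gene_a` with columns `gene_a`, `gene_b`,
#'   `identity_ab`, `identity_ba`, `coverage_a`, `coverage_b`.
#' @export
reciprocal_best_hits <- function(set_a = NULL, set_b = NULL,
                                 hits_ab = NULL, hits_ba = NULL,
                                 min_identity = 80, min_coverage = 0.8,
                                 coverage_mode = c("both", "query"),
                                 match = 1, mismatch = -1, gap_open = 0,
                                 gap_extend = 2) {
  coverage_mode <- match.arg(coverage_mode)
  check_fraction(min_identity, "min_identity", 0, 100)
  check_fraction(min_coverage, "min_coverage")
  if (is.null(hits_ab) != is.null(hits_ba))
    stop("provide both 'hits_ab' and 'hits_ba', or neither")
  if (is.null(hits_ab)) {
    ab <- best_hits(set_a, set_b, match, mismatch, gap_open, gap_extend)
    ba <- best_hits(set_b, set_a, match, mismatch, gap_open, gap_extend)
  } else {
    ab <- best_hits_from_table(hits_ab)
    ba <- best_hits_from_table(hits_ba)
  }
  empty <- data.frame(gene_a = character(0), gene_b = character(0),
                      identity_ab = numeric(0), identity_ba = numeric(0),
                      coverage_a = numeric(0), coverage_b = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(ab) == 0 || nrow(ba) == 0) return(empty)
  ba_top <- ba$subject_id[match(ab$subject_id, ba$query_id)]
  rows <- list()
  for (i in seq_len(nrow(ab))) {
    if (is.na(ba_top[i]) || ba_top[i] != ab$query_id[i]) next
    j <- match(ab$subject_id[i], ba$query_id)
    cov_a <- ab$aln_len[i] / ab$query_len[i]
    cov_b <- ba$aln_len[j] / ba$query_len[j]
    if (ab$identity[i] <= min_identity) next
    if (ba$identity[j] <= min_identity) next
    if (cov_a <= min_coverage) next
    if (coverage_mode == "both" && cov_b <= min_coverage) next
    rows[[length(rows) + 1]] <- data.frame(
      gene_a = ab$query_id[i], gene_b = ab$subject_id[i],
      identity_ab = ab$identity[i], identity_ba = ba$identity[j],
      coverage_a = cov_a, coverage_b = cov_b, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of reference genes with an ortholog
#'
#' @param pairs ortholog pair data.frame (see [reciprocal_best_hits()]).
#' @param reference_gene_count number of genes in the reference set.
#' @return percentage: `100 * nrow(pairs) / reference_gene_count`.
#' @export
ortholog_fraction <- function(pairs, reference_gene_count) {
  check_count(reference_gene_count, "reference_gene_count", min = 1)
  100 * nrow(pairs) / reference_gene_count
}
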
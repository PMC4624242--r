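#' Generate two gene sets related by mutated ortholog copies
#'
#' Set A is the reference's gene (CDS) sequences. Set B contains, for a
#' `1 - drop_fraction` subset of genes, a copy mutated by point substitutions
#' at exactly `round((1 - target_identity) * length)` distinct positions, so
#' each retained pair's identity matches `target_identity` to well within
#' +/- 2 percent. `drop_fraction` of the genes receive no counterpart in B
#' (and dropped genes are chosen at random). B ids carry a `_b` suffix.
#'
#' @param ref a `reference_genome` with at least one gene.
#' @param target_identity intended pairwise identity in (0, 1].
#' @param drop_fraction fraction of genes in `[0, 1)` with no counterpart.
#' @param seed integer seed.
#' @return list with `set_a`, `set_b` (named character vectors) and `truth`
#'   (data.frame `gene_a`, `gene_b` of true ortholog pairs).
#' @export
generate_ortholog_sets <- function(ref, target_identity = 0.95,
                                   drop_fraction = 0, seed = 1) {
  validate_reference(ref)
  if (nrow(ref$genes) == 0) stop("reference has no genes")
  check_fraction(target_identity, "target_identity")
  if (target_identity <= 0) stop("'target_identity' must be in (0, 1]")
  check_fraction(drop_fraction, "drop_fraction")
  if (drop_fraction >= 1) stop("'drop_fraction' must be below 1")
  check_count(seed, "seed")
  set.seed(seed)

  g <- ref$genes
  set_a <- vapply(seq_len(nrow(g)), function(i) {
    cds <- substr(ref$sequence, g$start[i] + 1L, g$end[i])
    if (g$strand[i] == "-") revcomp(cds) else cds
  }, "")
  names(set_a) <- g$gene_id

  n <- length(set_a)
  n_drop <- round(drop_fraction * n)
  keep <- sort(sample.int(n, n - n_drop))
  mutate <- function(s) {
    len <- nchar(s)
    n_mut <- round((1 - target_identity) * len)
    if (n_mut == 0) return(s)
    pos <- sample.int(len, n_mut)
    ch <- strsplit(s, "")[[1]]
    ch[pos] <- vapply(ch[pos], function(b)
      sample(setdiff(BASES, b), 1), "")
    paste(ch, collapse = "")
  }
  set_b <- vapply(set_a[keep], mutate, "")
  names(set_b) <- paste0(names(set_a)[keep], "_b")
  list(set_a = set_a, set_b = set_b,
       truth = data.frame(gene_a = names(set_a)[keep],
                          gene_b = names(set_b),
                          stringsAsFactors = FALSE))
}

#' Write a named set of sequences as FASTA, or read one back
#'
#' @param seqs named character vector of sequences.
#' @param path FASTA file path.
#' @return `read_gene_set` returns a named character vector.
#' @export
write_gene_set <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_gene_set
#' @export
read_gene_set <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
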
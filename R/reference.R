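#' Generate a synthetic haploid reference genome with gene models
#'
#' Builds a single-replicon DNA sequence containing `n_genes` non-overlapping
#' protein-coding genes separated by intergenic spacers. Every gene starts
#' with ATG, contains no in-frame stop codon except its terminal stop, and
#' has a CDS length that is a multiple of 3. All genes are emitted on the
#' forward strand; the classifier supports both strands.
#'
#' Coordinates are 0-based half-open internally (`start` inclusive, `end`
#' exclusive), the convention used throughout the package; VCF output is
#' 1-based as the format requires.
#'
#' @param n_genes number of genes (may be 0).
#' @param gene_len length 2 vector: min and max CDS length in bp; both must
#'   be positive multiples of 3 (the terminal stop codon is included).
#' @param intergap_len length 2 vector: min and max intergenic spacer length
#'   in bp (minimum 1 so intergenic positions always exist).
#' @param gc target GC fraction in `[0, 1]` for sampled bases.
#' @param seed integer seed; identical seeds give byte-identical genomes.
#' @param name label used as the FASTA record / VCF CHROM name.
#' @return An object of class `reference_genome`: a list with `name`,
#'   `sequence` (single character string) and `genes` (data.frame with
#'   `gene_id`, `start`, `end`, `strand`).
#' @examples
#' ref <- generate_reference(n_genes = 5, seed = 1)
#' ref
#' @export
generate_reference <- function(n_genes, gene_len = c(300, 600),
                               intergap_len = c(50, 150), gc = 0.45,
                               seed = 1, name = "synthetic_ref") {
  check_count(n_genes, "n_genes")
  check_range(gene_len, "gene_len")
  check_range(intergap_len, "intergap_len")
  if (any(gene_len %% 3 != 0) || gene_len[1] < 9)
    stop("'gene_len' bounds must be multiples of 3 and at least 9")
  if (intergap_len[1] < 1) stop("'intergap_len' minimum must be >= 1")
  check_fraction(gc, "gc")
  check_count(seed, "seed")

  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sample_bases <- function(n) {
    if (n == 0) return(character(0))
    sample(BASES, n, replace = TRUE, prob = p)
  }
  # safe against R's scalar-x sample() surprise when a range collapses
  sample_from <- function(values, n = 1, replace = FALSE)
    values[sample.int(length(values), n, replace = replace)]
  sample_cds <- function(len) {
    n_codon <- len / 3
    # internal codons: resample until none is a stop codon
    internal <- character(0)
    if (n_codon > 2) {
      b <- sample_bases(3 * (n_codon - 2))
      cod <- apply(matrix(b, nrow = 3), 2, paste, collapse = "")
      while (any(bad <- cod %in% STOP_CODONS)) {
        b2 <- sample_bases(3 * sum(bad))
        cod[bad] <- apply(matrix(b2, nrow = 3), 2, paste, collapse = "")
      }
      internal <- cod
    }
    paste0("ATG", paste(internal, collapse = ""),
           sample(STOP_CODONS, 1, prob = c(0.6, 0.2, 0.2)))
  }

  parts <- character(0)
  genes <- vector("list", n_genes)
  cursor <- 0L
  gene_lens <- if (n_genes > 0)
    sample_from(seq(gene_len[1], gene_len[2], by = 3), n_genes,
                replace = TRUE)
  else integer(0)
  for (i in seq_len(n_genes)) {
    gap <- sample_from(seq(intergap_len[1], intergap_len[2]))
    parts <- c(parts, paste(sample_bases(gap), collapse = ""))
    cursor <- cursor + gap
    cds <- sample_cds(gene_lens[i])
    parts <- c(parts, cds)
    genes[[i]] <- data.frame(
      gene_id = sprintf("gene%03d", i),
      start = cursor, end = cursor + nchar(cds), strand = "+",
      stringsAsFactors = FALSE)
    cursor <- cursor + nchar(cds)
  }
  gap <- sample_from(seq(intergap_len[1], intergap_len[2]))
  parts <- c(parts, paste(sample_bases(gap), collapse = ""))

  ref <- structure(list(
    name = name,
    sequence = paste(parts, collapse = ""),
    genes = if (n_genes > 0) do.call(rbind, genes) else
      data.frame(gene_id = character(0), start = integer(0),
                 end = integer(0), strand = character(0),
                 stringsAsFactors = FALSE)),
    class = "reference_genome")
  validate_reference(ref)
  ref
}

validate_reference <- function(ref) {
  stopifnot(inherits(ref, "reference_genome"))
  g <- ref$genes
  len <- nchar(ref$sequence)
  if (nrow(g) > 0) {
    if (any(g$start < 0 | g$end > len | g$start >= g$end))
      stop("gene interval outside genome bounds")
    if (any((g$end - g$start) %% 3 != 0))
      stop("gene CDS length not a multiple of 3")
    o <- order(g$start)
    if (any(g$start[o][-1] < g$end[o][-nrow(g)]))
      stop("overlapping gene models are not supported")
  }
  invisible(ref)
}

#' @export
print.reference_genome <- function(x, ...) {
  cat("Reference genome '", x$name, "': ", nchar(x$sequence), " bp, ",
      nrow(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Write / read a reference genome as FASTA plus a gene coordinate table
#'
#' The gene table is tab-separated with columns `gene_id`, `start`, `end`,
#' `strand`, using 0-based half-open coordinates.
#'
#' @param ref a `reference_genome`.
#' @param fasta,gene_table output (or input) file paths.
#' @return `write_reference` returns the paths invisibly; `read_reference`
#'   returns a `reference_genome`.
#' @export
write_reference <- function(ref, fasta, gene_table) {
  validate_reference(ref)
  seqs <- Biostrings::DNAStringSet(ref$sequence)
  names(seqs) <- ref$name
  Biostrings::writeXStringSet(seqs, fasta)
  write.table(ref$genes, gene_table, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fasta = fasta, gene_table = gene_table))
}

#' @rdname write_reference
#' @export
read_reference <- function(fasta, gene_table) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) != 1)
    stop("expected a single-replicon reference FASTA, got ", length(seqs),
         " records")
  genes <- read.table(gene_table, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  need <- c("gene_id", "start", "end", "strand")
  if (!all(need %in% names(genes)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  ref <- structure(list(name = names(seqs)[1],
                        sequence = as.character(seqs[[1]]),
                        genes = genes[, need]),
                   class = "reference_genome")
  validate_reference(ref)
  ref
}

# gene containing 0-based position p0 (leftmost-base rule), or NA
gene_at <- function(ref, pos) {
  p0 <- pos - 1L
  g <- ref$genes
  hit <- which(g$start <= p0 & p0 < g$end)
  if (length(hit) == 0) NA_integer_ else hit[1]
}
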
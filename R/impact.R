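#' Filter variant records by depth and quality thresholds
#'
#' Retains records satisfying `dp >= dp_min`, `qual >= qual_min` and
#' `qd >= qd_min` simultaneously — the logical complement of the GATK-style
#' exclusion expressions `"DP < 10 || QUAL < 100.0"` and `"QD < 5.0"`.
#' Because the exclusions are strict inequalities, records sitting exactly
#' on a threshold are retained. Records with a missing `dp`, `qual` or `qd`
#' fail the filter and are dropped with a warning. Input order is preserved.
#'
#' @param records data.frame of variant records with numeric columns `dp`,
#'   `qual`, `qd` (e.g. from [read_vcf()]).
#' @param dp_min minimum read depth (default 10).
#' @param qual_min minimum phred-scaled site quality (default 100).
#' @param qd_min minimum quality-by-depth ratio (default 5).
#' @return the retained rows of `records`, order preserved.
#' @export
filter_variants <- function(records, dp_min = 10, qual_min = 100,
                            qd_min = 5) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) return(records)
  for (nm in c("dp", "qual", "qd"))
    if (!nm %in% names(records))
      stop("records must have a '", nm, "' column")
  if (!all(is.finite(c(dp_min, qual_min, qd_min))))
    stop("filter thresholds must be finite")
  miss <- is.na(records$dp) | is.na(records$qual) | is.na(records$qd)
  if (any(miss))
    warning(sum(miss), " record(s) with missing DP/QUAL/QD treated as ",
            "failing the filter")
  keep <- !miss & records$dp >= dp_min & records$qual >= qual_min &
    records$qd >= qd_min
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify the predicted impact of a single variant
#'
#' Assigns one of four impact levels following SnpEff-style semantics:
#' \describe{
#'   \item{high}{disruptive: frameshift indel, stop gained, start lost;}
#'   \item{moderate}{possibly effect-changing: missense SNP, in-frame indel;}
#'   \item{low}{mostly harmless: synonymous SNP;}
#'   \item{modifier}{outside all gene models (intergenic).}
#' }
#' A variant is assigned to the gene containing its leftmost reference base
#' (0-based containment); an indel whose deleted span extends past the CDS
#' end is a frameshift when the in-CDS deleted length is not a multiple of
#' 3. Genes on the minus strand are classified on the reverse complement of
#' their CDS. A SNP changing the terminal stop codon to a different stop is
#' synonymous; to a sense codon, it is treated as an amino-acid change
#' (missense).
#'
#' @param ref a `reference_genome`.
#' @param pos 1-based position of the variant's first reference base.
#' @param ref_allele,alt_allele reference and alternate allele strings.
#' @return a list with `gene_id` (NA for intergenic), `impact` and
#'   `consequence`.
#' @examples
#' ref <- generate_reference(n_genes = 3, seed = 1)
#' g <- ref$genes[1, ]
#' classify_impact(ref, g$start + 4, substr(ref$sequence, g$start + 4,
#'                 g$start + 5), substr(ref$sequence, g$start + 4,
#'                 g$start + 4))  # 1-bp CDS deletion -> frameshift
#' @export
classify_impact <- function(ref, pos, ref_allele, alt_allele) {
  validate_reference(ref)
  check_count(pos, "pos", min = 1)
  ref_allele <- toupper(ref_allele)
  alt_allele <- toupper(alt_allele)
  if (identical(ref_allele, alt_allele))
    stop("ref_allele and alt_allele must differ")
  lr <- nchar(ref_allele)
  if (pos + lr - 1L > nchar(ref$sequence))
    stop("variant at position ", pos, " extends past the genome end")
  genome_ref <- substr(ref$sequence, pos, pos + lr - 1L)
  if (genome_ref != ref_allele)
    stop("reference allele mismatch at position ", pos, ": VCF says '",
         ref_allele, "' but genome has '", genome_ref, "'")

  gi <- gene_at(ref, pos)
  if (is.na(gi))
    return(list(gene_id = NA_character_, impact = "modifier",
                consequence = "intergenic"))
  g <- ref$genes[gi, ]
  la <- nchar(alt_allele)

  if (lr != la) {                          # indel
    if (lr > la) {                         # deletion: anchored, shared prefix
      del_from <- pos + la                 # first deleted base (1-based)
      del_to <- pos + lr - 1L
      in_cds <- max(0L, min(del_to, g$end) - max(del_from, g$start + 1L) + 1L)
      if (in_cds %% 3 != 0)
        return(list(gene_id = g$gene_id, impact = "high",
                    consequence = "frameshift"))
      return(list(gene_id = g$gene_id, impact = "moderate",
                  consequence = "inframe_indel"))
    }
    ins_len <- la - lr                     # insertion
    if (ins_len %% 3 != 0)
      return(list(gene_id = g$gene_id, impact = "high",
                  consequence = "frameshift"))
    return(list(gene_id = g$gene_id, impact = "moderate",
                consequence = "inframe_indel"))
  }

  if (lr == 1L) {                          # SNP
    cds_len <- g$end - g$start
    n_codon <- cds_len / 3
    if (g$strand == "+") {
      off <- (pos - 1L) - g$start          # 0-based offset within CDS
      cpos <- g$start + 1L + 3L * (off %/% 3)
      codon <- substr(ref$sequence, cpos, cpos + 2L)
      within <- off %% 3 + 1L
      mut <- codon
      substr(mut, within, within) <- alt_allele
    } else {
      cds <- revcomp(substr(ref$sequence, g$start + 1L, g$end))
      off <- g$end - pos                   # 0-based offset on coding strand
      ci0 <- off %/% 3
      codon <- substr(cds, 3L * ci0 + 1L, 3L * ci0 + 3L)
      within <- off %% 3 + 1L
      mut <- codon
      substr(mut, within, within) <- complement(alt_allele)
    }
    codon_idx <- off %/% 3                 # 0-based codon index
    if (codon_idx == 0)
      return(list(gene_id = g$gene_id, impact = "high",
                  consequence = "start_lost"))
    aa0 <- translate_codon(codon)
    aa1 <- translate_codon(mut)
    if (aa1 == "*" && codon_idx < n_codon - 1)
      return(list(gene_id = g$gene_id, impact = "high",
                  consequence = "stop_gained"))
    if (aa0 == aa1)
      return(list(gene_id = g$gene_id, impact = "low",
                  consequence = "synonymous"))
    return(list(gene_id = g$gene_id, impact = "moderate",
                consequence = "missense"))
  }

  # equal-length multi-base substitution: mutate the CDS and compare
  # translations (strand-aware); stop gain takes precedence over missense
  cds0 <- substr(ref$sequence, g$start + 1L, g$end)
  mutated <- ref$sequence
  substr(mutated, pos, pos + lr - 1L) <- alt_allele
  cds1 <- substr(mutated, g$start + 1L, g$end)
  if (g$strand == "-") { cds0 <- revcomp(cds0); cds1 <- revcomp(cds1) }
  p0 <- strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(cds0), no.init.codon = TRUE)), "")[[1]]
  p1 <- strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(cds1), no.init.codon = TRUE)), "")[[1]]
  n_codon <- length(p0)
  if (p1[1] != p0[1])
    return(list(gene_id = g$gene_id, impact = "high",
                consequence = "start_lost"))
  gained <- which(p1 == "*" & p0 != "*")
  if (any(gained < n_codon))
    return(list(gene_id = g$gene_id, impact = "high",
                consequence = "stop_gained"))
  if (any(p0 != p1))
    return(list(gene_id = g$gene_id, impact = "moderate",
                consequence = "missense"))
  list(gene_id = g$gene_id, impact = "low", consequence = "synonymous")
}

#' Annotate a table of variant records with gene and impact
#'
#' Vectorized [classify_impact()] with gene assignment by interval lookup.
#' Output has one row per input record, in position-sorted order.
#'
#' @param records data.frame with columns `strain`, `pos`, `ref`, `alt`
#'   (quality columns are carried through if present).
#' @param ref a `reference_genome`.
#' @return the input data.frame with `gene_id`, `impact` and `consequence`
#'   columns appended.
#' @export
annotate_variants <- function(records, ref) {
  stopifnot(is.data.frame(records))
  validate_reference(ref)
  if (nrow(records) == 0) {
    records$gene_id <- character(0)
    records$impact <- character(0)
    records$consequence <- character(0)
    return(records)
  }
  records <- records[order(records$pos), , drop = FALSE]
  ann <- lapply(seq_len(nrow(records)), function(i)
    classify_impact(ref, records$pos[i], records$ref[i], records$alt[i]))
  records$gene_id <- vapply(ann, `[[`, "", "gene_id")
  records$impact <- vapply(ann, `[[`, "", "impact")
  records$consequence <- vapply(ann, `[[`, "", "consequence")
  rownames(records) <- NULL
  records
}

#' Write an annotated variant table as TSV
#'
#' Columns: strain, pos, ref, alt, gene_id, impact, consequence.
#'
#' @param annotated output of [annotate_variants()] (rows from several
#'   strains may be combined with `rbind`).
#' @param path file path.
#' @export
write_annotated <- function(annotated, path) {
  cols <- c("strain", "pos", "ref", "alt", "gene_id", "impact",
            "consequence")
  write.table(annotated[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotated
#' @export
read_annotated <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             na.strings = "NA")
}
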
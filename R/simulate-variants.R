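#' Plant variants of known impact class in a synthetic strain
#'
#' Generates a haploid variant set for one strain derived from a reference
#' genome, with exact requested counts per impact class. Each planted variant
#' is unambiguous for its class under the classifier's rules:
#' \describe{
#'   \item{high}{a 1-bp CDS deletion (frameshift) or a SNP creating a stop
#'     codon mid-CDS (stop gained), chosen at random per variant;}
#'   \item{moderate}{a nonsynonymous SNP (missense) or a 3-bp in-frame CDS
#'     deletion, chosen at random;}
#'   \item{low}{a synonymous SNP at a codon third position;}
#'   \item{modifier}{an intergenic SNP.}
#' }
#' Positions are unique within the strain (indel spans, including the VCF
#' anchor base, are reserved). Quality fields default to values above the
#' standard retention thresholds (DP >= 10, QUAL >= 100, QD >= 5).
#'
#' @param ref a `reference_genome`.
#' @param n_high,n_mod,n_low,n_modifier non-negative variant counts to plant.
#' @param seed integer seed; identical seeds give identical variant sets.
#' @param strain strain label.
#' @param dp,qual,qd quality fields written to every emitted record.
#' @return An object of class `strain_variants`: a list with `strain`,
#'   `records` (data.frame of variant records: `strain`, `pos`, `ref`,
#'   `alt`, `qual`, `dp`, `qd`, sorted by position) and `truth` (the same
#'   rows plus planted `gene_id`, `impact`, `consequence`).
#' @export
generate_strain_variants <- function(ref, n_high = 0, n_mod = 0, n_low = 0,
                                     n_modifier = 0, seed = 1,
                                     strain = "strain1",
                                     dp = 50, qual = 500, qd = 20) {
  validate_reference(ref)
  for (nm in c("n_high", "n_mod", "n_low", "n_modifier"))
    check_count(get(nm), nm)
  check_count(seed, "seed")
  n_cds <- sum(ref$genes$end - ref$genes$start)
  if ((n_high + n_mod + n_low > 0) && nrow(ref$genes) == 0)
    stop("capacity error: reference has no genes to host coding variants")
  # rough capacity guard; the retry loop below raises the definitive error
  if (4 * (n_high + n_mod + n_low) > n_cds)
    stop("capacity error: too many coding variants requested for ",
         n_cds, " bp of CDS")
  set.seed(seed)

  len <- nchar(ref$sequence)
  used <- logical(len)                     # 1-based occupancy incl. anchors
  base_at <- function(pos) substr(ref$sequence, pos, pos)
  ct <- codon_table()

  reserve <- function(pos, span = 1L) {
    idx <- pos:(pos + span - 1L)
    if (any(used[idx])) return(FALSE)
    used[idx] <<- TRUE
    TRUE
  }

  # pick a gene and a codon index (1-based, excluding start and stop codons)
  pick_codon <- function() {
    gi <- sample.int(nrow(ref$genes), 1)
    g <- ref$genes[gi, ]
    n_codon <- (g$end - g$start) / 3
    cand <- 2:(n_codon - 1)
    ci <- cand[sample.int(length(cand), 1)]
    cds_start1 <- g$start + 1L            # 1-based CDS start
    cpos <- cds_start1 + 3L * (ci - 1L)   # 1-based first base of codon
    list(gene = g, codon_idx = ci, codon_pos = cpos,
         codon = substr(ref$sequence, cpos, cpos + 2L))
  }

  snp_in_codon <- function(accept) {
    # accept(orig_codon, mut_codon, within) -> TRUE if class is achieved
    for (try in 1:200) {
      pc <- pick_codon()
      opts <- list()
      for (w in 1:3) {
        refb <- substr(pc$codon, w, w)
        for (alt in setdiff(BASES, refb)) {
          mut <- pc$codon
          substr(mut, w, w) <- alt
          if (accept(pc$codon, mut, w))
            opts[[length(opts) + 1]] <- list(w = w, alt = alt)
        }
      }
      if (length(opts) == 0) next
      o <- opts[[sample.int(length(opts), 1)]]
      pos <- pc$codon_pos + o$w - 1L
      if (!reserve(pos)) next
      return(list(pos = pos, ref = base_at(pos), alt = o$alt,
                  gene_id = pc$gene$gene_id))
    }
    stop("capacity error: could not place a SNP without collision")
  }

  make_high <- function() {
    if (runif(1) < 0.5) {
      # 1-bp deletion mid-CDS; VCF anchor is the previous base (also in CDS)
      for (try in 1:200) {
        pc <- pick_codon()
        w <- sample(1:3, 1)
        pos <- pc$codon_pos + w - 1L       # base to delete
        anchor <- pos - 1L
        if (anchor <= pc$gene$start) next  # anchor must sit inside the CDS
        if (!reserve(anchor, 2L)) next
        return(data.frame(pos = anchor,
                          ref = substr(ref$sequence, anchor, pos),
                          alt = base_at(anchor),
                          gene_id = pc$gene$gene_id, impact = "high",
                          consequence = "frameshift",
                          stringsAsFactors = FALSE))
      }
      stop("capacity error: could not place a frameshift deletion")
    }
    s <- snp_in_codon(function(orig, mut, w) mut %in% STOP_CODONS)
    data.frame(pos = s$pos, ref = s$ref, alt = s$alt, gene_id = s$gene_id,
               impact = "high", consequence = "stop_gained",
               stringsAsFactors = FALSE)
  }

  make_mod <- function() {
    if (runif(1) < 0.3) {
      # whole-codon (3-bp) in-frame deletion, anchored one base upstream
      for (try in 1:200) {
        pc <- pick_codon()
        if (pc$codon_idx < 3) next         # keep clear of the start codon
        anchor <- pc$codon_pos - 1L
        if (!reserve(anchor, 4L)) next
        return(data.frame(pos = anchor,
                          ref = substr(ref$sequence, anchor, anchor + 3L),
                          alt = base_at(anchor),
                          gene_id = pc$gene$gene_id, impact = "moderate",
                          consequence = "inframe_indel",
                          stringsAsFactors = FALSE))
      }
      stop("capacity error: could not place an in-frame deletion")
    }
    s <- snp_in_codon(function(orig, mut, w)
      !(mut %in% STOP_CODONS) && ct[mut] != ct[orig])
    data.frame(pos = s$pos, ref = s$ref, alt = s$alt, gene_id = s$gene_id,
               impact = "moderate", consequence = "missense",
               stringsAsFactors = FALSE)
  }

  make_low <- function() {
    s <- snp_in_codon(function(orig, mut, w)
      w == 3 && ct[mut] == ct[orig])
    data.frame(pos = s$pos, ref = s$ref, alt = s$alt, gene_id = s$gene_id,
               impact = "low", consequence = "synonymous",
               stringsAsFactors = FALSE)
  }

  intergenic <- rep(TRUE, len)
  for (i in seq_len(nrow(ref$genes)))
    intergenic[(ref$genes$start[i] + 1L):ref$genes$end[i]] <- FALSE
  make_modifier <- function() {
    cand <- which(intergenic & !used)
    if (length(cand) == 0)
      stop("capacity error: no intergenic positions left")
    pos <- cand[sample.int(length(cand), 1)]
    used[pos] <<- TRUE
    refb <- base_at(pos)
    data.frame(pos = pos, ref = refb, alt = sample(setdiff(BASES, refb), 1),
               gene_id = NA_character_, impact = "modifier",
               consequence = "intergenic", stringsAsFactors = FALSE)
  }

  rows <- c(lapply(seq_len(n_high), function(i) make_high()),
            lapply(seq_len(n_mod), function(i) make_mod()),
            lapply(seq_len(n_low), function(i) make_low()),
            lapply(seq_len(n_modifier), function(i) make_modifier()))
  truth <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(pos = integer(0), ref = character(0), alt = character(0),
               gene_id = character(0), impact = character(0),
               consequence = character(0), stringsAsFactors = FALSE)
  truth <- truth[order(truth$pos), , drop = FALSE]
  rownames(truth) <- NULL
  truth <- cbind(strain = rep(strain, nrow(truth)), truth,
                 stringsAsFactors = FALSE)

  records <- data.frame(strain = truth$strain, pos = truth$pos,
                        ref = truth$ref, alt = truth$alt,
                        qual = rep(qual, nrow(truth)),
                        dp = rep(dp, nrow(truth)),
                        qd = rep(qd, nrow(truth)),
                        stringsAsFactors = FALSE)
  structure(list(strain = strain, records = records, truth = truth),
            class = "strain_variants")
}

#' @export
print.strain_variants <- function(x, ...) {
  cat("Strain '", x$strain, "': ", nrow(x$records), " planted variants (",
      paste(sprintf("%s=%d", names(table(x$truth$impact)),
                    as.integer(table(x$truth$impact))), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Write variant records as VCF v4.2, or read one back
#'
#' Writes a minimal haploid VCF: QUAL column set per record, `DP` and `QD`
#' in INFO, genotype column `GT = 1`. `read_vcf` parses any VCF v4.2 file,
#' splits multi-allelic records into bi-allelic ones, and extracts `DP` and
#' `QD` from INFO (missing fields become `NA`).
#'
#' @param x a `strain_variants` object or a records data.frame with columns
#'   `strain`, `pos`, `ref`, `alt`, `qual`, `dp`, `qd`.
#' @param path file path.
#' @param chrom CHROM value to write.
#' @return `read_vcf` returns a records data.frame as above.
#' @export
write_vcf <- function(x, path, chrom = "synthetic_ref") {
  rec <- if (inherits(x, "strain_variants")) x$records else x
  strain <- if (nrow(rec) > 0) rec$strain[1] else "sample"
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", chrom),
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  strain))
  body <- if (nrow(rec) > 0)
    sprintf("%s\t%d\t.\t%s\t%s\t%.1f\t.\tDP=%d;QD=%.2f\tGT\t1",
            chrom, rec$pos, rec$ref, rec$alt, rec$qual,
            as.integer(rec$dp), rec$qd)
  else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_vcf
#' @param strain strain label to assign to the parsed records; defaults to
#'   the VCF's first sample column name (or "sample").
#' @export
read_vcf <- function(path, strain = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- v@fix
  if (is.null(strain)) {
    samples <- colnames(v@gt)
    strain <- if (!is.null(samples) && length(samples) > 1)
      samples[2] else "sample"
  }
  if (nrow(fx) == 0)
    return(data.frame(strain = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      qual = numeric(0), dp = numeric(0), qd = numeric(0),
                      stringsAsFactors = FALSE))
  dp <- suppressWarnings(as.numeric(vcfR::extract.info(v, "DP")))
  qd <- suppressWarnings(as.numeric(vcfR::extract.info(v, "QD")))
  out <- data.frame(strain = strain,
                    pos = as.integer(fx[, "POS"]),
                    ref = fx[, "REF"], alt = fx[, "ALT"],
                    qual = suppressWarnings(as.numeric(fx[, "QUAL"])),
                    dp = dp, qd = qd, stringsAsFactors = FALSE)
  # split multi-allelic records into bi-allelic ones
  multi <- grepl(",", out$alt, fixed = TRUE)
  if (any(multi)) {
    split_rows <- lapply(which(multi), function(i) {
      alts <- strsplit(out$alt[i], ",", fixed = TRUE)[[1]]
      r <- out[rep(i, length(alts)), , drop = FALSE]
      r$alt <- alts
      r
    })
    out <- rbind(out[!multi, , drop = FALSE], do.call(rbind, split_rows))
    out <- out[order(out$pos), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
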
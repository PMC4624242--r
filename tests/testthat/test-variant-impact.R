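# a tiny hand-built genome: 12 bp spacer, one 18-bp gene, 12 bp spacer.
# CDS codons: ATG GGA TAT CAT AAA TAA  ->  M G Y H K *
toy_genome <- function(strand = "+") {
  cds <- "ATGGGATATCATAAATAA"
  if (strand == "-") cds <- strainprofiler:::revcomp(cds)
  structure(list(
    name = "toy",
    sequence = paste0("TTTTTTTTTTTT", cds, "CCCCCCCCCCCC"),
    genes = data.frame(gene_id = "g1", start = 12L, end = 30L,
                       strand = strand, stringsAsFactors = FALSE)),
    class = "reference_genome")
}

test_that("filter retains exactly the records meeting all three thresholds", {
  rec <- data.frame(strain = "s", pos = 1:4, ref = "A", alt = "C",
                    qual = c(200, 200, 100, 99.9),
                    dp = c(9, 10, 10, 50),
                    qd = c(10, 5, 5, 10), stringsAsFactors = FALSE)
  out <- filter_variants(rec)
  # dp = 9 removed; boundary values dp = 10, qual = 100, qd = 5 retained;
  # qual = 99.9 removed
  expect_equal(out$pos, c(2, 3))

  expect_equal(nrow(filter_variants(rec[0, ])), 0)

  # idempotent
  expect_identical(filter_variants(out), out)

  # missing fields fail the filter, with a warning
  rec$dp[2] <- NA
  expect_warning(out2 <- filter_variants(rec), "missing")
  expect_equal(out2$pos, 3)
})

test_that("SNP classification matches codon semantics on both strands", {
  for (strand in c("+", "-")) {
    ref <- toy_genome(strand)
    # 1-based genome position of CDS offset (0-based), strand aware
    gpos <- function(off) if (strand == "+") 13L + off else 30L - off
    # base to write in VCF so the coding-strand base becomes 'b'
    vbase <- function(b) if (strand == "+") b else
      strainprofiler:::complement(b)

    # codon 2 GGA -> GGG: synonymous (Gly), third position
    r <- classify_impact(ref, gpos(5), vbase("A"), vbase("G"))
    expect_equal(r[c("impact", "consequence")],
                 list(impact = "low", consequence = "synonymous"))
    # codon 3 TAT -> TAA: stop gained mid-CDS
    r <- classify_impact(ref, gpos(8), vbase("T"), vbase("A"))
    expect_equal(r$impact, "high")
    expect_equal(r$consequence, "stop_gained")
    # oracle: translate the mutated CDS with Biostrings and find the stop
    cds <- "ATGGGATATCATAAATAA"
    mut <- cds; substr(mut, 9, 9) <- "A"
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(mut)))
    expect_equal(substr(aa, 3, 3), "*")
    # codon 4 CAT -> GAT: missense (His -> Asp)
    r <- classify_impact(ref, gpos(9), vbase("C"), vbase("G"))
    expect_equal(r$impact, "moderate")
    expect_equal(r$consequence, "missense")
    # codon 1: any SNP destroys the initiator ATG
    r <- classify_impact(ref, gpos(1), vbase("T"), vbase("C"))
    expect_equal(r$impact, "high")
    expect_equal(r$consequence, "start_lost")
    # terminal stop TAA -> TAG stays a stop: synonymous
    r <- classify_impact(ref, gpos(17), vbase("A"), vbase("G"))
    expect_equal(r$impact, "low")
    expect_equal(r$consequence, "synonymous")
    # intergenic SNP
    pos <- if (strand == "+") 3L else 3L
    r <- classify_impact(ref, pos, "T", "G")
    expect_equal(r$impact, "modifier")
    expect_true(is.na(r$gene_id))
  }
})

test_that("indel classification follows frame arithmetic", {
  ref <- toy_genome("+")
  # 1-bp deletion inside codon 2 (anchor at CDS base 4): frameshift
  r <- classify_impact(ref, 16L, substr(ref$sequence, 16, 17),
                       substr(ref$sequence, 16, 16))
  expect_equal(r$impact, "high")
  expect_equal(r$consequence, "frameshift")
  # 3-bp deletion of codon 3 (anchor at last base of codon 2): in-frame
  r <- classify_impact(ref, 18L, substr(ref$sequence, 18, 21),
                       substr(ref$sequence, 18, 18))
  expect_equal(r$impact, "moderate")
  expect_equal(r$consequence, "inframe_indel")
  # 2-bp insertion: frameshift
  r <- classify_impact(ref, 16L, substr(ref$sequence, 16, 16),
                       paste0(substr(ref$sequence, 16, 16), "AC"))
  expect_equal(r$consequence, "frameshift")
  # 3-bp insertion: in-frame
  r <- classify_impact(ref, 16L, substr(ref$sequence, 16, 16),
                       paste0(substr(ref$sequence, 16, 16), "ACG"))
  expect_equal(r$consequence, "inframe_indel")
  # deletion running past the CDS end: in-CDS deleted length decides;
  # here 14 CDS bases (from base 5) + 3 intergenic bases -> frameshift
  r <- classify_impact(ref, 16L, substr(ref$sequence, 16, 33),
                       substr(ref$sequence, 16, 16))
  expect_equal(r$consequence, "frameshift")
})

test_that("classification validates its inputs", {
  ref <- toy_genome("+")
  expect_error(classify_impact(ref, 13L, "C", "G"), "mismatch.*13")
  expect_error(classify_impact(ref, 5L, "T", "T"), "differ")
})

test_that("annotate_variants is total and consistent with interval lookup", {
  ref <- generate_reference(10, seed = 31)
  # all intergenic -> all modifier with no gene id
  gaps <- setdiff(seq_len(nchar(ref$sequence)),
                  unlist(mapply(function(s, e) (s + 1):e, ref$genes$start,
                                ref$genes$end, SIMPLIFY = FALSE)))
  pos <- gaps[seq(1, length(gaps), length.out = 5)]
  rec <- data.frame(strain = "s", pos = pos,
                    ref = substring(ref$sequence, pos, pos),
                    alt = "N", stringsAsFactors = FALSE)
  rec$alt <- vapply(rec$ref, function(b) setdiff(c("A", "C", "G", "T"),
                                                 b)[1], "")
  ann <- annotate_variants(rec, ref)
  expect_true(all(ann$impact == "modifier"))
  expect_true(all(is.na(ann$gene_id)))

  # one variant per class -> exactly one of each impact
  sv <- generate_strain_variants(ref, 1, 1, 1, 1, seed = 8)
  ann <- annotate_variants(sv$records, ref)
  expect_equal(sort(ann$impact),
               sort(c("high", "moderate", "low", "modifier")))
  expect_equal(nrow(ann), nrow(sv$records))
})

test_that("annotated tables round-trip through the TSV writer", {
  ref <- generate_reference(6, seed = 17)
  sv <- generate_strain_variants(ref, 2, 2, 2, 2, seed = 18)
  ann <- annotate_variants(sv$records, ref)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotated(ann, path)
  back <- read_annotated(path)
  expect_equal(back$pos, ann$pos)
  expect_equal(back$impact, ann$impact)
  expect_equal(back$gene_id, ann$gene_id)
})
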
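test_that("reference generator produces valid, deterministic gene models", {
  ref1 <- generate_reference(n_genes = 10, gene_len = c(300, 600), seed = 1)
  ref2 <- generate_reference(n_genes = 10, gene_len = c(300, 600), seed = 1)
  expect_identical(ref1$sequence, ref2$sequence)
  expect_identical(ref1$genes, ref2$genes)
  expect_equal(nrow(ref1$genes), 10)

  g <- ref1$genes
  expect_true(all((g$end - g$start) %% 3 == 0))
  # brute-force interval scan: no position belongs to two genes
  cover <- integer(nchar(ref1$sequence))
  for (i in seq_len(nrow(g)))
    cover[(g$start[i] + 1):g$end[i]] <- cover[(g$start[i] + 1):g$end[i]] + 1
  expect_true(all(cover <= 1))

  for (i in seq_len(nrow(g))) {
    cds <- substr(ref1$sequence, g$start[i] + 1, g$end[i])
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    expect_identical(codons[1], "ATG")
    expect_true(codons[length(codons)] %in% c("TAA", "TAG", "TGA"))
    expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("reference generator handles the empty case and bad parameters", {
  ref <- generate_reference(n_genes = 0, seed = 3)
  expect_equal(nrow(ref$genes), 0)
  expect_gt(nchar(ref$sequence), 0)
  expect_error(generate_reference(5, gene_len = c(100, 200)), "multiples")
  expect_error(generate_reference(5, gc = 1.5), "gc")
  expect_error(generate_reference(5, gene_len = c(600, 300)), "range")
})

test_that("reference FASTA and gene table are byte-identical across runs", {
  d <- withr::local_tempdir()
  f1 <- file.path(d, "a.fasta"); t1 <- file.path(d, "a.tsv")
  f2 <- file.path(d, "b.fasta"); t2 <- file.path(d, "b.tsv")
  write_reference(generate_reference(10, seed = 42), f1, t1)
  write_reference(generate_reference(10, seed = 42), f2, t2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(t1), readLines(t2))
  rt <- read_reference(f1, t1)
  expect_identical(rt$sequence, generate_reference(10, seed = 42)$sequence)
})

test_that("variant generator plants exactly the requested class counts", {
  ref <- generate_reference(12, seed = 5)
  sv <- generate_strain_variants(ref, n_high = 2, n_mod = 3, n_low = 5,
                                 n_modifier = 1, seed = 7)
  tab <- table(sv$truth$impact)
  expect_equal(as.integer(tab[c("high", "moderate", "low", "modifier")]),
               c(2, 3, 5, 1))
  expect_false(anyDuplicated(sv$truth$pos) > 0)

  empty <- generate_strain_variants(ref, 0, 0, 0, 0, seed = 1)
  expect_equal(nrow(empty$records), 0)

  a <- generate_strain_variants(ref, 3, 3, 3, 3, seed = 11)
  b <- generate_strain_variants(ref, 3, 3, 3, 3, seed = 11)
  expect_identical(a$records, b$records)
})

test_that("classifier recovers every planted label (round trip)", {
  ref <- generate_reference(15, seed = 2)
  sv <- generate_strain_variants(ref, 10, 10, 10, 5, seed = 3)
  ann <- annotate_variants(sv$records, ref)
  expect_identical(ann$impact, sv$truth$impact)
  expect_identical(ann$consequence, sv$truth$consequence)
  expect_identical(ann$gene_id, sv$truth$gene_id)
})

test_that("emitted VCF is deterministic and round-trips through a parser", {
  ref <- generate_reference(8, seed = 9)
  sv <- generate_strain_variants(ref, 2, 2, 2, 2, seed = 13, strain = "sX")
  d <- withr::local_tempdir()
  v1 <- file.path(d, "a.vcf"); v2 <- file.path(d, "b.vcf")
  write_vcf(sv, v1); write_vcf(sv, v2)
  expect_identical(readLines(v1), readLines(v2))
  rec <- read_vcf(v1)
  expect_equal(rec$pos, sv$records$pos)
  expect_equal(rec$ref, sv$records$ref)
  expect_equal(rec$alt, sv$records$alt)
  expect_equal(rec$dp, sv$records$dp)
  expect_equal(rec$strain, rep("sX", nrow(rec)))
})

test_that("variant generator raises a capacity error on infeasible requests", {
  ref <- generate_reference(2, gene_len = c(30, 30), seed = 1)
  expect_error(generate_strain_variants(ref, 50, 50, 50, 0, seed = 1),
               "capacity")
  ref0 <- generate_reference(0, seed = 1)
  expect_error(generate_strain_variants(ref0, 1, 0, 0, 0, seed = 1),
               "capacity")
})

test_that("ortholog sets hit the identity target and drop count exactly", {
  ref <- generate_reference(50, gene_len = c(300, 600), seed = 21)
  os <- generate_ortholog_sets(ref, target_identity = 0.9,
                               drop_fraction = 0.2, seed = 22)
  expect_equal(nrow(os$truth), 40)
  expect_equal(length(os$set_b), 40)
  # direct Hamming identity on equal-length copies
  idents <- vapply(seq_len(nrow(os$truth)), function(i) {
    a <- strsplit(os$set_a[[os$truth$gene_a[i]]], "")[[1]]
    b <- strsplit(os$set_b[[os$truth$gene_b[i]]], "")[[1]]
    mean(a == b)
  }, 0)
  expect_true(all(idents >= 0.88 & idents <= 0.92))
  expect_gte(mean(idents), 0.88)
  expect_lte(mean(idents), 0.92)

  ident <- generate_ortholog_sets(ref, 1.0, 0, seed = 1)
  expect_identical(unname(ident$set_b), unname(ident$set_a))
  expect_identical(ident$truth$gene_a, names(ident$set_a))
})

test_that("MLST simulation respects branch lengths and transition bias", {
  # zero branch lengths: all strains identical at every locus
  tr0 <- ape::read.tree(text = "((A:0,B:0):0,(C:0,D:0):0);")
  loci0 <- simulate_mlst_loci(tr0, c(l1 = 200L, l2 = 200L), seed = 1)
  for (l in loci0) expect_equal(length(unique(l)), 1L)

  # kappa = 4, long branches: transitions outnumber transversions
  tr <- ape::read.tree(text = "(A:0.15,B:0.15);")
  loci <- simulate_mlst_loci(tr, c(l1 = 20000L), kappa = 4, seed = 2)
  a <- strsplit(loci$l1[["A"]], "")[[1]]
  b <- strsplit(loci$l1[["B"]], "")[[1]]
  diff <- a != b
  ts_pair <- (a %in% c("A", "G") & b %in% c("A", "G")) |
    (a %in% c("C", "T") & b %in% c("C", "T"))
  n_ts <- sum(diff & ts_pair)
  n_tv <- sum(diff & !ts_pair)
  expect_gt(n_ts, n_tv)

  # kappa = 1: transition/transversion counts match the 1:2 neutral ratio
  loci1 <- simulate_mlst_loci(tr, c(l1 = 20000L), kappa = 1, seed = 3)
  a <- strsplit(loci1$l1[["A"]], "")[[1]]
  b <- strsplit(loci1$l1[["B"]], "")[[1]]
  diff <- a != b
  ts_pair <- (a %in% c("A", "G") & b %in% c("A", "G")) |
    (a %in% c("C", "T") & b %in% c("C", "T"))
  counts <- c(sum(diff & ts_pair), sum(diff & !ts_pair))
  p <- stats::chisq.test(counts, p = c(1 / 3, 2 / 3))$p.value
  expect_gt(p, 0.01)
})

test_that("MLST simulation is deterministic and NJ recovers a 4-taxon tree", {
  tr <- ape::read.tree(
    text = "((A:0.0125,B:0.0125):0.0125,(C:0.0125,D:0.0125):0.0125);")
  l1 <- simulate_mlst_loci(tr, default_mlst_loci(), kappa = 4, seed = 10)
  l2 <- simulate_mlst_loci(tr, default_mlst_loci(), kappa = 4, seed = 10)
  expect_identical(l1, l2)
  nj <- nj_tree(k2p_matrix(concatenate_loci(l1)))
  expect_identical(oracle_bipartitions(nj), oracle_bipartitions(tr))
  one_leaf <- structure(list(tip.label = "A",
                             edge = matrix(c(2L, 1L), 1, 2),
                             edge.length = 0.1, Nnode = 1L),
                        class = "phylo")
  expect_error(simulate_mlst_loci(one_leaf, c(l1 = 10L)), "tips")
})
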
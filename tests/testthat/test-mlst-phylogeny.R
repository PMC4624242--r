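two_locus_panel <- function() {
  list(
    glpF = c(s1 = "ACGTACGT", s2 = "ACGTACGT", s3 = "ACGTACGT"),
    ilvD = c(s1 = "TTTTCCCC", s2 = "TTTTCCCC", s3 = "TTTTCCCC"))
}

test_that("allele ids and sequence types follow first appearance", {
  loci <- two_locus_panel()
  p <- assign_alleles(loci)
  expect_equal(p$glpF, c(1, 1, 1))
  expect_equal(p$sequence_type, c(1, 1, 1))

  # one base difference at one locus -> new allele, new sequence type
  loci$ilvD[["s3"]] <- "TTTTCCCA"
  p <- assign_alleles(loci)
  expect_equal(p$ilvD, c(1, 1, 2))
  expect_equal(p$glpF, c(1, 1, 1))
  expect_equal(p$sequence_type, c(1, 1, 2))

  # missing strain at a locus is a data error naming both
  bad <- two_locus_panel()
  bad$ilvD <- bad$ilvD[c("s1", "s2")]
  expect_error(assign_alleles(bad), "s3.*ilvD")
  # unequal fragment lengths are rejected
  bad <- two_locus_panel()
  bad$glpF[["s2"]] <- "ACGT"
  expect_error(assign_alleles(bad), "equal length")
})

test_that("a zero-divergence five-strain group shares one sequence type", {
  strains <- sprintf("s%d", 1:8)
  tr <- simulate_strain_tree(strains, identical_group = strains[1:5],
                             seed = 61)
  loci <- simulate_mlst_loci(tr, seed = 62)
  p <- assign_alleles(loci)
  st <- p$sequence_type[match(strains[1:5], p$strain)]
  expect_equal(length(unique(st)), 1L)
  alleles <- p[match(strains[1:5], p$strain), names(loci)]
  expect_true(all(vapply(alleles, function(col)
    length(unique(col)) == 1, TRUE)))
})

test_that("locus concatenation preserves order, length and distances", {
  tr <- ape::read.tree(text = "((A:0.02,B:0.02):0.01,(C:0.02,D:0.02):0.01);")
  loci <- simulate_mlst_loci(tr, default_mlst_loci(), seed = 71)
  concat <- concatenate_loci(loci)
  expect_equal(unique(nchar(concat)), 7 * 450)

  single <- concatenate_loci(loci["glpF"])
  expect_identical(unname(single), unname(loci$glpF))

  # permuted locus order leaves pairwise distances unchanged
  perm <- concatenate_loci(loci, locus_order = rev(names(loci)))
  expect_equal(k2p_matrix(concat), k2p_matrix(perm[names(concat)]),
               tolerance = 1e-12)

  bad <- loci
  bad$pta[["A"]] <- substr(bad$pta[["A"]], 1, 10)
  expect_error(concatenate_loci(bad), "length mismatch")
})

test_that("K2P distance matches its closed form and flags saturation", {
  expect_equal(k2p_distance("ACGTACGT", "ACGTACGT"), 0)

  # 100 sites, 10 transitions (A->G), 5 transversions (A->C):
  # P = 0.10, Q = 0.05
  s1 <- paste(rep("A", 100), collapse = "")
  s2 <- paste(c(rep("G", 10), rep("C", 5), rep("A", 85)), collapse = "")
  expect_equal(k2p_distance(s1, s2),
               -0.5 * log(1 - 2 * 0.10 - 0.05) - 0.25 * log(1 - 2 * 0.05),
               tolerance = 1e-12)

  # Q = 0: d = -1/2 log(1 - 2P), and d >= p-distance
  s3 <- paste(c(rep("G", 10), rep("A", 90)), collapse = "")
  expect_equal(k2p_distance(s1, s3), -0.5 * log(1 - 0.2),
               tolerance = 1e-12)
  expect_gte(k2p_distance(s1, s3), 0.1)
  expect_gte(k2p_distance(s1, s2), 0.15)

  # saturation: P + Q too large for the log arguments
  s4 <- paste(c(rep("G", 60), rep("A", 40)), collapse = "")
  expect_error(k2p_distance(s1, s4), "saturation")

  expect_error(k2p_distance("ACGT", "ACG"), "equal length")
  expect_error(k2p_distance("NNNN", "ACGT"), "comparable")

  # gap/ambiguity columns are excluded pairwise
  expect_equal(k2p_distance("ACGTN-", "ACGTAC"), 0)
})

test_that("K2P matrix agrees with an independent implementation", {
  tr <- ape::read.tree(text = "((A:0.05,B:0.05):0.02,(C:0.05,D:0.05):0.02);")
  seqs <- concatenate_loci(simulate_mlst_loci(tr, seed = 81))
  d1 <- k2p_matrix(seqs)
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(seqs), "")))
  d2 <- as.matrix(ape::dist.dna(bin, model = "K80"))
  expect_equal(d1, d2[rownames(d1), colnames(d1)], tolerance = 1e-10)
})

test_that("neighbor joining solves the three-point case exactly", {
  d <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, 3, dimnames = list(c("A", "B", "C"),
                                                c("A", "B", "C")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], (3 + 4 - 5) / 2)
  expect_equal(bl[["B"]], (3 + 5 - 4) / 2)
  expect_equal(bl[["C"]], (4 + 5 - 3) / 2)
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("neighbor joining is exact on additive matrices", {
  # 4-taxon known tree
  tr <- ape::read.tree(text = "((A:1,B:2):1.5,(C:0.5,D:3):1);")
  d <- ape::cophenetic.phylo(tr)
  rec <- nj_tree(d)
  expect_identical(oracle_bipartitions(rec), oracle_bipartitions(tr))
  expect_equal(ape::cophenetic.phylo(rec)[rownames(d), colnames(d)], d,
               tolerance = 1e-10)

  # 20 random 6-taxon trees: topology and path lengths recovered
  for (seed in 1:20) {
    set.seed(seed)
    true <- ape::rtree(6, br = function(n) runif(n, 0.1, 2))
    d <- ape::cophenetic.phylo(true)
    rec <- nj_tree(d)
    expect_identical(oracle_bipartitions(rec), oracle_bipartitions(true))
    expect_equal(ape::cophenetic.phylo(rec)[rownames(d), colnames(d)], d,
                 tolerance = 1e-10)
    # second route: ape's own NJ agrees on the topology
    expect_identical(oracle_bipartitions(ape::nj(d)),
                     oracle_bipartitions(rec))
  }
})

test_that("bootstrap gives full support to a strongly separated split", {
  # two 2-strain groups: no variation within, 60 fixed transitions out of
  # 600 sites between groups (P = 0.1, far from saturation)
  g1 <- paste(rep("A", 600), collapse = "")
  g2 <- paste(c(rep("G", 60), rep("A", 540)), collapse = "")
  seqs <- c(s1 = g1, s2 = g1, s3 = g2, s4 = g2)
  set.seed(1)
  tr <- bootstrap_support(seqs, n_replicates = 100, seed = 5)
  sup <- attr(tr, "supports")
  expect_equal(length(sup), 1L)
  expect_equal(unname(sup), 100)
  expect_identical(names(sup), "s3|s4")

  tr2 <- bootstrap_support(seqs, n_replicates = 100, seed = 5)
  expect_identical(attr(tr2, "supports"), sup)

  # strain input order does not change supports
  tr3 <- bootstrap_support(seqs[c(3, 1, 4, 2)], n_replicates = 100,
                           seed = 5)
  expect_identical(attr(tr3, "supports"), sup)
})

test_that("K2P + NJ recovers simulated 8-taxon trees across seeds", {
  hits <- 0
  for (seed in 1:20) {
    strains <- sprintf("s%d", 1:8)
    true <- simulate_strain_tree(strains, edge_range = c(0.005, 0.025),
                                 seed = 200 + seed)
    seqs <- concatenate_loci(simulate_mlst_loci(true, kappa = 4,
                                                seed = 300 + seed))
    rec <- nj_tree(k2p_matrix(seqs))
    if (identical(oracle_bipartitions(rec), oracle_bipartitions(true)))
      hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("newick serialization round-trips trees with and without supports", {
  # 3-taxon star
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  txt <- write_newick(tr)
  back <- parse_newick(txt)
  expect_identical(sort(back$tip.label), c("A", "B", "C"))
  expect_equal(sort(back$edge.length), sort(tr$edge.length))

  # supports land on internal nodes only and survive the round trip
  seqs <- c(s1 = paste(rep("AACT", 200), collapse = ""),
            s2 = paste(rep("AACT", 200), collapse = ""),
            s3 = paste(rep("GACT", 200), collapse = ""),
            s4 = paste(rep("GACT", 200), collapse = ""))
  tr <- bootstrap_support(seqs, n_replicates = 50, seed = 2)
  back <- parse_newick(write_newick(tr))
  labs <- suppressWarnings(as.numeric(back$node.label))
  labs <- labs[!is.na(labs)]
  expect_true(all(labs >= 0 & labs <= 100))

  # 50 random trees round-trip exactly
  for (seed in 1:50) {
    set.seed(seed)
    t0 <- ape::unroot(ape::rtree(sample(4:10, 1)))
    t1 <- parse_newick(write_newick(t0))
    expect_identical(oracle_bipartitions(t1), oracle_bipartitions(t0))
    expect_equal(sort(t1$edge.length), sort(t0$edge.length),
                 tolerance = 1e-12)
  }
})
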
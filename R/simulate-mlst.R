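#' Default MLST locus set
#'
#' Internal fragments of the seven housekeeping genes conventionally used
#' for *B. subtilis* multilocus sequence typing, each 450 bp here.
#'
#' @return named integer vector: locus name -> fragment length (bp).
#' @export
default_mlst_loci <- function() {
  c(glpF = 450L, ilvD = 450L, pta = 450L, purH = 450L, pycA = 450L,
    rpoD = 450L, tpiA = 450L)
}

#' Simulate MLST locus sequences along a known tree
#'
#' Evolves each locus site-independently along the given tree under a
#' Kimura two-parameter substitution model: transitions (A<->G, C<->T)
#' occur at `kappa` times the rate of each transversion, and branch lengths
#' are expected substitutions per site (rates normalized so that the total
#' substitution rate per site is 1). The root sequence is uniform random
#' over A, C, G, T. Loci are generated gap-free and equal-length per locus,
#' i.e. pre-aligned.
#'
#' @param tree an [ape::phylo] tree with branch lengths (rooted or
#'   unrooted; at least 2 tips) whose tip labels are the strain names.
#' @param loci named integer vector locus -> length in bp (default
#'   [default_mlst_loci()]).
#' @param kappa transition/transversion rate ratio, > 0 (default 4).
#' @param seed integer seed; identical seeds give identical sequences.
#' @return named list: locus -> named character vector (strain -> sequence).
#' @examples
#' tr <- ape::read.tree(text = "((A:0.02,B:0.02):0.01,(C:0.02,D:0.02):0.01);")
#' loci <- simulate_mlst_loci(tr, c(locus1 = 100L), kappa = 4, seed = 1)
#' @export
simulate_mlst_loci <- function(tree, loci = default_mlst_loci(), kappa = 4,
                               seed = 1) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2)
    stop("tree must have at least 2 tips")
  if (is.null(tree$edge.length) || any(!is.finite(tree$edge.length)) ||
      any(tree$edge.length < 0))
    stop("tree must have finite non-negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("tip labels must be unique")
  if (!is.numeric(loci) || length(loci) == 0 || is.null(names(loci)) ||
      any(loci <= 0))
    stop("'loci' must be a named vector of positive lengths")
  if (!is.numeric(kappa) || kappa <= 0) stop("'kappa' must be > 0")
  check_count(seed, "seed")
  set.seed(seed)

  nsites <- sum(loci)
  ntip <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "cladewise")   # parents before children
  root <- ntip + 1L
  nnode <- ntip + tree$Nnode

  # K2P rates normalized to 1 substitution/site: alpha + 2 beta = 1
  beta <- 1 / (kappa + 2)
  alpha <- kappa / (kappa + 2)
  ts_map <- c(3L, 4L, 1L, 2L)          # A<->G, C<->T (A=1 C=2 G=3 T=4)
  tv1 <- c(2L, 1L, 2L, 1L)
  tv2 <- c(4L, 3L, 4L, 3L)

  seqs <- vector("list", nnode)
  seqs[[root]] <- sample.int(4L, nsites, replace = TRUE)
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    t <- tree$edge.length[e]
    e1 <- exp(-4 * beta * t)
    e2 <- exp(-2 * (alpha + beta) * t)
    p_same <- 0.25 + 0.25 * e1 + 0.5 * e2
    p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
    p_tv <- 0.25 - 0.25 * e1             # each of the two transversions
    x <- seqs[[parent]]
    r <- runif(nsites)
    y <- x
    is_ts <- r >= p_same & r < p_same + p_ts
    is_v1 <- r >= p_same + p_ts & r < p_same + p_ts + p_tv
    is_v2 <- r >= p_same + p_ts + p_tv
    y[is_ts] <- ts_map[x[is_ts]]
    y[is_v1] <- tv1[x[is_v1]]
    y[is_v2] <- tv2[x[is_v2]]
    seqs[[child]] <- y
  }

  ends <- cumsum(loci)
  starts <- ends - loci + 1L
  out <- lapply(seq_along(loci), function(l) {
    v <- vapply(seq_len(ntip), function(i)
      paste(BASES[seqs[[i]][starts[l]:ends[l]]], collapse = ""), "")
    names(v) <- tree$tip.label
    v
  })
  names(out) <- names(loci)
  out
}

#' Random strain tree, optionally with a zero-divergence strain group
#'
#' Builds a random binary topology by repeatedly joining two randomly
#' chosen subtrees, with edge lengths drawn uniformly from `edge_range`
#' (expected substitutions per site). Strains named in `identical_group`
#' are placed on a common subtree whose internal and pendant edges all have
#' length 0, so they end up with identical sequences at every simulated
#' locus (a planted shared sequence type).
#'
#' @param strains character vector of strain labels.
#' @param edge_range length-2 numeric range for edge lengths.
#' @param identical_group optional subset of `strains` forced to zero
#'   divergence.
#' @param seed integer seed.
#' @return an [ape::phylo] tree.
#' @export
simulate_strain_tree <- function(strains, edge_range = c(0.005, 0.03),
                                 identical_group = NULL, seed = 1) {
  stopifnot(length(strains) >= 2, !anyDuplicated(strains))
  check_range(edge_range, "edge_range")
  if (!all(identical_group %in% strains))
    stop("'identical_group' must be a subset of 'strains'")
  check_count(seed, "seed")
  set.seed(seed)
  rlen <- function() runif(1, edge_range[1], edge_range[2])

  join <- function(a, b, la, lb)
    sprintf("(%s:%.8f,%s:%.8f)", a, la, b, lb)
  nodes <- as.list(setdiff(strains, identical_group))
  if (length(identical_group) == 1)
    nodes <- c(nodes, identical_group)
  if (length(identical_group) >= 2) {
    grp <- identical_group[1]
    for (s in identical_group[-1]) grp <- join(grp, s, 0, 0)
    nodes <- c(nodes, grp)
  }
  while (length(nodes) > 1) {
    i <- sample.int(length(nodes), 2)
    merged <- join(nodes[[i[1]]], nodes[[i[2]]], rlen(), rlen())
    nodes <- c(nodes[-i], merged)
  }
  ape::read.tree(text = paste0(nodes[[1]], ";"))
}

#' Write simulated MLST loci as one FASTA per locus, or read them back
#'
#' Each file is named `<locus>.fasta` and its records are named by strain.
#'
#' @param loci_seqs named list locus -> named character vector
#'   (strain -> sequence).
#' @param dir directory path (created if missing).
#' @return `read_mlst_loci` returns the same list structure.
#' @export
write_mlst_loci <- function(loci_seqs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (locus in names(loci_seqs))
    write_gene_set(loci_seqs[[locus]], file.path(dir,
                                                 paste0(locus, ".fasta")))
  invisible(dir)
}

#' @rdname write_mlst_loci
#' @export
read_mlst_loci <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(fa|fasta)$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no FASTA files found in ", dir)
  out <- lapply(files, read_gene_set)
  names(out) <- sub("\\.(fa|fasta)$", "", basename(files))
  out
}
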
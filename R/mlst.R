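#' Assign MLST allele ids and sequence types
#'
#' For each locus, distinct sequences receive allele ids 1, 2, ... in order
#' of first appearance across strains (internal labels; no database
#' numbering). Strains with identical allele vectors across all loci share a
#' sequence type, likewise numbered by first appearance. Locus fragments
#' must be pre-aligned: equal length within each locus, every strain present
#' at every locus.
#'
#' @param loci_seqs named list locus -> named character vector
#'   (strain -> sequence), e.g. from [simulate_mlst_loci()] or
#'   [read_mlst_loci()].
#' @return data.frame with `strain`, one allele-id column per locus, and
#'   `sequence_type`.
#' @export
assign_alleles <- function(loci_seqs) {
  stopifnot(is.list(loci_seqs), length(loci_seqs) > 0)
  strains <- names(loci_seqs[[1]])
  if (is.null(strains) || length(strains) == 0)
    stop("locus sequences must be named by strain")
  for (locus in names(loci_seqs)) {
    v <- loci_seqs[[locus]]
    missing <- setdiff(strains, names(v))
    extra <- setdiff(names(v), strains)
    if (length(missing) || length(extra))
      stop("strain '", c(missing, extra)[1], "' missing or unexpected at ",
           "locus '", locus, "'")
    if (length(unique(nchar(v))) != 1)
      stop("locus '", locus, "' fragments are not equal length; supply ",
           "pre-aligned fragments")
  }
  alleles <- vapply(names(loci_seqs), function(locus) {
    v <- toupper(loci_seqs[[locus]][strains])
    match(v, unique(v))
  }, integer(length(strains)))
  alleles <- matrix(alleles, nrow = length(strains),
                    dimnames = list(NULL, names(loci_seqs)))
  profile_key <- apply(alleles, 1, paste, collapse = "-")
  st <- match(profile_key, unique(profile_key))
  out <- data.frame(strain = strains, alleles, sequence_type = st,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Concatenate MLST locus fragments into one sequence per strain
#'
#' @inheritParams assign_alleles
#' @param locus_order loci concatenation order (default: list order).
#' @return named character vector strain -> concatenated sequence; all
#'   outputs have equal length.
#' @export
concatenate_loci <- function(loci_seqs, locus_order = names(loci_seqs)) {
  stopifnot(all(locus_order %in% names(loci_seqs)))
  strains <- names(loci_seqs[[locus_order[1]]])
  for (locus in locus_order) {
    v <- loci_seqs[[locus]]
    if (!setequal(names(v), strains))
      stop("strains differ between loci")
    if (length(unique(nchar(v))) != 1)
      stop("length mismatch across strains at locus '", locus, "'")
  }
  out <- vapply(strains, function(s)
    paste(vapply(locus_order, function(l) loci_seqs[[l]][[s]], ""),
          collapse = ""), "")
  names(out) <- strains
  out
}

# integer-code a sequence: A=1 C=2 G=3 T=4, anything else NA
code_dna <- function(s) {
  x <- match(strsplit(toupper(s), "")[[1]], BASES)
  x
}

# K2P distance from transition/transversion/comparable-site counts
k2p_from_counts <- function(n_ts, n_tv, n_comp) {
  p <- n_ts / n_comp
  q <- n_tv / n_comp
  w1 <- 1 - 2 * p - q
  w2 <- 1 - 2 * q
  if (w1 <= 0 || w2 <= 0)
    stop("K2P distance undefined (saturation): 1-2P-Q = ", signif(w1, 4),
         ", 1-2Q = ", signif(w2, 4))
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' With P the transition proportion (A<->G, C<->T) and Q the transversion
#' proportion over comparable sites,
#' `d = -1/2 * ln(1 - 2P - Q) - 1/4 * ln(1 - 2Q)`.
#' Columns where either sequence has a non-ACGT character (gap, ambiguity)
#' are excluded pairwise. Saturated inputs (`1 - 2P - Q <= 0` or
#' `1 - 2Q <= 0`) raise an error: the distance is undefined.
#'
#' @param s1,s2 equal-length DNA strings.
#' @return non-negative evolutionary distance (substitutions per site).
#' @examples
#' k2p_distance("AAAA", "AAAA")  # 0
#' @export
k2p_distance <- function(s1, s2) {
  if (nchar(s1) != nchar(s2))
    stop("sequences must be equal length (aligned); got ", nchar(s1),
         " and ", nchar(s2))
  x <- code_dna(s1)
  y <- code_dna(s2)
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 1) stop("no comparable sites after pairwise deletion")
  x <- x[ok]; y <- y[ok]
  diff <- x != y
  ts <- diff & (abs(x - y) == 2)   # A(1)<->G(3), C(2)<->T(4)
  k2p_from_counts(sum(ts), sum(diff & !ts), n)
}

#' Pairwise K2P distance matrix for a set of aligned sequences
#'
#' @param seqs named character vector of equal-length DNA sequences.
#' @return symmetric numeric matrix with zero diagonal, labelled by strain.
#' @export
k2p_matrix <- function(seqs) {
  stopifnot(length(seqs) >= 2, !is.null(names(seqs)))
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- k2p_distance(seqs[[i]], seqs[[j]])
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with the standard Q-criterion
#' `Q(i, j) = (n - 2) d(i, j) - r(i) - r(j)` and two-point branch-length
#' formulas. Ties in the Q-criterion are broken by the lowest label-index
#' pair. Negative estimated branch lengths are clamped to 0 with the
#' deficit moved to the sister edge. On an additive (tree-like) matrix the
#' generating topology and branch lengths are recovered exactly.
#'
#' @param dm symmetric distance matrix with labelled rows/columns (at least
#'   3 labels), e.g. from [k2p_matrix()].
#' @return an unrooted [ape::phylo] tree with branch lengths.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3) stop("neighbor joining requires at least 3 labels")
  labels <- rownames(dm) %||% paste0("t", seq_len(n))
  if (!isTRUE(all.equal(unname(dm), unname(t(dm)))) || any(diag(dm) != 0))
    stop("distance matrix must be symmetric with zero diagonal")
  fmt <- function(x) sprintf("%.15g", x + 0)   # "+ 0" normalizes -0
  nwk <- labels
  D <- dm

  while (length(nwk) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    # lowest label-index pair among minima
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    vi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- max(0, vi + vj); vj <- 0 }
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(vi), nwk[j], fmt(vj))
    dk <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    D <- D2
    nwk <- c(nwk[keep], new_nwk)
  }
  # close with the three-point formulas
  a <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  c3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  v <- pmax(c(a, b, c3), 0)
  text <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[1], fmt(v[1]),
                  nwk[2], fmt(v[2]), nwk[3], fmt(v[3]))
  ape::read.tree(text = text)
}

# internal-edge bipartitions of an unrooted tree as canonical keys:
# the tip-label set on the side NOT containing the first label (sorted),
# collapsed to a string; trivial splits (single tip / all-but-one) excluded
tree_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  anchor <- sort(tree$tip.label)[1]
  keys <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    if (ch <= ntip) next                       # pendant edge
    side <- below[[ch]]
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) < 2 || length(side) > ntip - 2) next
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the reference tree from the full concatenated alignment (K2P
#' distances + neighbor joining), then resamples alignment columns with
#' replacement `n_replicates` times, rebuilds the tree per replicate, and
#' assigns each internal edge of the reference tree a support equal to the
#' percentage of replicate trees containing the same bipartition of strain
#' labels. Replicates whose resampled distances saturate are skipped and
#' counted (the percentage is taken over successful replicates).
#'
#' @param concat_seqs named character vector of equal-length concatenated
#'   sequences (at least 4 strains, so internal edges exist).
#' @param n_replicates number of bootstrap replicates (default 1500).
#' @param seed integer seed; supports are deterministic per seed.
#' @return an [ape::phylo] tree; internal-node labels carry supports in
#'   `[0, 100]` (the basal node has none), attribute `skipped_replicates`
#'   counts saturated replicates.
#' @export
bootstrap_support <- function(concat_seqs, n_replicates = 1500, seed = 1) {
  stopifnot(length(concat_seqs) >= 4, !is.null(names(concat_seqs)))
  check_count(n_replicates, "n_replicates", min = 1)
  check_count(seed, "seed")
  lens <- unique(nchar(concat_seqs))
  if (length(lens) != 1)
    stop("concatenated sequences must be equal length (aligned)")
  nsites <- lens
  set.seed(seed)

  ref_tree <- nj_tree(k2p_matrix(concat_seqs))

  # site-pattern compression: per strain pair, count transitions /
  # transversions / comparable sites per distinct alignment column, then a
  # bootstrap replicate only needs the resampled column multiplicities
  strains <- names(concat_seqs)
  n <- length(strains)
  coded <- do.call(rbind, lapply(concat_seqs, code_dna))
  pattern_key <- apply(coded, 2, paste, collapse = ",")
  pid <- match(pattern_key, unique(pattern_key))
  npat <- max(pid)
  first_col <- match(seq_len(npat), pid)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ts_mat <- matrix(0, nrow(pairs), npat)
  tv_mat <- matrix(0, nrow(pairs), npat)
  cmp_mat <- matrix(0, nrow(pairs), npat)
  for (k in seq_len(nrow(pairs))) {
    x <- coded[pairs[k, 1], first_col]
    y <- coded[pairs[k, 2], first_col]
    ok <- !is.na(x) & !is.na(y)
    diff <- ok & x != y
    ts <- diff & (abs(x - y) == 2)
    ts_mat[k, ] <- as.numeric(ts)
    tv_mat[k, ] <- as.numeric(diff & !ts)
    cmp_mat[k, ] <- as.numeric(ok)
  }

  ref_bip <- tree_bipartitions(ref_tree)
  tally <- setNames(numeric(length(ref_bip)), ref_bip)
  skipped <- 0L
  for (b in seq_len(n_replicates)) {
    w <- tabulate(pid[sample.int(nsites, nsites, replace = TRUE)], npat)
    nts <- ts_mat %*% w
    ntv <- tv_mat %*% w
    ncmp <- cmp_mat %*% w
    d <- matrix(0, n, n, dimnames = list(strains, strains))
    bad <- FALSE
    for (k in seq_len(nrow(pairs))) {
      dk <- tryCatch(k2p_from_counts(nts[k], ntv[k], ncmp[k]),
                     error = function(e) NA_real_)
      if (is.na(dk)) { bad <- TRUE; break }
      d[pairs[k, 1], pairs[k, 2]] <- d[pairs[k, 2], pairs[k, 1]] <- dk
    }
    if (bad) { skipped <- skipped + 1L; next }
    rep_bip <- tree_bipartitions(nj_tree(d))
    hit <- ref_bip %in% rep_bip
    tally[hit] <- tally[hit] + 1
  }
  n_ok <- n_replicates - skipped
  if (n_ok == 0) stop("all bootstrap replicates saturated")
  if (skipped > 0)
    message(skipped, " bootstrap replicate(s) skipped due to saturation")
  support <- 100 * tally / n_ok

  # attach supports as internal-node labels on the reference tree
  ntip <- length(ref_tree$tip.label)
  node_lab <- rep("", ref_tree$Nnode)
  tree_po <- ape::reorder.phylo(ref_tree, "postorder")
  below <- vector("list", ntip + ref_tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- ref_tree$tip.label[i]
  for (e in seq_len(nrow(tree_po$edge))) {
    p <- tree_po$edge[e, 1]; ch <- tree_po$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  anchor <- sort(ref_tree$tip.label)[1]
  for (nd in setdiff(seq_len(ref_tree$Nnode) + ntip, ntip + 1L)) {
    side <- below[[nd]]
    if (anchor %in% side) side <- setdiff(ref_tree$tip.label, side)
    if (length(side) < 2 || length(side) > ntip - 2) next
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(support))
      node_lab[nd - ntip] <- sprintf("%.4g", support[[key]])
  }
  ref_tree$node.label <- node_lab
  attr(ref_tree, "skipped_replicates") <- skipped
  attr(ref_tree, "supports") <- support
  ref_tree
}

#' Serialize a tree to Newick text (round-trip safe)
#'
#' Standard Newick with branch lengths; bootstrap supports, when present,
#' appear as internal-node labels. `parse_newick` is the inverse.
#'
#' @param tree an [ape::phylo] tree.
#' @return a single Newick string ending in ";".
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = 15)
}

#' @rdname write_newick
#' @param text a Newick string.
#' @export
parse_newick <- function(text) {
  ape::read.tree(text = text)
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param dm labelled symmetric matrix (e.g. from [k2p_matrix()]).
#' @param path output path.
#' @export
write_phylip <- function(dm, path) {
  dm <- as.matrix(dm)
  lines <- c(sprintf("%5d", nrow(dm)),
             vapply(seq_len(nrow(dm)), function(i)
               paste0(formatC(rownames(dm)[i], width = -10),
                      paste(sprintf("%.8f", dm[i, ]), collapse = "  ")),
               ""))
  writeLines(lines, path)
  invisible(path)
}
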
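# Independent oracles used across tests. Each re-derives a quantity from
# first principles (brute force, closed form, or a different library code
# path) so that package results are checked against a second route.

# local alignment score by exhaustive dynamic programming, linear gap cost
oracle_sw_score <- function(a, b, match = 1, mismatch = -1, gap = 2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  for (i in seq_len(n))
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j]) match else mismatch
      H[i + 1, j + 1] <- max(0, H[i, j] + s, H[i, j + 1] - gap,
                             H[i + 1, j] - gap)
    }
  max(H)
}

# PCA via eigendecomposition of the covariance matrix, with the same
# retained-component rule and sign convention as strain_pca
oracle_pca <- function(x, center = TRUE) {
  xc <- scale(x, center = center, scale = FALSE)
  ev <- eigen(stats::cov(xc), symmetric = TRUE)
  lambda <- pmax(ev$values, 0)
  tot <- sum(lambda)
  keep <- if (tot <= 0) integer(0) else which(lambda > tot * 1e-12)
  load <- ev$vectors[, keep, drop = FALSE]
  sco <- xc %*% load
  for (k in seq_len(ncol(load))) {
    j <- which.max(abs(load[, k]))
    if (load[j, k] < 0) { load[, k] <- -load[, k]; sco[, k] <- -sco[, k] }
  }
  list(lambda = lambda[keep], ratio = lambda[keep] / sum(lambda[keep]),
       loadings = load, scores = sco)
}

# complete-linkage agglomeration by literal iteration of the max rule;
# returns merge heights and the partition (list of label sets) after each
# merge
oracle_complete_linkage <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(rownames(d))
  heights <- numeric(0)
  partitions <- list()
  cdist <- function(c1, c2) max(d[c1, c2])
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters))
      for (j in seq_along(clusters))
        if (i < j) {
          h <- cdist(clusters[[i]], clusters[[j]])
          if (h < best[1]) best <- c(h, i, j)
        }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
    partitions[[length(partitions) + 1]] <- lapply(clusters, sort)
  }
  list(heights = heights, partitions = partitions)
}

# canonical key for a partition of labels (grouping only, order-free)
partition_key <- function(groups) {
  paste(sort(vapply(groups, function(g) paste(sort(g), collapse = ","),
                    "")), collapse = " | ")
}

partition_from_cutree <- function(ct) {
  partition_key(split(names(ct), ct))
}

# brute-force reciprocal best hits: enumerate every pair with align_pair
# and apply the definition directly (top hit both ways, strict identity
# and per-gene coverage thresholds)
oracle_rbh <- function(set_a, set_b, min_identity = 80,
                       min_coverage = 0.8) {
  hit_table <- function(qs, ss) {
    do.call(rbind, lapply(names(qs), function(q) do.call(rbind, lapply(
      names(ss), function(s) {
        h <- align_pair(qs[[q]], ss[[s]])
        data.frame(q = q, s = s, score = h$score, identity = h$identity,
                   aln_len = h$aln_len, qlen = h$query_len,
                   stringsAsFactors = FALSE)
      }))))
  }
  top <- function(tab) {
    do.call(rbind, lapply(split(tab, tab$q), function(h)
      h[order(-h$score, -h$identity, h$s), ][1, ]))
  }
  ab <- top(hit_table(set_a, set_b))
  ba <- top(hit_table(set_b, set_a))
  pairs <- list()
  for (i in seq_len(nrow(ab))) {
    a <- ab$q[i]; b <- ab$s[i]
    j <- which(ba$q == b)
    if (length(j) != 1 || ba$s[j] != a) next
    if (ab$identity[i] <= min_identity || ba$identity[j] <= min_identity)
      next
    if (ab$aln_len[i] <= min_coverage * ab$qlen[i]) next
    if (ba$aln_len[j] <= min_coverage * ba$qlen[j]) next
    pairs[[length(pairs) + 1]] <- c(a, b)
  }
  if (length(pairs) == 0) return(character(0))
  sort(vapply(pairs, paste, "", collapse = "~"))
}

# canonical bipartition keys of a tree via ape::prop.part (independent of
# the package's own bipartition code)
oracle_bipartitions <- function(tree) {
  labels <- tree$tip.label
  anchor <- sort(labels)[1]
  pp <- ape::prop.part(tree)
  keys <- vapply(pp, function(idx) {
    side <- labels[idx]
    if (anchor %in% side) side <- setdiff(labels, side)
    if (length(side) < 2 || length(side) > length(labels) - 2)
      return(NA_character_)
    paste(sort(side), collapse = "|")
  }, "")
  sort(unique(keys[!is.na(keys)]))
}

# random genes and sequence helpers
random_dna <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")

mutate_dna <- function(s, n_mut) {
  ch <- strsplit(s, "")[[1]]
  pos <- sample.int(length(ch), n_mut)
  ch[pos] <- vapply(ch[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  paste(ch, collapse = "")
}
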
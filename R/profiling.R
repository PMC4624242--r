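#' Principal component analysis of strain score vectors
#'
#' PCA of the strains-by-genes variant score matrix. Columns are
#' mean-centered by default but never variance-scaled: the gene variant
#' scores are already on a comparable scale, so no normalization to unit
#' variance is applied. Components are ordered by decreasing explained
#' variance, and each component's sign is fixed deterministically so that
#' its largest-magnitude loading is positive.
#'
#' If the matrix has no variance at all (e.g. identical strains) the result
#' is degenerate: zero components, empty loading/score matrices.
#'
#' @param m a `score_matrix` (or any numeric matrix, strains in rows).
#' @param center mean-center columns before decomposition (default TRUE).
#' @return object of class `strain_pca`: list with `loadings` (genes x
#'   components, unit-norm columns), `scores` (strains x components),
#'   `explained_variance_ratio` (sums to 1 over retained components),
#'   `sdev`, `center` and `degenerate`.
#' @export
strain_pca <- function(m, center = TRUE) {
  check_flag(center, "center")
  x <- unclass(as.matrix(m))
  if (nrow(x) < 2) stop("PCA requires at least 2 strains")
  if (ncol(x) < 1) stop("PCA requires at least 1 gene")
  p <- prcomp(x, center = center, scale. = FALSE)
  ev <- p$sdev^2
  tot <- sum(ev)
  keep <- if (tot <= 0) integer(0) else which(ev > tot * 1e-12)
  if (length(keep) == 0) {
    res <- list(
      loadings = matrix(0, ncol(x), 0, dimnames = list(colnames(x), NULL)),
      scores = matrix(0, nrow(x), 0, dimnames = list(rownames(x), NULL)),
      explained_variance_ratio = numeric(0), sdev = numeric(0),
      center = if (center) colMeans(x) else rep(0, ncol(x)),
      degenerate = TRUE)
    class(res) <- "strain_pca"
    return(res)
  }
  load <- p$rotation[, keep, drop = FALSE]
  sco <- p$x[, keep, drop = FALSE]
  for (k in seq_len(ncol(load))) {       # sign convention
    j <- which.max(abs(load[, k]))
    if (load[j, k] < 0) {
      load[, k] <- -load[, k]
      sco[, k] <- -sco[, k]
    }
  }
  res <- list(loadings = load, scores = sco,
              explained_variance_ratio = ev[keep] / sum(ev[keep]),
              sdev = p$sdev[keep],
              center = if (center) p$center else rep(0, ncol(x)),
              degenerate = FALSE)
  class(res) <- "strain_pca"
  res
}

#' @export
print.strain_pca <- function(x, ...) {
  if (x$degenerate || length(x$explained_variance_ratio) == 0) {
    cat("Degenerate PCA: total variance is 0 (no retained components)\n")
    return(invisible(x))
  }
  cat("PCA of strain score vectors:", ncol(x$scores), "components\n")
  cat("Explained variance ratio:",
      paste(sprintf("%.3f", x$explained_variance_ratio), collapse = " "),
      "\n")
  invisible(x)
}

#' Genes contributing most to a principal component
#'
#' Ranks genes by the absolute loading on the requested component,
#' descending; ties are broken by gene id, ascending. Asking for more genes
#' than exist returns all of them.
#'
#' @param res a `strain_pca` object.
#' @param component component index (1 = first principal component).
#' @param k number of genes to return (`k = 0` gives an empty result).
#' @return data.frame with `gene_id` and `loading`, in rank order.
#' @export
top_contributing_genes <- function(res, component = 1, k = 10) {
  stopifnot(inherits(res, "strain_pca"))
  check_count(component, "component", min = 1)
  check_count(k, "k")
  if (component > ncol(res$loadings))
    stop("component ", component, " out of range (", ncol(res$loadings),
         " retained)")
  l <- res$loadings[, component]
  ord <- order(-abs(l), names(l))
  ord <- ord[seq_len(min(k, length(ord)))]
  data.frame(gene_id = names(l)[ord], loading = unname(l[ord]),
             stringsAsFactors = FALSE)
}

#' Complete-linkage hierarchical clustering of strains
#'
#' Agglomerative clustering of strain score vectors using Euclidean
#' distance and the furthest-neighbor (complete linkage) rule: the distance
#' between two clusters is the maximum pairwise distance between their
#' members, which guarantees non-decreasing merge heights.
#'
#' @param m a `score_matrix` (or numeric matrix, strains in rows).
#' @return an [stats::hclust] object (merge order, heights, strain labels).
#' @export
cluster_strains <- function(m) {
  x <- unclass(as.matrix(m))
  if (nrow(x) < 2) stop("clustering requires at least 2 strains")
  hclust(dist(x, method = "euclidean"), method = "complete")
}

#' Write PCA results (coordinates, loadings, variance report)
#'
#' @param res a `strain_pca`.
#' @param prefix output path prefix; writes `<prefix>_scores.tsv`,
#'   `<prefix>_loadings.tsv` and `<prefix>_variance.json`.
#' @export
write_pca <- function(res, prefix) {
  write.table(data.frame(strain = rownames(res$scores), res$scores,
                         check.names = FALSE),
              paste0(prefix, "_scores.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(gene_id = rownames(res$loadings), res$loadings,
                         check.names = FALSE),
              paste0(prefix, "_loadings.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(explained_variance_ratio = res$explained_variance_ratio,
         degenerate = res$degenerate),
    paste0(prefix, "_variance.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
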
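#' Tally impact counts per gene for one strain
#'
#' Counts the high-, moderate- and low-impact variants per gene. Modifier
#' (intergenic) variants contribute to no count: the variant score formula
#' has only high/moderate/low terms. Genes absent from the table have
#' implicit counts (0, 0, 0).
#'
#' @param annotated annotated variant data.frame (see [annotate_variants()]).
#' @param strain strain label to subset on; `NULL` uses all rows (they must
#'   then belong to a single strain).
#' @return data.frame with columns `gene_id`, `n_high`, `n_mod`, `n_low`
#'   (class `impact_counts`, attribute `strain`).
#' @export
count_impacts <- function(annotated, strain = NULL) {
  stopifnot(is.data.frame(annotated))
  if (!is.null(strain)) {
    annotated <- annotated[annotated$strain == strain, , drop = FALSE]
  } else {
    strains <- unique(annotated$strain)
    if (length(strains) > 1)
      stop("annotations span several strains; pass 'strain' explicitly")
    strain <- if (length(strains) == 1) strains else "strain"
  }
  coding <- annotated[annotated$impact %in% c("high", "moderate", "low"), ,
                      drop = FALSE]
  if (nrow(coding) == 0) {
    out <- data.frame(gene_id = character(0), n_high = integer(0),
                      n_mod = integer(0), n_low = integer(0),
                      stringsAsFactors = FALSE)
  } else {
    genes <- sort(unique(coding$gene_id))
    tally <- function(level) {
      v <- table(factor(coding$gene_id[coding$impact == level],
                        levels = genes))
      as.integer(v)
    }
    out <- data.frame(gene_id = genes, n_high = tally("high"),
                      n_mod = tally("moderate"), n_low = tally("low"),
                      stringsAsFactors = FALSE)
  }
  attr(out, "strain") <- strain
  class(out) <- c("impact_counts", "data.frame")
  out
}

#' Strain-specific weighting constants for the gene variant score
#'
#' Implements the printed definition: `C_low = 1`, `C_mod = MAX_low / 2`,
#' `C_high = (C_mod + MAX_mod) / 2`, where `MAX_low` and `MAX_mod` are the
#' maximum per-gene counts of low and moderate effects within the strain
#' (0 for an empty table). The formulas are applied literally; when a
#' maximum is 0 the corresponding weight degenerates to 0 and a warning is
#' emitted if that zero weight would silence nonzero counts.
#'
#' @param counts an `impact_counts` table (see [count_impacts()]).
#' @return list with `strain`, `c_low`, `c_mod`, `c_high`, `max_low`,
#'   `max_mod`.
#' @export
strain_constants <- function(counts) {
  stopifnot(is.data.frame(counts))
  max_low <- if (nrow(counts)) max(counts$n_low) else 0L
  max_mod <- if (nrow(counts)) max(counts$n_mod) else 0L
  c_mod <- max_low / 2
  c_high <- (c_mod + max_mod) / 2
  if (c_mod == 0 && nrow(counts) && any(counts$n_mod > 0))
    warning("C_mod is 0 (no low-impact variants in this strain); ",
            "moderate-impact counts will not contribute to scores")
  if (c_high == 0 && nrow(counts) && any(counts$n_high > 0))
    warning("C_high is 0; high-impact counts will not contribute to scores")
  list(strain = attr(counts, "strain") %||% NA_character_,
       c_low = 1, c_mod = c_mod, c_high = c_high,
       max_low = max_low, max_mod = max_mod)
}

#' Gene variant score
#'
#' The per-gene, per-strain statistic
#' `score = ln(C_high * N_high + C_mod * N_mod + C_low * N_low + 1)`,
#' a log-compressed impact-weighted variant count. Natural logarithm is
#' used; the base only rescales all scores by a constant and leaves PCA
#' directions and clustering topology unchanged. Vectorized over counts.
#'
#' @param n_high,n_mod,n_low non-negative variant counts.
#' @param constants list with `c_high`, `c_mod`, `c_low` (see
#'   [strain_constants()]).
#' @return numeric score(s), `>= 0`; exactly 0 iff the weighted sum is 0.
#' @examples
#' gene_score(1, 1, 1, list(c_high = 2, c_mod = 2, c_low = 1))  # log(6)
#' @export
gene_score <- function(n_high, n_mod, n_low, constants) {
  if (any(c(n_high, n_mod, n_low) < 0, na.rm = FALSE) ||
      any(is.na(c(n_high, n_mod, n_low))))
    stop("variant counts must be non-negative")
  log(constants$c_high * n_high + constants$c_mod * n_mod +
        constants$c_low * n_low + 1)
}

#' Assemble the strains-by-genes variant score matrix
#'
#' Each row is a strain's gene variant score vector, computed with that
#' strain's own constants. The gene universe (columns, identical for all
#' strains) defaults to the sorted union of genes carrying at least one
#' scored variant in at least one strain; pass `genes` to force a fixed
#' universe (e.g. all reference genes). Genes without variants in a strain
#' score exactly 0.
#'
#' @param tables list of `impact_counts` tables, one per strain (see
#'   [count_impacts()]); strain labels must be unique.
#' @param genes optional character vector fixing the gene universe.
#' @return numeric matrix (strains x genes) of class `score_matrix` with a
#'   `constants` attribute (data.frame of per-strain constants).
#' @export
build_score_matrix <- function(tables, genes = NULL) {
  stopifnot(is.list(tables), length(tables) > 0)
  strains <- vapply(tables, function(t) attr(t, "strain") %||%
                      NA_character_, "")
  if (anyNA(strains) || anyDuplicated(strains))
    stop("strain labels must be present and unique across tables")
  if (is.null(genes))
    genes <- sort(unique(unlist(lapply(tables, function(t) t$gene_id))))
  const <- lapply(tables, strain_constants)
  m <- matrix(0, nrow = length(tables), ncol = length(genes),
              dimnames = list(strains, genes))
  for (i in seq_along(tables)) {
    t <- tables[[i]]
    keep <- t$gene_id %in% genes
    t <- t[keep, , drop = FALSE]
    if (nrow(t))
      m[i, t$gene_id] <- gene_score(t$n_high, t$n_mod, t$n_low, const[[i]])
  }
  attr(m, "constants") <- data.frame(
    strain = strains,
    c_low = vapply(const, `[[`, 0, "c_low"),
    c_mod = vapply(const, `[[`, 0, "c_mod"),
    c_high = vapply(const, `[[`, 0, "c_high"),
    max_low = vapply(const, `[[`, 0, "max_low"),
    max_mod = vapply(const, `[[`, 0, "max_mod"),
    stringsAsFactors = FALSE)
  class(m) <- c("score_matrix", class(m))
  m
}

#' Score a combined annotated table in one call
#'
#' Convenience wrapper: splits an annotated variant table by strain, tallies
#' impact counts, derives per-strain constants and builds the score matrix.
#'
#' @param annotated annotated variant data.frame covering several strains.
#' @param strains optional character vector fixing strain order (and
#'   including strains with zero variants).
#' @inheritParams build_score_matrix
#' @return a `score_matrix`.
#' @export
score_strains <- function(annotated, strains = NULL, genes = NULL) {
  if (is.null(strains)) strains <- unique(annotated$strain)
  tables <- lapply(strains, function(s) count_impacts(annotated, s))
  build_score_matrix(tables, genes = genes)
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("Gene variant score matrix: ", nrow(x), " strains x ", ncol(x),
      " genes\n", sep = "")
  print(unclass(x)[, seq_len(min(ncol(x), 8)), drop = FALSE], digits = 3)
  if (ncol(x) > 8) cat("... (", ncol(x) - 8, " more genes)\n", sep = "")
  invisible(x)
}

#' Write a score matrix as TSV (strains in rows) plus constants as JSON
#'
#' @param m a `score_matrix`.
#' @param path TSV output path.
#' @param constants_path optional JSON path for the per-strain constants.
#' @export
write_score_matrix <- function(m, path, constants_path = NULL) {
  df <- data.frame(strain = rownames(m), unclass(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(constants_path))
    jsonlite::write_json(attr(m, "constants"), constants_path,
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
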
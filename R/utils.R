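#' @keywords internal
"_PACKAGE"

#' @importFrom stats dist hclust prcomp runif setNames
#' @importFrom utils read.table write.table head
NULL

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# codon -> one-letter amino acid, "*" for stop (standard code)
codon_table <- function() {
  tab <- as.character(Biostrings::GENETIC_CODE)
  names(tab) <- names(Biostrings::GENETIC_CODE)
  tab
}

translate_codon <- function(codon) {
  aa <- codon_table()[codon]
  if (any(is.na(aa))) stop("cannot translate codon(s): ",
                           paste(codon[is.na(aa)], collapse = ", "))
  unname(aa)
}

revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", vapply(x, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""), ""))
}

complement <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop("'", name, "' must be TRUE or FALSE", call. = FALSE)
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x))
    stop("'", name, "' must be a single integer >= ", min, call. = FALSE)
}

check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop("'", name, "' must be a number in [", lo, ", ", hi, "]",
         call. = FALSE)
}

check_range <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2L || any(is.na(x)) || x[1] > x[2] ||
      any(x < 0))
    stop("'", name, "' must be a non-empty numeric range c(min, max)",
         call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
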
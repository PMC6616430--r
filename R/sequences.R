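RNA_BASES <- c("A", "C", "G", "U")

# Split an RNA string into a character vector of single bases.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Validate that `x` is a single uppercase RNA string over A/C/G/U.
check_rna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop("'", what, "' must be a single character string", call. = FALSE)
  bad <- setdiff(unique(seq_chars(x)), RNA_BASES)
  if (length(bad) > 0L)
    stop("'", what, "' contains non-RNA symbols: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(x)
}

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases the input and converts `T` to `U`.  Used on all external
#' sequence input so that the package works internally in RNA space.
#'
#' @param x Character vector of nucleotide sequences.
#' @param warn Emit a warning when any `T` was converted.
#' @return Character vector of uppercase RNA sequences.
#' @export
normalize_rna <- function(x, warn = TRUE) {
  x <- toupper(x)
  if (warn && any(grepl("T", x, fixed = TRUE)))
    warning("DNA alphabet detected: T normalized to U", call. = FALSE)
  gsub("T", "U", x, fixed = TRUE)
}

#' Reverse complement of an RNA sequence
#'
#' Standard antiparallel complement (A-U, G-C) over the RNA alphabet.
#'
#' @param x A single RNA string (uppercase, `A`/`C`/`G`/`U`).
#' @return The reverse-complemented RNA string.
#' @examples
#' revcomp("GCGGCGG") # the two acceptor-stem strands are complements
#' @export
revcomp <- function(x) {
  check_rna(x)
  comp <- chartr("ACGU", "UGCA", x)
  paste(rev(seq_chars(comp)), collapse = "")
}

# Complement of single bases (vectorized, no reversal).
complement_base <- function(b) chartr("ACGU", "UGCA", b)
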
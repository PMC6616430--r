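#' Read a FASTA file of tRNA sequences
#'
#' Wraps [Biostrings::readBStringSet()] with the package conventions:
#' identifiers are the first whitespace-delimited token of each header,
#' duplicates are an error, and DNA-alphabet input is normalized to RNA
#' (`T` to `U`) with a warning.
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase RNA sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    stop("malformed FASTA header at line ", nonblank[1], ": expected '>'",
         call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate record identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- normalize_rna(as.character(set))
  for (i in seq_along(seqs)) check_rna(seqs[[i]], ids[i])
  setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param records Named character vector of RNA sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path) {
  if (is.null(names(records)) || any(!nzchar(names(records))))
    stop("all records must be named", call. = FALSE)
  set <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a directed aaRS score matrix from CSV
#'
#' The CSV dialect of fold-recognition score tables: a header row of
#' target names, one row per query, integer scores, `ND` (not
#' detected) for missing comparisons and `NR` (not reported) on the
#' diagonal.
#'
#' @param path CSV path.
#' @return A `score_matrix` object: list with `enzymes` (ordered
#'   names), `scores` (numeric matrix, `NA` where not detected or not
#'   reported) and `tokens` (character matrix preserving `ND`/`NR`).
#' @export
read_matrix_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (ncol(raw) < 2L) stop("score matrix CSV needs a name column plus targets",
                           call. = FALSE)
  queries <- raw[[1]]
  targets <- colnames(raw)[-1]
  if (anyDuplicated(queries) || anyDuplicated(targets))
    stop("duplicate enzyme name in score matrix: ",
         paste(unique(c(queries[duplicated(queries)],
                        targets[duplicated(targets)])), collapse = ", "),
         call. = FALSE)
  if (length(queries) != length(targets) || !setequal(queries, targets))
    stop("score matrix is not square: ", length(queries), " queries vs ",
         length(targets), " targets", call. = FALSE)
  tokens <- as.matrix(raw[, -1, drop = FALSE])
  rownames(tokens) <- queries
  tokens <- tokens[, queries, drop = FALSE]  # align column order to rows

  scores <- matrix(NA_real_, nrow(tokens), ncol(tokens),
                   dimnames = dimnames(tokens))
  for (i in seq_len(nrow(tokens))) for (j in seq_len(ncol(tokens))) {
    tok <- trimws(tokens[i, j])
    tokens[i, j] <- tok
    if (tok == "NR") {
      if (i != j)
        stop("NR outside the diagonal at (", queries[i], ", ", queries[j],
             ")", call. = FALSE)
    } else if (tok == "ND") {
      # missing: stays NA
    } else if (grepl("^[0-9]+$", tok)) {
      val <- as.numeric(tok)
      if (val <= 0)
        stop("scores must be positive integers at (", queries[i], ", ",
             queries[j], ")", call. = FALSE)
      scores[i, j] <- val
    } else {
      stop("unknown token '", tok, "' at (", queries[i], ", ", queries[j],
           ")", call. = FALSE)
    }
  }
  if (!all(tokens[cbind(seq_along(queries), seq_along(queries))] == "NR"))
    stop("diagonal entries must be NR", call. = FALSE)
  structure(list(enzymes = queries, scores = scores, tokens = tokens),
            class = "score_matrix")
}

#' Write a score matrix to CSV
#'
#' Lossless counterpart of [read_matrix_csv()]: `ND` and `NR` tokens
#' are preserved, not coerced to zero.
#'
#' @param matrix A `score_matrix`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_matrix_csv <- function(matrix, path) {
  stopifnot(inherits(matrix, "score_matrix"))
  df <- data.frame(query = matrix$enzymes, matrix$tokens,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("Directed aaRS score matrix: ", length(x$enzymes), " enzymes, ",
      sum(!is.na(x$scores)), " scored pairs\n", sep = "")
  print(x$tokens, quote = FALSE)
  invisible(x)
}
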
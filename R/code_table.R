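# Standard genetic code in RNA codons (STOP spelled "STOP").
STANDARD_CODE <- c(
  UUU = "Phe", UUC = "Phe", UUA = "Leu", UUG = "Leu",
  CUU = "Leu", CUC = "Leu", CUA = "Leu", CUG = "Leu",
  AUU = "Ile", AUC = "Ile", AUA = "Ile", AUG = "Met",
  GUU = "Val", GUC = "Val", GUA = "Val", GUG = "Val",
  UCU = "Ser", UCC = "Ser", UCA = "Ser", UCG = "Ser",
  CCU = "Pro", CCC = "Pro", CCA = "Pro", CCG = "Pro",
  ACU = "Thr", ACC = "Thr", ACA = "Thr", ACG = "Thr",
  GCU = "Ala", GCC = "Ala", GCA = "Ala", GCG = "Ala",
  UAU = "Tyr", UAC = "Tyr", UAA = "STOP", UAG = "STOP",
  CAU = "His", CAC = "His", CAA = "Gln", CAG = "Gln",
  AAU = "Asn", AAC = "Asn", AAA = "Lys", AAG = "Lys",
  GAU = "Asp", GAC = "Asp", GAA = "Glu", GAG = "Glu",
  UGU = "Cys", UGC = "Cys", UGA = "STOP", UGG = "Trp",
  CGU = "Arg", CGC = "Arg", CGA = "Arg", CGG = "Arg",
  AGU = "Ser", AGC = "Ser", AGA = "Arg", AGG = "Arg",
  GGU = "Gly", GGC = "Gly", GGA = "Gly", GGG = "Gly")

# Row/column numbering: 1 = A, 2 = G, 3 = U, 4 = C, read at anticodon
# position 2 (columns) and position 3 (rows).
CODE_AXIS <- c(A = 1L, G = 2L, U = 3L, C = 4L)

#' Anticodon of a codon
#'
#' The antiparallel reverse complement, written 5' to 3' as (wobble,
#' position 2, position 3): the wobble base pairs the codon 3rd
#' position, position 2 the codon 2nd, position 3 the codon 1st.
#'
#' @param codon Character vector of RNA codons.
#' @return Character vector of anticodons (5' to 3').
#' @examples
#' anticodon_for_codon("AUG") # CAU, the Met anticodon
#' @export
anticodon_for_codon <- function(codon) {
  vapply(codon, function(cd) {
    check_rna(cd, "codon")
    if (nchar(cd) != 3L) stop("codon must be 3 nt", call. = FALSE)
    revcomp(cd)
  }, character(1), USE.NAMES = length(codon) > 1L)
}

#' Codon third-position bases read by an anticodon wobble base
#'
#' At the base of code evolution only purine/pyrimidine resolution is
#' achieved at the wobble position: wobble G reads codon-3rd
#' pyrimidines (U and C); wobble C and U together read codon-3rd
#' purines (C reads G; U reads A and G).  Wobble A is essentially
#' unused in archaeal and bacterial tRNAs and returns an empty set
#' with a warning.
#'
#' @param wobble_base Single base, one of `A`, `C`, `G`, `U`.
#' @return Character vector of codon 3rd-position bases (possibly
#'   empty).
#' @export
wobble_reads <- function(wobble_base) {
  if (!wobble_base %in% RNA_BASES)
    stop("invalid wobble base: ", wobble_base, call. = FALSE)
  switch(wobble_base,
         G = c("U", "C"),
         C = "G",
         U = c("A", "G"),
         A = {
           warning("anticodon wobble A is disfavored/unused in prokaryotes",
                   call. = FALSE)
           character(0)
         })
}

# Per-codon skeleton: codon, anticodon, cell coordinates.
codon_frame <- function() {
  codons <- names(STANDARD_CODE)
  c1 <- substr(codons, 1L, 1L)
  c2 <- substr(codons, 2L, 2L)
  c3 <- substr(codons, 3L, 3L)
  p2 <- complement_base(c2)       # column base
  p3 <- complement_base(c1)       # row base
  wob <- complement_base(c3)
  half <- ifelse(c3 %in% c("U", "C"), "A", "B")  # wobble G vs wobble C/U
  data.frame(
    codon = codons,
    anticodon = vapply(codons, revcomp, character(1), USE.NAMES = FALSE),
    wobble = wob, p2 = p2, p3 = p3,
    column = p2, row = p3,
    col_num = unname(CODE_AXIS[p2]), row_num = unname(CODE_AXIS[p3]),
    half = half,
    cell = paste0("c", CODE_AXIS[p2], "r", CODE_AXIS[p3], half),
    stringsAsFactors = FALSE)
}

#' Enumerate the 32 anticodon cells
#'
#' Under wobble purine/pyrimidine collapse the 64 mRNA codons reduce
#' to 32 tRNA "letters": 4 columns (anticodon position 2) x 4 rows
#' (anticodon position 3) x 2 wobble halves (half A = wobble G,
#' reading codon-3rd pyrimidines; half B = wobble C/U, reading
#' codon-3rd purines).  Each cell covers exactly two codons.
#'
#' @return Data frame of 32 rows: `cell`, `column`, `row`, `col_num`,
#'   `row_num`, `half`, `codons` (comma-joined pair).
#' @export
enumerate_cells <- function() {
  cf <- codon_frame()
  cells <- unique(cf[, c("cell", "column", "row", "col_num", "row_num",
                         "half")])
  cells <- cells[order(cells$col_num, cells$row_num, cells$half), ]
  cells$codons <- vapply(cells$cell, function(id)
    paste(cf$codon[cf$cell == id], collapse = ","), character(1))
  rownames(cells) <- NULL
  cells
}

new_code_state <- function(assignments, stage) {
  cf <- codon_frame()
  cf$assignment <- unname(assignments[cf$codon])
  structure(cf, class = c("code_state", "data.frame"), stage = stage)
}

#' The standard genetic code as a code state
#'
#' Loads the standard code per codon and groups it into the 32
#' anticodon cells.  Cells whose two codons carry different meanings
#' (Ile/Met at anticodon position AU(A/G); STOP/Trp at UG(A/G)) are
#' flagged mixed by [cells_of()].
#'
#' @return A `code_state`: a 64-row data frame (one row per codon)
#'   with cell coordinates and an `assignment` column; the stage label
#'   is `"standard"`.
#' @export
standard_code_state <- function() new_code_state(STANDARD_CODE, "standard")

#' Collapse a code state to its 32-cell view
#'
#' @param state A `code_state`.
#' @return Data frame of 32 rows with `cell`, coordinates,
#'   `assignments` (slash-joined distinct meanings) and `mixed` flag.
#' @export
cells_of <- function(state) {
  stopifnot(inherits(state, "code_state"))
  cells <- enumerate_cells()
  per <- lapply(cells$cell, function(id) {
    a <- state$assignment[state$cell == id]
    u <- unique(a)
    data.frame(assignments = paste(u, collapse = "/"),
               mixed = length(u) > 1L, stringsAsFactors = FALSE)
  })
  cbind(cells, do.call(rbind, per))
}

#' Amino acids present in a code state
#'
#' @param state A `code_state`.
#' @param exclude_stop Drop the STOP signal from the count.
#' @return Character vector of distinct assignments.
#' @export
amino_acids <- function(state, exclude_stop = TRUE) {
  aa <- unique(state$assignment)
  if (exclude_stop) aa <- setdiff(aa, "STOP")
  sort(aa)
}

#' @export
print.code_state <- function(x, ...) {
  cat("Code state [", attr(x, "stage"), "]: ",
      length(amino_acids(x)), " amino acids",
      if ("STOP" %in% x$assignment) " + STOP", "\n", sep = "")
  v <- cells_of(x)
  wide <- matrix("", 8L, 4L,
                 dimnames = list(paste0("r", rep(4:1, each = 2),
                                        c("A", "B")),
                                 paste0("c", 1:4, "(", names(CODE_AXIS), ")")))
  for (i in seq_len(nrow(v)))
    wide[paste0("r", v$row_num[i], v$half[i]), v$col_num[i]] <-
      v$assignments[i]
  print(wide, quote = FALSE)
  invisible(x)
}

# Ordinals of the anticodon preference scale C > (U ~ G) > A.
PREFERENCE_ORDINAL <- c(C = 2L, U = 1L, G = 1L, A = 0L)

#' Anticodon preference score
#'
#' The anticodon sequence preference C>(U~G)>A applied to positions 2
#' and 3: each base maps to an ordinal (C = 2, U = G = 1, A = 0) and
#' cells compare lexicographically on (position-2 ordinal, position-3
#' ordinal).
#'
#' @param p2,p3 Bases at anticodon positions 2 and 3, or pass a
#'   3-letter anticodon as `p2` with `p3` missing.
#' @return Integer vector `c(p2 = ..., p3 = ...)`.
#' @examples
#' preference_score("C", "C")  # the Gly cell, the unique maximum
#' @export
preference_score <- function(p2, p3) {
  if (missing(p3)) {
    check_rna(p2, "anticodon")
    if (nchar(p2) != 3L) stop("anticodon must be 3 nt", call. = FALSE)
    p3 <- substr(p2, 3L, 3L)
    p2 <- substr(p2, 2L, 2L)
  }
  if (!p2 %in% RNA_BASES || !p3 %in% RNA_BASES)
    stop("bases must be in A, C, G, U", call. = FALSE)
  c(p2 = PREFERENCE_ORDINAL[[p2]], p3 = PREFERENCE_ORDINAL[[p3]])
}

#' Rank the 32 cells by anticodon preference
#'
#' Stable descending sort on (position-2 ordinal, position-3 ordinal)
#' with explicit tie groups (U and G tie at each position).
#'
#' @param state A `code_state` (used for the current assignments; the
#'   ranking itself depends only on cell coordinates).
#' @return The 32-cell view with `p2_ordinal`, `p3_ordinal` and
#'   `tie_group` (1 = most favored), sorted descending.
#' @export
rank_cells <- function(state = standard_code_state()) {
  v <- cells_of(state)
  v$p2_ordinal <- PREFERENCE_ORDINAL[v$column]
  v$p3_ordinal <- PREFERENCE_ORDINAL[v$row]
  key <- v$p2_ordinal * 10L + v$p3_ordinal
  ord <- order(-key, v$cell)
  v <- v[ord, ]
  v$tie_group <- match(key[ord], sort(unique(key), decreasing = TRUE))
  rownames(v) <- NULL
  v
}

#' Serialize a code state to CSV
#'
#' One row per codon: codon, anticodon, column, row, half, assignment
#' and the mixed-cell flag.
#'
#' @param state A `code_state`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_code_state_csv <- function(state, path) {
  v <- cells_of(state)
  df <- as.data.frame(state)[, c("codon", "anticodon", "column", "row",
                                 "half", "cell", "assignment")]
  df$mixed <- v$mixed[match(df$cell, v$cell)]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
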
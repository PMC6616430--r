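#' Primordial sequence constants
#'
#' The repeat-derived building blocks of the primordial tRNA: the
#' 5' and 3' acceptor-stem strands (truncated GCG / CGC repeats), the
#' D-loop 17-mer (truncated UAGCC repeat), the stem-loop-stem 17-mer
#' shared by the anticodon and T arms, the 14-nt acceptor-stem junction
#' formed at each minihelix ligation seam, and the two 5-mer remnants
#' left by internal 9-nt deletion of that junction.
#'
#' The stem-loop-stem loop is the only weakly determined region; pass
#' `loop17` to explore alternative loop sequences (stems must still be
#' 5-bp inverted repeats).
#'
#' @param loop17 Optional replacement 17-mer for the anticodon/T
#'   stem-loop-stem.
#' @return A list of class `primordial_spec` with components `acc5`,
#'   `acc3`, `dloop17`, `sls17`, `junction14`, `remnant_d`, `remnant_v`,
#'   `acca` and `motifs`.
#' @examples
#' ps <- primordial_spec()
#' ps$junction14  # CCGCCGCGCGGCGG, the 3' + 5' acceptor seam
#' @export
primordial_spec <- function(loop17 = NULL) {
  spec <- list(
    acc5       = "GCGGCGG",
    acc3       = "CCGCCGC",
    dloop17    = "UAGCCUAGCCUAGCCUA",
    sls17      = if (is.null(loop17)) "CCGGGUUAAAAACCCGG" else loop17,
    acca       = "ACCA",
    motifs     = c("GCG", "CGC", "UAGCC")
  )
  check_rna(spec$sls17, "loop17")
  if (nchar(spec$sls17) != 17L)
    stop("stem-loop-stem must be 17 nt", call. = FALSE)
  spec$junction14 <- paste0(spec$acc3, spec$acc5)
  spec$remnant_d  <- substr(spec$junction14, 10L, 14L)  # GGCGG
  spec$remnant_v  <- substr(spec$junction14, 1L, 5L)    # CCGCC
  stopifnot(
    revcomp(spec$acc5) == spec$acc3,
    revcomp(substr(spec$sls17, 1L, 5L)) == substr(spec$sls17, 13L, 17L)
  )
  structure(spec, class = "primordial_spec")
}

segment_row <- function(name, sequence, start, origin) {
  data.frame(name = name, sequence = sequence, start = start,
             end = start + nchar(sequence) - 1L, origin = origin,
             stringsAsFactors = FALSE)
}

#' Build one 31-nt minihelix
#'
#' A minihelix is a 7-nt 5' acceptor strand, a 17-nt internal element,
#' and a 7-nt 3' acceptor strand.  The D-arm minihelix carries the
#' UAGCC-repeat 17-mer; the anticodon and T minihelices carry the
#' (identical) stem-loop-stem 17-mer.
#'
#' @param kind One of `"dloop"`, `"anticodon"`, `"tloop"`.
#' @param spec A [primordial_spec()].
#' @return A segment table (`name`, `sequence`, `start`, `end`,
#'   `origin`) tiling the 31-nt minihelix.
#' @export
build_minihelix <- function(kind = c("dloop", "anticodon", "tloop"),
                            spec = primordial_spec()) {
  kind <- match.arg(kind)
  inner_name <- switch(kind, dloop = "dloop", anticodon = "acloop",
                       tloop = "tloop")
  inner_seq <- if (kind == "dloop") spec$dloop17 else spec$sls17
  origin <- paste0("minihelix_", kind)
  rbind(
    segment_row("acc5", spec$acc5, 1L, origin),
    segment_row(inner_name, inner_seq, 8L, origin),
    segment_row("acc3", spec$acc3, 25L, origin)
  )
}

precursor_segments <- function(spec = primordial_spec()) {
  segs <- rbind(
    segment_row("acc5",    spec$acc5,    1L, "minihelix_dloop"),
    segment_row("dloop",   spec$dloop17, 8L, "minihelix_dloop"),
    segment_row("acc3_j1", spec$acc3,   25L, "minihelix_dloop"),
    segment_row("acc5_j1", spec$acc5,   32L, "minihelix_anticodon"),
    segment_row("acloop",  spec$sls17,  39L, "minihelix_anticodon"),
    segment_row("acc3_j2", spec$acc3,   56L, "minihelix_anticodon"),
    segment_row("acc5_j2", spec$acc5,   63L, "minihelix_tloop"),
    segment_row("tloop",   spec$sls17,  70L, "minihelix_tloop"),
    segment_row("acc3",    spec$acc3,   87L, "minihelix_tloop")
  )
  segs
}

#' Assemble the 93-nt tRNA precursor
#'
#' Ligates the three 31-nt minihelices in the order D-arm, anticodon,
#' T-arm.  Each ligation seam spells the 14-nt acceptor junction
#' (3' acceptor strand followed by 5' acceptor strand).
#'
#' @param spec A [primordial_spec()].
#' @return An object of class `trna_precursor`: a list with `sequence`
#'   (93-nt string) and `segments` (segment table).
#' @export
assemble_precursor <- function(spec = primordial_spec()) {
  segs <- precursor_segments(spec)
  seq <- paste(segs$sequence, collapse = "")
  stopifnot(nchar(seq) == 93L)
  structure(list(sequence = seq, segments = segs, spec = spec),
            class = "trna_precursor")
}

#' Delete 9 nt within an acceptor-junction 14-mer
#'
#' Internal RNA processing of the precursor: exactly nine contiguous
#' nucleotides are removed from within an occurrence of the 14-nt
#' junction `CCGCCGCGCGGCGG`.  With `retain = "three_prime"` the last
#' five bases (`GGCGG`, the D-loop remnant) survive; with
#' `retain = "five_prime"` the first five (`CCGCC`, the V loop) survive.
#' The canonical deletion window is the maximal prefix (respectively
#' suffix) of the 14-mer; any other 9-nt window leaving the same 5-mer
#' yields an identical string.
#'
#' @param sequence RNA string containing the junction.
#' @param junction_ordinal Which junction occurrence to process (1 or
#'   2, counted 5' to 3' on the precursor).  When only one occurrence
#'   remains (the other already processed), either ordinal addresses it.
#' @param retain `"three_prime"` or `"five_prime"`: which end of the
#'   14-mer survives.
#' @param spec A [primordial_spec()] supplying the junction sequence.
#' @return The processed sequence, 9 nt shorter.
#' @export
delete_junction <- function(sequence,
                            junction_ordinal = 1L,
                            retain = c("three_prime", "five_prime"),
                            spec = primordial_spec()) {
  retain <- match.arg(retain)
  check_rna(sequence)
  if (!junction_ordinal %in% c(1L, 2L))
    stop("'junction_ordinal' must be 1 or 2", call. = FALSE)
  j14 <- spec$junction14
  occ <- gregexpr(j14, sequence, fixed = TRUE)[[1]]
  occ <- occ[occ > 0L]
  if (length(occ) == 0L)
    stop("junction ", j14, " not found in sequence", call. = FALSE)
  # One remaining occurrence is unambiguous whichever precursor junction
  # it descends from; two occurrences are indexed 5' to 3'.
  idx <- if (length(occ) == 1L) 1L else junction_ordinal
  if (idx > length(occ))
    stop("junction occurrence ", junction_ordinal, " of ", j14,
         " not found", call. = FALSE)
  at <- occ[idx]
  window <- if (retain == "three_prime") c(at, at + 8L) else c(at + 5L, at + 13L)
  paste0(substr(sequence, 1L, window[1] - 1L),
         substr(sequence, window[2] + 1L, nchar(sequence)))
}

trna_pri_segments <- function(trna_type, spec) {
  shift <- function(segs, names, by) {
    i <- segs$name %in% names
    segs$start[i] <- segs$start[i] - by
    segs$end[i] <- segs$end[i] - by
    segs
  }
  segs <- precursor_segments(spec)
  # Junction 1 processing: acc3_j1 and the first 2 nt of acc5_j1 are
  # deleted; the acc5_j1 remnant (GGCGG) becomes the 3' end of the D
  # loop region.
  segs <- segs[segs$name != "acc3_j1", ]
  i <- segs$name == "acc5_j1"
  segs$sequence[i] <- spec$remnant_d
  segs$start[i] <- 25L
  segs$end[i] <- 29L
  segs <- shift(segs, c("acloop", "acc3_j2", "acc5_j2", "tloop", "acc3"), 9L)
  if (trna_type == "I") {
    # Junction 2 processing: the acc3_j2 remnant (CCGCC) becomes the
    # 5-nt V loop; acc5_j2 and the last 2 nt of acc3_j2 are deleted.
    segs <- segs[segs$name != "acc5_j2", ]
    i <- segs$name == "acc3_j2"
    segs$name[i] <- "vloop"
    segs$sequence[i] <- spec$remnant_v
    segs$end[i] <- segs$start[i] + 4L
    segs <- shift(segs, c("tloop", "acc3"), 9L)
  }
  rownames(segs) <- NULL
  segs
}

#' Build the primordial type I or type II tRNA model
#'
#' Applies the internal-deletion processing to the 93-nt precursor:
#' both junctions for type I (75-nt core, 5-nt V loop), only junction 1
#' for type II (84-nt core, 14-nt expanded V region).  Optionally
#' appends the 3'-ACCA to which the amino acid is attached.
#'
#' @param trna_type `"I"` or `"II"`.
#' @param with_acca Append 3'-ACCA.
#' @param spec A [primordial_spec()].
#' @return An object of class `trna_model`: list with `trna_type`,
#'   `segments` (tiling the full sequence), `core` (sequence without
#'   ACCA), `sequence` (with ACCA when flagged) and `with_acca`.
#' @examples
#' m <- build_trna_pri("I")
#' nchar(m$core)  # 75
#' @export
build_trna_pri <- function(trna_type = c("I", "II"), with_acca = FALSE,
                           spec = primordial_spec()) {
  trna_type <- match.arg(trna_type)
  segs <- trna_pri_segments(trna_type, spec)
  core <- paste(segs$sequence, collapse = "")

  # Cross-check: the segment construction must equal the string-level
  # deletion pipeline applied to the assembled precursor.
  pipe <- delete_junction(assemble_precursor(spec)$sequence, 1L,
                          "three_prime", spec)
  if (trna_type == "I")
    pipe <- delete_junction(pipe, 2L, "five_prime", spec)
  stopifnot(identical(core, pipe))

  sequence <- core
  if (with_acca) {
    segs <- rbind(segs, segment_row("acca", spec$acca,
                                    nchar(core) + 1L, "acca_addition"))
    sequence <- paste0(core, spec$acca)
  }
  structure(list(trna_type = trna_type, segments = segs, core = core,
                 sequence = sequence, with_acca = with_acca, spec = spec),
            class = "trna_model")
}

#' @export
print.trna_model <- function(x, ...) {
  cat("Primordial tRNA model, type ", x$trna_type, " (",
      nchar(x$core), "-nt core",
      if (x$with_acca) " + 3'-ACCA", ")\n", sep = "")
  cat(x$sequence, "\n")
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Validate a tRNA model
#'
#' Checks the structural invariants of a built model: 7-bp acceptor-stem
#' complementarity, 5-bp complementarity of both stem-loop-stem arms,
#' 7-nt loop length in each arm, the type-dependent core length, and
#' exact segment tiling.  Failures are reported, not raised.
#'
#' @param model A `trna_model`.
#' @return A data frame of class `trna_validation` with columns
#'   `check`, `pass`, `detail`.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "trna_model"))
  segs <- model$segments
  get_seg <- function(n) segs$sequence[segs$name == n]
  checks <- list()
  add <- function(check, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, pass = pass, detail = detail, stringsAsFactors = FALSE)
  }

  a5 <- get_seg("acc5"); a3 <- get_seg("acc3")
  mism <- which(seq_chars(a5) != seq_chars(revcomp(a3)))
  add("acceptor_stem_7bp", length(mism) == 0L,
      if (length(mism)) paste("mismatch at stem position",
                              paste(mism, collapse = ",")) else "")

  for (arm in c("acloop", "tloop")) {
    s <- get_seg(arm)
    stem5 <- substr(s, 1L, 5L); stem3 <- substr(s, 13L, 17L)
    mism <- which(seq_chars(stem5) != seq_chars(revcomp(stem3)))
    add(paste0(arm, "_stem_5bp"), length(mism) == 0L,
        if (length(mism)) paste("mismatch at stem position",
                                paste(mism, collapse = ",")) else "")
    add(paste0(arm, "_loop_7nt"), nchar(s) - 10L == 7L,
        paste0("loop length ", nchar(s) - 10L))
  }

  want <- if (model$trna_type == "I") 75L else 84L
  add("core_length", nchar(model$core) == want,
      paste0("observed ", nchar(model$core), ", expected ", want))

  tiled <- paste(segs$sequence, collapse = "")
  contiguous <- all(segs$start[-1] == head(segs$end, -1L) + 1L) &&
    segs$start[1] == 1L &&
    all(segs$end - segs$start + 1L == nchar(segs$sequence))
  add("segment_tiling", identical(tiled, model$sequence) && contiguous, "")

  out <- do.call(rbind, checks)
  class(out) <- c("trna_validation", class(out))
  out
}

#' Write a model to FASTA with a segment-annotation sidecar
#'
#' @param model A `trna_model`.
#' @param fasta_path Output FASTA path (uppercase RNA, one record).
#' @param segments_path Optional path for a tab-separated segment table
#'   (`name`, `start`, `end`, `origin`).
#' @return Invisibly, the record identifier.
#' @export
write_model <- function(model, fasta_path, segments_path = NULL) {
  id <- paste0("tRNA-Pri_type", model$trna_type,
               if (model$with_acca) "_ACCA")
  write_fasta(setNames(model$sequence, id), fasta_path)
  if (!is.null(segments_path))
    utils::write.table(
      model$segments[, c("name", "start", "end", "origin")],
      segments_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(id)
}
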
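# Alignment scoring defaults (exposed on every alignment entry point).
ALN_MATCH <- 1; ALN_MISMATCH <- -1; ALN_GAP_OPEN <- 4; ALN_GAP_EXTEND <- 1

# Pairwise alignment through Biostrings; RNA is mapped to DNA space
# (U -> T) for the substitution matrix and mapped back.
align_pair <- function(query, ref, match = ALN_MATCH, mismatch = ALN_MISMATCH,
                       gap_open = ALN_GAP_OPEN, gap_extend = ALN_GAP_EXTEND) {
  sub <- matrix(mismatch, 4L, 4L,
                dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  diag(sub) <- match
  q <- Biostrings::DNAString(gsub("U", "T", query, fixed = TRUE))
  r <- Biostrings::DNAString(gsub("U", "T", ref, fixed = TRUE))
  aln <- Biostrings::pairwiseAlignment(
    q, r, type = "global", substitutionMatrix = sub,
    gapOpening = gap_open, gapExtension = gap_extend)
  list(query = gsub("T", "U", as.character(Biostrings::pattern(aln)),
                    fixed = TRUE),
       ref = gsub("T", "U", as.character(Biostrings::subject(aln)),
                  fixed = TRUE),
       score = Biostrings::score(aln))
}

#' Assign each position of a tRNA sequence to a model segment
#'
#' Aligns a query tRNA to the core of a primordial model and labels
#' every query position with the segment of the model position it
#' aligns to, or `"insertion"`.  A query of exactly the core length is
#' mapped positionally without alignment.
#'
#' @param trna_seq RNA string; length must lie within
#'   `[core - min_slack, core + max_slack]`.
#' @param model A [build_trna_pri()] model.
#' @param match,mismatch,gap_open,gap_extend Alignment scores (match
#'   `+1`, mismatch `-1`, affine gap `-4`/`-1` by default).
#' @param min_slack,max_slack Allowed query-length deviation below and
#'   above the model core length.  The upper slack defaults to 8 for a
#'   type I model -- small enough that a type II sequence (84 nt, i.e.
#'   core + 9) is rejected as a probable type mismatch -- and 30 for a
#'   type II model, accommodating long expanded V loops.
#' @return Data frame with one row per query position: `position`,
#'   `base`, `model_position` (`NA` for insertions), `model_base`,
#'   `segment`, `identical`.
#' @export
segment_sequence <- function(trna_seq, model,
                             match = ALN_MATCH, mismatch = ALN_MISMATCH,
                             gap_open = ALN_GAP_OPEN,
                             gap_extend = ALN_GAP_EXTEND,
                             min_slack = 10L,
                             max_slack = if (model$trna_type == "I") 8L
                                         else 30L) {
  stopifnot(inherits(model, "trna_model"))
  trna_seq <- normalize_rna(trna_seq, warn = FALSE)
  check_rna(trna_seq, "trna_seq")
  core <- model$core
  n <- nchar(trna_seq); m <- nchar(core)
  if (n < m - min_slack || n > m + max_slack)
    stop("query length ", n, " outside [", m - min_slack, ", ",
         m + max_slack, "] for a type ", model$trna_type,
         " model; check the tRNA type", call. = FALSE)

  seg_at <- character(m)
  for (i in seq_len(nrow(model$segments))) {
    s <- model$segments[i, ]
    if (s$name == "acca") next
    seg_at[s$start:s$end] <- s$name
  }

  if (n == m) {
    qpos <- seq_len(n); mpos <- seq_len(m)
  } else {
    aln <- align_pair(trna_seq, core, match, mismatch, gap_open, gap_extend)
    qg <- seq_chars(aln$query); rg <- seq_chars(aln$ref)
    qpos <- cumsum(qg != "-")
    mpos_all <- cumsum(rg != "-")
    keep <- qg != "-"
    mpos <- ifelse(rg[keep] == "-", NA_integer_, mpos_all[keep])
    qpos <- qpos[keep]
  }
  qb <- seq_chars(trna_seq)[qpos]
  mb <- ifelse(is.na(mpos), NA_character_, seq_chars(core)[mpos])
  data.frame(
    position = qpos, base = qb, model_position = mpos, model_base = mb,
    segment = ifelse(is.na(mpos), "insertion", seg_at[ifelse(is.na(mpos), 1L, mpos)]),
    identical = !is.na(mb) & qb == mb,
    stringsAsFactors = FALSE)
}

#' Identity profile of a tRNA against the primordial model
#'
#' Per-segment and overall fractions of model positions carrying the
#' primordial base.  The overall value is the length-weighted mean of
#' the per-segment identities (weights are model segment lengths);
#' model positions deleted in the query count as non-identical and
#' query insertions are excluded.
#'
#' @inheritParams segment_sequence
#' @param ... Passed to [segment_sequence()] (alignment scores,
#'   length slack).
#' @return An object of class `identity_profile`: list with
#'   `per_segment` (named fractions), `overall`, `aligned_length`.
#' @export
identity_to_pri <- function(trna_seq, model, ...) {
  map <- segment_sequence(trna_seq, model, ...)
  segs <- model$segments[model$segments$name != "acca", ]
  seg_len <- setNames(segs$end - segs$start + 1L, segs$name)
  matches <- vapply(names(seg_len), function(nm)
    sum(map$identical[map$segment == nm]), numeric(1))
  per_segment <- matches / seg_len
  overall <- sum(matches) / sum(seg_len)
  stopifnot(abs(overall -
                  sum(per_segment * seg_len) / sum(seg_len)) < 1e-12)
  structure(list(per_segment = per_segment, overall = overall,
                 aligned_length = sum(!is.na(map$model_position))),
            class = "identity_profile")
}

#' @export
print.identity_profile <- function(x, ...) {
  cat(sprintf("Overall identity to model: %.3f (aligned length %d)\n",
              x$overall, x$aligned_length))
  print(round(x$per_segment, 3))
  invisible(x)
}

#' Permutation test of positional identity between two loops
#'
#' Tests the homology claim for two equal-length RNA segments (e.g.,
#' the anticodon and T stem-loop-stems).  The statistic is the
#' fraction of positions with identical bases; the null distribution
#' is the same statistic against uniform position-shuffles of the
#' second sequence, which preserves composition exactly.  The p-value
#' uses the add-one rule `(1 + #(null >= observed)) / (n_perm + 1)`.
#'
#' @param seq_a,seq_b Equal-length RNA strings.
#' @param n_perm Number of permutations (at least 99).
#' @param seed Integer seed; required for reproducibility.
#' @return An object of class `permutation_result`: `statistic`,
#'   `n_perm`, `p_value`, `seed`, `null_mean`, `null_sd`.
#' @export
loop_homology_test <- function(seq_a, seq_b, n_perm = 999L, seed) {
  check_rna(seq_a, "seq_a"); check_rna(seq_b, "seq_b")
  if (nchar(seq_a) != nchar(seq_b))
    stop("sequences must have equal length", call. = FALSE)
  if (n_perm < 99L) stop("n_perm must be at least 99", call. = FALSE)
  a <- seq_chars(seq_a); b <- seq_chars(seq_b)
  statistic <- mean(a == b)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    mean(a == sample(b)), numeric(1)))
  structure(list(statistic = statistic, n_perm = as.integer(n_perm),
                 p_value = (1 + sum(null >= statistic)) / (n_perm + 1),
                 seed = as.integer(seed),
                 null_mean = mean(null), null_sd = stats::sd(null)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Permutation test: statistic %.4f, p = %.4g (%d permutations, seed %d)\n",
    x$statistic, x$p_value, x$n_perm, x$seed))
  cat(sprintf("  null mean %.4f, sd %.4f\n", x$null_mean, x$null_sd))
  invisible(x)
}

#' Best-phase repeat match fraction
#'
#' How repeat-like a sequence is: the maximum over all cyclic phases
#' of the motif of the fraction of positions matching the infinitely
#' tiled motif.  A truncated perfect repeat scores 1.
#'
#' @param seq RNA string.
#' @param motif Repeat unit (length at least 1).
#' @return Fraction in `[0, 1]`.
#' @examples
#' repeat_score("GCGGCGG", "GCG")            # 1: truncated GCG repeat
#' repeat_score("UAGCCUAGCCUAGCCUA", "UAGCC") # 1: truncated UAGCC repeat
#' @export
repeat_score <- function(seq, motif) {
  check_rna(seq, "seq")
  if (!is.character(motif) || nchar(motif) < 1L)
    stop("motif must be a non-empty string", call. = FALSE)
  check_rna(motif, "motif")
  s <- seq_chars(seq); k <- nchar(motif); m <- seq_chars(motif)
  best <- 0
  for (phase in 0:(k - 1L)) {
    tiled <- m[((seq_along(s) - 1L + phase) %% k) + 1L]
    best <- max(best, mean(s == tiled))
  }
  best
}

#' Pairwise distance matrix for a tRNAome
#'
#' Global-alignment identity between every pair of records; distance
#' is `1 - identity` where identity is the fraction of alignment
#' columns (gaps included) with identical bases.  Also reports each
#' record's nearest neighbor, ties broken lexicographically by record
#' identifier.
#'
#' @param records Named character vector of RNA sequences (at least
#'   2, unique names), e.g. from [read_fasta()] or [synth_trnaome()].
#' @param match,mismatch,gap_open,gap_extend Alignment scores.
#' @return List of class `trnaome_distance`: `distance` (symmetric
#'   matrix, zero diagonal) and `nearest` (data frame `record`,
#'   `neighbor`, `distance`).
#' @export
trnaome_distance <- function(records, match = ALN_MATCH,
                             mismatch = ALN_MISMATCH,
                             gap_open = ALN_GAP_OPEN,
                             gap_extend = ALN_GAP_EXTEND) {
  if (length(records) < 2L) stop("need at least 2 records", call. = FALSE)
  ids <- names(records)
  if (is.null(ids) || anyDuplicated(ids))
    stop("records must have unique identifiers", call. = FALSE)
  n <- length(records)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    aln <- align_pair(records[[i]], records[[j]], match, mismatch,
                      gap_open, gap_extend)
    qa <- seq_chars(aln$query); ra <- seq_chars(aln$ref)
    ident <- mean(qa == ra & qa != "-")
    d[i, j] <- d[j, i] <- 1 - ident
  }
  nearest <- do.call(rbind, lapply(seq_len(n), function(i) {
    row <- d[i, -i]
    nb <- names(row)[row == min(row)]
    nb <- sort(nb)[1]
    data.frame(record = ids[i], neighbor = nb, distance = min(row),
               stringsAsFactors = FALSE)
  }))
  structure(list(distance = d, nearest = nearest),
            class = "trnaome_distance")
}

#' Write a tRNAome distance matrix to CSV
#'
#' @param x A `trnaome_distance`.
#' @param path Output CSV path (header row and column of identifiers).
#' @return Invisibly, `path`.
#' @export
write_distance_csv <- function(x, path) {
  stopifnot(inherits(x, "trnaome_distance"))
  utils::write.csv(x$distance, path, row.names = TRUE)
  invisible(path)
}
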
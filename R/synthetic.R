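#' Mutation configuration for synthetic tRNAomes
#'
#' Per-site substitution and indel probabilities with an explicit
#' seed.  Substitutions are uniform over the three alternative bases;
#' indels are single-base, deletion or insertion with equal
#' probability.
#'
#' @param substitution_rate Per-site substitution probability in
#'   `[0, 1)`.
#' @param indel_rate Per-site indel probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return A list of class `mutation_config`.
#' @export
mutation_config <- function(substitution_rate = 0.1, indel_rate = 0,
                            seed) {
  if (substitution_rate < 0 || substitution_rate >= 1 ||
      indel_rate < 0 || indel_rate >= 1)
    stop("rates must lie in [0, 1)", call. = FALSE)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  structure(list(substitution_rate = substitution_rate,
                 indel_rate = indel_rate, seed = as.integer(seed)),
            class = "mutation_config")
}

# Unseeded core, called inside an established RNG stream.
mutate_chars <- function(chars, sub_rate, indel_rate) {
  n <- length(chars)
  hit <- runif(n) < sub_rate
  if (any(hit))
    chars[hit] <- vapply(chars[hit], function(b)
      sample(setdiff(RNA_BASES, b), 1L), character(1))
  if (indel_rate > 0) {
    out <- vector("list", n)
    ind <- runif(n) < indel_rate
    del <- runif(n) < 0.5
    for (i in seq_len(n)) {
      if (!ind[i]) out[[i]] <- chars[i]
      else if (del[i]) out[[i]] <- character(0)
      else out[[i]] <- c(chars[i], sample(RNA_BASES, 1L))
    }
    chars <- unlist(out)
  }
  chars
}

#' Mutate an RNA sequence
#'
#' Seeded, reproducible point-mutation process: every site is
#' substituted with probability `substitution_rate` (uniformly over
#' the three alternative bases) and hit by a single-base indel with
#' probability `indel_rate`.  Identical `(sequence, config)` inputs
#' give byte-identical outputs.
#'
#' @param seq RNA string.
#' @param config A [mutation_config()].
#' @return The mutated RNA string.
#' @export
mutate_sequence <- function(seq, config) {
  stopifnot(inherits(config, "mutation_config"))
  check_rna(seq)
  with_seed(config$seed, paste(
    mutate_chars(seq_chars(seq), config$substitution_rate,
                 config$indel_rate), collapse = ""))
}

# Anticodon loop positions 3-5 within the 17-nt stem-loop-stem
# (5-bp stem + 7-nt loop + 5-bp stem).
ACLOOP_ANTICODON <- 8:10

#' Generate a synthetic tRNAome
#'
#' Emulates the radiation of a tRNAome from the primordial type I
#' tRNA: every record descends from the 75-nt primordial core by
#' seeded per-site mutation, with its anticodon (stem-loop-stem loop
#' positions 3-5) overwritten by an anticodon drawn from a code
#' state.  Anticodons with wobble A are excluded, matching archaeal
#' usage.  Records are assigned amino acids round-robin; records of
#' the same amino acid share a mutated parent (mutated at the full
#' substitution rate) and diverge from it at half that rate, so that
#' at low noise they are mutual nearest neighbors.  Indels are
#' restricted to the D-loop and V-loop segments, where real tRNA
#' length variation occurs, keeping the acceptor and anticodon
#' scaffolds alignable.
#'
#' @param n_records Number of records (at least 1).
#' @param config A [mutation_config()].
#' @param code_state Code state supplying codon assignments
#'   (default [standard_code_state()]).
#' @param amino_acids Optional subset of amino acids to draw from;
#'   default is every non-STOP assignment of `code_state`.  Restricting
#'   the set makes the round-robin allocate several records per amino
#'   acid, i.e. several children per shared parent.
#' @return Named character vector of RNA sequences; identifiers
#'   encode amino acid, anticodon and a serial number
#'   (`Gly-GCC_01`, ...).
#' @export
synth_trnaome <- function(n_records, config,
                          code_state = standard_code_state(),
                          amino_acids = NULL) {
  stopifnot(inherits(config, "mutation_config"), n_records >= 1L)
  model <- build_trna_pri("I")
  segs <- model$segments

  usable <- code_state[code_state$assignment != "STOP" &
                         code_state$wobble != "A", ]
  aas <- sort(unique(usable$assignment))
  if (!is.null(amino_acids)) {
    bad <- setdiff(amino_acids, aas)
    if (length(bad))
      stop("unknown or unusable amino acids: ",
           paste(bad, collapse = ", "), call. = FALSE)
    aas <- sort(amino_acids)
  }

  with_seed(config$seed, {
    aa_of <- rep(aas, length.out = n_records)
    parents <- list()
    out <- character(n_records)
    ids <- character(n_records)
    mutate_segments <- function(sub_rate) {
      pieces <- lapply(seq_len(nrow(segs)), function(i) {
        s <- segs[i, ]
        indel <- if (s$name %in% c("dloop", "vloop")) config$indel_rate else 0
        chars <- mutate_chars(seq_chars(s$sequence), sub_rate, indel)
        list(name = s$name, chars = chars)
      })
      names(pieces) <- segs$name
      pieces
    }
    for (k in seq_len(n_records)) {
      aa <- aa_of[k]
      if (is.null(parents[[aa]]))
        parents[[aa]] <- mutate_segments(config$substitution_rate)
      pieces <- parents[[aa]]
      # child divergence from the shared parent at half rate
      for (nm in names(pieces)) {
        indel <- if (nm %in% c("dloop", "vloop")) config$indel_rate / 2 else 0
        pieces[[nm]]$chars <- mutate_chars(pieces[[nm]]$chars,
                                           config$substitution_rate / 2,
                                           indel)
      }
      codons <- usable$codon[usable$assignment == aa]
      anticodon <- anticodon_for_codon(sample(codons, 1L))
      pieces$acloop$chars[ACLOOP_ANTICODON] <- seq_chars(anticodon)
      out[k] <- paste(unlist(lapply(pieces, `[[`, "chars")), collapse = "")
      ids[k] <- sprintf("%s-%s_%02d", aa, anticodon, k)
    }
    setNames(out, ids)
  })
}

#' Configuration for planted-tree score matrices
#'
#' @param n_nodes Number of enzymes (nodes).
#' @param base_score Score of a tree edge at distance 1 before noise.
#' @param decay Multiplicative decay per tree edge, in `(0, 1)`.
#' @param noise_sd Standard deviation of the Gaussian noise added
#'   independently to each direction.
#' @param seed Integer seed.
#' @param tree Optional user tree as a data frame `from`, `to` of
#'   1-based node indices; random (uniform labelled tree) when `NULL`.
#' @return A list of class `planted_matrix_config`.
#' @export
planted_matrix_config <- function(n_nodes = 13L, base_score = 800,
                                  decay = 0.6, noise_sd = 4, seed,
                                  tree = NULL) {
  if (base_score <= 0) stop("base_score must be positive", call. = FALSE)
  if (decay <= 0 || decay >= 1) stop("decay must be in (0, 1)", call. = FALSE)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (n_nodes < 2L) stop("need at least 2 nodes", call. = FALSE)
  structure(list(n_nodes = as.integer(n_nodes), base_score = base_score,
                 decay = decay, noise_sd = noise_sd,
                 seed = as.integer(seed), tree = tree),
            class = "planted_matrix_config")
}

# Decode a Pruefer sequence into a tree edge list (1-based indices).
pruefer_decode <- function(pruefer, n) {
  degree <- rep(1L, n)
  for (p in pruefer) degree[p] <- degree[p] + 1L
  edges <- matrix(0L, n - 1L, 2L)
  k <- 1L
  for (p in pruefer) {
    leaf <- min(which(degree == 1L))
    edges[k, ] <- c(leaf, p); k <- k + 1L
    degree[leaf] <- degree[leaf] - 1L
    degree[p] <- degree[p] - 1L
  }
  last <- which(degree == 1L)
  edges[k, ] <- last[1:2]
  edges
}

#' Generate a directed score matrix with a planted tree
#'
#' Emulates the structure of fold-recognition score tables: scores
#' between nodes decay geometrically with distance on a (random or
#' supplied) tree, `score(i, j) = base_score * decay^d(i, j) + noise`,
#' with independent Gaussian noise per direction, rounded to integers
#' and floored at 1; the diagonal is `NR`.  The planted tree is
#' returned so that recovery by [max_spanning_tree()] can be scored.
#'
#' @param config A [planted_matrix_config()].
#' @return List with `matrix` (a `score_matrix`), `tree` (data frame
#'   `from`, `to` of node names) and `min_gap` (smallest difference
#'   between expected scores of adjacent distance classes, the scale
#'   against which noise competes).
#' @export
planted_tree_matrix <- function(config) {
  stopifnot(inherits(config, "planted_matrix_config"))
  n <- config$n_nodes
  nodes <- sprintf("N%02d", seq_len(n))
  with_seed(config$seed, {
    edges <- if (is.null(config$tree)) {
      if (n == 2L) matrix(c(1L, 2L), 1L) else
        pruefer_decode(sample.int(n, n - 2L, replace = TRUE), n)
    } else as.matrix(config$tree[, c("from", "to")])

    # all-pairs tree distances by BFS
    adj <- lapply(seq_len(n), function(i)
      c(edges[edges[, 1] == i, 2], edges[edges[, 2] == i, 1]))
    dist <- matrix(NA_integer_, n, n)
    for (s in seq_len(n)) {
      d <- rep(NA_integer_, n); d[s] <- 0L; queue <- s
      while (length(queue)) {
        u <- queue[1]; queue <- queue[-1]
        for (v in adj[[u]]) if (is.na(d[v])) {
          d[v] <- d[u] + 1L; queue <- c(queue, v)
        }
      }
      dist[s, ] <- d
    }

    scores <- matrix(NA_real_, n, n, dimnames = list(nodes, nodes))
    tokens <- matrix("ND", n, n, dimnames = list(nodes, nodes))
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) { tokens[i, j] <- "NR"; next }
      val <- config$base_score * config$decay^dist[i, j] +
        rnorm(1L, 0, config$noise_sd)
      val <- max(1, round(val))
      scores[i, j] <- val
      tokens[i, j] <- as.character(val)
    }

    dists <- sort(unique(dist[upper.tri(dist)]))
    expected <- config$base_score * config$decay^dists
    min_gap <- if (length(expected) > 1L) min(abs(diff(expected))) else
      config$base_score * (1 - config$decay)

    list(matrix = structure(list(enzymes = nodes, scores = scores,
                                 tokens = tokens), class = "score_matrix"),
         tree = data.frame(from = nodes[pmin(edges[, 1], edges[, 2])],
                           to = nodes[pmax(edges[, 1], edges[, 2])],
                           stringsAsFactors = FALSE),
         min_gap = min_gap)
  })
}
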
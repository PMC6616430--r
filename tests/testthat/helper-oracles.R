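# Independent oracles used across the suite.  These deliberately avoid
# the package code paths they are used to check.

# Reverse complement through Biostrings (oracle for revcomp()).
oracle_revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::RNAString(x)))

# Seeded random RNA string.
random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                       replace = TRUE), collapse = "")

# Exhaustive maximum spanning tree weight: enumerate all (n-1)-subsets
# of the edge list and keep the best acyclic spanning one.  Feasible
# for n <= 6 on complete graphs.
brute_force_mst_weight <- function(edges, nodes) {
  n <- length(nodes)
  best <- -Inf
  idx <- utils::combn(nrow(edges), n - 1L)
  for (k in seq_len(ncol(idx))) {
    sub <- edges[idx[, k], ]
    # spanning + acyclic check via union-find
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    ok <- TRUE
    for (r in seq_len(nrow(sub))) {
      a <- find(match(sub$from[r], nodes)); b <- find(match(sub$to[r], nodes))
      if (a == b) { ok <- FALSE; break }
      parent[a] <- b
    }
    if (ok) best <- max(best, sum(sub$weight))
  }
  best
}

# Independent Prim's algorithm for the maximum spanning tree weight on
# a connected weighted graph (edge data frame from/to/weight).
prim_mst_weight <- function(edges, nodes) {
  w <- matrix(-Inf, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    w[edges$from[r], edges$to[r]] <- edges$weight[r]
    w[edges$to[r], edges$from[r]] <- edges$weight[r]
  }
  in_tree <- nodes[1]
  total <- 0
  while (length(in_tree) < length(nodes)) {
    out <- setdiff(nodes, in_tree)
    sub <- w[in_tree, out, drop = FALSE]
    best <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    total <- total + max(sub)
    in_tree <- c(in_tree, out[best[["col"]]])
  }
  total
}

# The primordial building blocks, restated independently of
# primordial_spec() so model tests do not consume what they check.
ORACLE <- list(
  acc5 = "GCGGCGG", acc3 = "CCGCCGC",
  dloop17 = "UAGCCUAGCCUAGCCUA", sls17 = "CCGGGUUAAAAACCCGG",
  junction14 = "CCGCCGCGCGGCGG")
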
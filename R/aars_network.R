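#' Load a directed aaRS score matrix
#'
#' Convenience wrapper around [read_matrix_csv()], optionally dropping
#' enzymes (e.g. excluding LysRS-IIB as a bacterial innovation when
#' reconstructing the archaeal radiation).
#'
#' @param path CSV path; see [read_matrix_csv()] for the dialect.
#' @param exclude Character vector of enzyme names to drop.
#' @return A `score_matrix`.
#' @export
load_matrix <- function(path, exclude = NULL) {
  m <- read_matrix_csv(path)
  if (length(exclude)) {
    bad <- setdiff(exclude, m$enzymes)
    if (length(bad))
      stop("cannot exclude unknown enzymes: ", paste(bad, collapse = ", "),
           call. = FALSE)
    keep <- setdiff(m$enzymes, exclude)
    m$enzymes <- keep
    m$scores <- m$scores[keep, keep, drop = FALSE]
    m$tokens <- m$tokens[keep, keep, drop = FALSE]
  }
  m
}

#' Paths to the packaged aaRS score fixtures
#'
#' Directed fold-recognition homology scores among the class I (11
#' enzymes) and class II (13 enzymes) aminoacyl-tRNA synthetases,
#' transcribed from the printed tables (row = query, column = target,
#' `ND` = not detected, `NR` = not reported on the diagonal).
#'
#' @param class `"I"` or `"II"`.
#' @return File path of the fixture CSV.
#' @export
aars_fixture <- function(class = c("II", "I")) {
  class <- match.arg(class)
  system.file("extdata",
              if (class == "II") "class2_scores.csv" else "class1_scores.csv",
              package = "trnacode", mustWork = TRUE)
}

#' Symmetrize a directed score matrix into a homology network
#'
#' Comparisons were run in both directions; the undirected connection
#' strength is the maximum (default; the better direction is reported
#' as the homology) or the mean of the available directions.  A pair
#' with no score in either direction has no edge -- "not detected" is
#' absence of evidence, not a zero score.
#'
#' @param matrix A `score_matrix`.
#' @param method `"max"` or `"mean"`.
#' @return An object of class `aars_network`: list with `nodes` and
#'   `edges` (data frame `from`, `to`, `weight`, `from < to`
#'   lexicographically) plus the symmetrization tag.
#' @export
symmetrize <- function(matrix, method = c("max", "mean")) {
  stopifnot(inherits(matrix, "score_matrix"))
  method <- match.arg(method)
  enz <- matrix$enzymes
  edges <- list()
  for (i in seq_along(enz)) for (j in seq_along(enz)) {
    if (i >= j) next
    a <- matrix$scores[i, j]; b <- matrix$scores[j, i]
    if (is.na(a) && is.na(b)) next
    w <- switch(method,
                max = max(a, b, na.rm = TRUE),
                mean = mean(c(a, b), na.rm = TRUE))
    pair <- sort(c(enz[i], enz[j]))
    edges[[length(edges) + 1L]] <- data.frame(
      from = pair[1], to = pair[2], weight = w, stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0), weight = numeric(0))
  edges <- edges[order(edges$from, edges$to), ]
  rownames(edges) <- NULL
  structure(list(nodes = enz, edges = edges, method = method),
            class = "aars_network")
}

#' @export
print.aars_network <- function(x, ...) {
  cat("aaRS homology network (", x$method, " symmetrization): ",
      length(x$nodes), " nodes, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Maximum-score spanning tree of a homology network
#'
#' Kruskal's algorithm on edges sorted by decreasing weight, ties
#' broken lexicographically on the node pair, so equal-weight
#' alternatives resolve identically across runs.  When the network is
#' disconnected, a maximum spanning forest is returned (one tree per
#' component).  An optional root orients parent pointers; rooting is a
#' presentation choice, not an inference.
#'
#' @param network An `aars_network`.
#' @param root Optional root node name (defaults to the
#'   lexicographically first node of the largest component).
#' @return Object of class `spanning_tree`: `edges` (data frame
#'   `from`, `to`, `weight`), `root`, `parent` (named vector, `NA`
#'   for roots of components and for isolated nodes).
#' @export
max_spanning_tree <- function(network, root = NULL) {
  stopifnot(inherits(network, "aars_network"))
  if (length(network$nodes) == 0L || nrow(network$edges) == 0L)
    stop("empty network", call. = FALSE)
  edges <- network$edges[order(-network$edges$weight, network$edges$from,
                               network$edges$to), ]
  comp <- setNames(seq_along(network$nodes), network$nodes)
  find <- function(x) { while (comp[[x]] != match(x, names(comp))) {
    x <- names(comp)[comp[[x]]] }; x }
  picked <- logical(nrow(edges))
  for (k in seq_len(nrow(edges))) {
    ra <- find(edges$from[k]); rb <- find(edges$to[k])
    if (ra != rb) {
      comp[[ra]] <- match(rb, names(comp))
      picked[k] <- TRUE
    }
  }
  tree_edges <- edges[picked, ]
  rownames(tree_edges) <- NULL

  adj <- lapply(setNames(nm = network$nodes), function(n)
    c(tree_edges$to[tree_edges$from == n],
      tree_edges$from[tree_edges$to == n]))
  if (is.null(root)) {
    root <- sort(network$nodes)[1]
  } else if (!root %in% network$nodes)
    stop("unknown root: ", root, call. = FALSE)
  parent <- setNames(rep(NA_character_, length(network$nodes)),
                     network$nodes)
  visited <- setNames(logical(length(network$nodes)), network$nodes)
  queue <- root; visited[root] <- TRUE
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (v in adj[[u]]) if (!visited[v]) {
      visited[v] <- TRUE; parent[v] <- u; queue <- c(queue, v)
    }
  }
  # Components not reachable from the root keep their own BFS roots.
  for (n in sort(network$nodes)) if (!visited[n]) {
    queue <- n; visited[n] <- TRUE
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in adj[[u]]) if (!visited[v]) {
        visited[v] <- TRUE; parent[v] <- u; queue <- c(queue, v)
      }
    }
  }
  structure(list(edges = tree_edges, root = root, parent = parent),
            class = "spanning_tree")
}

#' @export
print.spanning_tree <- function(x, ...) {
  cat("Maximum-score spanning tree rooted at ", x$root, " (",
      nrow(x$edges), " edges, total weight ", sum(x$edges$weight), ")\n",
      sep = "")
  print(x$edges, row.names = FALSE)
  invisible(x)
}

#' Best-hit digraph of a directed score matrix
#'
#' For each query enzyme with at least one score, its single highest
#' scoring target (ties broken lexicographically).
#'
#' @param matrix A `score_matrix`.
#' @return Data frame `query`, `target`, `score` (possibly empty).
#' @export
best_hit_digraph <- function(matrix) {
  stopifnot(inherits(matrix, "score_matrix"))
  rows <- lapply(matrix$enzymes, function(q) {
    sc <- matrix$scores[q, ]
    sc <- sc[!is.na(sc)]
    if (length(sc) == 0L) return(NULL)
    best <- sc[sc == max(sc)]
    tgt <- sort(names(best))[1]
    data.frame(query = q, target = tgt, score = unname(best[tgt]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(query = character(0), target = character(0),
                      score = numeric(0))
  out
}

#' Genetic-code column membership of aaRS enzymes
#'
#' The column clades described for the archaeal radiations: class I
#' clusters in column 1 (Val/Ile/Leu/Met-RS), column 3 wobble-C/U
#' (Glu/Gln-RS-IB, LysRS-IE) and column 4 (Cys/Arg-RS); class II in
#' column 2 (Pro/Thr/Ser-RS-IIA) and column 3 (Asp/Asn-RS-IIB,
#' HisRS-IIA).
#'
#' @param class `"I"` or `"II"`.
#' @return Named character vector: names are enzymes, values column
#'   labels.
#' @export
aars_column_map <- function(class = c("I", "II")) {
  class <- match.arg(class)
  if (class == "I")
    c("ValRS-IA" = "col1", "IleRS-IA" = "col1", "LeuRS-IA" = "col1",
      "MetRS-IA" = "col1",
      "GluRS-IB" = "col3", "GlnRS-IB" = "col3", "LysRS-IE" = "col3",
      "CysRS-IB" = "col4", "ArgRS-ID" = "col4")
  else
    c("ProRS-IIA" = "col2", "ThrRS-IIA" = "col2", "SerRS-IIA" = "col2",
      "AspRS-IIB" = "col3", "AsnRS-IIB" = "col3", "HisRS-IIA" = "col3")
}

#' Permutation test of genetic-code column coherence
#'
#' Tests whether homology scores are higher among enzymes that share a
#' genetic-code column.  The statistic is the mean symmetrized score
#' over same-column pairs connected by an edge; the null re-computes
#' it under uniform permutations of the column labels across the
#' mapped enzymes, with the add-one p-value.
#'
#' @param network An `aars_network`.
#' @param column_map Named character vector (enzyme -> column label)
#'   covering at least two columns with at least two members each;
#'   see [aars_column_map()].
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return Object of class `coherence_result`: `statistic`, `n_perm`,
#'   `p_value`, `seed`, `null_mean`, `null_sd`.
#' @export
column_coherence <- function(network, column_map, n_perm = 999L, seed) {
  stopifnot(inherits(network, "aars_network"))
  column_map <- column_map[names(column_map) %in% network$nodes]
  sizes <- table(column_map)
  if (length(sizes) < 2L || sum(sizes >= 2L) < 2L)
    stop("column_map must cover >= 2 columns with >= 2 members each",
         call. = FALSE)
  edges <- network$edges
  stat_for <- function(map) {
    same <- !is.na(map[edges$from]) & !is.na(map[edges$to]) &
      map[edges$from] == map[edges$to]
    if (!any(same)) return(NA_real_)
    mean(edges$weight[same])
  }
  observed <- stat_for(column_map)
  if (is.na(observed))
    stop("no same-column pair is connected by an edge", call. = FALSE)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    perm <- setNames(sample(unname(column_map)), names(column_map))
    stat_for(perm)
  }, numeric(1)))
  null[is.na(null)] <- -Inf
  structure(list(statistic = observed, n_perm = as.integer(n_perm),
                 p_value = (1 + sum(null >= observed)) / (n_perm + 1),
                 seed = as.integer(seed),
                 null_mean = mean(null[is.finite(null)]),
                 null_sd = stats::sd(null[is.finite(null)])),
            class = c("coherence_result", "permutation_result"))
}

#' Edge report for a spanning tree
#'
#' Tree edges sorted by ascending weight, so the weakest (least
#' certain) connections of the lineage come first.
#'
#' @param tree A `spanning_tree`.
#' @param matrix Optional `score_matrix` used to attach both directed
#'   scores for each edge.
#' @return Data frame `from`, `to`, `weight` (and `score_from_to`,
#'   `score_to_from` when `matrix` is given), ascending by weight.
#' @export
tree_report <- function(tree, matrix = NULL) {
  stopifnot(inherits(tree, "spanning_tree"))
  rep <- tree$edges[order(tree$edges$weight, tree$edges$from,
                          tree$edges$to), ]
  if (!is.null(matrix)) {
    stopifnot(inherits(matrix, "score_matrix"))
    rep$score_from_to <- matrix$scores[cbind(rep$from, rep$to)]
    rep$score_to_from <- matrix$scores[cbind(rep$to, rep$from)]
  }
  rownames(rep) <- NULL
  rep
}

#' Serialize a spanning tree
#'
#' @param tree A `spanning_tree`.
#' @param path Output path; format chosen by extension: `.csv` writes
#'   the edge list, `.nwk` a parenthesized (Newick-like) text rooted
#'   at `tree$root` with edge weights as branch annotations.
#' @return Invisibly, `path`.
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "spanning_tree"))
  if (grepl("\\.csv$", path)) {
    utils::write.csv(tree$edges, path, row.names = FALSE, quote = FALSE)
  } else {
    kids <- split(names(tree$parent)[!is.na(tree$parent)],
                  tree$parent[!is.na(tree$parent)])
    wt <- function(a, b) {
      e <- tree$edges
      e$weight[(e$from == a & e$to == b) | (e$from == b & e$to == a)][1]
    }
    rec <- function(node) {
      ch <- sort(kids[[node]])
      if (is.null(ch) || length(ch) == 0L) return(node)
      paste0("(", paste(vapply(ch, function(c)
        paste0(rec(c), ":", wt(node, c)), character(1)), collapse = ","),
        ")", node)
    }
    writeLines(paste0(rec(tree$root), ";"), path)
  }
  invisible(path)
}
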
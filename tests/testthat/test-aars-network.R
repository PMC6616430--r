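class2 <- load_matrix(aars_fixture("II"))
class1 <- load_matrix(aars_fixture("I"))

test_that("fixtures load with the printed dimensions and entries", {
  expect_length(class2$enzymes, 13L)
  expect_length(class1$enzymes, 11L)
  expect_equal(class2$scores["AspRS-IIB", "HisRS-IIA"], 156)
  expect_true(is.na(class2$scores["AlaRS-IID", "SerRS-IIA"]))  # ND
  expect_equal(class2$tokens["AlaRS-IID", "SerRS-IIA"], "ND")
  expect_true(all(diag(class2$tokens) == "NR"))
  expect_true(all(is.na(diag(class2$scores))))
})

test_that("matrix CSV loading rejects malformed input with coordinates", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("query,A,B", "A,NR,5", "B,xyz,NR"), tmp)
  expect_error(read_matrix_csv(tmp), "'xyz' at \\(B, A\\)")
  writeLines(c("query,A,B", "A,NR,NR", "B,3,NR"), tmp)
  expect_error(read_matrix_csv(tmp), "NR outside the diagonal")
  writeLines(c("query,A,B,C", "A,NR,1,2", "B,3,NR,4"), tmp)
  expect_error(read_matrix_csv(tmp), "not square")
  writeLines(c("query,A,A", "A,NR,1", "A,3,NR"), tmp)
  expect_error(read_matrix_csv(tmp), "duplicate")
})

test_that("matrix CSV round trip is lossless including ND/NR tokens", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_matrix_csv(class2, tmp)
  expect_identical(readLines(tmp), readLines(aars_fixture("II")))
  back <- read_matrix_csv(tmp)
  expect_identical(back$tokens, class2$tokens)
})

test_that("symmetrization takes the better direction and drops ND pairs", {
  net <- symmetrize(class2)
  w <- function(net, a, b) {
    e <- net$edges
    e$weight[(e$from == a & e$to == b) | (e$from == b & e$to == a)]
  }
  expect_equal(w(net, "HisRS-IIA", "AspRS-IIB"), 156)  # directions 79/156
  expect_equal(w(net, "AspRS-IIB", "AsnRS-IIB"), 807)  # equal directions
  # ND in both directions -> absent edge (e.g. AlaRS-IID vs ThrRS-IIA)
  expect_length(w(net, "AlaRS-IID", "ThrRS-IIA"), 0L)
  # max >= mean edge-wise, same edge set
  net_mean <- symmetrize(class2, "mean")
  expect_equal(nrow(net$edges), nrow(net_mean$edges))
  expect_true(all(net$edges$weight >= net_mean$edges$weight))
})

test_that("best-hit digraph picks row maxima with deterministic ties", {
  bh2 <- best_hit_digraph(class2)
  expect_equal(bh2$target[bh2$query == "AspRS-IIB"], "LysRS-IIB")
  expect_equal(bh2$score[bh2$query == "AspRS-IIB"], 816)
  bh1 <- best_hit_digraph(class1)
  expect_equal(bh1$target[bh1$query == "GlnRS-IB"], "GluRS-IB")
  expect_equal(bh1$score[bh1$query == "GlnRS-IB"], 1538)
  # single-enzyme matrix -> empty digraph
  single <- structure(list(enzymes = "X",
                           scores = matrix(NA_real_, 1, 1,
                                           dimnames = list("X", "X")),
                           tokens = matrix("NR", 1, 1,
                                           dimnames = list("X", "X"))),
                      class = "score_matrix")
  expect_equal(nrow(best_hit_digraph(single)), 0L)
})

test_that("the greedy spanning tree is optimal", {
  # unique-optimum toy instance
  toy <- structure(list(
    nodes = c("A", "B", "C"),
    edges = data.frame(from = c("A", "A", "B"), to = c("B", "C", "C"),
                       weight = c(10, 1, 5)),
    method = "max"), class = "aars_network")
  tr <- max_spanning_tree(toy)
  expect_setequal(paste(tr$edges$from, tr$edges$to),
                  c("A B", "B C"))
  # brute-force enumeration oracle on random complete graphs (n <= 6)
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(4:6, 1)
    nodes <- LETTERS[1:n]
    pairs <- t(combn(nodes, 2))
    edges <- data.frame(from = pairs[, 1], to = pairs[, 2],
                        weight = sample(1:40, nrow(pairs), replace = TRUE),
                        stringsAsFactors = FALSE)
    net <- structure(list(nodes = nodes, edges = edges, method = "max"),
                     class = "aars_network")
    tr <- max_spanning_tree(net)
    expect_equal(nrow(tr$edges), n - 1L)
    expect_equal(sum(tr$edges$weight), brute_force_mst_weight(edges, nodes))
  }
  # independent Prim's algorithm agrees on both printed fixtures
  for (m in list(class1, class2)) {
    net <- symmetrize(m)
    tr <- max_spanning_tree(net)
    expect_equal(sum(tr$edges$weight),
                 prim_mst_weight(net$edges, net$nodes))
    expect_equal(nrow(tr$edges), length(net$nodes) - 1L)
  }
  expect_error(max_spanning_tree(structure(
    list(nodes = character(0),
         edges = data.frame(from = character(0), to = character(0),
                            weight = numeric(0)), method = "max"),
    class = "aars_network")), "empty")
})

test_that("equal-weight alternatives resolve identically across runs", {
  nodes <- c("A", "B", "C", "D")
  pairs <- t(combn(nodes, 2))
  edges <- data.frame(from = pairs[, 1], to = pairs[, 2], weight = 7,
                      stringsAsFactors = FALSE)
  net <- structure(list(nodes = nodes, edges = edges, method = "max"),
                   class = "aars_network")
  t1 <- max_spanning_tree(net)
  # shuffled edge order must give the same tree
  net2 <- net
  net2$edges <- net2$edges[c(4, 2, 6, 1, 3, 5), ]
  t2 <- max_spanning_tree(net2)
  expect_identical(t1$edges, t2$edges)
})

test_that("rooting orients parents without changing the edge set", {
  net <- symmetrize(class2)
  tr <- max_spanning_tree(net, root = "GlyRS-IIA")
  expect_equal(tr$root, "GlyRS-IIA")
  expect_true(is.na(tr$parent[["GlyRS-IIA"]]))
  expect_equal(sum(is.na(tr$parent)), 1L)  # connected: single root
  expect_error(max_spanning_tree(net, root = "nope"), "unknown root")
})

test_that("tree report sorts ascending and flags the AlaRS-IID weakness", {
  # archaeal view: LysRS-IIB and GlyRS-IID are bacterial innovations
  m <- load_matrix(aars_fixture("II"),
                   exclude = c("LysRS-IIB", "GlyRS-IID"))
  net <- symmetrize(m)
  tr <- max_spanning_tree(net, root = "GlyRS-IIA")
  rep <- tree_report(tr, m)
  expect_equal(nrow(rep), length(net$nodes) - 1L)
  expect_false(is.unsorted(rep$weight))
  expect_true("AlaRS-IID" %in% c(rep$from[1], rep$to[1]))
  expect_lte(rep$weight[1], 40)
  # weights agree with the symmetrized network
  for (i in seq_len(nrow(rep))) {
    e <- net$edges
    expect_equal(rep$weight[i],
                 e$weight[(e$from == rep$from[i] & e$to == rep$to[i]) |
                            (e$from == rep$to[i] & e$to == rep$from[i])])
  }
  expect_error(load_matrix(aars_fixture("II"), exclude = "nope"),
               "unknown enzymes")
})

test_that("column coherence exceeds its permutation null on class I", {
  net <- symmetrize(class1)
  res <- column_coherence(net, aars_column_map("I"), n_perm = 499, seed = 2)
  expect_gt(res$statistic, res$null_mean)
  expect_lt(res$p_value, 0.05)
  # permuting labels back to identity reproduces the observed statistic
  edges <- net$edges
  map <- aars_column_map("I")
  same <- map[edges$from] == map[edges$to] &
    !is.na(map[edges$from]) & !is.na(map[edges$to])
  expect_equal(res$statistic, mean(edges$weight[same]))
  # all-equal weights -> no signal, p near 1
  flat <- net
  flat$edges$weight <- 100
  res_flat <- column_coherence(flat, aars_column_map("I"),
                               n_perm = 199, seed = 2)
  expect_gt(res_flat$p_value, 0.9)
  expect_error(column_coherence(net, c("ValRS-IA" = "col1")), "2 columns")
})

test_that("newick serialization contains every node and the root last", {
  tr <- max_spanning_tree(symmetrize(class1), root = "ValRS-IA")
  tmp <- withr::local_tempfile(fileext = ".nwk")
  write_tree(tr, tmp)
  nwk <- readLines(tmp)
  for (n in class1$enzymes) expect_match(nwk, n, fixed = TRUE)
  expect_match(nwk, "ValRS-IA;$")
})
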
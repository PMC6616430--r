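model_I <- build_trna_pri("I")

test_that("segment_sequence maps the core to itself and labels insertions", {
  map <- segment_sequence(model_I$core, model_I)
  expect_equal(map$model_position, seq_len(75))
  expect_true(all(map$identical))
  expect_setequal(unique(map$segment),
                  c("acc5", "dloop", "acc5_j1", "acloop", "vloop",
                    "tloop", "acc3"))
  # one inserted base -> exactly one insertion label, rest mapped
  q <- paste0(substr(model_I$core, 1, 10), "A", substr(model_I$core, 11, 75))
  map2 <- segment_sequence(q, model_I)
  expect_equal(sum(map2$segment == "insertion"), 1L)
  expect_equal(sum(!is.na(map2$model_position)), 75L)
  # a type II query is rejected against a type I model
  expect_error(segment_sequence(build_trna_pri("II")$core, model_I),
               "type")
})

test_that("identity_to_pri matches hand-computed fractions", {
  prof <- identity_to_pri(model_I$core, model_I)
  expect_equal(prof$overall, 1)
  expect_true(all(prof$per_segment == 1))
  expect_equal(prof$aligned_length, 75L)
  # 15 substitutions at fixed positions -> overall (75-15)/75
  set.seed(7)
  chars <- strsplit(model_I$core, "")[[1]]
  pos <- sample(75, 15)
  chars[pos] <- vapply(chars[pos], function(b)
    sample(setdiff(c("A", "C", "G", "U"), b), 1), character(1))
  prof2 <- identity_to_pri(paste(chars, collapse = ""), model_I)
  expect_equal(prof2$overall, 60 / 75)
  # overall is the length-weighted mean of per-segment identities
  segs <- model_I$segments
  w <- setNames(segs$end - segs$start + 1L, segs$name)
  expect_equal(prof2$overall,
               sum(prof2$per_segment * w[names(prof2$per_segment)]) / sum(w))
})

test_that("mean identity of composition-matched 75-mers matches Monte Carlo", {
  # oracle: direct positional comparison over shuffles of the core,
  # computed here without the alignment machinery
  chars <- strsplit(model_I$core, "")[[1]]
  set.seed(11)
  oracle <- mean(vapply(1:10000, function(i) mean(sample(chars) == chars),
                        numeric(1)))
  set.seed(12)
  via_pkg <- mean(vapply(1:200, function(i)
    identity_to_pri(paste(sample(chars), collapse = ""), model_I)$overall,
    numeric(1)))
  # both estimate sum(p_b^2) for the core composition
  p <- table(chars) / length(chars)
  expect_equal(oracle, sum(p^2), tolerance = 0.01)
  expect_equal(via_pkg, oracle, tolerance = 0.02)
})

test_that("loop homology permutation test behaves at the extremes", {
  s <- "CCGGGUUAAAAACCCGG"
  res <- loop_homology_test(s, s, n_perm = 199, seed = 3)
  expect_equal(res$statistic, 1)
  expect_equal(res$p_value, 1 / 200)
  # the two stem-loop-stems of the primordial model are identical
  segs <- model_I$segments
  res2 <- loop_homology_test(segs$sequence[segs$name == "acloop"],
                             segs$sequence[segs$name == "tloop"],
                             n_perm = 199, seed = 3)
  expect_equal(res2$statistic, 1)
  # zero positional matches -> p near 1
  a <- "ACGUACGUACGUACGUA"
  b <- chartr("ACGU", "GUAC", a)  # every position differs
  res3 <- loop_homology_test(a, b, n_perm = 199, seed = 3)
  expect_equal(res3$statistic, 0)
  expect_gt(res3$p_value, 0.9)
  expect_error(loop_homology_test("ACGU", "ACGUA", seed = 1), "equal length")
  expect_error(loop_homology_test(s, s, n_perm = 10, seed = 1), "99")
  # reproducible under a fixed seed
  expect_identical(loop_homology_test(a, b, n_perm = 99, seed = 5),
                   loop_homology_test(a, b, n_perm = 99, seed = 5))
})

test_that("repeat_score matches exhaustive-phase brute force", {
  expect_equal(repeat_score("UAGCCUAGCCUAGCCUA", "UAGCC"), 1)
  expect_equal(repeat_score("GCGGCGG", "GCG"), 1)
  # brute-force oracle: all phases, explicit tiling
  brute <- function(seq, motif) {
    s <- strsplit(seq, "")[[1]]; m <- strsplit(motif, "")[[1]]
    max(vapply(seq_along(m), function(ph) {
      tiled <- rep(c(m[ph:length(m)], if (ph > 1) m[1:(ph - 1)]),
                   length.out = length(s))
      mean(s == tiled)
    }, numeric(1)))
  }
  expect_equal(repeat_score("AAAAAAA", "GCG"), brute("AAAAAAA", "GCG"))
  expect_equal(brute("AAAAAAA", "GCG"), 0)
  set.seed(21)
  for (i in 1:20) {
    s <- random_rna(sample(5:30, 1))
    motif <- random_rna(sample(1:6, 1))
    expect_equal(repeat_score(s, motif), brute(s, motif))
    # invariance to cyclic rotation of the motif
    k <- sample(nchar(motif), 1)
    rot <- paste0(substr(motif, k, nchar(motif)),
                  substr(motif, 1, k - 1))
    expect_equal(repeat_score(s, rot), repeat_score(s, motif))
  }
  expect_error(repeat_score("ACGU", ""), "non-empty")
})

test_that("trnaome_distance is a symmetric zero-diagonal matrix", {
  recs <- c(a = model_I$core, b = model_I$core,
            c = paste0(substr(model_I$core, 1, 70), "AAAAA"))
  d <- trnaome_distance(recs)
  expect_equal(diag(d$distance), c(a = 0, b = 0, c = 0))
  expect_identical(d$distance, t(d$distance))
  expect_equal(d$distance["a", "b"], 0)
  expect_gt(d$distance["a", "c"], 0)
  # lexicographic nearest-neighbor tie-break: b and c tie for nothing,
  # but a's equal-distance neighbors resolve to the lexicographic first
  expect_equal(d$nearest$neighbor[d$nearest$record == "a"], "b")
  expect_error(trnaome_distance(c(a = "ACGU", a = "ACGU")), "unique")
  expect_error(trnaome_distance(c(a = "ACGU")), "at least 2")
})

test_that("same-parent synthetic records are mutual nearest neighbors", {
  cfg <- mutation_config(substitution_rate = 0.05, indel_rate = 0, seed = 9)
  recs <- synth_trnaome(6, cfg, amino_acids = c("Gly", "Leu", "Val"))
  aa <- sub("-.*$", "", names(recs))
  d <- trnaome_distance(recs)
  # verify by exhaustive pairwise identity: for each record, the closest
  # other record shares its amino acid (hence its mutated parent)
  for (i in seq_along(recs)) {
    nb <- d$nearest$neighbor[d$nearest$record == names(recs)[i]]
    expect_equal(aa[match(nb, names(recs))], aa[i])
  }
})

test_that("identity to the model decays monotonically on the rate ladder", {
  rates <- c(0, 0.05, 0.1, 0.2, 0.4)
  means <- vapply(seq_along(rates), function(k) {
    cfg <- mutation_config(substitution_rate = rates[k], indel_rate = 0,
                           seed = 100 + k)
    recs <- synth_trnaome(20, cfg)
    mean(vapply(recs, function(s) identity_to_pri(s, model_I)$overall,
                numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("permutation p-values are super-uniform under the null", {
  set.seed(31)
  p <- vapply(1:500, function(i) {
    a <- random_rna(17)
    b <- paste(sample(strsplit(a, "")[[1]]), collapse = "")
    loop_homology_test(a, b, n_perm = 99, seed = i)$p_value
  }, numeric(1))
  for (alpha in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    emp <- mean(p <= alpha)
    se <- sqrt(alpha * (1 - alpha) / 500)
    expect_lte(emp, alpha + 3 * se)
  }
})
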
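two_cliques_net <- function() {
  a <- letters[1:5]; b <- letters[6:10]
  skull_network(rbind(complete_edges(a), complete_edges(b), c("e", "f")),
                "twocliques")
}

test_that("intersection p-value matches closed forms", {
  expect_equal(intersection_pvalue(letters[1:3], letters[4:6], 10), 1)
  expect_equal(intersection_pvalue(letters[1:5], letters[1:5], 20),
               1 / choose(20, 5))
  expect_error(intersection_pvalue(letters[1:8], letters[1:2], 5),
               class = "skullnet_bad_input")
})

test_that("intersection p-value matches exhaustive enumeration at small N", {
  # all C(8,3) x C(8,4) subset pairs; P(overlap >= 2)
  n <- 8
  a_sets <- combn(n, 3)
  b_sets <- combn(n, 4)
  hits <- 0L
  for (i in seq_len(ncol(a_sets)))
    for (j in seq_len(ncol(b_sets)))
      if (length(intersect(a_sets[, i], b_sets[, j])) >= 2) hits <- hits + 1L
  expected <- hits / (ncol(a_sets) * ncol(b_sets))
  # observed sets with overlap exactly 2
  got <- intersection_pvalue(c("a", "b", "c"), c("a", "b", "e", "f"), n)
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("local module anchored in a clique recovers that clique", {
  net <- two_cliques_net()
  m <- local_module(net, "a", seed = 3)
  expect_true(all(letters[1:5] %in% m))
  expect_false(any(letters[7:10] %in% m))
  # determinism under a fixed seed
  expect_identical(m, local_module(net, "a", seed = 3))
})

test_that("complete graphs yield a single module for any focal bone", {
  net <- skull_network(complete_edges(sprintf("b%d", 1:7)))
  expect_setequal(local_module(net, "b3", seed = 1), net$bones)
  ms <- detect_modules(net, seed = 1)
  expect_equal(ms$n_modules, 1)
  expect_equal(parcellation(ms), 0)
})

test_that("small skulls use the exhaustive partition and allow one module", {
  net <- skull_network(complete_edges(letters[1:5]))
  ms <- detect_modules(net, seed = 9)
  expect_equal(ms$n_modules, 1)
  # two triangles joined by one edge, N=6 > 5 would anneal; N=5 barbell:
  bar <- skull_network(rbind(complete_edges(letters[1:3]),
                             complete_edges(letters[3:5])))
  ms2 <- detect_modules(bar, seed = 1)
  expect_lte(ms2$n_modules, 2)
  expect_true(all(bar$bones %in% unlist(ms2$modules)))
})

test_that("two well-separated cliques are detected as two modules, all seeds", {
  net <- two_cliques_net()
  for (seed in 1:5) {
    ms <- detect_modules(net, seed = seed)
    expect_equal(ms$n_modules, 2)
    expect_setequal(unique(ms$partition), c("M01", "M02"))
  }
})

test_that("module sets cover every bone and partitions assign exactly once", {
  pp <- planted_partition_network(c(6, 6, 6), 0.8, 0.08, seed = 3)
  ms <- detect_modules(pp$network, seed = 11)
  expect_setequal(unlist(ms$modules), pp$network$bones)
  expect_equal(sort(names(ms$partition)), pp$network$bones)
  expect_false(anyNA(ms$partition))
  expect_lte(ms$n_modules, n_bones(pp$network))
})

test_that("detection is deterministic under a fixed master seed", {
  pp <- planted_partition_network(c(7, 7), 0.8, 0.1, seed = 5)
  a <- detect_modules(pp$network, seed = 21)
  b <- detect_modules(pp$network, seed = 21)
  expect_identical(a$modules, b$modules)
  expect_identical(a$partition, b$partition)
})

test_that("completing the graph collapses detection to one module", {
  pp <- planted_partition_network(c(6, 6), 0.9, 0.1, seed = 2)
  full <- skull_network(complete_edges(pp$network$bones))
  expect_equal(detect_modules(full, seed = 3)$n_modules, 1)
})

test_that("disjointify follows majority rule with deterministic ties", {
  net <- skull_network(rbind(
    c("x", "a1"), c("x", "a2"), c("x", "a3"), c("x", "y1"),
    complete_edges(c("a1", "a2", "a3")), c("y1", "y2"), c("y2", "a1")))
  mods <- list(c("a1", "a2", "a3", "x"), c("x", "y1", "y2"))
  part <- disjointify(mods, net)
  # x has 3 links into module 1, 1 into module 2 -> majority
  expect_equal(unname(part[["x"]]), "M01")
  # non-overlapping modules give the identity assignment
  mods2 <- list(c("a1", "a2", "a3"), c("x", "y1", "y2"))
  part2 <- disjointify(mods2, net)
  expect_equal(unname(part2[c("a1", "y1")]), c("M01", "M02"))
  # deterministic across repeated calls
  expect_identical(part, disjointify(mods, net))
  expect_error(disjointify(list(c("a1")), net), class = "skullnet_bad_input")
})

test_that("merge log records significant-overlap merges", {
  pp <- planted_partition_network(c(8, 8), 0.85, 0.05, seed = 4)
  ms <- detect_modules(pp$network, seed = 13)
  if (!is.null(ms$merge_log)) {
    expect_true(all(ms$merge_log$p_adj < ms$params$alpha))
    expect_true(all(ms$merge_log$p_raw <= ms$merge_log$p_adj))
  }
  expect_equal(ms$params$seed, 13)
})
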